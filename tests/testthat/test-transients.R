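test_that("dF/F follows the baseline-normalized formula", {
  # constant trace: identically zero
  x <- CaTraceExperiment(matrix(100, 1, 20), frame_interval_s = 4,
                         stim_time_s = 40)
  expect_true(all(assay(computeDff(x), "dff") == 0))
  # 10 baseline frames at 100, excursion to 250 -> dF/F = 1.5 there
  f <- c(rep(100, 10), rep(100, 9), 250)
  x2 <- computeDff(CaTraceExperiment(matrix(f, 1), frame_interval_s = 4,
                                     stim_time_s = 40))
  expect_equal(assay(x2, "dff")[1, 20], 1.5)
  expect_equal(unname(baselineF0(x2)), 100)
  # randomized matrices match the elementwise oracle
  for (s in 1:20) {
    xr <- make_small_traces(n_cells = 4, n_frames = 12, seed = s)
    expect_equal(unname(assay(computeDff(xr), "dff")),
                 oracle_dff(assay(xr, "F")), tolerance = 1e-9)
  }
})

test_that("dF/F input validation names the offending condition", {
  x <- CaTraceExperiment(matrix(100, 2, 8), frame_interval_s = 4,
                         stim_time_s = 16)
  expect_error(computeDff(x, n_baseline_frames = 10), "baseline")
  Fneg <- matrix(c(rep(0, 20), rep(100, 20)), 2, 20, byrow = TRUE)
  rownames(Fneg) <- c("bad_cell", "ok_cell")
  xneg <- CaTraceExperiment(Fneg, frame_interval_s = 4, stim_time_s = 40)
  expect_error(computeDff(xneg), "bad_cell")
})

test_that("release transform is the sign-flipped dF/F", {
  f <- c(rep(100, 10), 60, rep(100, 5))
  x <- CaTraceExperiment(matrix(f, 1), frame_interval_s = 4, stim_time_s = 36)
  rel <- computeRelease(x)
  expect_equal(assay(rel, "dff")[1, 11], 0.4)
  expect_equal(responseMode(rel), "release")
  for (s in 1:10) {
    xr <- make_small_traces(n_cells = 3, n_frames = 15, seed = s)
    expect_equal(unname(assay(computeRelease(xr), "dff")),
                 oracle_release(assay(xr, "F")), tolerance = 1e-9)
  }
})

test_that("responder rule is at-or-above, post-stimulus only", {
  # peak exactly at threshold counts as responder
  mk <- function(peak, at_frame) {
    f <- rep(100, 40)
    f[at_frame] <- 100 * (1 + peak)
    computeDff(CaTraceExperiment(matrix(f, 1), frame_interval_s = 4,
                                 stim_time_s = 60))
  }
  expect_true(classifyResponders(mk(1.6, 30))$is_responder)
  expect_true(classifyResponders(mk(1.5, 30))$is_responder)
  expect_false(classifyResponders(mk(1.49, 30))$is_responder)
  expect_false(classifyResponders(mk(1.5, 30), comparison = ">")$is_responder)
  # large pre-stimulus excursion never counts
  f <- rep(100, 40)
  f[12] <- 300                 # t = 44 s < stimulus at 60 s
  f[30] <- 240                 # post-stimulus peak dF/F = 1.4
  x <- computeDff(CaTraceExperiment(matrix(f, 1), frame_interval_s = 4,
                                    stim_time_s = 60))
  calls <- classifyResponders(x)
  expect_false(calls$is_responder)
  expect_equal(calls$peak_dff, 1.4, tolerance = 1e-6)
  expect_gte(calls$peak_time_s, 60)
  expect_error(classifyResponders(x, stim_time_s = 1000), "span")
})

test_that("classification is invariant to affine rescaling of fluorescence", {
  x <- simulateTraces(simConfig(n_cells = 40, preset = "eaa-withdrawal",
                                seed = 8))
  calls1 <- classifyResponders(computeDff(x))
  for (k in c(0.25, 3, 1000)) {
    xk <- CaTraceExperiment(k * assay(x, "F"),
                            times_s = traceTimes(x),
                            stim_time_s = stimTime(x))
    callsk <- classifyResponders(computeDff(xk))
    expect_identical(calls1$is_responder, callsk$is_responder)
    expect_equal(calls1$peak_dff, callsk$peak_dff, tolerance = 1e-9)
  }
})

test_that("noise-only recordings classify zero responders", {
  for (noise in c(0.05, 0.1)) {
    p <- conditionPreset("noise-only", responder_prob = 0, noise_sd = noise)
    x <- computeDff(simulateTraces(simConfig(n_cells = 200, preset = p,
                                             seed = round(1000 * noise))))
    expect_equal(percentResponders(classifyResponders(x)), 0)
  }
})

test_that("percent responders is count-over-total times 100", {
  calls <- data.frame(cell_id = paste0("c", 1:50),
                      is_responder = rep(c(TRUE, FALSE), c(21, 29)))
  expect_equal(percentResponders(calls), 42)
  expect_equal(percentResponders(calls[calls$is_responder == FALSE, ]), 0)
  expect_error(percentResponders(calls[0, ]), "empty")
  # grouped percentages match the count-and-divide oracle
  set.seed(13)
  for (rep in 1:20) {
    n <- 30
    calls <- data.frame(cell_id = paste0("c", 1:n),
                        is_responder = runif(n) < 0.4)
    grp <- sample(c("g1", "g2", "g3"), n, replace = TRUE)
    res <- percentResponders(calls, grouping = grp)
    for (g in unique(grp)) {
      expect_equal(res$percent_responders[res$group == g],
                   oracle_percent(calls$is_responder[grp == g]),
                   tolerance = 1e-9)
    }
  }
})

test_that("segment topography reproduces per-prep percentages and SEM", {
  cells <- data.frame(cell_id = paste0("c", 1:4), prep_id = "prep_1",
                      segment = "A3", hemisegment = "L")
  calls <- data.frame(cell_id = cells$cell_id,
                      is_responder = c(TRUE, TRUE, FALSE, FALSE))
  tp <- segmentTopography(calls, cells)
  expect_equal(tp$per_prep$percent_responders, 50)
  expect_equal(tp$across_preps$mean_percent[tp$across_preps$hemisegment == "A3L"], 50)
  # five preps with identical percentages -> SEM 0
  cells5 <- data.frame(cell_id = paste0("c", 1:10),
                       prep_id = rep(paste0("prep_", 1:5), each = 2),
                       segment = "A1", hemisegment = "R")
  calls5 <- data.frame(cell_id = cells5$cell_id,
                       is_responder = rep(c(TRUE, FALSE), 5))
  tp5 <- segmentTopography(calls5, cells5)
  a1r <- tp5$across_preps[tp5$across_preps$hemisegment == "A1R", ]
  expect_equal(a1r$mean_percent, 50)
  expect_equal(a1r$sem_percent, 0)
  expect_error(segmentTopography(
    data.frame(cell_id = "zz", is_responder = TRUE), cells), "zz")
  bad <- cells; bad$segment[1] <- "A9"
  expect_error(segmentTopography(calls, bad), "A9")
})

test_that("segment topography matches an independent group-by oracle", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 60
    cells <- data.frame(cell_id = paste0("c", 1:n),
                        prep_id = sample(paste0("prep_", 1:4), n, TRUE),
                        segment = sample(c("T3", "A1", "A2", "A3", "A4", "A5"), n, TRUE),
                        hemisegment = sample(c("L", "R"), n, TRUE))
    calls <- data.frame(cell_id = cells$cell_id, is_responder = runif(n) < 0.5)
    tp <- segmentTopography(calls, cells)
    for (i in seq_len(nrow(tp$per_prep))) {
      row <- tp$per_prep[i, ]
      sel <- cells$prep_id == row$prep_id &
        paste0(cells$segment, cells$hemisegment) == row$hemisegment
      expect_equal(row$percent_responders,
                   oracle_percent(calls$is_responder[sel]), tolerance = 1e-9)
    }
  }
})

test_that("AUC matches closed forms, the trapezoid oracle, and adds over windows", {
  tm <- seq(0, 600, by = 4)
  # dF/F identically 1 over the recording: AUC over [0,600] = 600
  ones <- CaTraceExperiment(matrix(200, 1, length(tm)), times_s = tm,
                            stim_time_s = 60,
                            dff = matrix(1, 1, length(tm)))
  expect_equal(phaseAUC(ones, c(0, 600))$auc, 600)
  expect_equal(phaseAUC(ones, c(0, 600), method = "rectangular")$auc, 600)
  # linear ramp 0 -> 2 over [60, 300]: closed-form area 240
  ramp <- approx(c(0, 60, 300, 600), c(0, 0, 2, 2), xout = tm)$y
  xr <- CaTraceExperiment(matrix(100, 1, length(tm)), times_s = tm,
                          stim_time_s = 60, dff = matrix(ramp, 1))
  expect_equal(phaseAUC(xr, c(60, 300))$auc, 240, tolerance = 1e-9)
  # zero signal: zero area
  expect_equal(phaseAUC(CaTraceExperiment(matrix(100, 1, length(tm)),
                                          times_s = tm, stim_time_s = 60,
                                          dff = matrix(0, 1, length(tm))),
                        c(60, 600))$auc, 0)
  # randomized traces: trapezoid oracle + additivity at a shared grid point
  for (s in 1:20) {
    x <- computeDff(make_small_traces(n_cells = 3, n_frames = 26, seed = s,
                                      stim_time_s = 20))
    tmx <- traceTimes(x)
    full <- phaseAUC(x, c(tmx[2], tmx[26]))
    left <- phaseAUC(x, c(tmx[2], tmx[14]))
    right <- phaseAUC(x, c(tmx[14], tmx[26]))
    expect_equal(full$auc, left$auc + right$auc, tolerance = 1e-9)
    for (ci in 1:3) {
      sel <- seq(2, 26)
      expect_equal(full$auc[ci],
                   unname(oracle_trapz(tmx[sel], assay(x, "dff")[ci, sel])),
                   tolerance = 1e-9)
    }
  }
  # off-grid boundaries are interpolated, empty windows are errors
  expect_equal(phaseAUC(ones, c(1, 599))$auc, 598)
  expect_error(phaseAUC(ones, c(300, 300)), "empty|malformed")
  expect_error(phaseAUC(ones, c(500, 700)), "span")
})

test_that("AUC respects the requested cell subset", {
  x <- computeDff(simulateTraces(simConfig(n_cells = 10,
                                           preset = "eaa-withdrawal", seed = 19)))
  sub <- rownames(x)[c(2, 5)]
  res <- phaseAUC(x, cells = sub)
  expect_setequal(unique(res$cell_id), sub)
  expect_error(phaseAUC(x, cells = "nope"), "nope")
})

test_that("release-mode AUC of a synthetic decline matches the analytic integral", {
  # noise-free release trace: r(t) = d * (1 - exp(-(t - t0)/tau)) after t0
  d <- 0.4; tau <- 120; t0 <- 60
  tm <- seq(0, 600, by = 4)
  p <- conditionPreset("mock"); p$noise_sd <- 0
  cfg <- simConfig(n_cells = 1, preset = p, seed = 23)
  x <- computeRelease(simulateReleaseTraces(cfg, release_fraction = 1,
                                            drop_magnitude = d,
                                            tau_release_s = tau))
  got <- phaseAUC(x, c(t0, 600))$auc
  # trapezoid of the exact generating curve on the same grid
  r <- ifelse(tm < t0, 0, d * (1 - exp(-(tm - t0) / tau)))
  expect_equal(got, oracle_trapz(tm[tm >= t0], r[tm >= t0]), tolerance = 1e-9)
})

test_that("peak amplitude reports the post-stimulus maximum per cell", {
  f <- rep(100, 40)
  x <- computeDff(CaTraceExperiment(matrix(f, 1), frame_interval_s = 4,
                                    stim_time_s = 60))
  expect_equal(unname(peakAmplitude(x)), 0)
  # single-event synthetic trace: peak equals the event amplitude (no noise)
  p <- conditionPreset("single", responder_prob = 1,
                       init_event_rate = 1 / 240, maint_event_rate = 0,
                       maint_multiplier = 0, amp_log_sd = 0, noise_sd = 0)
  repeat_seed <- 29
  x1 <- simulateTraces(simConfig(n_cells = 30, preset = p, seed = repeat_seed))
  gt <- groundTruth(x1)
  one_ev <- gt$cell_id[gt$n_events == 1]
  expect_gt(length(one_ev), 0)
  pk <- peakAmplitude(computeDff(x1))[one_ev]
  # sampled peak within the frame-resolution loss of the kernel peak (amp = 3)
  expect_true(all(pk <= 3 + 1e-6))
  expect_true(all(pk >= 3 * 0.9))
})
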