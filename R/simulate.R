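# Difference-of-exponentials transient kernel, unit peak, zero before onset.
transientKernel <- function(t, tau_rise, tau_decay) {
  tpk <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  pk <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  k <- (exp(-t / tau_decay) - exp(-t / tau_rise)) / pk
  k[t < 0] <- 0
  k
}

# Assign cell metadata: round-robin preps, hemisegments sampled per probs.
.simCellData <- function(cfg, condition) {
  n <- cfg$n_cells
  hemis <- hemisegmentLevels()
  probs <- cfg$hemisegment_probs
  hs <- if (is.null(probs)) {
    sample(hemis, n, replace = TRUE)
  } else {
    sample(hemis, n, replace = TRUE, prob = probs)
  }
  data.frame(
    cell_id = sprintf("cell_%03d", seq_len(n)),
    prep_id = sprintf("prep_%d", ((seq_len(n) - 1L) %% cfg$n_preps) + 1L),
    segment = substr(hs, 1L, 2L),
    hemisegment = substr(hs, 3L, 3L),
    condition = condition,
    genotype = "simulated",
    stringsAsFactors = FALSE
  )
}

#' Simulate a population calcium-imaging recording
#'
#' Generates a cells-x-frames fluorescence matrix under the generative model:
#' each cell draws a log-normal baseline F0; responder cells (Bernoulli with
#' the preset's `responder_prob`) receive a Poisson event train — rate
#' `init_event_rate` during the initiation phase (first 240 s after the
#' stimulus) and `maint_event_rate * maint_multiplier` during the maintenance
#' phase (stimulus + 240 s to the end) — each event contributing a
#' log-normal amplitude times a unit-peak difference-of-exponentials kernel.
#' Fluorescence is `F0 * (1 + signal) * exp(-bleach_rate * t)` plus Gaussian
#' noise with SD `noise_sd * F0`. No event contributes before the stimulus,
#' so the noise-free signal is exactly zero pre-stimulus.
#'
#' @param config A [simConfig()] object (its seed fixes all randomness;
#'   identical configs reproduce byte-identical datasets).
#'
#' @return A [CaTraceExperiment-class] with assay `"F"`; `groundTruth()`
#'   returns the per-cell responder indicator and event count, and
#'   `metadata(x)$signal` holds the noise-free dF/F signal matrix.
#' @export
#' @examples
#' cfg <- simConfig(n_cells = 5, preset = "eaa-withdrawal", seed = 42)
#' x <- simulateTraces(cfg)
#' groundTruth(x)
simulateTraces <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  p <- config$preset
  set.seed(config$seed, kind = "Mersenne-Twister")
  times <- seq(0, config$duration_s, by = config$frame_interval_s)
  n <- config$n_cells
  stim <- config$stim_time_s
  init_end <- min(stim + 240, config$duration_s)

  F0 <- rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  is_resp <- rbinom(n, 1L, p$responder_prob) == 1L
  signal <- matrix(0, nrow = n, ncol = length(times))
  event_times <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is_resp[i]) next
    n_init <- rpois(1L, p$init_event_rate * (init_end - stim))
    n_maint <- rpois(1L, p$maint_event_rate * p$maint_multiplier *
                           max(0, config$duration_s - init_end))
    ev <- c(runif(n_init, stim, init_end),
            runif(n_maint, init_end, config$duration_s))
    ev <- sort(ev)
    event_times[[i]] <- ev
    if (length(ev)) {
      amps <- rlnorm(length(ev), p$amp_log_mean, p$amp_log_sd)
      K <- outer(times, ev, function(t, t0) {
        transientKernel(t - t0, p$tau_rise_s, p$tau_decay_s)
      })
      signal[i, ] <- as.vector(K %*% amps)
    }
  }
  noise <- matrix(rnorm(n * length(times), 0, 1), nrow = n) * (p$noise_sd * F0)
  Fmat <- F0 * (1 + signal) * exp(-p$bleach_rate * rep(times, each = n)) + noise
  dimnames(Fmat) <- list(sprintf("cell_%03d", seq_len(n)), NULL)
  dimnames(signal) <- dimnames(Fmat)

  cells <- .simCellData(config, condition = p$name)
  truth <- data.frame(cell_id = cells$cell_id,
                      is_responder = is_resp,
                      n_events = vapply(event_times, length, 0L),
                      stringsAsFactors = FALSE)
  CaTraceExperiment(Fmat, times_s = times, stim_time_s = stim,
                    cellData = cells,
                    metadata = list(ground_truth = truth,
                                    signal = signal,
                                    event_times = event_times,
                                    true_F0 = F0,
                                    preset = p,
                                    seed = config$seed))
}

#' Simulate peptide-release recordings
#'
#' Peptide release is reported by loss of fluorescence of a GFP-tagged
#' cargo: releasing cells decline smoothly and monotonically after the
#' stimulus toward `F0 * (1 - drop_magnitude)` (exponential approach with
#' time constant `tau_release_s`), while non-releasing cells fluctuate
#' around baseline. The release transform `(F0 - Ft)/F0` of a releasing
#' cell therefore rises toward `drop_magnitude`.
#'
#' @param config A [simConfig()]; its preset supplies `noise_sd`.
#' @param release_fraction Probability in \[0,1\] that a cell releases.
#' @param drop_magnitude Asymptotic fractional fluorescence loss in \[0,1).
#' @param tau_release_s Time constant (s) of the post-stimulus decline.
#'
#' @return A [CaTraceExperiment-class]; `groundTruth()` has columns
#'   `cell_id`, `is_releasing`.
#' @export
#' @examples
#' cfg <- simConfig(n_cells = 6, preset = "mock", seed = 7)
#' simulateReleaseTraces(cfg, release_fraction = 0.5, drop_magnitude = 0.4)
simulateReleaseTraces <- function(config, release_fraction, drop_magnitude,
                                  tau_release_s = 120) {
  stopifnot(inherits(config, "SimConfig"))
  if (drop_magnitude < 0 || drop_magnitude >= 1) {
    stop("invalid parameter 'drop_magnitude': must lie in [0, 1)")
  }
  if (release_fraction < 0 || release_fraction > 1) {
    stop("invalid parameter 'release_fraction': must lie in [0, 1]")
  }
  p <- config$preset
  set.seed(config$seed, kind = "Mersenne-Twister")
  times <- seq(0, config$duration_s, by = config$frame_interval_s)
  n <- config$n_cells
  stim <- config$stim_time_s

  F0 <- rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  releasing <- rbinom(n, 1L, release_fraction) == 1L
  drop <- outer(releasing * drop_magnitude,
                (1 - exp(-pmax(times - stim, 0) / tau_release_s)))
  drop[, times < stim] <- 0
  noise <- matrix(rnorm(n * length(times), 0, 1), nrow = n) * (p$noise_sd * F0)
  Fmat <- F0 * (1 - drop) + noise
  dimnames(Fmat) <- list(sprintf("cell_%03d", seq_len(n)), NULL)

  cells <- .simCellData(config, condition = "release")
  truth <- data.frame(cell_id = cells$cell_id, is_releasing = releasing,
                      stringsAsFactors = FALSE)
  CaTraceExperiment(Fmat, times_s = times, stim_time_s = stim,
                    cellData = cells,
                    metadata = list(ground_truth = truth,
                                    drop_magnitude = drop_magnitude,
                                    tau_release_s = tau_release_s,
                                    true_F0 = F0,
                                    seed = config$seed))
}
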