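# Independent brute-force oracles, deliberately written as literal
# transcriptions of the definitions rather than reusing package code.

oracle_dff <- function(Fmat, n_baseline = 10) {
  out <- Fmat
  for (i in seq_len(nrow(Fmat))) {
    f0 <- mean(Fmat[i, 1:n_baseline])
    for (j in seq_len(ncol(Fmat))) out[i, j] <- (Fmat[i, j] - f0) / f0
  }
  unname(out)
}

oracle_release <- function(Fmat, n_baseline = 10) {
  out <- Fmat
  for (i in seq_len(nrow(Fmat))) {
    f0 <- mean(Fmat[i, 1:n_baseline])
    for (j in seq_len(ncol(Fmat))) out[i, j] <- (f0 - Fmat[i, j]) / f0
  }
  unname(out)
}

oracle_trapz <- function(t, y) {
  s <- 0
  for (i in seq_len(length(t) - 1)) {
    s <- s + (t[i + 1] - t[i]) * (y[i] + y[i + 1]) / 2
  }
  s
}

oracle_percent <- function(flags) 100 * sum(flags) / length(flags)

oracle_t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = tt, df = na + nb - 2,
       p = 2 * pt(-abs(tt), na + nb - 2))
}

oracle_anova_F <- function(groups) {
  gm <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(unlist(groups)) - length(groups)
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(F = Fv, df_between = dfb, df_within = dfw,
       p = pf(Fv, dfb, dfw, lower.tail = FALSE))
}

# Tukey-Kramer adjusted p: studentized-range tail of the q statistic
oracle_tukey_p <- function(groups, ga, gb) {
  k <- length(groups)
  ns <- lengths(groups)
  dfw <- sum(ns) - k
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / dfw
  q <- abs(mean(groups[[ga]]) - mean(groups[[gb]])) /
    sqrt(mse / 2 * (1 / ns[ga] + 1 / ns[gb]))
  ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
}

oracle_venn <- function(A, B, C) {
  u <- unique(c(A, B, C))
  tab <- sapply(u, function(g) c(g %in% A, g %in% B, g %in% C))
  count <- function(a, b, c) {
    sum(apply(tab, 2, function(m) m[1] == a && m[2] == b && m[3] == c))
  }
  c(abc = count(TRUE, TRUE, TRUE),
    ab = count(TRUE, TRUE, FALSE), ac = count(TRUE, FALSE, TRUE),
    bc = count(FALSE, TRUE, TRUE),
    a = count(TRUE, FALSE, FALSE), b = count(FALSE, TRUE, FALSE),
    c = count(FALSE, FALSE, TRUE))
}

# exact binomial 95 % CI (Clopper-Pearson)
binom_ci95 <- function(x, n) {
  lo <- if (x == 0) 0 else qbeta(0.025, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(0.975, x + 1, n - x)
  c(lo, hi)
}

# share-a-letter predicate for CLD checks
shares_letter <- function(letters_vec, a, b) {
  any(strsplit(letters_vec[[a]], "")[[1]] %in% strsplit(letters_vec[[b]], "")[[1]])
}

make_small_traces <- function(n_cells = 3, n_frames = 20, seed = 1,
                              stim_time_s = 16, dt = 4) {
  set.seed(seed)
  F <- matrix(runif(n_cells * n_frames, 50, 200), nrow = n_cells)
  CaTraceExperiment(F, frame_interval_s = dt, stim_time_s = stim_time_s)
}
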