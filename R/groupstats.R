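#' @importFrom stats t.test aov anova TukeyHSD approx aggregate lm pt
NULL

#' Two-tailed pooled-variance Student t test
#'
#' Classical two-sample Student t with pooled variance and a two-sided p
#' value (Welch's unequal-variance form available via `welch = TRUE`).
#' Degenerate inputs are handled explicitly: zero combined variance with
#' equal means gives t = 0, p = 1; zero variance with unequal means gives
#' p = 0 and is flagged.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's correction instead of pooled variance.
#' @return A list with `statistic`, `df`, `p`, `mean_a`, `mean_b`,
#'   `degenerate`.
#' @export
#' @examples
#' tTestTwoTailed(c(1, 2, 3), c(4, 5, 6))
tTestTwoTailed <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs n >= 2 for a variance-based test")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- mean(a) == mean(b)
    return(list(statistic = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2L,
                p = if (eq) 1 else 0,
                mean_a = mean(a), mean_b = mean(b),
                degenerate = !eq))
  }
  ht <- t.test(a, b, var.equal = !welch, alternative = "two.sided")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b),
       degenerate = FALSE)
}

.asGroupList <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, factor(groups$group, unique(groups$group)))
  }
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a named list (or group/value data.frame) of >= 2 groups")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  lapply(groups, as.numeric)
}

#' One-way ANOVA
#'
#' F = MS_between / MS_within with k-1 and N-k degrees of freedom, fitted
#' through `stats::aov`. All-identical groups (zero within-group variance)
#' return F = 0 with a degenerate flag rather than 0/0.
#'
#' @param groups Named list of numeric vectors, or a `data.frame` with
#'   `group` and `value` columns. Every group needs n >= 2.
#' @return A list with `F`, `df_between`, `df_within`, `p`, `group_means`,
#'   `degenerate`.
#' @export
#' @examples
#' oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(8, 9, 10)))
oneWayAnova <- function(groups) {
  groups <- .asGroupList(groups)
  ns <- lengths(groups)
  if (any(ns < 2L)) {
    stop(sprintf("group(s) with n < 2: %s",
                 paste(names(groups)[ns < 2L], collapse = ", ")))
  }
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), ns),
                                  levels = names(groups)))
  means <- vapply(groups, mean, 0)
  if (all(unlist(lapply(groups, sd)) == 0) && length(unique(means)) == 1L) {
    return(list(F = 0, df_between = length(groups) - 1L,
                df_within = sum(ns) - length(groups), p = 1,
                group_means = means, degenerate = TRUE))
  }
  tab <- anova(aov(value ~ group, data = df))
  list(F = tab$`F value`[1L],
       df_between = tab$Df[1L], df_within = tab$Df[2L],
       p = tab$`Pr(>F)`[1L], group_means = means, degenerate = FALSE)
}

#' Tukey honestly-significant-difference test
#'
#' Post hoc all-pairs comparison after one-way ANOVA, with studentized-range
#' adjusted p values; unequal group sizes are handled by the Tukey–Kramer
#' extension (via `stats::TukeyHSD`).
#'
#' @inheritParams oneWayAnova
#' @param conf_level Confidence level of the reported intervals.
#' @return A `data.frame` with one row per pair: `group_a`, `group_b`,
#'   `diff` (mean b - mean a reversed to a-vs-b order as `TukeyHSD`
#'   reports), `lwr`, `upr`, `p_adj`.
#' @export
#' @examples
#' tukeyHsd(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(18, 19, 20)))
tukeyHsd <- function(groups, conf_level = 0.95) {
  groups <- .asGroupList(groups)
  ns <- lengths(groups)
  if (any(ns < 2L)) {
    stop(sprintf("group(s) with n < 2: %s",
                 paste(names(groups)[ns < 2L], collapse = ", ")))
  }
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), ns),
                                  levels = names(groups)))
  if (all(vapply(groups, sd, 0) == 0)) {
    # no within-group variance: identical means -> p 1, distinct -> p 0
    prs <- utils::combn(names(groups), 2L)
    means <- vapply(groups, mean, 0)
    d <- means[prs[2L, ]] - means[prs[1L, ]]
    return(data.frame(group_a = prs[1L, ], group_b = prs[2L, ],
                      diff = unname(d), lwr = unname(d), upr = unname(d),
                      p_adj = as.numeric(d == 0), stringsAsFactors = FALSE))
  }
  th <- TukeyHSD(aov(value ~ group, data = df), conf.level = conf_level)$group
  prs <- strsplit(rownames(th), "-", fixed = TRUE)
  data.frame(group_a = vapply(prs, `[`, "", 2L),
             group_b = vapply(prs, `[`, "", 1L),
             diff = unname(th[, "diff"]), lwr = unname(th[, "lwr"]),
             upr = unname(th[, "upr"]), p_adj = unname(th[, "p adj"]),
             stringsAsFactors = FALSE)
}

#' Compact letter display
#'
#' Assigns lowercase letters to groups so that two groups share at least
#' one letter exactly when their pairwise adjusted p value is at or above
#' `alpha` — the "bars with the same letter are statistically
#' indistinguishable" annotation of the figures. Uses the insert–absorb
#' algorithm; assignments are deterministic given the input group order
#' (letter count is not guaranteed minimal). Intransitive patterns (A~B,
#' B~C, A!=C) are represented by multi-letter groups.
#'
#' @param pairwise A `data.frame` as returned by [tukeyHsd()] (columns
#'   `group_a`, `group_b`, `p_adj`); must cover all k(k-1)/2 pairs.
#' @param alpha Significance level (default 0.05).
#' @param groups Optional character vector fixing group order; defaults to
#'   order of first appearance.
#' @return Named character vector of letter strings, one per group.
#' @export
#' @examples
#' pw <- tukeyHsd(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(18, 19, 20)))
#' compactLetterDisplay(pw)
compactLetterDisplay <- function(pairwise, alpha = 0.05, groups = NULL) {
  need <- c("group_a", "group_b", "p_adj")
  if (!all(need %in% colnames(pairwise))) {
    stop("pairwise table needs columns group_a, group_b, p_adj")
  }
  if (is.null(groups)) {
    groups <- unique(c(rbind(pairwise$group_a, pairwise$group_b)))
  }
  k <- length(groups)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pmap <- setNames(pairwise$p_adj, key(pairwise$group_a, pairwise$group_b))
  prs <- utils::combn(groups, 2L)
  missing_pairs <- !(key(prs[1L, ], prs[2L, ]) %in% names(pmap))
  if (any(missing_pairs)) {
    stop(sprintf("pairwise table is incomplete; missing pair(s): %s",
                 paste(prs[1L, missing_pairs], prs[2L, missing_pairs],
                       sep = "-", collapse = ", ")))
  }
  distinct <- function(a, b) pmap[[key(a, b)]] < alpha

  # insert-absorb: columns are letter classes (logical membership vectors)
  cols <- list(rep(TRUE, k))
  for (pi in seq_len(ncol(prs))) {
    a <- match(prs[1L, pi], groups); b <- match(prs[2L, pi], groups)
    if (!distinct(groups[a], groups[b])) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[a] && col[b]) {
        ca <- col; ca[b] <- FALSE
        cb <- col; cb[a] <- FALSE
        cols[[ci]] <- ca
        cols[[length(cols) + 1L]] <- cb
      }
    }
    # absorb: drop columns whose membership is a subset of another's
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) {
      for (j in seq_along(cols)) {
        if (i != j && keep[i] && keep[j] &&
            all(cols[[i]] | !cols[[j]]) && !identical(cols[[i]], cols[[j]])) {
          keep[j] <- FALSE
        }
      }
    }
    cols <- cols[keep]
    # among identical columns keep the first
    sig <- vapply(cols, function(cc) paste(as.integer(cc), collapse = ""), "")
    cols <- cols[!duplicated(sig)]
  }
  letters_out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, `[`, TRUE, g))], collapse = "")
  }, "")
  setNames(letters_out, groups)
}

#' One-way ANOVA with Tukey post hoc and letter groups
#'
#' Convenience wrapper running [oneWayAnova()], [tukeyHsd()] and
#' [compactLetterDisplay()] and summarizing each group (n, mean, SEM,
#' letters) the way the figure panels annotate them.
#'
#' @inheritParams oneWayAnova
#' @param alpha Significance level for the letter display.
#' @return A list of class `AnovaTukeyResult` with elements `anova`,
#'   `pairwise`, `letters`, `summary`.
#' @export
anovaTukey <- function(groups, alpha = 0.05) {
  groups <- .asGroupList(groups)
  an <- oneWayAnova(groups)
  pw <- tukeyHsd(groups)
  let <- compactLetterDisplay(pw, alpha = alpha, groups = names(groups))
  summ <- data.frame(
    group = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, 0),
    sem = vapply(groups, function(v) sd(v) / sqrt(length(v)), 0),
    letters = unname(let[names(groups)]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(anova = an, pairwise = pw, letters = let, summary = summ),
            class = "AnovaTukeyResult")
}

#' @export
print.AnovaTukeyResult <- function(x, ...) {
  a <- x$anova
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.4f, p = %.3g\n",
              a$df_between, a$df_within, a$F, a$p))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Pupariation batch summaries
#'
#' Larvae are transferred to test media in batches (25 animals by default)
#' and scored for pupariation over a 10 day horizon; genotypes are
#' monitored every 12 h for the rate curve. Given per-larva outcomes, this
#' computes per-batch percent pupariation, the across-batch mean and SEM,
#' and the cumulative rate curve on 12 h bins (non-decreasing by
#' construction).
#'
#' @param records A `data.frame` with columns `batch`, `pupariated`
#'   (logical) and optionally `time_h` (hours to pupariation, required for
#'   the rate curve; `NA` for larvae that never pupariated).
#' @param batch_size Nominal batch size; larger observed batches are
#'   flagged, not dropped.
#' @param horizon_d Scoring horizon in days.
#' @param bin_h Rate-curve bin width in hours.
#' @return A list of class `BatchSummary`: `per_batch`, `mean_percent`,
#'   `sem_percent`, `rate_curve` (time_h, percent_pupariated),
#'   `oversized_batches`.
#' @export
summarizeBatches <- function(records, batch_size = 25, horizon_d = 10,
                             bin_h = 12) {
  if (!all(c("batch", "pupariated") %in% colnames(records))) {
    stop("records need columns 'batch' and 'pupariated'")
  }
  n <- tapply(records$pupariated, records$batch, length)
  r <- tapply(records$pupariated, records$batch, sum)
  per_batch <- data.frame(batch = names(n), n = as.integer(n),
                          n_pupariated = as.integer(r),
                          percent = 100 * as.numeric(r) / as.numeric(n),
                          stringsAsFactors = FALSE)
  oversized <- per_batch$batch[per_batch$n > batch_size]
  if (length(oversized)) {
    warning(sprintf("batch(es) larger than %d larvae: %s",
                    batch_size, paste(oversized, collapse = ", ")))
  }
  pct <- per_batch$percent
  rate <- NULL
  if ("time_h" %in% colnames(records)) {
    bins <- seq(0, horizon_d * 24, by = bin_h)
    total <- nrow(records)
    done <- vapply(bins, function(b) {
      sum(records$pupariated & !is.na(records$time_h) & records$time_h <= b)
    }, 0L)
    rate <- data.frame(time_h = bins, percent_pupariated = 100 * done / total)
  }
  structure(list(per_batch = per_batch,
                 mean_percent = mean(pct),
                 sem_percent = if (length(pct) > 1L) sd(pct) / sqrt(length(pct)) else NA_real_,
                 rate_curve = rate,
                 oversized_batches = oversized),
            class = "BatchSummary")
}

#' @export
print.BatchSummary <- function(x, ...) {
  cat(sprintf("BatchSummary: %d batches, mean %.1f%% +/- %.1f%% (SEM)\n",
              nrow(x$per_batch), x$mean_percent, x$sem_percent))
  invisible(x)
}

#' Two-choice preference index
#'
#' `PI = (n_test - n_control) / (n_test + n_control)` for animals scored on
#' the test versus control substrate; +1 is complete preference for the
#' test side, -1 complete avoidance. Animals that left the arena are
#' excluded from both counts before calling this.
#'
#' @param n_test,n_control Non-negative counts; their sum must be >= 1.
#' @return Preference index in \[-1, 1\].
#' @export
#' @examples
#' preferenceIndex(15, 5)  # 0.5
preferenceIndex <- function(n_test, n_control) {
  if (n_test < 0 || n_control < 0) stop("counts must be non-negative")
  if (n_test + n_control < 1) {
    stop("no scored animals: preference index undefined")
  }
  (n_test - n_control) / (n_test + n_control)
}
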