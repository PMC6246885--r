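#' Threshold-based responder classification
#'
#' A cell is classified as a responder when its normalized signal reaches
#' the threshold (dF/F >= 1.5 by default) at any frame at or after the
#' stimulus; pre-stimulus frames are never counted. Because dF/F is
#' scale-free, classification is invariant to affine rescaling of the raw
#' fluorescence.
#'
#' @param x A normalized [CaTraceExperiment-class].
#' @param threshold Classification threshold in dF/F units (> 0).
#' @param comparison `">="` (default, at-or-above) or `">"`.
#' @param stim_time_s Stimulus time; defaults to the object's own.
#'
#' @return A `data.frame` with columns `cell_id`, `is_responder`,
#'   `peak_dff`, `peak_time_s`; the threshold used is kept as attribute
#'   `"threshold"`.
#' @export
#' @examples
#' x <- computeDff(simulateTraces(
#'   simConfig(n_cells = 20, preset = "eaa-withdrawal", seed = 2)))
#' calls <- classifyResponders(x)
#' table(calls$is_responder)
classifyResponders <- function(x, threshold = 1.5, comparison = c(">=", ">"),
                               stim_time_s = stimTime(x)) {
  stopifnot(is(x, "CaTraceExperiment"))
  comparison <- match.arg(comparison)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("'threshold' must be a positive dF/F value")
  }
  if (!"dff" %in% assayNames(x)) {
    stop("no 'dff' assay; run computeDff() or computeRelease() first")
  }
  tm <- traceTimes(x)
  if (stim_time_s < tm[1L] || stim_time_s > tm[length(tm)]) {
    stop("stimulus time lies outside the recorded time span")
  }
  post <- which(tm >= stim_time_s)
  dff <- assay(x, "dff")[, post, drop = FALSE]
  pk_idx <- apply(dff, 1L, which.max)
  peak <- dff[cbind(seq_len(nrow(dff)), pk_idx)]
  hit <- if (comparison == ">=") peak >= threshold else peak > threshold
  out <- data.frame(cell_id = rownames(x),
                    is_responder = hit,
                    peak_dff = peak,
                    peak_time_s = tm[post][pk_idx],
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}

#' Percent responders
#'
#' `(number of responder cells / total number of cells) x 100`, overall or
#' per group.
#'
#' @param calls Output of [classifyResponders()].
#' @param grouping Optional factor/character vector, one entry per call,
#'   to split percentages by (e.g. condition or preparation).
#'
#' @return Ungrouped: a single percentage. Grouped: a `data.frame` with
#'   columns `group`, `n_cells`, `n_responders`, `percent_responders`.
#' @export
#' @examples
#' calls <- data.frame(cell_id = 1:50, is_responder = rep(c(TRUE, FALSE), c(21, 29)))
#' percentResponders(calls)  # 42
percentResponders <- function(calls, grouping = NULL) {
  if (nrow(calls) == 0L) stop("empty call table: percentage undefined (0/0)")
  if (is.null(grouping)) {
    return(100 * sum(calls$is_responder) / nrow(calls))
  }
  if (length(grouping) != nrow(calls)) {
    stop("'grouping' must have one entry per call")
  }
  grouping <- as.character(grouping)
  if (anyNA(grouping)) stop("'grouping' must not contain missing values")
  n <- tapply(calls$is_responder, grouping, length)
  r <- tapply(calls$is_responder, grouping, sum)
  data.frame(group = names(n),
             n_cells = as.integer(n),
             n_responders = as.integer(r),
             percent_responders = 100 * as.numeric(r) / as.numeric(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Segmental topography of responders
#'
#' Maps responder calls onto the T3–A5 hemisegments of the ventral ganglion:
#' per preparation and hemisegment, the number of cells, responders, and
#' percent responders; across preparations, the mean and SEM (sd/sqrt(n
#' preps), n-1 denominator) per hemisegment.
#'
#' @param calls Output of [classifyResponders()].
#' @param cells Cell metadata `data.frame` with columns `cell_id`,
#'   `prep_id`, `segment`, `hemisegment`; every call's cell must resolve.
#'
#' @return A list of class `SegmentSummary`: `per_prep` (prep_id,
#'   hemisegment, n_cells, n_responders, percent_responders) and
#'   `across_preps` (hemisegment, n_preps, mean_percent, sem_percent).
#' @export
segmentTopography <- function(calls, cells) {
  need <- c("cell_id", "prep_id", "segment", "hemisegment")
  miss <- setdiff(need, colnames(cells))
  if (length(miss)) {
    stop(sprintf("cell table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  idx <- match(calls$cell_id, cells$cell_id)
  if (anyNA(idx)) {
    stop(sprintf("cell id(s) missing from the cell table: %s",
                 paste(calls$cell_id[is.na(idx)], collapse = ", ")))
  }
  seg <- as.character(cells$segment[idx])
  side <- as.character(cells$hemisegment[idx])
  badseg <- setdiff(unique(seg), SEGMENT_LEVELS)
  badside <- setdiff(unique(side), HEMISEGMENT_SIDES)
  if (length(badseg) || length(badside)) {
    stop(sprintf("unknown segment/hemisegment label(s): %s",
                 paste(c(badseg, badside), collapse = ", ")))
  }
  hemi <- factor(paste0(seg, side), levels = hemisegmentLevels())
  prep <- as.character(cells$prep_id[idx])

  agg <- aggregate(calls$is_responder,
                   by = list(prep_id = prep, hemisegment = as.character(hemi)),
                   FUN = function(v) c(n = length(v), r = sum(v)))
  per_prep <- data.frame(prep_id = agg$prep_id,
                         hemisegment = agg$hemisegment,
                         n_cells = as.integer(agg$x[, "n"]),
                         n_responders = as.integer(agg$x[, "r"]),
                         stringsAsFactors = FALSE)
  per_prep$percent_responders <- 100 * per_prep$n_responders / per_prep$n_cells
  ord <- order(per_prep$prep_id, match(per_prep$hemisegment, hemisegmentLevels()))
  per_prep <- per_prep[ord, , drop = FALSE]
  rownames(per_prep) <- NULL

  across <- do.call(rbind, lapply(hemisegmentLevels(), function(h) {
    v <- per_prep$percent_responders[per_prep$hemisegment == h]
    data.frame(hemisegment = h, n_preps = length(v),
               mean_percent = if (length(v)) mean(v) else NA_real_,
               sem_percent = if (length(v) > 1L) sd(v) / sqrt(length(v))
                             else if (length(v) == 1L) NA_real_ else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_prep = per_prep, across_preps = across),
            class = "SegmentSummary")
}

#' @export
print.SegmentSummary <- function(x, ...) {
  cat("SegmentSummary over", length(unique(x$per_prep$prep_id)),
      "preparation(s)\n")
  print(x$across_preps, row.names = FALSE)
  invisible(x)
}
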