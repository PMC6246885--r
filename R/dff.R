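.baseline <- function(x, n_baseline_frames) {
  Fmat <- assay(x, "F")
  if (ncol(Fmat) <= n_baseline_frames) {
    stop(sprintf("trace has %d frames; need more than the %d baseline frames",
                 ncol(Fmat), n_baseline_frames))
  }
  F0 <- rowMeans(Fmat[, seq_len(n_baseline_frames), drop = FALSE])
  bad <- which(F0 <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive baseline F0 for cell(s): %s",
                 paste(rownames(Fmat)[bad], collapse = ", ")))
  }
  F0
}

#' Fractional fluorescence change (dF/F)
#'
#' Normalizes each cell's trace as `dF/F = (F_t - F0)/F0`, where `F0` is the
#' mean fluorescence over the first `n_baseline_frames` frames of that cell
#' (10 by default). Negative excursions are kept unclipped.
#'
#' @param x A [CaTraceExperiment-class] with raw assay `"F"`.
#' @param n_baseline_frames Number of leading frames averaged into the
#'   baseline `F0`.
#'
#' @return The object with an added `"dff"` assay, `baselineF0()` set, and
#'   `responseMode` `"response"`.
#' @export
#' @examples
#' x <- simulateTraces(simConfig(n_cells = 4, preset = "mock", seed = 1))
#' x <- computeDff(x)
#' range(assay(x, "dff"))
computeDff <- function(x, n_baseline_frames = 10) {
  stopifnot(is(x, "CaTraceExperiment"))
  F0 <- .baseline(x, n_baseline_frames)
  dff <- sweep(sweep(assay(x, "F"), 1L, F0, "-"), 1L, F0, "/")
  assay(x, "dff", withDimnames = FALSE) <- dff
  rowData(x)$baseline_F0 <- unname(F0)
  x@responseMode <- "response"
  validObject(x)
  x
}

#' Peptide-release transform
#'
#' Quantifies release of a GFP-tagged cargo by fractional fluorescence loss:
#' `(F0 - F_t)/F0` with the same first-frames baseline as [computeDff()].
#' Values increase as fluorescence is lost, so a releasing cell's trace
#' rises toward its asymptotic released fraction.
#'
#' @inheritParams computeDff
#' @return The object with a `"dff"` assay holding release values and
#'   `responseMode` `"release"`.
#' @export
computeRelease <- function(x, n_baseline_frames = 10) {
  x <- computeDff(x, n_baseline_frames)
  assay(x, "dff", withDimnames = FALSE) <- -assay(x, "dff")
  x@responseMode <- "release"
  x
}

#' Per-cell post-stimulus peak response
#'
#' Maximum of the normalized signal over frames at or after the stimulus —
#' the peak change in fluorescence for response mode, the peak fractional
#' loss for release mode.
#'
#' @param x A normalized [CaTraceExperiment-class] (after [computeDff()] or
#'   [computeRelease()]).
#' @param stim_time_s Stimulus time; defaults to the object's own.
#'
#' @return Named numeric vector, one peak per cell.
#' @export
peakAmplitude <- function(x, stim_time_s = stimTime(x)) {
  stopifnot(is(x, "CaTraceExperiment"))
  if (!"dff" %in% assayNames(x)) {
    stop("no 'dff' assay; run computeDff() or computeRelease() first")
  }
  tm <- traceTimes(x)
  if (stim_time_s < tm[1L] || stim_time_s > tm[length(tm)]) {
    stop("stimulus time lies outside the recorded time span")
  }
  post <- tm >= stim_time_s
  apply(assay(x, "dff")[, post, drop = FALSE], 1L, max)
}
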