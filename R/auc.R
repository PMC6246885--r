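#' Default phase windows
#'
#' The full response window runs from the stimulus (60 s by default) to
#' 600 s; the initiation phase covers 60–300 s (sensory-driven onset of the
#' transients) and the maintenance phase 300–600 s (neuropeptide-dependent
#' persistence). Windows are absolute recording times.
#'
#' @param stim_time_s Stimulus time in seconds.
#' @param end_s End of the full window in seconds.
#' @param split_s Boundary between initiation and maintenance phases.
#' @return Named list of `c(start, end)` windows: `full`, `initial`, `late`.
#' @export
#' @examples
#' defaultWindows()
defaultWindows <- function(stim_time_s = 60, end_s = 600, split_s = 300) {
  list(full = c(stim_time_s, end_s),
       initial = c(stim_time_s, split_s),
       late = c(split_s, end_s))
}

# Trapezoidal integral of y(t) over [a, b], linear interpolation at
# off-grid boundaries; rectangular mode is sum(y) * dt over in-window frames.
.windowIntegral <- function(tm, y, a, b, method) {
  if (method == "rectangular") {
    keep <- tm >= a & tm < b
    return(sum(y[keep]) * (tm[2L] - tm[1L]))
  }
  inside <- tm > a & tm < b
  ts <- c(a, tm[inside], b)
  ys <- c(approx(tm, y, xout = a)$y, y[inside], approx(tm, y, xout = b)$y)
  sum(diff(ts) * (ys[-1L] + ys[-length(ys)]) / 2)
}

#' Phase-windowed area under the curve
#'
#' Per-cell time integral of the normalized signal over one or more named
#' windows, in dF/F·s. The default integrates from the stimulus to 600 s
#' (`defaultWindows()` adds the 60–300 s initiation and 300–600 s
#' maintenance phases). Integration is trapezoidal on the frame grid with
#' linear interpolation at off-grid window boundaries; a rectangular
#' (sum x frame interval) mode is available for cross-checking. Negative
#' excursions are included unclipped. When both windows share a grid-point
#' boundary, adjacent-window AUCs add exactly to the enclosing window's.
#'
#' @param x A normalized [CaTraceExperiment-class].
#' @param windows A single `c(start, end)` window or a named list of them;
#'   default [defaultWindows()] anchored at the object's stimulus time.
#' @param cells Optional character vector of cell ids to integrate (e.g.
#'   responders only, the convention for response-mode AUC plots); default
#'   all cells.
#' @param method `"trapezoid"` (default) or `"rectangular"`.
#'
#' @return A `data.frame` with columns `cell_id`, `window`, `start_s`,
#'   `end_s`, `auc`.
#' @export
#' @examples
#' x <- computeDff(simulateTraces(
#'   simConfig(n_cells = 4, preset = "eaa-withdrawal", seed = 5)))
#' head(phaseAUC(x))
phaseAUC <- function(x, windows = defaultWindows(stimTime(x),
                                                 max(traceTimes(x))),
                     cells = NULL, method = c("trapezoid", "rectangular")) {
  stopifnot(is(x, "CaTraceExperiment"))
  method <- match.arg(method)
  if (!"dff" %in% assayNames(x)) {
    stop("no 'dff' assay; run computeDff() or computeRelease() first")
  }
  if (is.numeric(windows) && length(windows) == 2L) {
    windows <- list(window = windows)
  }
  if (is.null(names(windows)) || any(!nzchar(names(windows)))) {
    stop("windows must be named")
  }
  tm <- traceTimes(x)
  dff <- assay(x, "dff")
  if (!is.null(cells)) {
    miss <- setdiff(cells, rownames(dff))
    if (length(miss)) {
      stop(sprintf("unknown cell id(s): %s", paste(miss, collapse = ", ")))
    }
    dff <- dff[cells, , drop = FALSE]
  }
  out <- lapply(names(windows), function(wn) {
    w <- windows[[wn]]
    if (length(w) != 2L || w[2L] <= w[1L]) {
      stop(sprintf("window '%s' is empty or malformed", wn))
    }
    if (w[1L] < tm[1L] || w[2L] > tm[length(tm)]) {
      stop(sprintf("window '%s' [%g, %g) lies outside the recorded span",
                   wn, w[1L], w[2L]))
    }
    data.frame(cell_id = rownames(dff), window = wn,
               start_s = w[1L], end_s = w[2L],
               auc = apply(dff, 1L, function(y) {
                 .windowIntegral(tm, y, w[1L], w[2L], method)
               }),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
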