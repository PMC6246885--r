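#' Read a wide ROI trace table
#'
#' Reads the comma-separated wide table produced by ImageJ-style ROI
#' time-series export: the first column is a frame index or time in
#' seconds, every other column one cell's fluorescence. Any header wording
#' is accepted; the first column is treated as time in seconds when
#' `frame_interval_s` is `NULL`, otherwise as a 0-based frame index
#' converted via the declared interval. Missing or non-numeric values and
#' non-uniform spacing are schema errors naming the offending cell/frame.
#'
#' @param path CSV file path.
#' @param frame_interval_s Declared frame interval in seconds when the
#'   first column is a frame index; `NULL` when it already holds seconds.
#' @param stim_time_s Stimulus time recorded on the returned object.
#' @param cellData Optional per-cell metadata (see [readCellTable()]).
#'
#' @return A validated [CaTraceExperiment-class].
#' @export
readTraceTable <- function(path, frame_interval_s = NULL,
                           stim_time_s = NA_real_, cellData = NULL) {
  if (!file.exists(path)) stop(sprintf("trace table not found: %s", path))
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("trace table needs a time/frame column plus >= 1 cell column")
  first <- suppressWarnings(as.numeric(tab[[1L]]))
  if (anyNA(first)) {
    stop(sprintf("non-numeric value in time/frame column at frame %d",
                 which(is.na(first))[1L]))
  }
  times <- if (is.null(frame_interval_s)) first else first * frame_interval_s
  if (length(times) >= 2L) {
    dt <- diff(times)
    if (any(dt <= 0) || max(dt) - min(dt) > 1e-6) {
      stop("frame times are not strictly increasing and uniformly spaced")
    }
  }
  cellcols <- colnames(tab)[-1L]
  Fmat <- matrix(NA_real_, nrow = length(cellcols), ncol = nrow(tab),
                 dimnames = list(cellcols, NULL))
  for (j in seq_along(cellcols)) {
    v <- suppressWarnings(as.numeric(tab[[j + 1L]]))
    if (anyNA(v)) {
      stop(sprintf("missing or non-numeric value at (cell %s, frame %d)",
                   cellcols[j], which(is.na(v))[1L]))
    }
    Fmat[j, ] <- v
  }
  CaTraceExperiment(Fmat, times_s = times, stim_time_s = stim_time_s,
                    cellData = cellData)
}

#' Write a wide ROI trace table
#'
#' Inverse of [readTraceTable()]: time in seconds in the first column,
#' one comma-separated column per cell. Round-trips bit-faithfully at
#' full double precision.
#'
#' @param x A [CaTraceExperiment-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeTraceTable <- function(x, path) {
  stopifnot(is(x, "CaTraceExperiment"))
  tab <- data.frame(time_s = traceTimes(x),
                    t(assay(x, "F")), check.names = FALSE)
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write cell-metadata tables
#'
#' Comma-separated cell metadata with required columns `cell_id`,
#' `prep_id`, `segment` (T3, A1–A5), `hemisegment` (L/R) and optional
#' `condition`, `genotype`. Unknown segment labels and duplicated cell ids
#' are schema errors.
#'
#' @param path CSV path.
#' @return `readCellTable()`: a `data.frame`; `writeCellTable()`: `path`.
#' @export
readCellTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("cell table not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "prep_id", "segment", "hemisegment")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) {
    stop(sprintf("cell table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(tab$cell_id)) {
    stop(sprintf("duplicated cell_id: %s",
                 paste(unique(tab$cell_id[duplicated(tab$cell_id)]),
                       collapse = ", ")))
  }
  badseg <- setdiff(unique(tab$segment), SEGMENT_LEVELS)
  badside <- setdiff(unique(tab$hemisegment), HEMISEGMENT_SIDES)
  if (length(badseg) || length(badside)) {
    stop(sprintf("unknown segment/hemisegment label(s): %s",
                 paste(c(badseg, badside), collapse = ", ")))
  }
  tab
}

#' @rdname readCellTable
#' @param cells Cell metadata `data.frame`.
#' @export
writeCellTable <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a responder-topography heatmap matrix
#'
#' Serializes a [segmentTopography()] summary as the tab-delimited matrix
#' expected by matrix-image tools (matrix2png convention): one row per
#' preparation ordered by `prep_id`, one column per hemisegment in the
#' canonical order T3L, T3R, A1L, ..., A5R, cell values percent responders;
#' hemisegments with no cells in a preparation are written as `NA`.
#'
#' @param summary A `SegmentSummary` from [segmentTopography()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeHeatmapMatrix <- function(summary, path) {
  stopifnot(inherits(summary, "SegmentSummary"))
  pp <- summary$per_prep
  preps <- sort(unique(pp$prep_id))
  hemis <- hemisegmentLevels()
  mat <- matrix(NA_real_, nrow = length(preps), ncol = length(hemis),
                dimnames = list(preps, hemis))
  mat[cbind(match(pp$prep_id, preps), match(pp$hemisegment, hemis))] <-
    pp$percent_responders
  out <- cbind(data.frame(prep_id = preps), as.data.frame(mat))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a heatmap matrix written by [writeHeatmapMatrix()]
#' @param path TSV path.
#' @return A `data.frame`, preparations as rows.
#' @export
readHeatmapMatrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("heatmap matrix not found: %s", path))
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a per-method differential-expression table
#'
#' CSV with columns `gene`, `expr_a`, `expr_b`, `fold_change`,
#' `significance` (and optionally `method`), as consumed by
#' [consensusDE()].
#'
#' @param path CSV path.
#' @param method Method label attached when the file lacks a `method`
#'   column.
#' @return A `data.frame`.
#' @export
readDeTable <- function(path, method = NULL) {
  if (!file.exists(path)) stop(sprintf("DE table not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "expr_a", "expr_b", "fold_change", "significance")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) {
    stop(sprintf("DE table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!"method" %in% colnames(tab)) {
    tab$method <- if (is.null(method)) basename(path) else method
  }
  tab
}

#' Read a qPCR Ct table
#'
#' CSV with columns `sample`, `gene`, `replicate`, `Ct` (and optionally
#' `condition`); Ct values must be positive.
#'
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
readCtTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("Ct table not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "replicate", "Ct")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) {
    stop(sprintf("Ct table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(tab$Ct)) || any(tab$Ct <= 0)) {
    stop("Ct values must be positive finite cycle numbers")
  }
  tab
}

#' Write a tidy long-format result table
#'
#' One metric per row: `cell_id` (or group), `metric`, `window`, `value`;
#' duplicated (cell_id, metric, window) combinations are rejected.
#'
#' @param results A `data.frame` with those columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeTidyResults <- function(results, path) {
  key_cols <- intersect(c("cell_id", "group", "metric", "window"),
                        colnames(results))
  key <- do.call(paste, c(results[key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicated (cell_id, metric, window) rows in tidy results")
  }
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
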