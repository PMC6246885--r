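#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom stats rnorm rbinom rpois rlnorm runif sd setNames
NULL

SEGMENT_LEVELS <- c("T3", "A1", "A2", "A3", "A4", "A5")
HEMISEGMENT_SIDES <- c("L", "R")

#' Hemisegment labels in canonical order
#'
#' The ventral ganglion segments imaged in the larval preparations are T3
#' through A5, each with a left and a right hemisegment. Topography summaries
#' and heatmap matrices order hemisegments T3L, T3R, A1L, ..., A5R.
#'
#' @return Character vector of the 12 hemisegment labels.
#' @export
#' @examples
#' hemisegmentLevels()
hemisegmentLevels <- function() {
  as.vector(t(outer(SEGMENT_LEVELS, HEMISEGMENT_SIDES, paste0)))
}

#' Container for ROI fluorescence time series
#'
#' `CaTraceExperiment` extends [SummarizedExperiment::SummarizedExperiment]
#' for population calcium-imaging recordings: rows are cells (ROIs), columns
#' are frames. The `"F"` assay holds raw fluorescence in arbitrary units;
#' after normalization a `"dff"` assay holds the fractional fluorescence
#' change. Frame times in seconds live in `colData(x)$time_s` (uniformly
#' spaced), cell metadata (preparation, segment, hemisegment, condition,
#' genotype) in `rowData`, and the stimulus (withdrawal) time in a dedicated
#' slot.
#'
#' @slot stimTime numeric(1), stimulus/withdrawal time in seconds.
#' @slot frameInterval numeric(1), frame spacing in seconds.
#' @slot responseMode character(1): `"raw"` before normalization,
#'   `"response"` for dF/F, `"release"` for the fluorescence-loss transform.
#'
#' @aliases CaTraceExperiment-class
#' @exportClass CaTraceExperiment
setClass("CaTraceExperiment",
  contains = "SummarizedExperiment",
  slots = c(
    stimTime = "numeric",
    frameInterval = "numeric",
    responseMode = "character"
  ),
  prototype = prototype(
    stimTime = NA_real_,
    frameInterval = NA_real_,
    responseMode = "raw"
  )
)

setValidity("CaTraceExperiment", function(object) {
  msgs <- character()
  tm <- object@colData$time_s
  if (is.null(tm)) {
    return("colData must contain a 'time_s' column of frame times")
  }
  if (ncol(object) >= 2L) {
    dt <- diff(tm)
    if (any(dt <= 0)) {
      msgs <- c(msgs, "frame times must be strictly increasing")
    } else if (max(dt) - min(dt) > 1e-6) {
      msgs <- c(msgs, "frame times must be uniformly spaced (tolerance 1e-6)")
    }
    if (is.finite(object@frameInterval) &&
        abs(object@frameInterval - dt[1L]) > 1e-6) {
      msgs <- c(msgs, "frameInterval slot disagrees with colData time_s spacing")
    }
  }
  if (length(object@stimTime) != 1L) {
    msgs <- c(msgs, "stimTime must be a single number")
  } else if (is.finite(object@stimTime) &&
             (object@stimTime < tm[1L] || object@stimTime > tm[length(tm)])) {
    msgs <- c(msgs, "stimTime must lie within the recorded time span")
  }
  if (!object@responseMode %in% c("raw", "response", "release")) {
    msgs <- c(msgs, "responseMode must be 'raw', 'response' or 'release'")
  }
  if (!"F" %in% assayNames(object)) {
    msgs <- c(msgs, "assay 'F' (raw fluorescence) is required")
  }
  if (anyDuplicated(rownames(object))) {
    msgs <- c(msgs, "cell ids (rownames) must be unique")
  }
  rd <- rowData(object)
  if ("segment" %in% colnames(rd)) {
    bad <- setdiff(unique(as.character(rd$segment)), SEGMENT_LEVELS)
    if (length(bad)) {
      msgs <- c(msgs, sprintf("unknown segment label(s): %s",
                              paste(bad, collapse = ", ")))
    }
  }
  if ("hemisegment" %in% colnames(rd)) {
    bad <- setdiff(unique(as.character(rd$hemisegment)), HEMISEGMENT_SIDES)
    if (length(bad)) {
      msgs <- c(msgs, sprintf("unknown hemisegment label(s): %s",
                              paste(bad, collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CaTraceExperiment
#'
#' @param F Numeric matrix of fluorescence, cells x frames. Rownames are cell
#'   ids (generated as `cell_1`, ... when absent).
#' @param times_s Frame times in seconds, one per column, uniformly spaced.
#'   Mutually exclusive with `frame_interval_s`.
#' @param frame_interval_s Frame spacing in seconds; times are then
#'   `0, dt, 2*dt, ...` (frame 0 at 0 s).
#' @param stim_time_s Stimulus (withdrawal) time in seconds.
#' @param cellData `data.frame`/`DataFrame` of per-cell metadata (prep_id,
#'   segment, hemisegment, condition, genotype), one row per cell.
#' @param mode `"raw"`, `"response"`, or `"release"`.
#' @param dff Optional matrix of normalized values, same shape as `F`.
#' @param metadata Named list stored in `metadata()`.
#'
#' @return A validated [CaTraceExperiment-class] object.
#' @export
#' @examples
#' F <- matrix(100, nrow = 2, ncol = 150)
#' cte <- CaTraceExperiment(F, frame_interval_s = 4, stim_time_s = 60)
#' cte
CaTraceExperiment <- function(F, times_s = NULL, frame_interval_s = NULL,
                              stim_time_s = NA_real_, cellData = NULL,
                              mode = "raw", dff = NULL, metadata = list()) {
  F <- as.matrix(F)
  if (!is.numeric(F)) stop("fluorescence matrix must be numeric")
  if (is.null(times_s)) {
    if (is.null(frame_interval_s)) {
      stop("supply either times_s or frame_interval_s")
    }
    times_s <- (seq_len(ncol(F)) - 1) * frame_interval_s
  }
  if (length(times_s) != ncol(F)) {
    stop("length(times_s) must equal the number of frames (columns)")
  }
  dt <- if (length(times_s) >= 2L) times_s[2L] - times_s[1L] else NA_real_
  if (is.null(rownames(F))) {
    rownames(F) <- paste0("cell_", seq_len(nrow(F)))
  }
  rd <- if (is.null(cellData)) {
    DataFrame(cell_id = rownames(F), row.names = rownames(F))
  } else {
    rd <- DataFrame(cellData)
    if (!"cell_id" %in% colnames(rd)) rd$cell_id <- rownames(F)
    rownames(rd) <- rownames(F)
    rd
  }
  assays <- list(F = F)
  if (!is.null(dff)) {
    dff <- as.matrix(dff)
    dimnames(dff) <- dimnames(F)
    assays$dff <- dff
  }
  se <- SummarizedExperiment(
    assays = assays,
    rowData = rd,
    colData = DataFrame(time_s = as.numeric(times_s),
                        row.names = paste0("frame_", seq_along(times_s))),
    metadata = metadata
  )
  new("CaTraceExperiment", se,
      stimTime = as.numeric(stim_time_s),
      frameInterval = as.numeric(dt),
      responseMode = mode)
}

#' @describeIn CaTraceExperiment Frame times in seconds.
#' @param x A `CaTraceExperiment`.
#' @export
traceTimes <- function(x) colData(x)$time_s

#' @describeIn CaTraceExperiment Stimulus (withdrawal) time in seconds.
#' @export
stimTime <- function(x) x@stimTime

#' @describeIn CaTraceExperiment Frame interval in seconds.
#' @export
frameInterval <- function(x) x@frameInterval

#' @describeIn CaTraceExperiment Normalization mode of the object.
#' @export
responseMode <- function(x) x@responseMode

#' @describeIn CaTraceExperiment Per-cell baseline fluorescence (set by
#'   [computeDff()] / [computeRelease()]).
#' @export
baselineF0 <- function(x) {
  f0 <- rowData(x)$baseline_F0
  if (is.null(f0)) stop("no baseline recorded; run computeDff() first")
  setNames(f0, rownames(x))
}

#' @describeIn CaTraceExperiment Per-cell metadata as a base data.frame.
#' @export
cellData <- function(x) as.data.frame(rowData(x))

#' @describeIn CaTraceExperiment Simulation ground truth (cell_id,
#'   is_responder, n_events) for simulated objects.
#' @export
groundTruth <- function(x) {
  gt <- metadata(x)$ground_truth
  if (is.null(gt)) stop("object carries no simulation ground truth")
  gt
}

setMethod("show", "CaTraceExperiment", function(object) {
  cat(sprintf("CaTraceExperiment: %d cells x %d frames\n",
              nrow(object), ncol(object)))
  tm <- traceTimes(object)
  cat(sprintf("  time: %g..%g s at %g s/frame; stimulus at %g s; mode: %s\n",
              tm[1L], tm[length(tm)], frameInterval(object),
              stimTime(object), responseMode(object)))
  cat(sprintf("  assays: %s\n", paste(assayNames(object), collapse = ", ")))
  extra <- setdiff(colnames(rowData(object)), "cell_id")
  if (length(extra)) {
    cat(sprintf("  cell metadata: %s\n", paste(extra, collapse = ", ")))
  }
  invisible(NULL)
})
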