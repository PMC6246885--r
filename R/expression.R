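#' Three-method consensus differential-expression gate
#'
#' Deterministic filter over the tabular outputs of three upstream
#' differential-expression engines. Per method, a gene is kept when (i) its
#' expression is nonzero in both conditions, (ii) its significance value is
#' below `sig_cutoff`, and (iii) its fold change departs from 1 by at least
#' `min_change` (default 25 %): up means `FC >= 1 + min_change`, down means
#' `FC <= 1 - min_change` on the linear scale. With
#' `symmetric = FALSE` the reciprocal reading is used for down-regulation
#' (`FC <= 1/(1 + min_change)`). The consensus up/down sets are the
#' direction-consistent intersections across all three methods; genes
#' called in opposite directions by different methods are excluded and
#' listed. A seven-region Venn partition of the per-method
#' (direction-agnostic) gated sets is reported.
#'
#' @param tables List of exactly three per-method `data.frame`s with
#'   columns `gene`, `expr_a`, `expr_b`, `fold_change`, `significance`
#'   (e.g. from [simulateDeTables()] or [readDeTable()]).
#' @param min_change Minimum fractional change (0.25 = 25 %).
#' @param sig_cutoff Per-method significance cutoff (q or FDR-adjusted p).
#' @param symmetric Use the symmetric linear reading for down-regulation.
#' @return A list of class `ConsensusResult`: `up`, `down` (consensus gene
#'   sets), `per_method` (list of per-method up/down sets), `venn`
#'   (seven-region counts), `conflicting` (direction-inconsistent genes),
#'   `two_of_three` (genes gated by at least two methods, any direction
#'   mix excluded).
#' @export
#' @examples
#' de <- simulateDeTables(n_genes = 40, n_down = 6, n_up = 3, seed = 9)
#' consensusDE(de)
consensusDE <- function(tables, min_change = 0.25, sig_cutoff = 0.05,
                        symmetric = TRUE) {
  if (length(tables) != 3L) {
    stop("exactly three per-method DE tables are required")
  }
  need <- c("gene", "expr_a", "expr_b", "fold_change", "significance")
  gated <- lapply(tables, function(tab) {
    miss <- setdiff(need, colnames(tab))
    if (length(miss)) {
      stop(sprintf("DE table lacks column(s): %s", paste(miss, collapse = ", ")))
    }
    up_cut <- 1 + min_change
    down_cut <- if (symmetric) 1 - min_change else 1 / (1 + min_change)
    keep <- tab$expr_a != 0 & tab$expr_b != 0 & tab$significance < sig_cutoff
    list(up = tab$gene[keep & tab$fold_change >= up_cut],
         down = tab$gene[keep & tab$fold_change <= down_cut])
  })
  if (is.null(names(gated)) || any(!nzchar(names(gated)))) {
    names(gated) <- paste0("method", seq_len(3L))
  }
  up <- Reduce(intersect, lapply(gated, `[[`, "up"))
  down <- Reduce(intersect, lapply(gated, `[[`, "down"))
  all_by_method <- lapply(gated, function(g) union(g$up, g$down))
  in_any_up <- Reduce(union, lapply(gated, `[[`, "up"))
  in_any_down <- Reduce(union, lapply(gated, `[[`, "down"))
  conflicting <- intersect(in_any_up, in_any_down)
  up <- setdiff(up, conflicting)
  down <- setdiff(down, conflicting)
  n_hits <- table(unlist(lapply(all_by_method, unique)))
  two_of_three <- setdiff(names(n_hits)[n_hits >= 2L], conflicting)
  structure(list(up = sort(up), down = sort(down),
                 per_method = gated,
                 venn = vennPartition(all_by_method),
                 conflicting = sort(conflicting),
                 two_of_three = sort(two_of_three)),
            class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("Consensus DE gate: %d up, %d down (all three methods)\n",
              length(x$up), length(x$down)))
  if (length(x$conflicting)) {
    cat(sprintf("  direction-conflicting genes excluded: %d\n",
                length(x$conflicting)))
  }
  print(x$venn)
  invisible(x)
}

#' Seven-region Venn partition of three sets
#'
#' Counts the elements in each of the seven nonempty regions of a
#' three-set Venn diagram. Region names use the set names joined by
#' `&` (e.g. `"A&B"` holds elements in A and B but not C); regions
#' containing a given set sum to that set's size.
#'
#' @param sets A named list of three character vectors.
#' @return Named integer vector of the seven region counts.
#' @export
#' @examples
#' vennPartition(list(A = c("x", "y"), B = c("y"), C = c("y", "z")))
vennPartition <- function(sets) {
  if (length(sets) != 3L) stop("exactly three sets are required")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- c("A", "B", "C")
  }
  sets <- lapply(sets, unique)
  universe <- Reduce(union, sets)
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  region_names <- apply(expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                                    c = c(TRUE, FALSE))[-8L, , drop = FALSE],
                        1L, function(r) {
    paste(names(sets)[unlist(r)], collapse = "&")
  })
  counts <- integer(7L)
  pat <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                     c = c(TRUE, FALSE))[-8L, , drop = FALSE]
  for (i in seq_len(7L)) {
    counts[i] <- sum(member[, 1L] == pat$a[i] &
                     member[, 2L] == pat$b[i] &
                     member[, 3L] == pat$c[i])
  }
  setNames(counts, region_names)
}

#' qPCR fold change by the 2^-ddCt method
#'
#' Relative quantification of a target gene against a housekeeping gene:
#' technical duplicates are averaged per (sample, gene), then
#' `ddCt = (Ct_target - Ct_housekeeping)_expt - (Ct_target -
#' Ct_housekeeping)_control` and the fold change is `2^-ddCt`. With
#' several biological replicates per condition, each experimental
#' replicate's dCt is compared against the mean control dCt, and the
#' per-replicate fold changes are summarized as mean and SEM. Several
#' housekeeping genes may be given; each yields its own normalization row,
#' and a housekeeping gene normalized to itself returns fold 1.
#'
#' @param ct A Ct table (`sample`, `condition` or explicit sample lists,
#'   `gene`, `replicate`, `Ct`), e.g. from [simulateCtTable()] or
#'   [readCtTable()].
#' @param target Target gene label (vectorized: several targets allowed).
#' @param housekeeping Housekeeping gene label(s).
#' @param expt,control Condition labels matched against `ct$condition`, or
#'   character vectors of sample names.
#' @return A `data.frame` with one row per target x housekeeping pair:
#'   `gene`, `housekeeping`, `fold_change` (mean over biological
#'   replicates), `sem`, `n`, `ddct`.
#' @export
#' @examples
#' ct <- simulateCtTable("dStim", 0.5, seed = 1)
#' ddctFoldChange(ct, "dStim", "rp49", expt = "expt", control = "control")
ddctFoldChange <- function(ct, target, housekeeping, expt, control) {
  need <- c("sample", "gene", "replicate", "Ct")
  miss <- setdiff(need, colnames(ct))
  if (length(miss)) {
    stop(sprintf("Ct table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  pick_samples <- function(label) {
    if ("condition" %in% colnames(ct) && any(ct$condition == label)) {
      unique(ct$sample[ct$condition == label])
    } else {
      hit <- unique(ct$sample[ct$sample %in% label])
      if (!length(hit)) stop(sprintf("no samples match condition '%s'", label))
      hit
    }
  }
  expt_s <- pick_samples(expt)
  ctrl_s <- pick_samples(control)

  # technical duplicates averaged per (sample, gene)
  mean_ct <- function(smp, gene) {
    v <- ct$Ct[ct$sample == smp & ct$gene == gene]
    if (!length(v)) {
      stop(sprintf("no Ct value for (gene %s, sample %s)", gene, smp))
    }
    mean(v)
  }
  out <- expand.grid(gene = target, housekeeping = housekeeping,
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    tg <- out$gene[i]; hk <- out$housekeeping[i]
    dct_ctrl <- vapply(ctrl_s, function(s) mean_ct(s, tg) - mean_ct(s, hk), 0)
    dct_expt <- vapply(expt_s, function(s) mean_ct(s, tg) - mean_ct(s, hk), 0)
    ddct <- dct_expt - mean(dct_ctrl)
    folds <- 2^(-ddct)
    data.frame(gene = tg, housekeeping = hk,
               fold_change = mean(folds),
               sem = if (length(folds) > 1L) sd(folds) / sqrt(length(folds))
                     else NA_real_,
               n = length(folds),
               ddct = mean(ddct),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
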