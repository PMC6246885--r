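#' Simulate per-method differential-expression tables
#'
#' Builds three per-method result tables (emulating the tabular output of
#' three upstream differential-expression engines) over a shared gene
#' universe, with planted down- and up-regulated genes at stated fold
#' changes and the remainder null. Planted genes are significant in every
#' method unless listed in `dropout`, which forces a method to miss them —
#' useful for testing how the consensus intersection shrinks.
#'
#' @param n_genes Size of the gene universe.
#' @param n_down,n_up Numbers of planted down-/up-regulated genes
#'   (`n_down + n_up <= n_genes`).
#' @param fc_down,fc_up Planted linear fold changes, `fc_down < 1 < fc_up`.
#' @param seed Integer RNG seed (required).
#' @param methods Labels of the three emulated engines.
#' @param dropout Named list (by method label) of gene ids that method fails
#'   to call significant.
#'
#' @return Named list of three `data.frame`s with columns `method`, `gene`,
#'   `expr_a`, `expr_b`, `fold_change`, `significance`, plus an attribute
#'   `"planted"` (data.frame of gene, direction).
#' @export
#' @examples
#' de <- simulateDeTables(n_genes = 50, n_down = 10, n_up = 2, seed = 1)
#' attr(de, "planted")
simulateDeTables <- function(n_genes, n_down, n_up, fc_down = 0.5, fc_up = 2,
                             seed, methods = c("cuffdiff2", "deseq", "edger"),
                             dropout = list()) {
  if (missing(seed)) stop("a numeric 'seed' is required")
  if (n_down + n_up > n_genes) {
    stop("inconsistent counts: n_down + n_up must not exceed n_genes")
  }
  if (!(fc_down < 1 && fc_up > 1)) {
    stop("planted fold changes must satisfy fc_down < 1 < fc_up")
  }
  if (length(methods) != 3L) stop("exactly three method labels are required")
  set.seed(seed, kind = "Mersenne-Twister")
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  direction <- rep("null", n_genes)
  if (n_down > 0) direction[seq_len(n_down)] <- "down"
  if (n_up > 0) direction[n_down + seq_len(n_up)] <- "up"
  fc_true <- ifelse(direction == "down", fc_down,
                    ifelse(direction == "up", fc_up, 1))
  expr_a <- rlnorm(n_genes, log(50), 0.5)
  # null genes wobble well inside the 25 % band so only planted genes pass
  null_fc <- exp(runif(n_genes, log(0.9), log(1.1)))
  fc_obs <- ifelse(direction == "null", null_fc, fc_true)

  tabs <- lapply(methods, function(m) {
    sig <- ifelse(direction == "null", runif(n_genes, 0.3, 1),
                  runif(n_genes, 0, 0.01))
    miss <- dropout[[m]]
    if (!is.null(miss)) sig[genes %in% miss] <- runif(sum(genes %in% miss), 0.5, 1)
    data.frame(method = m, gene = genes,
               expr_a = expr_a, expr_b = expr_a * fc_obs,
               fold_change = fc_obs, significance = sig,
               stringsAsFactors = FALSE)
  })
  names(tabs) <- methods
  attr(tabs, "planted") <- data.frame(gene = genes[direction != "null"],
                                      direction = direction[direction != "null"],
                                      stringsAsFactors = FALSE)
  tabs
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Generates threshold-cycle (Ct) values with technical duplicates and
#' biological replicates such that the expected housekeeping-normalized
#' fold change `2^-ddCt` of each target gene equals its planted value.
#' Housekeeping genes are planted at fold 1 by construction.
#'
#' @param genes Character vector of target gene labels.
#' @param true_fold_changes Numeric vector of planted linear fold changes
#'   (experimental vs control), one per target gene; all > 0.
#' @param housekeeping Labels of housekeeping genes (fold fixed at 1).
#' @param n_replicates Biological replicates per condition.
#' @param n_technical Technical duplicates per reaction.
#' @param ct_noise_sd Gaussian noise SD on each Ct, in cycles.
#' @param seed Integer RNG seed (required).
#' @param base_ct Mean control Ct of target genes; `hk_ct` that of
#'   housekeeping genes.
#' @param hk_ct See `base_ct`.
#'
#' @return A long-format `data.frame` with columns `sample`, `condition`
#'   (`"control"`/`"expt"`), `gene`, `replicate`, `Ct`, carrying the planted
#'   folds as attribute `"planted"`.
#' @export
#' @examples
#' ct <- simulateCtTable(c("dStim", "cac"), c(0.58, 0.42), seed = 3)
#' head(ct)
simulateCtTable <- function(genes, true_fold_changes,
                            housekeeping = c("rp49", "tubulin"),
                            n_replicates = 3, n_technical = 2,
                            ct_noise_sd = 0, seed,
                            base_ct = 22, hk_ct = 16) {
  if (missing(seed)) stop("a numeric 'seed' is required")
  if (length(true_fold_changes) != length(genes)) {
    stop("'true_fold_changes' must have one entry per target gene")
  }
  if (any(true_fold_changes <= 0)) {
    stop("planted fold changes must be positive (2^-ddCt is never <= 0)")
  }
  set.seed(seed, kind = "Mersenne-Twister")
  all_genes <- c(genes, housekeeping)
  # control Ct per gene; experimental target Ct shifted by -log2(fold)
  ctrl_ct <- c(base_ct + seq_along(genes) * 0.5,
               hk_ct + seq_along(housekeeping) * 0.5)
  shift <- c(-log2(true_fold_changes), rep(0, length(housekeeping)))
  grid <- expand.grid(condition = c("control", "expt"),
                      bio = seq_len(n_replicates),
                      gene = all_genes,
                      replicate = seq_len(n_technical),
                      stringsAsFactors = FALSE)
  gi <- match(grid$gene, all_genes)
  mu <- ctrl_ct[gi] + ifelse(grid$condition == "expt", shift[gi], 0)
  ct <- data.frame(
    sample = paste0(grid$condition, "_", grid$bio),
    condition = grid$condition,
    gene = grid$gene,
    replicate = grid$replicate,
    Ct = mu + rnorm(nrow(grid), 0, ct_noise_sd),
    stringsAsFactors = FALSE
  )
  attr(ct, "planted") <- data.frame(gene = genes,
                                    fold_change = true_fold_changes,
                                    stringsAsFactors = FALSE)
  ct
}
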