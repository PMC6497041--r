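#' Run the full ceRNA discovery pipeline
#'
#' Chains the analysis stages on count matrices: per-class FPKM abundance
#' filtering, stage-wise negative-binomial differential expression against
#' the normal samples, four-way common-DEG intersection, lncRNA-mRNA
#' co-expression screening on log2-normalized values over all samples,
#' shared-miRNA hypergeometric testing with BH control, and network
#' assembly.
#'
#' @param counts Named list of three `ExpressionMatrix` objects with unit
#'   `"counts"`: `mRNA`, `lncRNA`, `miRNA`.
#' @param samples A `SampleTable`.
#' @param lengths Named gene-length vector covering all genes.
#' @param interactions An `InteractionTable`.
#' @param fpkm_threshold Named numeric vector of abundance thresholds per
#'   class (defaults: mRNA 1, lncRNA 0.1, miRNA 1).
#' @param min_fraction Abundance filter sample fraction (default 0.1).
#' @param fc_threshold,fdr_threshold Common-DEG cutoffs (defaults 1 and
#'   0.01).
#' @param r_threshold,p_threshold Co-expression cutoffs (defaults 0.8 and
#'   0.05).
#' @param module_fdr,min_shared Module cutoffs (defaults 0.05 and 1).
#' @return List with `retained` (post-filter gene ids per class),
#'   `de_tables` (per class, per stage), `degs` (per-class
#'   `CommonDEGSet`), `correlations`, `modules`, `network`.
#' @export
run_cerna_pipeline <- function(counts, samples, lengths, interactions,
                               fpkm_threshold = c(mRNA = 1, lncRNA = 0.1,
                                                  miRNA = 1),
                               min_fraction = 0.1,
                               fc_threshold = 1, fdr_threshold = 0.01,
                               r_threshold = 0.8, p_threshold = 0.05,
                               module_fdr = 0.05, min_shared = 1) {
  classes <- c("mRNA", "lncRNA", "miRNA")
  if (!all(classes %in% names(counts))) {
    stop("`counts` must be a named list with elements mRNA, lncRNA, miRNA")
  }
  samples <- validate_sample_table(samples)
  stages <- paste0("T", 1:4)

  retained <- list()
  de_tables <- list()
  degs <- list()
  filtered <- list()
  for (cls in classes) {
    cm <- counts[[cls]]
    fpkm <- compute_fpkm(cm, lengths)
    keep <- abundance_filter(fpkm, threshold = fpkm_threshold[[cls]],
                             min_fraction = min_fraction)
    retained[[cls]] <- keep
    sub <- expression_matrix(unclass(cm)[keep, , drop = FALSE],
                             gene_class = cls, unit = "counts")
    filtered[[cls]] <- sub
    de_tables[[cls]] <- lapply(stats::setNames(stages, stages),
                               function(s) nb_de_test(sub, samples, s))
    degs[[cls]] <- common_degs(de_tables[[cls]],
                               fc_threshold = fc_threshold,
                               fdr_threshold = fdr_threshold)
  }

  lnc_ids <- degs$lncRNA$gene_id
  mrna_ids <- degs$mRNA$gene_id
  correlations <- data.frame(lncrna_id = character(), mrna_id = character(),
                             r = numeric(), pvalue = numeric(),
                             stringsAsFactors = FALSE)
  if (length(lnc_ids) && length(mrna_ids)) {
    lnc_log <- normalize_log2(filtered$lncRNA)
    mrna_log <- normalize_log2(filtered$mRNA)
    correlations <- correlate_pairs(
      expression_matrix(unclass(lnc_log)[lnc_ids, , drop = FALSE],
                        "lncRNA", "log2norm"),
      expression_matrix(unclass(mrna_log)[mrna_ids, , drop = FALSE],
                        "mRNA", "log2norm"),
      r_threshold = r_threshold, p_threshold = p_threshold)
  }

  net <- if (nrow(correlations)) {
    build_cerna_network(degs, interactions, correlations,
                        module_fdr = module_fdr, min_shared = min_shared)
  } else {
    list(modules = data.frame(), network = list(
      nodes = data.frame(), edges = data.frame()))
  }

  list(retained = retained, de_tables = de_tables, degs = degs,
       correlations = correlations, modules = net$modules,
       network = net$network)
}
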