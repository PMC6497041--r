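#' Abundance filter on FPKM
#'
#' Keeps a gene when its FPKM exceeds `threshold` in at least
#' `ceiling(min_fraction * n_samples)` samples. Applied before testing so
#' that multiple-testing correction only counts genes that were actually
#' testable. The conventional thresholds are 1 for mRNA and miRNA and 0.1
#' for lncRNA, with `min_fraction = 0.1`.
#'
#' @param fpkm An `ExpressionMatrix` with unit `"fpkm"`.
#' @param threshold Expression threshold (strict `>`).
#' @param min_fraction Minimum fraction of samples, in (0, 1].
#' @return Character vector of retained gene ids, in input order.
#' @export
abundance_filter <- function(fpkm, threshold = 1, min_fraction = 0.1) {
  .stopifnot_unit(fpkm, "fpkm")
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    stop("`min_fraction` must be in (0, 1]")
  }
  n <- ncol(fpkm)
  # epsilon shields ceiling() from upward FP noise in min_fraction * n
  k <- ceiling(min_fraction * n - 1e-9)
  keep <- rowSums(unclass(fpkm) > threshold) >= k
  rownames(fpkm)[keep]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity. `NA` entries pass
#' through unchanged and do not count towards the number of tests.
#'
#' @param pvalues Numeric vector in \[0, 1\], `NA` allowed.
#' @return Vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("`pvalues` must be numeric")
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Stage-wise negative-binomial Wald test
#'
#' Compares one tumor stage against the normal samples, gene by gene, on
#' size-factor-normalized counts. The fold change is
#' `log2((mean_tumor + 0.5) / (mean_normal + 0.5))` (the 0.5 pseudo-count
#' keeps it finite); the test statistic is a Wald z from a delta-method
#' standard error under a negative-binomial variance with a per-gene
#' method-of-moments dispersion, pooled across the two groups and floored
#' at 1e-8. Genes with zero counts in every selected sample get `NA`
#' statistics and are excluded from the BH correction.
#'
#' @param counts An `ExpressionMatrix` with unit `"counts"`.
#' @param samples A `SampleTable` covering the matrix's samples.
#' @param stage One of `"T1"`..`"T4"`.
#' @return A `data.frame` (class `DETable`) with columns `gene_id`,
#'   `base_mean`, `log2fc`, `pvalue`, `fdr`, `comparison`.
#' @export
nb_de_test <- function(counts, samples, stage = c("T1", "T2", "T3", "T4")) {
  .stopifnot_unit(counts, "counts")
  stage <- match.arg(stage)
  samples <- validate_sample_table(samples)
  idx <- match(colnames(counts), samples$sample_id)
  if (anyNA(idx)) stop("samples missing from sample table: ",
                       paste(colnames(counts)[is.na(idx)], collapse = ", "))
  st <- samples[idx, ]
  is_norm <- st$condition == "normal"
  is_tum <- st$condition == "tumor" & st$stage == stage
  if (sum(is_norm) < 3 || sum(is_tum) < 3) {
    stop("need >= 3 samples per group (normal: ", sum(is_norm),
         ", ", stage, ": ", sum(is_tum), ")")
  }
  sub <- expression_matrix(unclass(counts)[, is_norm | is_tum, drop = FALSE],
                           gene_class = gene_class(counts), unit = "counts")
  grp_tum <- is_tum[is_norm | is_tum]
  sf <- estimate_size_factors(sub)
  x <- sweep(unclass(sub), 2, sf, "/")

  n1 <- sum(!grp_tum)
  n2 <- sum(grp_tum)
  x1 <- x[, !grp_tum, drop = FALSE]
  x2 <- x[, grp_tum, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mp <- (m1 + m2) / 2
  disp <- pmax((vp - mp) / mp^2, 1e-8)

  l2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  se2 <- (1 / log(2))^2 *
    ((m1 + disp * m1^2) / n1 / (m1 + 0.5)^2 +
     (m2 + disp * m2^2) / n2 / (m2 + 0.5)^2)
  z <- l2fc / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(z))
  p[m1 == m2] <- 1  # identical group means carry no evidence

  allzero <- rowSums(unclass(sub)) == 0
  l2fc[allzero] <- NA_real_
  p[allzero] <- NA_real_
  base_mean <- rowMeans(x)
  base_mean[allzero] <- NA_real_

  res <- data.frame(gene_id = rownames(counts),
                    base_mean = base_mean,
                    log2fc = l2fc,
                    pvalue = p,
                    fdr = bh_adjust(p),
                    comparison = stage,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("DETable", "data.frame")
  res
}

#' Intersect stage-wise DE calls into a common DEG set
#'
#' A gene is a common DEG when it satisfies `|log2FC| >= fc_threshold` and
#' `fdr < fdr_threshold` in all four stage-vs-normal comparisons, with the
#' same fold-change sign throughout. The consistent direction is recorded as
#' `"up"` or `"down"` (tumor relative to normal).
#'
#' @param tables List of exactly four `DETable`s, one per stage T1..T4.
#' @param fc_threshold Minimum absolute log2 fold change (default 1, i.e.
#'   two-fold).
#' @param fdr_threshold FDR cutoff (strict `<`, default 0.01).
#' @return A `data.frame` (class `CommonDEGSet`) with columns `gene_id`,
#'   `direction`.
#' @export
common_degs <- function(tables, fc_threshold = 1, fdr_threshold = 0.01) {
  stages <- vapply(tables, function(t) t$comparison[1], character(1))
  miss <- setdiff(paste0("T", 1:4), stages)
  if (length(miss)) stop("missing stage comparison(s): ",
                         paste(miss, collapse = ", "))
  tables <- tables[match(paste0("T", 1:4), stages)]
  ids <- Reduce(intersect, lapply(tables, function(t) t$gene_id))
  sig <- vapply(tables, function(t) {
    t <- t[match(ids, t$gene_id), ]
    !is.na(t$fdr) & !is.na(t$log2fc) &
      abs(t$log2fc) >= fc_threshold & t$fdr < fdr_threshold
  }, logical(length(ids)))
  sgn <- vapply(tables, function(t) {
    sign(t$log2fc[match(ids, t$gene_id)])
  }, numeric(length(ids)))
  if (length(ids) == 1L) {
    sig <- matrix(sig, nrow = 1)
    sgn <- matrix(sgn, nrow = 1)
  }
  all_sig <- rowSums(sig) == 4L
  same_dir <- abs(rowSums(sgn)) == 4L
  keep <- all_sig & same_dir
  res <- data.frame(gene_id = ids[keep],
                    direction = ifelse(sgn[keep, 1] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  class(res) <- c("CommonDEGSet", "data.frame")
  res
}
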