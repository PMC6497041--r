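#' Median-of-ratios size factors
#'
#' Library-size normalization in the negative-binomial RNA-seq convention:
#' each sample's factor is the median, over genes with no zero count, of the
#' ratio of its count to the gene's geometric mean across samples. Factors
#' are rescaled to have geometric mean 1, so normalized counts stay on the
#' counts scale.
#'
#' @param counts An `ExpressionMatrix` with unit `"counts"` and at least two
#'   samples.
#' @return Named positive numeric vector, one factor per sample, geometric
#'   mean 1.
#' @examples
#' m <- matrix(c(2, 6, 4, 12), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' estimate_size_factors(expression_matrix(m, "mRNA", "counts"))
#' @export
estimate_size_factors <- function(counts) {
  .stopifnot_unit(counts, "counts")
  if (ncol(counts) < 2) stop("need at least two samples")
  x <- unclass(counts)
  zero_free <- rowSums(x == 0) == 0
  if (!any(zero_free)) {
    stop("no gene has all-positive counts; cannot form the geometric-mean ",
         "reference (pseudo-reference fallback is deliberately not applied)")
  }
  lx <- log(x[zero_free, , drop = FALSE])
  ref <- rowMeans(lx)
  sf <- exp(apply(lx - ref, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Convert raw counts to FPKM
#'
#' `fpkm[g, s] = counts[g, s] * 1e9 / (length[g] * total_counts[s])`, i.e.
#' fragments per kilobase of transcript per million mapped fragments, using
#' each sample's raw column total as the library size.
#'
#' @param counts An `ExpressionMatrix` with unit `"counts"`.
#' @param lengths Named vector of gene lengths in bp covering every gene in
#'   `counts`.
#' @return An `ExpressionMatrix` with unit `"fpkm"`.
#' @export
compute_fpkm <- function(counts, lengths) {
  .stopifnot_unit(counts, "counts")
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss)) stop("missing gene length for: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("per-sample total counts must be positive")
  len <- as.numeric(lengths[rownames(counts)])
  vals <- unclass(counts) * 1e9 / (len %o% tot)
  expression_matrix(vals, gene_class = gene_class(counts), unit = "fpkm")
}

#' Log2 normalized expression
#'
#' Divides counts by size factors (median-of-ratios unless supplied) and
#' returns `log2(normalized + 1)`. This is the scale on which all pairwise
#' correlations and survival covariates are computed.
#'
#' @param counts An `ExpressionMatrix` with unit `"counts"`.
#' @param size_factors Optional named vector of per-sample factors; computed
#'   by [estimate_size_factors()] when `NULL`.
#' @return An `ExpressionMatrix` with unit `"log2norm"`.
#' @export
normalize_log2 <- function(counts, size_factors = NULL) {
  .stopifnot_unit(counts, "counts")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (!all(colnames(counts) %in% names(size_factors))) {
    stop("size_factors must cover all samples")
  }
  sf <- size_factors[colnames(counts)]
  vals <- log2(sweep(unclass(counts), 2, sf, "/") + 1)
  expression_matrix(vals, gene_class = gene_class(counts), unit = "log2norm")
}
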