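#' Tree-ensemble regulatory importance of TFs for each target gene
#'
#' GENIE3-style scoring: for every target gene, a random forest of
#' regression trees predicts the target's log2-normalized expression from
#' the candidate transcription factors' expression, and each TF's
#' importance is its share of the ensemble's impurity (variance) reduction.
#' To keep the score honest on uninformative targets, the per-target shares
#' are scaled by the forest's out-of-bag R-squared floored at zero, so a
#' target the TFs cannot predict out-of-sample gets importances near zero
#' and the per-target importances always sum to at most 1.
#'
#' Samples are sorted by sample id before fitting, so the result does not
#' depend on the column order of the inputs; with a fixed `seed` the
#' ensemble is fully deterministic.
#'
#' @param tf_expr Numeric matrix, TFs x samples (rownames = TF ids,
#'   colnames = sample ids).
#' @param targets An `ExpressionMatrix` with unit `"log2norm"` (or a plain
#'   named matrix) of candidate target genes over the same samples. Rows
#'   whose id equals a TF id are skipped with a warning.
#' @param n_trees Trees per target ensemble (default 500).
#' @param seed Integer seed.
#' @return Numeric matrix, TFs x targets, entries in \[0, 1\].
#' @export
tree_importance <- function(tf_expr, targets, n_trees = 500, seed = 1) {
  if (!is.matrix(tf_expr) || is.null(rownames(tf_expr)) ||
      is.null(colnames(tf_expr))) {
    stop("`tf_expr` must be a matrix with TF rownames and sample colnames")
  }
  tg <- unclass(targets)
  if (!is.matrix(tg) || is.null(rownames(tg))) {
    stop("`targets` must be a matrix with gene rownames")
  }
  common <- intersect(colnames(tf_expr), colnames(tg))
  if (length(common) < 10) stop("need at least 10 shared samples")
  common <- sort(common)  # canonical sample order
  X <- t(tf_expr[, common, drop = FALSE])
  colnames(X) <- rownames(tf_expr)
  overlap <- intersect(rownames(tg), rownames(tf_expr))
  if (length(overlap)) {
    warning("skipping target(s) that are themselves TFs: ",
            paste(overlap, collapse = ", "))
    tg <- tg[!rownames(tg) %in% overlap, , drop = FALSE]
  }
  imp <- matrix(0, nrow(tf_expr), nrow(tg),
                dimnames = list(rownames(tf_expr), rownames(tg)))
  for (j in seq_len(nrow(tg))) {
    y <- tg[j, common]
    if (stats::sd(y) == 0) next
    y <- (y - mean(y)) / stats::sd(y)  # affine invariance by construction
    df <- data.frame(.y = y, X, check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = n_trees, mtry = ncol(X), min.node.size = 5,
      importance = "impurity", seed = seed + j, num.threads = 1,
      verbose = FALSE)
    share <- pmax(fit$variable.importance, 0)
    tot <- sum(share)
    if (tot > 0) share <- share / tot else share[] <- 0
    r2 <- max(0, fit$r.squared)
    imp[, j] <- share[colnames(X)] * r2
  }
  imp
}

#' Build TF regulons from importance and positive correlation
#'
#' Retains a (TF, target) link when the tree-ensemble importance exceeds
#' `importance_cutoff` and the Spearman correlation between the TF and the
#' target exceeds `rho_cutoff` (strict `>` in both cases); the correlation
#' filter discards repression-like and spurious negative links.
#'
#' @param importance TFs x targets matrix from [tree_importance()].
#' @param tf_expr,targets The matrices used to compute `importance`.
#' @param importance_cutoff Importance threshold (default 0.005).
#' @param rho_cutoff Spearman threshold (default 0.03; permissive by
#'   design, any positive association passes).
#' @return A `data.frame` with columns `tf`, `target`, `importance`,
#'   `rho`, `retained`; the retained rows per TF form that TF's regulon.
#' @export
build_regulon <- function(importance, tf_expr, targets,
                          importance_cutoff = 0.005, rho_cutoff = 0.03) {
  tg <- unclass(targets)
  common <- sort(intersect(colnames(tf_expr), colnames(tg)))
  tfs <- rownames(importance)
  tgt <- colnames(importance)
  rho <- stats::cor(t(tf_expr[tfs, common, drop = FALSE]),
                    t(tg[tgt, common, drop = FALSE]), method = "spearman")
  res <- data.frame(
    tf = rep(tfs, times = length(tgt)),
    target = rep(tgt, each = length(tfs)),
    importance = as.vector(importance),
    rho = as.vector(rho),
    stringsAsFactors = FALSE)
  res$retained <- res$importance > importance_cutoff & res$rho > rho_cutoff
  res <- res[order(res$tf, -res$importance, res$target), , drop = FALSE]
  rownames(res) <- NULL
  res
}
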