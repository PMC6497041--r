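#' Co-expression screen for candidate lncRNA-mRNA pairs
#'
#' Pearson correlation between every differentially expressed lncRNA and
#' mRNA on log2-normalized expression over a shared sample set, with a
#' two-sided p-value from the t transform on n - 2 degrees of freedom. A
#' pair is retained when `r > r_threshold` (signed, strict: strongly
#' anti-correlated pairs are not ceRNA candidates) and `p < p_threshold`.
#'
#' @param lnc,mrna `ExpressionMatrix` objects with unit `"log2norm"` sharing
#'   the same samples (any order).
#' @param r_threshold Correlation cutoff (strict `>`, default 0.8).
#' @param p_threshold P-value cutoff (strict `<`, default 0.05).
#' @return A `data.frame` with columns `lncrna_id`, `mrna_id`, `r`,
#'   `pvalue`, retained pairs only.
#' @export
correlate_pairs <- function(lnc, mrna, r_threshold = 0.8, p_threshold = 0.05) {
  .stopifnot_unit(lnc, "log2norm")
  .stopifnot_unit(mrna, "log2norm")
  common <- intersect(colnames(lnc), colnames(mrna))
  if (length(common) < 3) stop("need at least 3 shared samples")
  A <- unclass(lnc)[, common, drop = FALSE]
  B <- unclass(mrna)[, common, drop = FALSE]
  n <- length(common)
  sd0a <- apply(A, 1, stats::sd) == 0
  sd0b <- apply(B, 1, stats::sd) == 0
  if (any(sd0a) || any(sd0b)) {
    warning("skipping zero-variance gene(s): ",
            paste(c(rownames(A)[sd0a], rownames(B)[sd0b]), collapse = ", "))
    A <- A[!sd0a, , drop = FALSE]
    B <- B[!sd0b, , drop = FALSE]
  }
  if (nrow(A) == 0 || nrow(B) == 0) {
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      r = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  r <- stats::cor(t(A), t(B))  # lnc x mrna
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  keep <- which(r > r_threshold & p < p_threshold, arr.ind = TRUE)
  res <- data.frame(lncrna_id = rownames(A)[keep[, 1]],
                    mrna_id = rownames(B)[keep[, 2]],
                    r = r[keep],
                    pvalue = p[keep],
                    stringsAsFactors = FALSE)
  res <- res[order(res$lncrna_id, res$mrna_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Hypergeometric shared-miRNA enrichment test
#'
#' Tests whether an mRNA and a lncRNA share more targeting miRNAs than
#' expected by chance. With `N` the size of the miRNA universe, `K` the
#' number of miRNAs targeting the mRNA, `n` the number targeting the
#' lncRNA and `c` the observed overlap, the upper-tail probability is
#' \deqn{P = \sum_{i=c}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}}
#' accumulated in log-gamma space for numerical stability.
#'
#' @param mrna_targeting,lnc_targeting Character vectors of miRNA ids
#'   targeting the mRNA / the lncRNA; must be subsets of `universe`.
#' @param universe Character vector: all candidate miRNA ids.
#' @return List with elements `c` (overlap size), `pvalue`, `N`, `K`, `n`,
#'   and `shared` (the overlapping ids).
#' @examples
#' shared_mirna_test(paste0("m", 1:4), paste0("m", c(1:3, 9, 10)),
#'                   paste0("m", 1:10))  # P = 66/252
#' @export
shared_mirna_test <- function(mrna_targeting, lnc_targeting, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("miRNA universe is empty")
  mrna_targeting <- unique(mrna_targeting)
  lnc_targeting <- unique(lnc_targeting)
  out1 <- setdiff(mrna_targeting, universe)
  out2 <- setdiff(lnc_targeting, universe)
  if (length(out1) || length(out2)) {
    stop("miRNA(s) outside the universe: ",
         paste(c(out1, out2), collapse = ", "))
  }
  N <- length(universe)
  K <- length(mrna_targeting)
  n <- length(lnc_targeting)
  shared <- intersect(mrna_targeting, lnc_targeting)
  cc <- length(shared)
  i <- seq(cc, min(K, n))
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  p <- min(sum(exp(logp)), 1)
  list(c = cc, pvalue = p, N = N, K = K, n = n,
       shared = sort(shared))
}

#' Assemble the lncRNA-miRNA-mRNA ceRNA network
#'
#' For each co-expression-retained lncRNA-mRNA pair, runs the shared-miRNA
#' hypergeometric test against the universe of differentially expressed
#' miRNAs that have at least one interaction (after restricting the
#' interaction table to DE genes), applies BH correction across all tested
#' pairs, and keeps modules with `fdr < module_fdr` and at least
#' `min_shared` shared miRNAs. Each kept module contributes one
#' lncRNA-miRNA and one miRNA-mRNA edge per shared miRNA; edges are
#' deduplicated across modules.
#'
#' @param degs Named list of `CommonDEGSet`s with elements `mRNA`, `lncRNA`,
#'   `miRNA`.
#' @param interactions An `InteractionTable`.
#' @param correlations Retained pairs from [correlate_pairs()].
#' @param module_fdr BH FDR cutoff for modules (strict `<`, default 0.05).
#' @param min_shared Minimum shared-miRNA count (default 1).
#' @return List with `modules` (a `data.frame`, one row per kept module:
#'   `module_id`, `lncrna_id`, `mrna_id`, `N`, `K`, `n`, `c`,
#'   `shared_mirnas` (semicolon-joined), `pvalue`, `fdr`, `r`) and
#'   `network` (list of `nodes` and `edges` data frames).
#' @export
build_cerna_network <- function(degs, interactions, correlations,
                                module_fdr = 0.05, min_shared = 1) {
  for (cls in c("mRNA", "lncRNA", "miRNA")) {
    if (is.null(degs[[cls]])) stop("`degs` must contain element '", cls, "'")
  }
  de_ids <- lapply(degs, function(d) d$gene_id)
  it <- as.data.frame(interactions)
  it <- it[it$mirna_id %in% de_ids$miRNA &
             ((it$target_class == "mRNA" & it$target_id %in% de_ids$mRNA) |
              (it$target_class == "lncRNA" & it$target_id %in% de_ids$lncRNA)), ,
           drop = FALSE]
  universe <- sort(unique(it$mirna_id))
  if (length(universe) == 0) {
    stop("empty miRNA universe: no DE miRNA has an interaction with a DE target")
  }
  targets_of <- split(it$mirna_id, it$target_id)

  empty_modules <- data.frame(
    module_id = character(), lncrna_id = character(), mrna_id = character(),
    N = integer(), K = integer(), n = integer(), c = integer(),
    shared_mirnas = character(), pvalue = numeric(), fdr = numeric(),
    r = numeric(), stringsAsFactors = FALSE)
  empty_net <- list(
    nodes = data.frame(id = character(), class = character(),
                       direction = character(), stringsAsFactors = FALSE),
    edges = data.frame(source = character(), target = character(),
                       edge_type = character(), module_id = character(),
                       stringsAsFactors = FALSE))
  if (nrow(correlations) == 0) {
    return(list(modules = empty_modules, network = empty_net))
  }

  tests <- vector("list", nrow(correlations))
  for (i in seq_len(nrow(correlations))) {
    lnc <- correlations$lncrna_id[i]
    mr <- correlations$mrna_id[i]
    ht <- shared_mirna_test(targets_of[[mr]] %||% character(),
                            targets_of[[lnc]] %||% character(),
                            universe)
    tests[[i]] <- data.frame(
      lncrna_id = lnc, mrna_id = mr, N = ht$N, K = ht$K, n = ht$n, c = ht$c,
      shared_mirnas = paste(ht$shared, collapse = ";"),
      pvalue = ht$pvalue, r = correlations$r[i], stringsAsFactors = FALSE)
  }
  mod <- do.call(rbind, tests)
  mod$fdr <- bh_adjust(mod$pvalue)
  mod <- mod[mod$fdr < module_fdr & mod$c >= min_shared, , drop = FALSE]
  mod <- mod[order(mod$lncrna_id, mod$mrna_id), , drop = FALSE]
  if (nrow(mod) == 0) {
    return(list(modules = empty_modules, network = empty_net))
  }
  mod$module_id <- sprintf("M%03d", seq_len(nrow(mod)))
  mod <- mod[, c("module_id", "lncrna_id", "mrna_id", "N", "K", "n", "c",
                 "shared_mirnas", "pvalue", "fdr", "r")]
  rownames(mod) <- NULL

  edge_rows <- list()
  for (i in seq_len(nrow(mod))) {
    sh <- strsplit(mod$shared_mirnas[i], ";", fixed = TRUE)[[1]]
    sh <- sh[nzchar(sh)]
    if (!length(sh)) next
    edge_rows[[i]] <- rbind(
      data.frame(source = mod$lncrna_id[i], target = sh,
                 edge_type = "lncRNA-miRNA", module_id = mod$module_id[i],
                 stringsAsFactors = FALSE),
      data.frame(source = sh, target = mod$mrna_id[i],
                 edge_type = "miRNA-mRNA", module_id = mod$module_id[i],
                 stringsAsFactors = FALSE))
  }
  edges <- do.call(rbind, edge_rows)
  key <- paste(edges$source, edges$target, edges$edge_type, sep = "\r")
  # deduplicate across modules; keep all originating module ids on the edge
  mods_per_edge <- tapply(edges$module_id, key,
                          function(z) paste(sort(unique(z)), collapse = ";"))
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges$module_id <- as.character(mods_per_edge[paste(edges$source,
                                                      edges$target,
                                                      edges$edge_type,
                                                      sep = "\r")])
  edges <- edges[order(edges$edge_type, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  dir_of <- function(cls) {
    stats::setNames(degs[[cls]]$direction, degs[[cls]]$gene_id)
  }
  node_ids <- unique(c(mod$lncrna_id,
                       unlist(strsplit(mod$shared_mirnas, ";", fixed = TRUE)),
                       mod$mrna_id))
  node_ids <- node_ids[nzchar(node_ids)]
  cls_map <- c(stats::setNames(rep("lncRNA", length(de_ids$lncRNA)), de_ids$lncRNA),
               stats::setNames(rep("mRNA", length(de_ids$mRNA)), de_ids$mRNA),
               stats::setNames(rep("miRNA", length(de_ids$miRNA)), de_ids$miRNA))
  dir_map <- c(dir_of("lncRNA"), dir_of("mRNA"), dir_of("miRNA"))
  nodes <- data.frame(id = sort(node_ids),
                      class = as.character(cls_map[sort(node_ids)]),
                      direction = as.character(dir_map[sort(node_ids)]),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  list(modules = mod, network = list(nodes = nodes, edges = edges))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank network nodes by degree
#'
#' Degree is the number of incident (deduplicated) edges. Ordering is by
#' decreasing degree with lexicographic tie-break on the node id, so the
#' ranking is deterministic.
#'
#' @param network The `network` element returned by [build_cerna_network()].
#' @return A `data.frame` with columns `id`, `class`, `degree`, sorted.
#' @export
degree_ranking <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  if (is.null(nodes) || nrow(nodes) == 0) {
    return(data.frame(id = character(), class = character(),
                      degree = integer(), stringsAsFactors = FALSE))
  }
  inc <- table(factor(c(edges$source, edges$target), levels = nodes$id))
  res <- data.frame(id = nodes$id, class = nodes$class,
                    degree = as.integer(inc[nodes$id]),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$degree, res$id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
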