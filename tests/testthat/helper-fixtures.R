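# Small cohort used where full paper-scale sampling is unnecessary.
small_config <- function(seed = 1, n_planted_triplets = 3, ...) {
  sim_config(n_normal = 20, n_t1 = 18, n_t2 = 18, n_t3 = 15, n_t4 = 15,
             n_mrna = 60, n_lncrna = 30, n_mirna = 20,
             n_de_mrna = 8, n_de_lncrna = 6, n_de_mirna = 8,
             n_planted_triplets = n_planted_triplets, seed = seed, ...)
}

# Expression matrix built from explicit values.
make_em <- function(values, gene_class = "mRNA", unit = "counts",
                    genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, gene_class = gene_class, unit = unit)
}

# Minimal sample table: n1 normal then n2 tumor samples of one stage.
make_samples <- function(n_normal, n_tumor, stage = "T1",
                         ids = NULL) {
  if (is.null(ids)) {
    ids <- c(sprintf("n%d", seq_len(n_normal)),
             sprintf("t%d", seq_len(n_tumor)))
  }
  validate_sample_table(data.frame(
    sample_id = ids,
    condition = rep(c("normal", "tumor"), c(n_normal, n_tumor)),
    stage = c(rep(NA_character_, n_normal), rep(stage, n_tumor)),
    os_time = NA_real_, os_event = NA_integer_,
    stringsAsFactors = FALSE))
}

# Brute-force BH step-up: sort, p*m/rank, cumulative min from the largest
# rank, unsort. Independent oracle for bh_adjust().
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o] * m / seq_len(m)
  ps <- rev(cummin(rev(ps)))
  ps <- pmin(ps, 1)
  out <- numeric(m)
  out[o] <- ps
  out
}

# Exhaustive hypergeometric upper tail by direct pmf enumeration.
hyper_tail_brute <- function(N, K, n, c) {
  i <- c:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# One planted triplet: pair (l1, m1) shares 5 miRNAs; 15 other DE miRNAs
# interact with a decoy DE mRNA so the universe is larger than the sets.
isolated_module_fixture <- function() {
  sh <- sprintf("mir%02d", 1:5)
  others <- sprintf("mir%02d", 6:20)
  degs <- list(
    mRNA = structure(data.frame(gene_id = c("m1", "m2"),
                                direction = c("down", "up"),
                                stringsAsFactors = FALSE),
                     class = c("CommonDEGSet", "data.frame")),
    lncRNA = structure(data.frame(gene_id = "l1", direction = "down",
                                  stringsAsFactors = FALSE),
                       class = c("CommonDEGSet", "data.frame")),
    miRNA = structure(data.frame(gene_id = c(sh, others),
                                 direction = "up",
                                 stringsAsFactors = FALSE),
                      class = c("CommonDEGSet", "data.frame")))
  inter <- validate_interactions(data.frame(
    mirna_id = c(sh, sh, others),
    target_id = c(rep("l1", 5), rep("m1", 5), rep("m2", 15)),
    target_class = c(rep("lncRNA", 5), rep("mRNA", 20)),
    source = "fixture", stringsAsFactors = FALSE))
  corr <- data.frame(lncrna_id = "l1", mrna_id = "m1", r = 0.95,
                     pvalue = 1e-8, stringsAsFactors = FALSE)
  list(degs = degs, interactions = inter, correlations = corr)
}
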