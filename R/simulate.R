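#' Configuration for the synthetic ceRNA cohort
#'
#' Defaults mirror the sample design of a TCGA-style lung adenocarcinoma
#' series: 59 normal and 510 tumor samples with stages T1:T2:T3:T4 split
#' 168:276:47:19, three expression layers (mRNA, lncRNA, miRNA) at
#' desk-scale gene counts, a bipartite miRNA-target graph, and eight
#' planted ceRNA triplets: co-expressed lncRNA-mRNA pairs sharing five
#' targeting miRNAs each, whose joint latent factor also drives
#' proportional-hazards survival. The full sample design is kept because
#' the smallest stage's size bounds the power of the four-way common-DEG
#' intersection; only the gene space is scaled down.
#'
#' @param n_normal,n_t1,n_t2,n_t3,n_t4 Sample counts per group.
#' @param n_mrna,n_lncrna,n_mirna Gene counts per class.
#' @param n_de_mrna,n_de_lncrna,n_de_mirna Truly differential genes per
#'   class (planted triplet members are drawn from these).
#' @param n_planted_triplets Number of planted lncRNA-mRNA-miRNA-set
#'   triplets (>= 0).
#' @param planted_log2fc Absolute log2 fold change of DE genes, identical
#'   in direction across all four tumor stages (default 2).
#' @param nb_dispersion Negative-binomial dispersion (default 0.05, in the
#'   typical bulk RNA-seq range for moderately-to-highly expressed genes;
#'   the planted pairs' extra latent variance comes on top of this).
#' @param latent_corr Target log-scale Pearson correlation of planted
#'   lncRNA-mRNA pairs, in (0, 1) (default 0.9).
#' @param shared_mirnas_per_triplet Shared miRNAs planted per triplet
#'   (default 5).
#' @param background_edge_prob Bernoulli probability of a background
#'   miRNA-target edge (default 0.02).
#' @param survival_beta Log hazard ratio per standard deviation of the
#'   first planted module's latent score (default 0.8).
#' @param baseline_hazard Baseline exponential hazard per day (default
#'   1/730, i.e. a two-year median survival).
#' @param censor_rate Fraction of tumor samples administratively censored,
#'   in \[0, 1) (default 0.3).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_normal = 59, n_t1 = 168, n_t2 = 276, n_t3 = 47,
                       n_t4 = 19,
                       n_mrna = 300, n_lncrna = 100, n_mirna = 60,
                       n_de_mrna = 30, n_de_lncrna = 12, n_de_mirna = 15,
                       n_planted_triplets = 8, planted_log2fc = 2,
                       nb_dispersion = 0.05, latent_corr = 0.9,
                       shared_mirnas_per_triplet = 5,
                       background_edge_prob = 0.02,
                       survival_beta = 0.8, baseline_hazard = 1 / 730,
                       censor_rate = 0.3, seed = 1) {
  cfg <- list(n_normal = n_normal, n_t1 = n_t1, n_t2 = n_t2, n_t3 = n_t3,
              n_t4 = n_t4, n_mrna = n_mrna, n_lncrna = n_lncrna,
              n_mirna = n_mirna, n_de_mrna = n_de_mrna,
              n_de_lncrna = n_de_lncrna, n_de_mirna = n_de_mirna,
              n_planted_triplets = n_planted_triplets,
              planted_log2fc = planted_log2fc,
              nb_dispersion = nb_dispersion, latent_corr = latent_corr,
              shared_mirnas_per_triplet = shared_mirnas_per_triplet,
              background_edge_prob = background_edge_prob,
              survival_beta = survival_beta,
              baseline_hazard = baseline_hazard,
              censor_rate = censor_rate, seed = seed)
  counts <- cfg[c("n_normal", "n_t1", "n_t2", "n_t3", "n_t4", "n_mrna",
                  "n_lncrna", "n_mirna")]
  if (any(unlist(counts) < 1)) stop("sample and gene counts must be >= 1")
  if (n_planted_triplets < 0) stop("n_planted_triplets must be >= 0")
  if (!(latent_corr > 0 && latent_corr < 1)) {
    stop("latent_corr must lie strictly in (0, 1)")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (!(censor_rate >= 0 && censor_rate < 1)) {
    stop("censor_rate must lie in [0, 1)")
  }
  if (n_planted_triplets > n_de_lncrna || n_planted_triplets > n_de_mrna) {
    stop("more planted triplets than available DE lncRNAs/mRNAs")
  }
  if (n_de_mrna > n_mrna || n_de_lncrna > n_lncrna || n_de_mirna > n_mirna) {
    stop("more DE genes requested than genes in a class")
  }
  if (n_planted_triplets > 0 && shared_mirnas_per_triplet > n_de_mirna) {
    stop("shared_mirnas_per_triplet exceeds the DE miRNA pool")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a tumor/normal cohort with planted ceRNA triplets
#'
#' Counts are negative-binomial around per-gene base means (log-uniform
#' between 5 and 2000) times a per-sample sequencing-depth factor.
#' Differential genes have their tumor mean shifted by `planted_log2fc` in
#' a fixed direction across all four stages. Each planted lncRNA-mRNA pair
#' additionally shares a per-sample standard-normal latent factor that
#' multiplies both genes' means on the log scale; the factor loading is
#' chosen from `latent_corr` and the genes' negative-binomial log-scale
#' noise so that the expected log-expression correlation matches the
#' target. The interaction graph contains the planted shared miRNA edges
#' (miRNA -> lncRNA and miRNA -> mRNA) plus independent Bernoulli
#' background edges. Tumor survival is exponential with hazard
#' `baseline_hazard * exp(survival_beta * score)`, where `score` is the
#' standardized latent factor of the first planted triplet, with
#' administrative censoring at the `1 - censor_rate` quantile of the
#' simulated event times.
#'
#' All draws come from R's default Mersenne-Twister generator seeded with
#' `config$seed`, so a given seed reproduces the cohort exactly.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort` with elements `counts` (list of
#'   three `ExpressionMatrix` objects: `mRNA`, `lncRNA`, `miRNA`),
#'   `samples` (`SampleTable`), `lengths` (named vector),
#'   `interactions` (`InteractionTable`) and `truth` (`ground_truth`: the
#'   planted triplets, per-class DE genes with direction, `survival_beta`
#'   and the per-tumor-sample module score).
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(config$seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  n_tumor <- config$n_t1 + config$n_t2 + config$n_t3 + config$n_t4
  n_samp <- config$n_normal + n_tumor
  sample_ids <- c(sprintf("N%03d", seq_len(config$n_normal)),
                  sprintf("T%03d", seq_len(n_tumor)))
  stage <- c(rep(NA_character_, config$n_normal),
             rep(paste0("T", 1:4),
                 c(config$n_t1, config$n_t2, config$n_t3, config$n_t4)))
  is_tumor <- !is.na(stage)

  gene_ids <- list(
    mRNA = sprintf("MRNA%04d", seq_len(config$n_mrna)),
    lncRNA = sprintf("LNC%04d", seq_len(config$n_lncrna)),
    miRNA = sprintf("MIR%04d", seq_len(config$n_mirna)))

  lengths <- c(
    stats::setNames(sample(500:5000, config$n_mrna, replace = TRUE),
                    gene_ids$mRNA),
    stats::setNames(sample(300:3000, config$n_lncrna, replace = TRUE),
                    gene_ids$lncRNA),
    stats::setNames(sample(60:120, config$n_mirna, replace = TRUE),
                    gene_ids$miRNA))

  # truly differential genes and their directions
  de <- list(
    mRNA = sort(sample(gene_ids$mRNA, config$n_de_mrna)),
    lncRNA = sort(sample(gene_ids$lncRNA, config$n_de_lncrna)),
    miRNA = sort(sample(gene_ids$miRNA, config$n_de_mirna)))
  dir_of <- lapply(de, function(ids) {
    stats::setNames(sample(c("up", "down"), length(ids), replace = TRUE), ids)
  })

  # planted triplets: pairs drawn from the DE lncRNA/mRNA pools, both
  # members forced to the same direction so the pair co-expresses positively
  npl <- config$n_planted_triplets
  planted_lnc <- if (npl) de$lncRNA[seq_len(npl)] else character()
  planted_mrna <- if (npl) de$mRNA[seq_len(npl)] else character()
  shared_sets <- lapply(seq_len(npl), function(i) {
    sort(sample(de$miRNA, config$shared_mirnas_per_triplet))
  })
  if (npl) {
    pair_dir <- sample(c("up", "down"), npl, replace = TRUE)
    dir_of$lncRNA[planted_lnc] <- pair_dir
    dir_of$mRNA[planted_mrna] <- pair_dir
  }

  # latent co-expression factors, one per triplet and sample
  latent <- if (npl) {
    matrix(stats::rnorm(npl * n_samp), npl, n_samp)
  } else matrix(numeric(), 0, n_samp)

  depth <- exp(stats::rnorm(n_samp, 0, 0.2))
  disp <- config$nb_dispersion
  rc <- config$latent_corr

  sim_class <- function(cls) {
    ids <- gene_ids[[cls]]
    ng <- length(ids)
    base <- exp(stats::runif(ng, log(5), log(2000)))
    names(base) <- ids
    planted_here <- switch(cls, lncRNA = planted_lnc, mRNA = planted_mrna,
                           character())
    # planted genes kept well expressed so correlation is not shot-noise
    # limited and the abundance filter never removes them
    base[planted_here] <- stats::runif(length(planted_here), 200, 800)
    lfc <- stats::setNames(rep(0, ng), ids)
    lfc[de[[cls]]] <- ifelse(dir_of[[cls]][de[[cls]]] == "up",
                             config$planted_log2fc, -config$planted_log2fc)
    mu <- outer(base, rep(1, n_samp))
    mu <- mu * 2^(outer(lfc, as.numeric(is_tumor)))
    if (length(planted_here)) {
      for (i in seq_along(planted_here)) {
        g <- planted_here[i]
        # loading chosen so corr(log expr) within a pair ~ latent_corr:
        # NB log-scale noise variance is about 1/mu + dispersion
        sig2 <- 1 / base[g] + disp
        a <- sqrt(rc / (1 - rc) * sig2)
        mu[g, ] <- mu[g, ] * exp(a * latent[i, ] - a^2 / 2)
      }
    }
    mu <- sweep(mu, 2, depth, "*")
    cnts <- matrix(stats::rnbinom(ng * n_samp, mu = as.vector(mu),
                                  size = 1 / disp),
                   ng, n_samp, dimnames = list(ids, sample_ids))
    expression_matrix(cnts, gene_class = cls, unit = "counts")
  }
  counts <- list(mRNA = sim_class("mRNA"), lncRNA = sim_class("lncRNA"),
                 miRNA = sim_class("miRNA"))

  # interaction graph: planted shared edges + Bernoulli background
  all_targets <- c(gene_ids$mRNA, gene_ids$lncRNA)
  target_class <- rep(c("mRNA", "lncRNA"),
                      c(config$n_mrna, config$n_lncrna))
  bg <- which(matrix(stats::runif(config$n_mirna * length(all_targets)) <
                       config$background_edge_prob,
                     config$n_mirna, length(all_targets)),
              arr.ind = TRUE)
  inter <- data.frame(
    mirna_id = gene_ids$miRNA[bg[, 1]],
    target_id = all_targets[bg[, 2]],
    target_class = target_class[bg[, 2]],
    source = rep("background", nrow(bg)),
    stringsAsFactors = FALSE)
  if (npl) {
    pl <- do.call(rbind, lapply(seq_len(npl), function(i) {
      sh <- shared_sets[[i]]
      rbind(data.frame(mirna_id = sh, target_id = planted_lnc[i],
                       target_class = "lncRNA", source = "planted",
                       stringsAsFactors = FALSE),
            data.frame(mirna_id = sh, target_id = planted_mrna[i],
                       target_class = "mRNA", source = "planted",
                       stringsAsFactors = FALSE))
    }))
    inter <- rbind(pl, inter)
  }
  inter <- inter[order(inter$mirna_id, inter$target_id), , drop = FALSE]
  rownames(inter) <- NULL
  inter <- suppressMessages(validate_interactions(inter))

  # survival: hazard follows the first planted module's latent factor
  score <- if (npl) {
    s <- latent[1, is_tumor]
    (s - mean(s)) / stats::sd(s)
  } else rep(0, n_tumor)
  names(score) <- sample_ids[is_tumor]
  hazard <- config$baseline_hazard * exp(config$survival_beta * score)
  ev_time <- stats::rexp(n_tumor, rate = hazard)
  cens_at <- if (config$censor_rate > 0) {
    stats::quantile(ev_time, 1 - config$censor_rate, names = FALSE)
  } else Inf
  os_time <- pmin(ev_time, cens_at)
  os_event <- as.integer(ev_time <= cens_at)
  os_time <- round(pmax(os_time, 0.5), 1)

  samples <- validate_sample_table(data.frame(
    sample_id = sample_ids,
    condition = ifelse(is_tumor, "tumor", "normal"),
    stage = stage,
    os_time = c(rep(NA_real_, config$n_normal), os_time),
    os_event = c(rep(NA_integer_, config$n_normal), os_event),
    stringsAsFactors = FALSE))

  truth <- structure(list(
    planted_triplets = data.frame(
      lncrna_id = planted_lnc,
      mrna_id = planted_mrna,
      shared_mirnas = vapply(shared_sets, paste, character(1),
                             collapse = ";"),
      stringsAsFactors = FALSE),
    de_genes = lapply(dir_of, function(d) {
      data.frame(gene_id = names(d), direction = unname(d),
                 stringsAsFactors = FALSE)
    }),
    survival_beta = config$survival_beta,
    module_score = score), class = "ground_truth")

  structure(list(counts = counts, samples = samples, lengths = lengths,
                 interactions = inter, truth = truth, config = config),
            class = "sim_cohort")
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Writes `mrna_counts.tsv`, `lncrna_counts.tsv`, `mirna_counts.tsv`,
#' `samples.tsv`, `gene_lengths.tsv`, `interactions.tsv` and
#' `ground_truth.tsv` (the planted triplets).
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "sim_cohort")) stop("`cohort` must be a sim_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$counts$mRNA, file.path(dir, "mrna_counts.tsv"))
  write_expression_matrix(cohort$counts$lncRNA,
                          file.path(dir, "lncrna_counts.tsv"))
  write_expression_matrix(cohort$counts$miRNA,
                          file.path(dir, "mirna_counts.tsv"))
  write_sample_table(cohort$samples, file.path(dir, "samples.tsv"))
  write_gene_lengths(cohort$lengths, file.path(dir, "gene_lengths.tsv"))
  write_interactions(cohort$interactions, file.path(dir, "interactions.tsv"))
  utils::write.table(cohort$truth$planted_triplets,
                     file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Compare reported modules against the planted ground truth
#'
#' Sensitivity is the fraction of planted lncRNA-mRNA pairs that appear in
#' the reported module list; the false-discovery proportion is the fraction
#' of reported pairs that were not planted (0 when nothing is reported).
#'
#' @param truth A `ground_truth` object.
#' @param modules Module table from [build_cerna_network()] (or any data
#'   frame with `lncrna_id` and `mrna_id` columns).
#' @return List with `sensitivity`, `fdp`, `n_planted`, `n_reported`,
#'   `n_recovered`.
#' @export
truth_report <- function(truth, modules) {
  if (!inherits(truth, "ground_truth")) stop("`truth` must be a ground_truth")
  planted <- paste(truth$planted_triplets$lncrna_id,
                   truth$planted_triplets$mrna_id, sep = "\r")
  reported <- if (is.null(modules) || nrow(modules) == 0) character() else {
    unique(paste(modules$lncrna_id, modules$mrna_id, sep = "\r"))
  }
  n_rec <- sum(planted %in% reported)
  sens <- if (length(planted)) n_rec / length(planted) else 0
  fdp <- if (length(reported)) sum(!reported %in% planted) / length(reported)
         else 0
  list(sensitivity = sens, fdp = fdp, n_planted = length(planted),
       n_reported = length(reported), n_recovered = n_rec)
}
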