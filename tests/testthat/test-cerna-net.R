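test_that("pair correlation respects the strict signed threshold", {
  # perfectly correlated pair is retained, anti-correlated is not
  x <- c(1, 3, 2, 5, 4, 6)
  lnc <- make_em(rbind(x, -x), gene_class = "lncRNA", unit = "log2norm",
                 genes = c("l1", "l2"))
  mr <- make_em(rbind(x), gene_class = "mRNA", unit = "log2norm",
                genes = "m1")
  got <- correlate_pairs(lnc, mr)
  expect_identical(got$lncrna_id, "l1")
  expect_equal(got$r, 1)

  # r = 0.8 exactly: excluded because the threshold is strict
  lnc2 <- make_em(rbind(c(1, 2, 3, 4)), gene_class = "lncRNA",
                  unit = "log2norm", genes = "l1")
  mr2 <- make_em(rbind(c(1, 2, 4, 3)), gene_class = "mRNA",
                 unit = "log2norm", genes = "m1")
  expect_identical(nrow(correlate_pairs(lnc2, mr2)), 0L)
  # ...but retained once the threshold drops below 0.8
  expect_identical(nrow(correlate_pairs(lnc2, mr2, r_threshold = 0.79,
                                        p_threshold = 1)), 1L)

  # zero-variance genes are skipped with a warning
  lnc3 <- make_em(rbind(x, rep(2, 6)), gene_class = "lncRNA",
                  unit = "log2norm", genes = c("l1", "flat"))
  expect_warning(res3 <- correlate_pairs(lnc3, mr), "flat")
  expect_identical(res3$lncrna_id, "l1")

  expect_error(correlate_pairs(
    make_em(rbind(1:2), "lncRNA", "log2norm"),
    make_em(rbind(1:2), "mRNA", "log2norm")), "3 shared samples")
})

test_that("hypergeometric tail matches enumeration and phyper", {
  u <- paste0("m", 1:10)
  # N=10, K=4, n=5, c=3 -> 66/252
  got <- shared_mirna_test(u[1:4], u[c(1:3, 9, 10)], u)
  expect_identical(got$c, 3L)
  expect_equal(got$pvalue, 66 / 252, tolerance = 1e-14)
  # N=6, K=3, n=3, c=3 -> 1/20
  got2 <- shared_mirna_test(paste0("m", 1:3), paste0("m", 1:3), paste0("m", 1:6))
  expect_equal(got2$pvalue, 1 / 20, tolerance = 1e-14)
  # zero overlap sums the whole support
  got3 <- shared_mirna_test(u[1:4], u[5:8], u)
  expect_equal(got3$pvalue, 1)

  # agreement with the independent distribution implementation
  set.seed(3)
  for (i in 1:40) {
    N <- sample(2:40, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    univ <- paste0("x", seq_len(N))
    A <- sample(univ, K)
    B <- sample(univ, n)
    cc <- length(intersect(A, B))
    expect_equal(shared_mirna_test(A, B, univ)$pvalue,
                 min(1, phyper(cc - 1, K, N - K, n, lower.tail = FALSE)),
                 tolerance = 1e-12)
  }

  expect_error(shared_mirna_test(c("zz"), u[1], u), "outside the universe")
})

test_that("tail probability is nonincreasing in the overlap", {
  for (N in c(10, 15)) {
    for (K in c(2, 3)) {
      for (n in c(4, 6)) {
        ps <- vapply(0:min(K, n), function(cc) {
          univ <- paste0("u", 1:N)
          # realize sets with the exact requested overlap
          A <- univ[seq_len(K)]
          B <- c(univ[seq_len(cc)], rev(univ)[seq_len(n - cc)])
          shared_mirna_test(A, B, univ)$pvalue
        }, numeric(1))
        expect_true(all(diff(ps) <= 1e-12))
      }
    }
  }
})


test_that("an isolated planted triplet yields one module with 2c edges", {
  fx <- isolated_module_fixture()
  net <- build_cerna_network(fx$degs, fx$interactions, fx$correlations)
  expect_identical(nrow(net$modules), 1L)
  mod <- net$modules
  expect_identical(c(mod$N, mod$K, mod$n, mod$c), c(20L, 5L, 5L, 5L))
  expect_equal(mod$pvalue, 1 / choose(20, 5), tolerance = 1e-12)

  nodes <- net$network$nodes
  expect_identical(sum(nodes$class == "lncRNA"), 1L)
  expect_identical(sum(nodes$class == "mRNA"), 1L)
  expect_identical(sum(nodes$class == "miRNA"), 5L)
  expect_identical(nrow(net$network$edges), 10L)  # 2 * c

  rk <- degree_ranking(net$network)
  expect_identical(rk$id[1:2], c("l1", "m1"))  # degree-5 tie, lexicographic
  expect_identical(rk$degree[1:2], c(5L, 5L))
  expect_true(all(rk$degree[rk$class == "miRNA"] == 2L))
})

test_that("network assembly is invariant to input row order", {
  fx <- isolated_module_fixture()
  net1 <- build_cerna_network(fx$degs, fx$interactions, fx$correlations)
  perm_it <- fx$interactions[rev(seq_len(nrow(fx$interactions))), ]
  net2 <- build_cerna_network(fx$degs, validate_interactions(perm_it),
                              fx$correlations)
  expect_equal(net1$network$edges, net2$network$edges)
  expect_equal(net1$modules, net2$modules)
})

test_that("degenerate network inputs are handled", {
  fx <- isolated_module_fixture()
  empty_corr <- fx$correlations[0, ]
  net <- build_cerna_network(fx$degs, fx$interactions, empty_corr)
  expect_identical(nrow(net$modules), 0L)
  expect_identical(nrow(net$network$edges), 0L)
  expect_identical(nrow(degree_ranking(net$network)), 0L)

  no_de_mir <- fx$degs
  no_de_mir$miRNA <- no_de_mir$miRNA[0, ]
  expect_error(build_cerna_network(no_de_mir, fx$interactions,
                                   fx$correlations), "empty miRNA universe")
})

test_that("degree ranking breaks ties lexicographically on a star", {
  net <- list(
    nodes = data.frame(id = c("hub", "a", "b", "c", "d"),
                       class = "miRNA", direction = "up",
                       stringsAsFactors = FALSE),
    edges = data.frame(source = "hub", target = c("a", "b", "c", "d"),
                       edge_type = "x", module_id = "M1",
                       stringsAsFactors = FALSE))
  rk <- degree_ranking(net)
  expect_identical(rk$id, c("hub", "a", "b", "c", "d"))
  expect_identical(rk$degree, c(4L, 1L, 1L, 1L, 1L))
})
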