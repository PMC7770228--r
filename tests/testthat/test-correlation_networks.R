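test_that("a planted perfectly-correlated pair is selected at every timepoint", {
  tensor <- planted_pair_tensor(n_noise = 8L)
  tps <- per_timepoint_networks(tensor, fdr = 0.10)
  expect_length(tps, 12L)
  for (tp in tps) {
    expect_true(any(tp$edges$gene_a == "g01" & tp$edges$gene_b == "g02"),
                info = paste("ZT", tp$timepoint_zt))
    # every selected pair honours the realized BH threshold
    expect_true(all(tp$edges$p <= tp$bh_threshold + 1e-15))
  }
  net <- build_variability_network(tensor)
  expect_true(any(net$edges$gene_a == "g01" & net$edges$gene_b == "g02"))
})

test_that("per-timepoint selection respects the FDR on null data", {
  # mean selected fraction over seeds stays at or below the nominal rate
  fracs <- vapply(1:20, function(s) {
    tensor <- null_tensor(n_genes = 50L, seed = s)
    tps <- per_timepoint_networks(tensor, fdr = 0.10)
    mean(vapply(tps, function(tp) tp$n_selected / tp$n_tested, numeric(1)))
  }, numeric(1))
  expect_lte(mean(fracs), 0.10)
})

test_that("persistence filtering drastically reduces null edges", {
  tot_sel <- 0L; tot_surv <- 0L
  for (s in 1:5) {
    tensor <- null_tensor(n_genes = 60L, seed = 100 + s)
    tps <- per_timepoint_networks(tensor, fdr = 0.10)
    net <- build_variability_network(tensor, fdr = 0.10, k = 4, gaps = 1)
    tot_sel <- tot_sel + max(vapply(tps, function(tp) tp$n_selected,
                                    integer(1)))
    tot_surv <- tot_surv + n_edges(net)
  }
  expect_lt(tot_surv, tot_sel / 10 + 1)
})

test_that("coupling restricted to 2 timepoints yields no persistent edges", {
  coupling <- rep(0, 12); coupling[5:6] <- 0.95
  spec <- synthetic_spec(
    modules = list(list(size = 10L, hvg = FALSE, coupling = coupling,
                        profile = "flat")),
    n_background = 30L)
  sim <- generate_expression(spec, seed = 5)
  net <- build_variability_network(sim$tensor, k = 4, gaps = 1)
  ikey <- paste(net$edges$gene_a, net$edges$gene_b)
  tkey <- paste(sim$truth$true_edges$gene_a, sim$truth$true_edges$gene_b)
  expect_length(intersect(ikey, tkey), 0L)
})

test_that("every surviving edge re-verifies its persistence predicate", {
  spec <- synthetic_spec(n_background = 50L)
  sim <- generate_expression(spec, seed = 2)
  net <- build_variability_network(sim$tensor, k = 4, gaps = 1)
  expect_gt(n_edges(net), 0)
  for (e in seq_len(n_edges(net)))
    expect_true(oracle_persistence(net$support[e, ], 4, 1))
})

test_that("network inference is invariant under gene input order", {
  spec <- synthetic_spec(
    modules = list(list(size = 8L, hvg = FALSE, coupling = rep(0.9, 12),
                        profile = "sin_peak6")),
    n_background = 20L)
  sim <- generate_expression(spec, seed = 6)
  net1 <- build_variability_network(sim$tensor)
  set.seed(1)
  perm <- sample(length(sim$tensor$gene_ids))
  shuffled <- expression_tensor(sim$tensor$values[perm, , ],
                                sim$tensor$gene_ids[perm],
                                sim$tensor$timepoints_zt)
  net2 <- build_variability_network(shuffled)
  expect_identical(net1$edges[c("gene_a", "gene_b")],
                   net2$edges[c("gene_a", "gene_b")])
  expect_identical(net1$support, net2$support)
})

test_that("positive-only mode drops negative-rho support", {
  tensor <- planted_pair_tensor()
  tensor$values[2L, , ] <- -tensor$values[1L, , ]  # perfect anticorrelation
  both <- build_variability_network(tensor)
  pos <- build_variability_network(tensor, positive_only = TRUE)
  key <- function(n) paste(n$edges$gene_a, n$edges$gene_b)
  expect_true("g01 g02" %in% key(both))
  expect_false("g01 g02" %in% key(pos))
})

test_that("averaged network: identical and mirrored profiles are edges", {
  nt <- 12L; ni <- 4L
  zt <- seq(0L, 22L, by = 2L)
  base <- sin(2 * pi * zt / 24)
  set.seed(9)
  vals <- array(rnorm(6 * nt * ni, sd = 0.01), dim = c(6, nt, ni))
  for (i in seq_len(ni)) {
    vals[1, , i] <- vals[1, , i] + base
    vals[2, , i] <- vals[2, , i] + 2 * base + 5   # same profile shape
    vals[3, , i] <- vals[3, , i] + rev(seq_len(nt))  # decreasing
    vals[4, , i] <- vals[4, , i] + seq_len(nt)       # increasing
  }
  tensor <- expression_tensor(vals, sprintf("g%d", 1:6), zt)
  net <- build_averaged_network(tensor, alpha = 0.05)
  key <- paste(net$edges$gene_a, net$edges$gene_b)
  expect_true("g1 g2" %in% key)
  expect_true("g3 g4" %in% key)   # rho = -1, two-sided test keeps it
  r34 <- net$edges$rho[key == "g3 g4"]
  expect_equal(r34, -1)
})

test_that("averaged network on flat noisy profiles is essentially empty", {
  n_edges_total <- sum(vapply(1:5, function(s) {
    set.seed(s)
    vals <- array(rnorm(50 * 12 * 4), dim = c(50, 12, 4))
    tensor <- expression_tensor(vals, sprintf("g%02d", 1:50),
                                seq(0L, 22L, by = 2L))
    n_edges(build_averaged_network(tensor, alpha = 0.05))
  }, numeric(1)))
  expect_lte(n_edges_total, 2)
})

test_that("network overlap counts shared genes and canonical edges", {
  sup1 <- matrix(TRUE, 2, 1)
  a <- coexpression_network(data.frame(gene_a = c("g1", "g2"),
                                       gene_b = c("g2", "g3")),
                            sup1, sup1 * 0.5, 0L)
  b <- coexpression_network(data.frame(gene_a = c("g2", "g4"),
                                       gene_b = c("g3", "g5")),
                            sup1, sup1 * 0.5, 0L)
  ov <- network_overlap(a, b)
  expect_equal(ov$shared_genes, 2L)
  expect_equal(ov$shared_edges, 1L)
  expect_equal(network_overlap(a, a),
               list(shared_genes = 3L, shared_edges = 2L))
  empty <- varnet:::empty_network(0L)
  expect_equal(network_overlap(a, empty),
               list(shared_genes = 0L, shared_edges = 0L))
})

test_that("missing values are handled pair-wise with a joint-observation floor", {
  tensor <- planted_pair_tensor(n_noise = 4L)
  # knock out individuals 1-3 of gene 1 at every timepoint: 11 joint obs remain
  tensor$values[1L, , 1:3] <- NA_real_
  net <- build_variability_network(tensor, n_min = 8L)
  expect_true(any(net$edges$gene_a == "g01" & net$edges$gene_b == "g02"))
  # raising the floor above the available joint observations unscores the pair
  net2 <- build_variability_network(tensor, n_min = 12L)
  expect_false(any(net2$edges$gene_a == "g01" & net2$edges$gene_b == "g02"))
})
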