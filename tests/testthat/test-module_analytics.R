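# 6-edge toy network over two modules with hand-known support masks
analytics_toy <- function() {
  edges <- data.frame(
    gene_a = c("a1", "a1", "a2", "b1", "b1", "a3"),
    gene_b = c("a2", "a3", "a3", "b2", "b3", "b1"))
  sup <- matrix(FALSE, 6, 12)
  sup[1, 1:4] <- TRUE          # a1-a2 at ZT0..6
  sup[2, c(1, 2)] <- TRUE      # a1-a3 at ZT0,2
  sup[3, 2:5] <- TRUE          # a2-a3 at ZT2..8
  sup[4, 7:10] <- TRUE         # b1-b2 at ZT12..18
  sup[5, c(7, 12)] <- TRUE     # b1-b3 at ZT12, ZT22
  sup[6, c(6, 7)] <- TRUE      # a3-b1 (inter-module) at ZT10,12
  net <- toy_network(edges, sup)
  part <- make_partition(c("a1", "a2", "a3", "b1", "b2", "b3"),
                         c(1, 1, 1, 2, 2, 2))
  list(net = net, part = part, sup = sup)
}

test_that("edge-time distribution equals the hand-computed table", {
  toy <- analytics_toy()
  etd <- edge_time_distribution(toy$net, toy$part)
  # module of the a-genes: rows 1-3 of the support matrix (intra only)
  ma <- as.character(toy$part$assignment[["a1"]])
  mb <- as.character(toy$part$assignment[["b1"]])
  expect_equal(unname(etd[ma, ]), unname(colSums(toy$sup[1:3, ])))
  expect_equal(unname(etd[mb, ]), unname(colSums(toy$sup[4:5, ])))
  # the inter-module edge contributes to neither row
  expect_equal(sum(etd), sum(toy$sup[1:5, ]))
  # an edge supported at 4 timepoints contributes exactly 4 detections
  expect_equal(sum(etd[ma, ]) , 4 + 2 + 4)
})

test_that("intra-module detections never exceed total network detections", {
  spec <- synthetic_spec(n_background = 50L)
  sim <- generate_expression(spec, seed = 3)
  net <- build_variability_network(sim$tensor)
  part <- louvain_partition(net, seed = 0)
  etd <- edge_time_distribution(net, part)
  total <- edge_counts_by_timepoint(net)
  expect_true(all(colSums(etd) <= total))
})

test_that("night-edge percentage: all-night, balanced, hand case, undefined", {
  counts <- setNames(rep(0L, 12), seq(0, 22, by = 2))
  night_only <- counts; night_only[8:12] <- 5L
  expect_equal(night_edge_percentage(night_only), 100)
  balanced <- counts; balanced[c(1, 8)] <- 3L
  expect_equal(night_edge_percentage(balanced), 50)
  hand <- counts; hand[1] <- 2L; hand[7] <- 1L  # ZT0 day, ZT12 night
  expect_equal(night_edge_percentage(hand), 100 / 3)
  expect_message(res <- night_edge_percentage(counts), "undefined")
  expect_true(is.na(res))
})

test_that("day-window boundaries are half-open and configurable", {
  counts <- setNames(c(1L, rep(0L, 5), 1L, rep(0L, 5)), seq(0, 22, by = 2))
  # default [0,12): ZT0 day, ZT12 night
  expect_equal(night_edge_percentage(counts), 50)
  # shifted window [2,14): both fall on opposite sides again
  expect_equal(night_edge_percentage(counts, day_window = c(2, 14)), 50)
  # window [0,14): ZT12 becomes day
  expect_equal(night_edge_percentage(counts, day_window = c(0, 14)), 0)
})

test_that("Fisher enrichment equals brute-force hypergeometric summation", {
  # 5-gene module, all in a 5-gene set, background 10: p = 1/C(10,5)
  bg <- sprintf("g%02d", 1:10)
  res <- set_enrichment(bg[1:5], bg[1:5], bg)
  expect_equal(res$overlap, 5L)
  expect_equal(res$p_enrich, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$p_enrich, oracle_hyper_p_enrich(5, 5, 5, 10),
               tolerance = 1e-12)

  # random small tables against the summation oracle
  set.seed(13)
  for (i in 1:25) {
    nbg <- sample(10:50, 1)
    bg <- sprintf("x%03d", seq_len(nbg))
    mod <- sample(bg, sample(2:(nbg / 2), 1))
    gset <- sample(bg, sample(2:(nbg / 2), 1))
    res <- set_enrichment(mod, gset, bg)
    expect_equal(res$p_enrich,
                 oracle_hyper_p_enrich(res$overlap, length(mod),
                                       length(gset), nbg),
                 tolerance = 1e-9, info = paste("table", i))
  }
})

test_that("enrichment conventions: disjoint set, balanced table, subset rule", {
  bg <- sprintf("g%02d", 1:20)
  res <- set_enrichment(bg[1:5], c("zz1", "zz2"), bg)
  expect_equal(res$overlap, 0L)
  expect_equal(res$p_enrich, 1)

  # module matching the background proportion exactly: odds ratio 1
  bal <- set_enrichment(bg[1:10], bg[c(1:5, 11:15)], bg)
  expect_equal(bal$odds_ratio, 1)

  expect_error(set_enrichment(c("not_there"), bg[1:2], bg), "subset")
  expect_error(set_enrichment(bg[1], bg[1], character(0)), "empty background")
})

test_that("averaged-network overlap per module: full, none, fractional", {
  part <- make_partition(sprintf("g%02d", 1:16),
                         c(rep(1, 8), rep(2, 4), rep(3, 4)))
  sup <- matrix(logical(0), 7, 0)
  avg <- coexpression_network(
    data.frame(gene_a = sprintf("g%02d", 1:7), gene_b = rep("g99", 7)),
    sup, matrix(numeric(0), 7, 0), integer(0))
  ov <- averaged_overlap_per_module(part, avg)
  m1 <- ov[ov$size == 8, ]
  expect_equal(m1$n_in_averaged, 7L)
  expect_equal(m1$pct_in_averaged, 87.5)
  expect_equal(ov$pct_in_averaged[ov$size == 4], c(0, 0))
})

test_that("module graph weights equal hand-counted inter-module edges", {
  toy <- analytics_toy()
  mg <- build_module_graph(toy$net, toy$part, min_size = 2L,
                           hvg = c("a1", "a2"))
  expect_equal(nrow(mg$nodes), 2L)
  expect_equal(nrow(mg$edges), 1L)
  expect_equal(mg$edges$weight, 1L)  # single a3-b1 bridge
  ma <- toy$part$assignment[["a1"]]
  expect_equal(mg$nodes$pct_hvg[mg$nodes$module_id == ma], 100 * 2 / 3)
  # modules below min_size are dropped, removing their edges too
  mg5 <- build_module_graph(toy$net, toy$part, min_size = 5L)
  expect_equal(nrow(mg5$nodes), 0L)
  expect_equal(nrow(mg5$edges), 0L)
})

test_that("assortativity: closed form on 4 points, sign, invariances", {
  mg <- structure(list(
    nodes = data.frame(module_id = 1:4, size = 5,
                       attr = c(0.9, 0.8, 0.1, 0.2)),
    edges = data.frame(module_a = c(1L, 3L), module_b = c(2L, 4L),
                       weight = c(1L, 1L))), class = "module_graph")
  # also need a third edge for the df>=1 requirement; closed-form check first
  mg3 <- mg
  mg3$edges <- rbind(mg3$edges, data.frame(module_a = 1L, module_b = 2L,
                                           weight = 1L))
  res <- assortativity_pearson(mg3, "attr")
  # endpoints pair high-high and low-low twice: strong positive correlation
  expect_gt(res$r, 0.9)

  # edges only between high- and low-attribute modules: negative
  mgneg <- mg
  mgneg$edges <- data.frame(module_a = c(1L, 1L, 2L),
                            module_b = c(3L, 4L, 3L), weight = 1L)
  expect_lt(assortativity_pearson(mgneg, "attr")$r, 0)

  # invariance under module relabeling and edge order
  perm <- c(3L, 4L, 1L, 2L)
  mgrel <- mgneg
  mgrel$nodes$module_id <- perm[mgneg$nodes$module_id]
  mgrel$edges$module_a <- perm[mgneg$edges$module_a]
  mgrel$edges$module_b <- perm[mgneg$edges$module_b]
  mgrel$edges <- mgrel$edges[c(3, 1, 2), ]
  expect_equal(assortativity_pearson(mgrel, "attr")$r,
               assortativity_pearson(mgneg, "attr")$r, tolerance = 1e-12)

  # orientation symmetry: r identical when every edge is stated reversed
  mgrev <- mgneg
  mgrev$edges[c("module_a", "module_b")] <- mgneg$edges[c("module_b", "module_a")]
  expect_equal(assortativity_pearson(mgrev, "attr")$r,
               assortativity_pearson(mgneg, "attr")$r, tolerance = 1e-12)

  # constant attribute flagged undefined
  mgconst <- mgneg
  mgconst$nodes$attr <- 1
  expect_message(rc <- assortativity_pearson(mgconst, "attr"), "constant")
  expect_true(is.na(rc$r))
})

test_that("random attributes give near-zero assortativity on a large module graph", {
  set.seed(17)
  n <- 40L
  rs <- vapply(1:20, function(i) {
    edges <- data.frame(module_a = sample(n, 120, replace = TRUE),
                        module_b = sample(n, 120, replace = TRUE))
    edges <- edges[edges$module_a != edges$module_b, ]
    mg <- structure(list(
      nodes = data.frame(module_id = seq_len(n), size = 5,
                         attr = runif(n)),
      edges = cbind(edges, weight = 1L)), class = "module_graph")
    assortativity_pearson(mg, "attr")$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("z-scored profiles have mean 0, sd 1 and preserve shape", {
  tensor <- random_tensor(n_genes = 6L, n_timepoints = 5L, n_individuals = 4L)
  # make gene 2 proportional to gene 1 and gene 6 constant
  tensor$values[2, , ] <- 3 * tensor$values[1, , ] + 7
  tensor$values[6, , ] <- 1
  expect_message(z <- zscore_profiles(tensor), "constant")
  zmat <- as.matrix(z[, grep("^zt_", names(z))])
  rownames(zmat) <- z$gene_id
  expect_equal(unname(rowMeans(zmat)), rep(0, nrow(zmat)), tolerance = 1e-12)
  expect_equal(unname(apply(zmat, 1, sd)), rep(1, nrow(zmat)),
               tolerance = 1e-12)
  expect_equal(zmat["g02", ], zmat["g01", ], tolerance = 1e-12)
  expect_false("g06" %in% z$gene_id)
  # hand case: profile 1,3,5 with sample sd -> z = (-1, 0, 1)
  v <- array(rep(c(1, 3, 5), each = 1), dim = c(1, 3, 1))
  t3 <- expression_tensor(array(rep(c(1, 3, 5), 2), dim = c(1, 3, 2)),
                          "gX", c(0L, 8L, 16L))
  z3 <- zscore_profiles(t3)
  expect_equal(unname(as.numeric(z3[1, c("zt_0", "zt_8", "zt_16")])),
               c(-1, 0, 1))
})

test_that("planted HVG modules separate from non-HVG modules in the summary", {
  spec <- synthetic_spec(n_background = 100L)
  sim <- generate_expression(spec, seed = 1)
  net <- build_variability_network(sim$tensor)
  part <- louvain_partition(net, seed = 0, restarts = 3)
  hvg <- names(sim$truth$hvg)[sim$truth$hvg]
  summ <- module_summary(net, part, hvg = hvg, min_size = 5L)
  expect_gt(nrow(summ), 1)
  expect_true(any(summ$pct_hvg > 80))
  expect_true(any(summ$pct_hvg < 20))
  # the HVG-tier module is significantly enriched against the network genes
  expect_lt(min(summ$hvg_fisher_p[summ$pct_hvg > 80]), 0.01)
})
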