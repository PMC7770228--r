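# Small in-code fixtures shared across test files.

# tensor with given dimensions filled from a seeded normal draw
random_tensor <- function(n_genes = 6L, n_timepoints = 4L,
                          n_individuals = 5L, seed = 42L) {
  set.seed(seed)
  zt <- seq(0L, by = 2L, length.out = n_timepoints)
  expression_tensor(
    array(rnorm(n_genes * n_timepoints * n_individuals),
          dim = c(n_genes, n_timepoints, n_individuals)),
    sprintf("g%02d", seq_len(n_genes)), zt)
}

# tensor of pure i.i.d. noise on the full 12 x 14 study grid
null_tensor <- function(n_genes = 100L, seed = 1L) {
  set.seed(seed)
  expression_tensor(
    array(rnorm(n_genes * 12L * 14L), dim = c(n_genes, 12L, 14L)),
    sprintf("g%03d", seq_len(n_genes)), seq(0L, 22L, by = 2L))
}

# a planted pair perfectly correlated at every timepoint + noise genes
planted_pair_tensor <- function(n_noise = 8L, seed = 7L) {
  set.seed(seed)
  nt <- 12L; ni <- 14L
  vals <- array(rnorm((n_noise + 2L) * nt * ni),
                dim = c(n_noise + 2L, nt, ni))
  vals[2L, , ] <- vals[1L, , ] * 2 + 1  # monotone copy of gene 1
  expression_tensor(vals, sprintf("g%02d", seq_len(n_noise + 2L)),
                    seq(0L, 22L, by = 2L))
}

# hand-built network: edges with explicit support masks on a 12-slot grid
toy_network <- function(edges, support, zt = seq(0L, 22L, by = 2L)) {
  rho <- matrix(NA_real_, nrow(support), ncol(support))
  rho[support] <- 0.9
  coexpression_network(edges, support, rho, zt,
                       provenance = list(route = "variability"))
}

make_partition <- function(genes, modules) {
  module_partition(stats::setNames(as.integer(modules), genes))
}
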