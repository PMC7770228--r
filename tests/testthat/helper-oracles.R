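# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition, by enumeration, so they stay
# independent of the implementation paths they check.

# all permutations of 1..n, built by recursive prefix extension (distinct
# from the package's iterative insertion scheme)
oracle_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- oracle_permutations(n - 1L)
  out <- NULL
  for (first in seq_len(n)) {
    remaining <- setdiff(seq_len(n), first)
    out <- rbind(out, cbind(first, matrix(remaining[sub], nrow(sub))))
  }
  unname(out)
}

# exact two-sided Spearman p by enumerating every ordering of y
oracle_spearman_exact_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- oracle_permutations(length(y))
  null_rho <- apply(perms, 1L, function(pm) cor(rx, ry[pm]))
  mean(abs(null_rho) >= obs - 1e-12)
}

# hand-coded Benjamini-Hochberg step-up rule straight from its definition
oracle_bh_select <- function(p, fdr) {
  m <- sum(!is.na(p))
  o <- order(p, na.last = NA)
  ps <- p[o]
  ok <- ps <= seq_along(ps) * fdr / m
  kstar <- if (any(ok)) max(which(ok)) else 0L
  out <- rep(FALSE, length(p))
  if (kstar > 0L) out[!is.na(p) & p <= ps[kstar]] <- TRUE
  out
}

# brute-force persistence scan: try every contiguous window (with optional
# wrap-around), apply the predicate literally
oracle_persistence <- function(mask, k, gaps, circular = FALSE) {
  nt <- length(mask)
  idx_sets <- list()
  for (s in seq_len(nt)) {
    maxlen <- if (circular) nt else nt - s + 1L
    for (len in seq_len(maxlen)) {
      w <- ((s - 1L + seq_len(len) - 1L) %% nt) + 1L
      idx_sets[[length(idx_sets) + 1L]] <- w
    }
  }
  for (w in idx_sets) {
    v <- mask[w]
    if (v[1L] && v[length(v)] && sum(v) >= k && sum(!v) <= gaps)
      return(TRUE)
  }
  FALSE
}

# one-sided (enrichment) hypergeometric p by direct summation over the tail
oracle_hyper_p_enrich <- function(overlap, module_size, set_size, bg_size) {
  kk <- overlap:min(module_size, set_size)
  sum(choose(set_size, kk) * choose(bg_size - set_size, module_size - kk)) /
    choose(bg_size, module_size)
}

# all set partitions of 1..n (Bell-number enumeration) as membership vectors
oracle_set_partitions <- function(n) {
  parts <- list(c(1L))
  for (el in seq_len(n)[-1L]) {
    nxt <- list()
    for (p in parts) {
      for (b in seq_len(max(p) + 1L))
        nxt[[length(nxt) + 1L]] <- c(p, b)
    }
    parts <- nxt
  }
  parts
}

# modularity computed straight from its definition Q = sum_c (e_c/m - (d_c/2m)^2)
oracle_modularity <- function(g, membership) {
  m <- igraph::ecount(g)
  if (m == 0L) return(NA_real_)
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  q <- 0
  for (c in unique(membership)) {
    inc <- sum(membership[el[, 1L]] == c & membership[el[, 2L]] == c)
    dc <- sum(deg[membership == c])
    q <- q + inc / m - (dc / (2 * m))^2
  }
  q
}

# maximum modularity over all partitions of a small graph
oracle_max_modularity <- function(g) {
  n <- igraph::vcount(g)
  best <- -Inf
  for (p in oracle_set_partitions(n))
    best <- max(best, oracle_modularity(g, p))
  best
}
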