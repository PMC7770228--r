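#' Spearman rank correlation with a two-sided p-value
#'
#' Rho is the Pearson correlation of average ranks (midranks for ties). The
#' two-sided p-value is exact — computed from the full permutation null over
#' all `n!` orderings of one vector — for `n <= exact_n_max`, and uses the
#' t-distribution approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom above that. Constant vectors yield an unscored result
#' (`rho = NA`, `p = NA`) rather than an error, so callers can skip the pair.
#'
#' @param x,y numeric vectors of equal length `n >= 3`; `NA`s are removed
#'   pair-wise.
#' @param exact_n_max largest `n` for which the exact permutation null is
#'   enumerated (default 9; `9!` = 362,880 orderings).
#' @return list with `rho`, `p`, `n` (observations used) and `method`
#'   (`"exact"`, `"t-approx"` or `"unscored"`).
#' @export
spearman_with_p <- function(x, y, exact_n_max = 9L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "unscored"))
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "unscored"))
  rho <- stats::cor(rx, ry)
  if (n <= exact_n_max) {
    p <- exact_spearman_p(rx, ry, rho)
    list(rho = rho, p = p, n = n, method = "exact")
  } else {
    list(rho = rho, p = spearman_t_p(rho, n), n = n, method = "t-approx")
  }
}

# two-sided p from the t-approximation; rho of +/-1 maps to p = 0 under the
# approximation (the exact route never returns 0)
spearman_t_p <- function(rho, n) {
  r2 <- pmin(rho^2, 1)
  tt <- ifelse(r2 >= 1, Inf, abs(rho) * sqrt((n - 2) / (1 - r2)))
  2 * stats::pt(-tt, df = n - 2)
}

# exact two-sided p by enumerating all n! permutations of the y-ranks
# (valid with or without ties because the actual midranks are permuted)
exact_spearman_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perms <- all_permutations(n)
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2)) * sqrt(sum(ryc^2))
  # rho for every permutation of ry against fixed rx
  rho_null <- as.vector(matrix(ryc[perms], ncol = n) %*% rxc) / denom
  mean(abs(rho_null) >= abs(rho_obs) - 1e-12)
}

.perm_cache <- new.env(parent = emptyenv())

# all n! permutations of 1..n as an (n!) x n integer matrix, cached
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  if (n > 10L) stop("refusing to enumerate permutations for n > 10")
  p <- matrix(1L, 1L, 1L)
  for (m in 2L:n) {
    prev <- p
    p <- matrix(0L, nrow(prev) * m, m)
    row <- 0L
    for (pos in seq_len(m)) {
      block <- matrix(0L, nrow(prev), m)
      block[, pos] <- m
      block[, -pos] <- prev
      p[row + seq_len(nrow(prev)), ] <- block
      row <- row + nrow(prev)
    }
  }
  .perm_cache[[key]] <- p
  p
}

# All-pairs Spearman rho and two-sided p for a genes x individuals matrix at
# one timepoint. Complete non-constant genes take the vectorized rank/cor
# path; genes with missing values fall back to pair-wise spearman_with_p,
# scored only when >= n_min joint observations remain. Returns NA rho/p for
# unscored pairs.
spearman_pairs_matrix <- function(mat, exact_n_max = 9L, n_min = 8L) {
  g <- nrow(mat)
  rho <- matrix(NA_real_, g, g)
  p <- matrix(NA_real_, g, g)
  complete <- !apply(mat, 1L, anyNA)
  constant <- apply(mat, 1L, function(v) {
    v <- v[!is.na(v)]
    length(v) < 3L || stats::sd(v) == 0
  })
  fast <- which(complete & !constant)
  n <- ncol(mat)
  if (length(fast) >= 2L && n >= 3L) {
    ranks <- t(apply(mat[fast, , drop = FALSE], 1L, rank))
    r <- stats::cor(t(ranks))
    if (n <= exact_n_max) {
      # exact p per pair (small-n path used by tests / sparse designs)
      for (ii in seq_along(fast)) for (jj in seq_len(ii - 1L)) {
        pv <- exact_spearman_p(ranks[ii, ], ranks[jj, ], r[ii, jj])
        p[fast[ii], fast[jj]] <- p[fast[jj], fast[ii]] <- pv
      }
    } else {
      p[fast, fast] <- spearman_t_p(r, n)
    }
    rho[fast, fast] <- r
    diag(p)[fast] <- NA_real_
  }
  slow <- which(!complete & !constant)
  if (length(slow) > 0L) {
    others <- which(!constant)
    for (i in slow) for (j in others) {
      if (j >= i && j %in% slow) next  # handled once
      if (i == j) next
      keep <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      if (sum(keep) < n_min) next
      s <- spearman_with_p(mat[i, ], mat[j, ], exact_n_max = exact_n_max)
      rho[i, j] <- rho[j, i] <- s$rho
      p[i, j] <- p[j, i] <- s$p
    }
  }
  list(rho = rho, p = p)
}

#' Benjamini-Hochberg selection mask
#'
#' Standard step-up procedure: with sorted p-values `p_(1) <= ... <= p_(m)`,
#' reject all hypotheses with `p <= p_(k*)` where
#' `k* = max{k : p_(k) <= k * fdr / m}`. Implemented via
#' [stats::p.adjust()] with `method = "BH"`, which is algebraically the same
#' rule; `NA` p-values are never selected and do not count toward `m`.
#'
#' @param p_values numeric vector of p-values in `(0, 1]` (NA allowed).
#' @param fdr target false-discovery rate in `(0, 1)`.
#' @return logical mask aligned to the input order.
#' @export
bh_select <- function(p_values, fdr) {
  stopifnot(fdr > 0, fdr < 1)
  if (length(p_values) == 0L) return(logical(0))
  adj <- stats::p.adjust(p_values, method = "BH")
  out <- !is.na(adj) & adj <= fdr
  out
}

#' Temporal persistence filter on an edge's significance mask
#'
#' An edge is kept when its per-timepoint significance mask contains a window
#' of consecutive timepoint slots whose first and last slots are significant,
#' holding at least `k` significant slots and at most `gaps` non-significant
#' slots. With the defaults (`k = 4`, `gaps = 1`) this is the rule "significant
#' in at least four consecutive timepoints, with one gap allowed": e.g. on the
#' 2-h ZT grid, significance at ZT 8, 10, 14 and 16 passes (ZT 12 is the one
#' gap). With `circular = TRUE` windows may wrap from the last slot to ZT0.
#'
#' @param mask logical vector over ordered timepoint slots.
#' @param k minimum number of significant slots in the window (default 4).
#' @param gaps maximum number of non-significant slots inside the window
#'   (default 1).
#' @param circular allow windows to wrap past the end of the day (default
#'   FALSE).
#' @return TRUE if any qualifying window exists.
#' @export
persistence_filter <- function(mask, k = 4L, gaps = 1L, circular = FALSE) {
  stopifnot(k >= 1L, gaps >= 0L)
  mask <- as.logical(mask)
  nt <- length(mask)
  if (sum(mask, na.rm = TRUE) < k) return(FALSE)
  mask[is.na(mask)] <- FALSE
  maxw <- k + gaps
  if (circular) {
    ext <- c(mask, mask[seq_len(min(maxw - 1L, nt))])
    starts <- seq_len(nt)
  } else {
    ext <- mask
    starts <- seq_len(nt)
  }
  # a qualifying window always contains a qualifying sub-window of length
  # <= k + gaps whose ends are significant, so windows longer than that
  # need not be scanned
  for (s in starts) {
    if (!ext[s]) next
    first_end <- s + k - 1L
    last <- min(s + maxw - 1L, length(ext))
    if (first_end > last) next
    for (e in first_end:last) {
      if (!ext[e]) next
      w <- ext[s:e]
      nsig <- sum(w)
      if (nsig >= k && (length(w) - nsig) <= gaps) return(TRUE)
    }
  }
  FALSE
}
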