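#' K-modes clustering of binary response patterns
#'
#' Partitions the rows of a binary matrix into \code{K} clusters by
#' minimizing the total Hamming distance to cluster modes, in the style of
#' Huang's K-modes algorithm. Initial modes are drawn from distinct observed
#' rows under a supplied seed; the best of \code{n_init} runs by total
#' within-cluster Hamming cost is returned, so the result is deterministic
#' given the seed. Ties in mode computation are broken toward 0.
#'
#' @param x binary (0/1) matrix, one row per unit.
#' @param K number of clusters, \code{K >= 1}.
#' @param seed integer seed controlling the random restarts.
#' @param n_init number of random initializations.
#' @param max_iter maximum passes over the data per initialization.
#' @return A list with \code{cluster} (length-\code{nrow(x)} assignment in
#'   \code{1..K}), \code{modes} (\code{K x ncol(x)}), \code{cost} (total
#'   Hamming distance) and \code{empty} (indices of empty clusters, if any).
#' @export
kmodes_binary <- function(x, K, seed = 1L, n_init = 10L, max_iter = 50L) {
  x <- as.matrix(x)
  stopifnot(K >= 1L, all(x == 0 | x == 1))
  N <- nrow(x)
  if (K == 1L) {
    mode <- as.numeric(colMeans(x) > 0.5)  # ties (mean == .5) toward 0
    return(list(cluster = rep(1L, N), modes = rbind(mode),
                cost = sum(abs(sweep(x, 2L, mode))), empty = integer(0)))
  }
  distinct <- unique(x)
  if (nrow(distinct) < K) {
    warning("fewer distinct rows than clusters; surplus clusters left empty")
  }
  best <- NULL
  rng <- local({ set.seed(seed); lapply(seq_len(n_init), function(i)
    sample.int(nrow(distinct), min(K, nrow(distinct)))) })
  hamming <- function(modes) {
    # d[i,k] = sum_h |x_ih - m_kh|, via two matrix products
    x %*% t(1 - modes) + (1 - x) %*% t(modes)
  }
  for (r in seq_len(n_init)) {
    modes <- matrix(0, K, ncol(x))
    modes[seq_along(rng[[r]]), ] <- distinct[rng[[r]], , drop = FALSE]
    cl <- rep(1L, N)
    for (it in seq_len(max_iter)) {
      d <- hamming(modes)
      new_cl <- max.col(-d, ties.method = "first")
      if (it > 1L && all(new_cl == cl)) break
      cl <- new_cl
      for (k in seq_len(K)) {
        idx <- cl == k
        if (any(idx)) {
          modes[k, ] <- as.numeric(colMeans(x[idx, , drop = FALSE]) > 0.5)
        }
      }
    }
    cost <- sum(d[cbind(seq_len(N), cl)])
    if (is.null(best) || cost < best$cost) {
      best <- list(cluster = cl, modes = modes, cost = cost)
    }
  }
  best$empty <- setdiff(seq_len(K), unique(best$cluster))
  best
}
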