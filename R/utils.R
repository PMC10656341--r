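# Numerical helpers shared across the EM routines.

# Probabilities are kept strictly inside the unit interval before any log.
.PROB_EPS <- 1e-10

clip_prob <- function(p, eps = .PROB_EPS) {
  pmin(pmax(p, eps), 1 - eps)
}

# Clip and renormalize so simplex constraints hold to machine precision.
clip_simplex_rows <- function(p, eps = .PROB_EPS) {
  p <- matrix(clip_prob(p, eps), nrow = nrow(p))
  p / rowSums(p)
}

clip_simplex_vec <- function(p, eps = .PROB_EPS) {
  p <- clip_prob(p, eps)
  p / sum(p)
}

# Row-wise maxima without per-row function calls (columns are few; rows
# can be many).
row_max <- function(x) {
  m <- x[, 1L]
  for (k in seq_len(ncol(x))[-1L]) m <- pmax(m, x[, k])
  m
}

# Row-wise log-sum-exp with max subtraction; x is a matrix.
row_logsumexp <- function(x) {
  m <- row_max(x)
  m + log(rowSums(exp(x - m)))
}

# Row-wise softmax with max subtraction.
row_softmax <- function(x) {
  e <- exp(x - row_max(x))
  e / rowSums(e)
}

# Extract slice m of an N x T x M array as an N x T matrix (robust to
# T = 1, where plain indexing would drop to a vector).
slice_m <- function(v, m) {
  matrix(v[, , m], dim(v)[1L], dim(v)[2L])
}

# Sum an N x T x M array over its third margin, returning N x T.
sum_over_m <- function(v) {
  out <- matrix(0, dim(v)[1L], dim(v)[2L])
  for (m in seq_len(dim(v)[3L])) out <- out + slice_m(v, m)
  out
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Relative log-likelihood convergence check; never true on the first
# iteration (ll_old is -Inf).
em_converged <- function(ll, ll_old, tol) {
  is.finite(ll_old) && abs(ll - ll_old) / (abs(ll_old) + 1) < tol
}

# xlogy with the 0 * log 0 = 0 convention (entropy terms).
xlogx <- function(p) {
  out <- p * log(p)
  out[p <= 0] <- 0
  out
}
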