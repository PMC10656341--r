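# EM algorithm for the unconditional multilevel latent class model
# (step 1 of the two-step estimator), using the upward-downward
# decomposition of the joint posteriors: group posteriors u_jm are computed
# first, then unit-level conditionals q_ijt|m, so that the E-step cost is
# linear in the number of low-level units rather than exponential in group
# size.

#' EM control parameters
#'
#' @param tol relative log-likelihood change threshold for convergence:
#'   iteration stops when \eqn{|\ell_k - \ell_{k-1}| / (|\ell_{k-1}| + 1)}
#'   falls below \code{tol}.
#' @param max_iter maximum number of EM iterations.
#' @param n_starts number of EM starts for the measurement model: the first
#'   uses the hierarchical K-modes initialization, the remainder are seeded
#'   perturbations of it.
#' @param seed integer seed for initialization randomness.
#' @param kmodes_n_init number of K-modes restarts inside the initializer.
#' @return A list of class \code{"mlca_control"}.
#' @export
mlca_control <- function(tol = 1e-8, max_iter = 1000L, n_starts = 5L,
                         seed = 1L, kmodes_n_init = 10L) {
  stopifnot(tol > 0, max_iter >= 1L, n_starts >= 1L)
  structure(list(tol = tol, max_iter = max_iter, n_starts = n_starts,
                 seed = as.integer(seed), kmodes_n_init = kmodes_n_init),
            class = "mlca_control")
}

# E-step of the unconditional model. Returns the posteriors
#   u: J x M group posteriors P(W_j = m | Y_j)
#   q: N x T x M conditionals P(X_ij = t | W_j = m, Y_ij)
#   v: N x T x M joint posteriors u_jm * q_ijt|m
# together with the current log-likelihood (a free by-product).
estep_measurement <- function(phi, pi, omega, data, logB = NULL) {
  Y <- data$Y
  T <- ncol(phi)
  M <- length(omega)
  if (is.null(logB)) logB <- item_logdens(Y, phi)
  logpi <- log(clip_prob(pi))
  A <- matrix(0, data$N, M)
  q <- array(0, c(data$N, T, M))
  for (m in seq_len(M)) {
    x <- sweep(logB, 2L, logpi[m, ], "+")
    a <- row_logsumexp(x)
    A[, m] <- a
    q[, , m] <- exp(x - a)
  }
  C <- rowsum(A, data$group, reorder = FALSE)
  lj <- sweep(C, 2L, log(clip_prob(omega)), "+")
  lse <- row_logsumexp(lj)
  u <- exp(lj - lse)
  dimnames(u) <- NULL
  v <- q
  for (m in seq_len(M)) v[, , m] <- q[, , m] * u[data$group, m]
  list(u = u, q = q, v = v, loglik = sum(lse), logB = logB)
}

# Closed-form M-step updates (relative-frequency ratios of posterior mass).
mstep_measurement <- function(post, data) {
  u <- post$u
  v <- post$v
  M <- ncol(u)
  T <- dim(v)[2L]
  omega <- clip_simplex_vec(colSums(u) / nrow(u))
  pi <- matrix(0, M, T)
  for (m in seq_len(M)) {
    mass <- colSums(slice_m(v, m))
    tot <- sum(mass)
    pi[m, ] <- if (tot > 0) mass / tot else rep(1 / T, T)
  }
  pi <- clip_simplex_rows(pi)
  vmarg <- sum_over_m(post$v)                       # N x T, sum over m
  denom <- colSums(vmarg)
  if (any(denom < .PROB_EPS)) {
    warning("empty low-level class in M-step; parameters clipped")
    denom <- pmax(denom, .PROB_EPS)
  }
  phi <- crossprod(data$Y, vmarg) / rep(denom, each = data$H)
  phi <- matrix(clip_prob(phi), data$H, T)
  list(phi = phi, pi = pi, omega = omega)
}

# Expected complete-data log-likelihood Q at (params, posteriors).
expected_cdll <- function(phi, pi, omega, post, data) {
  u <- post$u
  v <- post$v
  M <- length(omega)
  T <- ncol(phi)
  phi <- clip_prob(phi)
  q1 <- sum(sweep(u, 2L, log(clip_prob(omega)), "*"))
  logpi <- log(clip_prob(pi))
  q2 <- 0
  for (m in seq_len(M)) {
    q2 <- q2 + sum(sweep(slice_m(v, m), 2L, logpi[m, ], "*"))
  }
  vmarg <- sum_over_m(v)
  logB <- item_logdens(data$Y, phi)
  q3 <- sum(vmarg * logB)
  q1 + q2 + q3
}

# Entropy of the joint posterior distribution of (W_j, X_1j..X_njj); with
# the upward-downward factorization it is H(u_j) + sum_m u_jm sum_i H(q_i|m).
posterior_entropy <- function(post, data) {
  u <- post$u
  q <- post$q
  M <- ncol(u)
  ent <- -sum(xlogx(u))
  for (m in seq_len(M)) {
    hq <- -rowSums(xlogx(slice_m(q, m)))                        # per unit
    hq_group <- rowsum(hq, data$group, reorder = FALSE)
    ent <- ent + sum(u[, m] * hq_group)
  }
  ent
}

# One EM run from given starting values.
run_em_measurement <- function(phi, pi, omega, data, control) {
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  post <- NULL
  for (k in seq_len(control$max_iter)) {
    post <- estep_measurement(phi, pi, omega, data)
    trace <- c(trace, post$loglik)
    if (em_converged(post$loglik, ll_old, control$tol)) {
      converged <- TRUE
      break
    }
    ll_old <- post$loglik
    upd <- mstep_measurement(post, data)
    phi <- upd$phi; pi <- upd$pi; omega <- upd$omega
  }
  list(phi = phi, pi = pi, omega = omega, posteriors = post,
       loglik = post$loglik, loglik_trace = trace,
       converged = converged, n_iter = length(trace))
}

#' Fit the unconditional multilevel latent class model (step 1)
#'
#' Maximizes the measurement-model log-likelihood by EM from the
#' hierarchical K-modes initialization, optionally with additional seeded
#' perturbed starts; the solution with the highest log-likelihood is
#' retained and put in canonical class order (low-level classes by
#' decreasing mean response probability, high-level classes by decreasing
#' size).
#'
#' @param data an \code{\link{mlca_data}} object.
#' @param T,M number of low- and high-level latent classes.
#' @param control an \code{\link{mlca_control}} list.
#' @param init optional starting values: a list with \code{phi}, \code{pi},
#'   \code{omega}. When supplied, only this single start is used.
#' @return A list of class \code{"mlca_step1"} with the estimated
#'   \code{phi}, \code{pi}, \code{omega}, the \code{posteriors} at
#'   convergence, \code{loglik}, \code{loglik_trace}, \code{converged} and
#'   \code{n_iter}.
#' @export
fit_measurement <- function(data, T, M, control = mlca_control(),
                            init = NULL) {
  stopifnot(inherits(data, "mlca_data"), T >= 1L, M >= 1L)
  starts <- if (!is.null(init)) {
    list(init)
  } else {
    make_starts(data, T, M, control)
  }
  best <- NULL
  for (s in starts) {
    fit <- run_em_measurement(s$phi, s$pi, s$omega, data, control)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged) {
    warning("step-1 EM did not converge within max_iter; best iterate returned")
  }
  best <- canonicalize_step1(best, data)
  class(best) <- "mlca_step1"
  best
}

# Reorder the best solution into canonical class order and refresh the
# posteriors so labels are consistent everywhere.
canonicalize_step1 <- function(fit, data) {
  ord <- reorder_classes(fit$phi, fit$pi, fit$omega)
  if (!identical(ord$low_order, seq_along(ord$low_order)) ||
      !identical(ord$high_order, seq_along(ord$high_order))) {
    fit$phi <- ord$phi; fit$pi <- ord$pi; fit$omega <- ord$omega
    fit$posteriors <- estep_measurement(fit$phi, fit$pi, fit$omega, data)
  }
  fit
}
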