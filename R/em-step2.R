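# Step-2 EM: maximize the pseudo log-likelihood of the model with
# covariates over the structural parameters (Gamma, omega), keeping the
# item-response probabilities Phi fixed at their step-1 estimates. The
# E-step is the upward-downward decomposition with unit-specific low-class
# probabilities; the M-step combines the closed-form omega update with M
# independent weighted multinomial-logit fits (the joint posterior weights
# factor by high-level class).

# E-step of the structural model; phi enters only through the cached logB.
estep_structural <- function(gamma, omega, phi, data, design, logB = NULL) {
  if (is.null(logB)) logB <- item_logdens(data$Y, phi)
  T <- ncol(phi)
  M <- length(omega)
  A <- matrix(0, data$N, M)
  q <- array(0, c(data$N, T, M))
  for (m in seq_len(M)) {
    x <- logB + log_class_probs_m(gamma, m, design$Z, T)
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

# Weighted multinomial logistic fit for one high-level class m: maximize
# sum_i sum_t w_it log p_it(G) over the (T-1) x K coefficient matrix G,
# where p_i is the softmax of (0, Z_i' G') and w_it = u_jm * q_ijt|m.
# Newton-Raphson with step halving; coefficients capped at +/- 20 on the
# logit scale to guard against quasi-separation.
wml_fit <- function(Z, W, start, max_iter = 50L, tol = 1e-10, cap = 20) {
  T <- ncol(W)
  K <- ncol(Z)
  G <- start                                   # (T-1) x K
  r <- rowSums(W)                              # per-unit total weight
  obj <- function(G) {
    eta <- cbind(0, Z %*% t(G))
    logp <- eta - row_logsumexp(eta)
    sum(W * logp)
  }
  f_old <- obj(G)
  for (it in seq_len(max_iter)) {
    eta <- cbind(0, Z %*% t(G))
    p <- row_softmax(eta)
    # score: for t = 2..T, Z' (w_t - r p_t)
    resid <- W[, -1L, drop = FALSE] - r * p[, -1L, drop = FALSE]
    score <- as.vector(crossprod(Z, resid))    # K-major within each t
    if (max(abs(score)) < 1e-8 && it > 1L) break
    # Hessian of the expected CDLL (negative definite); (T-1)K square
    Hn <- matrix(0, (T - 1L) * K, (T - 1L) * K)
    for (t in 2:T) {
      for (s in 2:T) {
        wts <- r * p[, t] * ((s == t) - p[, s])
        blk <- crossprod(Z * wts, Z)
        Hn[((t - 2L) * K + 1L):((t - 1L) * K),
           ((s - 2L) * K + 1L):((s - 1L) * K)] <- blk
      }
    }
    step <- tryCatch(solve(Hn + diag(1e-10, nrow(Hn)), score),
                     error = function(e) MASS_ginv(Hn) %*% score)
    step_mat <- matrix(step, T - 1L, K, byrow = TRUE)
    lambda <- 1
    repeat {
      G_new <- G + lambda * step_mat
      f_new <- obj(G_new)
      if (f_new >= f_old - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (any(abs(G_new) > cap)) {
      warning("structural coefficients capped at |gamma| = 20 (possible separation)")
      G_new <- pmin(pmax(G_new, -cap), cap)
      f_new <- obj(G_new)
    }
    delta <- abs(f_new - f_old) / (abs(f_old) + 1)
    G <- G_new
    f_old <- f_new
    if (delta < tol) break
  }
  eta <- cbind(0, Z %*% t(G))
  p <- row_softmax(eta)
  resid <- W[, -1L, drop = FALSE] - r * p[, -1L, drop = FALSE]
  list(G = G, score_norm = max(abs(crossprod(Z, resid))), value = f_old)
}

# Moore-Penrose pseudo-inverse via SVD (small matrices only).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

#' Starting values for step 2 from the step-1 fit
#'
#' The label-switching safeguard of the two-step estimator: \eqn{\omega} is
#' started at its step-1 estimate, the structural intercepts at
#' \eqn{\log(\hat\pi_{t|m} / \hat\pi_{1|m})}, and every slope at zero, so
#' that the step-2 EM starts exactly at the step-1 solution of the
#' equivalent intercept-only model.
#'
#' @param step1 a fitted \code{mlca_step1} object.
#' @param K number of design columns of the structural model.
#' @return A list with \code{gamma} (\eqn{M \times (T-1) \times K} array,
#'   slopes zero) and \code{omega}.
#' @export
init_from_step1 <- function(step1, K) {
  pi <- step1$pi
  M <- nrow(pi)
  T <- ncol(pi)
  gamma <- array(0, c(M, T - 1L, K))
  if (T > 1L) {
    gamma[, , 1L] <- log(pi[, -1L, drop = FALSE] / pi[, 1L])
  }
  list(gamma = gamma, omega = step1$omega)
}

#' Fit the structural model with fixed measurement parameters (step 2)
#'
#' EM maximization of the pseudo log-likelihood over \eqn{(\Gamma, \omega)}
#' with \eqn{\Phi} fixed. A single EM run is started from
#' \code{\link{init_from_step1}} (or the supplied starting values); the
#' M-step solves the weighted multinomial-logit score equations separately
#' for each high-level class by Newton-Raphson with step halving.
#'
#' @param data an \code{\link{mlca_data}} object.
#' @param design an \code{mlca_design} aligned with \code{data}.
#' @param phi_fixed \eqn{H \times T} item-response probabilities, held
#'   fixed throughout.
#' @param M number of high-level classes.
#' @param control an \code{\link{mlca_control}} list.
#' @param init starting values as returned by \code{\link{init_from_step1}}.
#' @return A list of class \code{"mlca_step2"} with \code{gamma},
#'   \code{omega}, \code{phi_fixed}, the \code{posteriors} at convergence,
#'   \code{loglik}, \code{loglik_trace}, \code{converged}, \code{n_iter}.
#' @export
fit_structural <- function(data, design, phi_fixed, M, control = mlca_control(),
                           init) {
  T <- ncol(phi_fixed)
  gamma <- init$gamma
  omega <- init$omega
  logB <- item_logdens(data$Y, phi_fixed)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  post <- NULL
  for (k in seq_len(control$max_iter)) {
    post <- estep_structural(gamma, omega, phi_fixed, data, design, logB)
    trace <- c(trace, post$loglik)
    if (em_converged(post$loglik, ll_old, control$tol)) {
      converged <- TRUE
      break
    }
    ll_old <- post$loglik
    omega <- clip_simplex_vec(colSums(post$u) / nrow(post$u))
    if (T > 1L) {
      for (m in seq_len(M)) {
        W <- slice_m(post$v, m)
        G0 <- matrix(gamma[m, , ], T - 1L, design$K)
        gamma[m, , ] <- wml_fit(design$Z, W, G0)$G
      }
    }
  }
  if (!converged) {
    warning("step-2 EM did not converge within max_iter; best iterate returned")
  }
  structure(list(gamma = gamma, omega = omega, phi_fixed = phi_fixed,
                 posteriors = post, loglik = post$loglik,
                 loglik_trace = trace, converged = converged,
                 n_iter = length(trace)),
            class = "mlca_step2")
}
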