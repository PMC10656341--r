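# Core likelihood machinery for the multilevel latent class model.
#
# Measurement model: P(Y_j) = sum_m omega_m prod_i sum_t pi_{t|m}
#   prod_h phi_{h|t}^y (1-phi_{h|t})^{1-y}, with an H x T matrix Phi of
#   item-response probabilities, an M x T matrix Pi of low-class
#   probabilities given the high class, and high-class probabilities omega.
# Structural model: pi_{t|m} is replaced per unit by a multinomial logit in
#   covariates Z_ij with class 1 as the reference category.
# All mixture sums are computed in the log domain with max subtraction; the
# product over units inside a group is a sum of per-unit log mixtures.

# N x T matrix of per-unit item log densities log P(Y_ij | X_ij = t).
item_logdens <- function(Y, phi) {
  phi <- clip_prob(phi)
  Y %*% log(phi) + (1 - Y) %*% log1p(-phi)
}

#' Conditional low-class probabilities under the multinomial logit model
#'
#' Computes \eqn{P(X = t \mid W = m, Z = z)} for \eqn{t = 1, \dots, T} from
#' the \eqn{(T-1) \times K} coefficient matrix of high-level class \eqn{m}.
#' Class 1 is the reference category with linear predictor 0. Overflow-prone
#' predictors are handled by max subtraction.
#'
#' @param gamma_m numeric \eqn{(T-1) \times K} coefficient matrix (rows are
#'   classes \eqn{2..T}), or a length \eqn{T-1} vector when \eqn{K = 1}.
#' @param z numeric covariate vector of length \eqn{K}; its first entry must
#'   be 1 (the intercept).
#' @return A probability vector of length \eqn{T} summing to 1.
#' @export
class_probs <- function(gamma_m, z) {
  gamma_m <- rbind(gamma_m)  # (T-1) x K
  if (!all(is.finite(z)) || abs(z[1L] - 1) > 1e-12) {
    stop("'z' must be finite with first entry 1")
  }
  eta <- c(0, drop(gamma_m %*% z))
  drop(row_softmax(matrix(eta, nrow = 1L)))
}

# N x T matrix of log P(X = t | W = m, Z_ij) for one high-level class.
# gamma is the M x (T-1) x K coefficient array; Z is the N x K design.
log_class_probs_m <- function(gamma, m, Z, T) {
  K <- dim(gamma)[3L]
  G <- matrix(gamma[m, , ], nrow = T - 1L, ncol = K)
  eta <- cbind(0, Z %*% t(G))
  eta - row_logsumexp(eta)
}

# Shared skeleton: per-unit log mixture over t, aggregated to groups.
# logpi_list[[m]] is either a length-T vector (measurement model) or an
# N x T matrix (structural model) of log class probabilities.
loglik_core <- function(logB, logpi_list, omega, group, J) {
  M <- length(omega)
  N <- nrow(logB)
  A <- matrix(0, N, M)
  for (m in seq_len(M)) {
    lp <- logpi_list[[m]]
    x <- if (is.matrix(lp)) logB + lp else sweep(logB, 2L, lp, "+")
    A[, m] <- row_logsumexp(x)
  }
  C <- rowsum(A, group, reorder = FALSE)           # J x M
  lj <- sweep(C, 2L, log(clip_prob(omega)), "+")
  sum(row_logsumexp(lj))
}

#' Log-likelihood of the unconditional multilevel latent class model
#'
#' Evaluates \eqn{\sum_j \log P(Y_j)} under the measurement model, entirely
#' in the log domain (log-sum-exp over high classes of per-group sums of
#' per-unit log mixtures over low classes).
#'
#' @param phi \eqn{H \times T} item-response probabilities.
#' @param pi \eqn{M \times T} low-class probabilities given the high class;
#'   rows sum to 1.
#' @param omega length-\eqn{M} high-class probabilities.
#' @param data an \code{\link{mlca_data}} object.
#' @return The scalar log-likelihood.
#' @export
loglik_measurement <- function(phi, pi, omega, data) {
  stopifnot(inherits(data, "mlca_data"))
  pi <- rbind(pi)
  if (ncol(phi) != ncol(pi)) stop("phi and pi disagree on the number of low classes")
  logB <- item_logdens(data$Y, phi)
  logpi <- lapply(seq_len(nrow(pi)), function(m) log(clip_prob(pi[m, ])))
  loglik_core(logB, logpi, omega, data$group, data$J)
}

#' Log-likelihood of the multilevel latent class model with covariates
#'
#' Evaluates \eqn{\sum_j \log P(Y_j \mid Z_j)}, where the low-class
#' probabilities are unit-specific multinomial-logit functions of the
#' covariates and the item-response probabilities \code{phi} are treated as
#' fixed constants (the step-2 pseudo log-likelihood).
#'
#' @param gamma \eqn{M \times (T-1) \times K} coefficient array.
#' @param omega length-\eqn{M} high-class probabilities.
#' @param phi \eqn{H \times T} item-response probabilities, held fixed.
#' @param data an \code{\link{mlca_data}} object.
#' @param design an \code{mlca_design} object aligned with \code{data}.
#' @return The scalar log-likelihood.
#' @export
loglik_structural <- function(gamma, omega, phi, data, design) {
  stopifnot(inherits(data, "mlca_data"), inherits(design, "mlca_design"))
  if (nrow(design$Z) != data$N) stop("design and data are misaligned")
  T <- ncol(phi)
  logB <- item_logdens(data$Y, phi)
  logpi <- lapply(seq_along(omega), function(m)
    log_class_probs_m(gamma, m, design$Z, T))
  loglik_core(logB, logpi, omega, data$group, data$J)
}

#' Number of free parameters of the multilevel latent class model
#'
#' \eqn{HT} item-response probabilities, \eqn{M(T-1)} (or \eqn{M(T-1)K} with
#' covariates) structural coefficients, and \eqn{M-1} free high-class
#' probabilities.
#'
#' @param H,T,M model dimensions (items, low classes, high classes).
#' @param K number of covariate columns (including the intercept); only used
#'   when \code{with_covariates} is \code{TRUE}.
#' @param with_covariates logical; does the model include covariates?
#' @return Integer parameter count.
#' @export
npar_mlca <- function(H, T, M, K = 1L, with_covariates = FALSE) {
  stopifnot(H >= 1, T >= 1, M >= 1, K >= 1)
  slope <- if (with_covariates) M * (T - 1L) * K else M * (T - 1L)
  as.integer(H * T + slope + (M - 1L))
}

#' Identification checks for the multilevel latent class model
#'
#' Reports on the sufficient conditions for generic identification of the
#' unconditional model: (A1) every item's response probabilities differ
#' across low-level classes; (A2) the matrix \eqn{\Pi} has full row rank
#' \eqn{M}; plus the side conditions \eqn{M \le T} and \eqn{\min_j n_j \ge
#' 3}. The report never blocks estimation. These conditions are sufficient,
#' not necessary: profiles in which two classes share response
#' probabilities on some items (common in simulation designs) fail the
#' strict per-item check (A1) yet may still be identified.
#'
#' @param phi \eqn{H \times T} item-response probabilities.
#' @param pi \eqn{M \times T} matrix of low-class probabilities.
#' @param data an \code{\link{mlca_data}} object.
#' @param tol numerical tolerance for equality of probabilities and for the
#'   rank of \eqn{\Pi}.
#' @return A list with components \code{A1} (logical per item), \code{A2},
#'   \code{M_le_T} and \code{min_group_ok}, plus an overall \code{identified}
#'   flag.
#' @export
check_identification <- function(phi, pi, data, tol = 1e-6) {
  pi <- rbind(pi)
  T <- ncol(phi)
  a1 <- apply(phi, 1L, function(row) {
    if (T == 1L) return(TRUE)
    min(dist(row)) > tol
  })
  sv <- svd(pi)$d
  a2 <- sum(sv > tol * max(sv, 1)) >= nrow(pi)
  out <- list(
    A1 = a1,
    A2 = a2,
    M_le_T = nrow(pi) <= T,
    min_group_ok = min(data$group_sizes) >= 3L
  )
  out$identified <- all(a1) && a2 && out$M_le_T && out$min_group_ok
  out
}
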