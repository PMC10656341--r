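# Hierarchical K-modes-based initialization for the step-1 EM.
#
# 1. K-modes with K = M on the pooled units; each group gets the majority
#    label of its units, and the group-label frequencies (sorted decreasing)
#    initialize omega.
# 2. A pooled single-level T-class latent class model (itself K-modes
#    initialized) gives phi0; cross-tabulating its MAP assignments against
#    the group labels, row-normalized, gives pi0.

#' High-level initialization from unit-level cluster assignments
#'
#' Assigns each group the within-group majority cluster label and
#' initializes the high-class probabilities from the relative frequencies of
#' those labels across groups, sorted in decreasing order.
#'
#' @param assignments length-N vector of unit cluster labels in \code{1..M}.
#' @param data an \code{\link{mlca_data}} object.
#' @param M number of high-level classes.
#' @return A list with \code{omega0} (length-\code{M}, interior of the
#'   simplex) and \code{W_tilde} (length-\code{J} group labels).
#' @export
init_high_level <- function(assignments, data, M) {
  W_tilde <- vapply(seq_len(data$J), function(j) {
    tab <- tabulate(assignments[data$group == j], nbins = M)
    which.max(tab)  # ties broken toward the lower label
  }, integer(1L))
  freq <- tabulate(W_tilde, nbins = M) / data$J
  perm <- order(-freq)                  # decreasing size; class 1 largest
  invperm <- match(seq_len(M), perm)
  W_tilde <- invperm[W_tilde]           # relabel groups consistently
  list(omega0 = clip_simplex_vec(freq[perm]), W_tilde = W_tilde)
}

#' Low-level initialization from a pooled single-level latent class fit
#'
#' Fits a single-level T-class latent class model to the pooled items
#' (initialized by K-modes with K = T) to obtain starting response
#' probabilities, then cross-tabulates the fit's maximum-a-posteriori class
#' assignments against the group labels \code{W_tilde} to initialize
#' \eqn{\Pi}. Empty cross-tabulation cells are smoothed by adding 0.5 to
#' every cell of the table before row-normalizing.
#'
#' @param data an \code{\link{mlca_data}} object.
#' @param T number of low-level classes.
#' @param W_tilde length-\code{J} group labels in \code{1..M}.
#' @param M number of high-level classes.
#' @param control an \code{\link{mlca_control}} list (seed, tolerances).
#' @return A list with \code{phi0} (\eqn{H \times T}) and \code{pi0}
#'   (\eqn{M \times T}, rows on the simplex).
#' @export
init_low_level <- function(data, T, W_tilde, M, control = mlca_control()) {
  pooled <- fit_single_level(data, T, control)
  X_tilde <- max.col(pooled$post_x, ties.method = "first")
  tab <- matrix(0, M, T)
  for (m in seq_len(M)) {
    units <- data$group %in% which(W_tilde == m)
    tab[m, ] <- tabulate(X_tilde[units], nbins = T)
  }
  if (any(tab == 0)) tab <- tab + 0.5
  pi0 <- clip_simplex_rows(tab / rowSums(tab))
  list(phi0 = clip_prob(pooled$phi), pi0 = pi0)
}

# Pooled single-level T-class LCA: the M = 1 special case of the multilevel
# model (the group structure then drops out of the likelihood). Initialized
# from a single seeded K-modes run per the hierarchical strategy.
fit_single_level <- function(data, T, control = mlca_control()) {
  km <- kmodes_binary(data$Y, T, seed = control$seed,
                      n_init = control$kmodes_n_init)
  phi0 <- class_item_means(data$Y, km$cluster, T)
  pi0 <- rbind(clip_simplex_vec(tabulate(km$cluster, nbins = T) /
                                  length(km$cluster)))
  fit <- run_em_measurement(phi0, pi0, 1, data, control)
  # unit-level posteriors P(X_ij = t | Y_ij): with M = 1 they are q[, , 1]
  list(phi = fit$phi, pi = drop(fit$pi),
       post_x = fit$posteriors$q[, , 1L],
       loglik = fit$loglik, converged = fit$converged,
       n_iter = fit$n_iter)
}

# Cluster-wise item means, clipped to the interior.
class_item_means <- function(Y, cluster, K) {
  phi <- matrix(0.5, ncol(Y), K)
  for (k in seq_len(K)) {
    idx <- cluster == k
    if (any(idx)) phi[, k] <- colMeans(Y[idx, , drop = FALSE])
  }
  matrix(clip_prob(phi), ncol(Y), K)
}

# Full set of EM starting values: the hierarchical initialization first,
# then seeded logit-scale perturbations of it.
make_starts <- function(data, T, M, control) {
  km <- kmodes_binary(data$Y, M, seed = control$seed,
                      n_init = control$kmodes_n_init)
  hi <- init_high_level(km$cluster, data, M)
  lo <- init_low_level(data, T, hi$W_tilde, M, control)
  base <- list(phi = lo$phi0, pi = lo$pi0, omega = hi$omega0)
  starts <- list(base)
  if (control$n_starts > 1L) {
    set.seed(control$seed + 1L)
    for (s in seq_len(control$n_starts - 1L)) {
      phi <- stats::plogis(stats::qlogis(base$phi) +
                             matrix(stats::rnorm(length(base$phi), sd = 0.5),
                                    nrow(base$phi)))
      pi <- clip_simplex_rows(base$pi *
                                matrix(stats::rexp(length(base$pi)), M, T))
      omega <- clip_simplex_vec(base$omega * stats::rexp(M))
      starts[[s + 1L]] <- list(phi = clip_prob(phi), pi = pi, omega = omega)
    }
  }
  starts
}

#' Canonical reordering of latent class labels
#'
#' Sorts low-level classes by decreasing mean response probability (the
#' arithmetic mean of \eqn{\phi_{\cdot|t}} over items, a numerically robust
#' version of ordering classes by their propensity to score 1 on all
#' items), applied consistently to the columns of \eqn{\Phi} and \eqn{\Pi};
#' high-level classes are sorted by decreasing \eqn{\omega}. Ties are broken
#' by original index (stable sort), so reordering an already-ordered
#' parameter set is the identity and composing it with any label
#' permutation recovers the same canonical form.
#'
#' @param phi \eqn{H \times T} item-response probabilities.
#' @param pi \eqn{M \times T} low-class probabilities given high class.
#' @param omega length-\eqn{M} high-class probabilities.
#' @return A list with reordered \code{phi}, \code{pi}, \code{omega} and the
#'   permutations applied (\code{low_order}, \code{high_order}).
#' @export
reorder_classes <- function(phi, pi, omega) {
  pi <- rbind(pi)
  low_order <- order(-colMeans(phi))            # stable for ties
  high_order <- order(-omega)
  list(phi = phi[, low_order, drop = FALSE],
       pi = pi[high_order, low_order, drop = FALSE],
       omega = omega[high_order],
       low_order = low_order, high_order = high_order)
}
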