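# Corrected asymptotic covariance for the step-2 (structural) estimator.
#
# The two-step estimator is a pseudo-maximum-likelihood estimator: theta_2
# is estimated with theta_1 = vec(Phi) fixed at its step-1 estimate. Its
# asymptotic covariance is
#   V = I22^{-1} + I22^{-1} I21 Sigma11 I21' I22^{-1} = V2 + V1,
# where I22 and I21 are blocks of the Fisher information at (theta1, theta2)
# and Sigma11 is the asymptotic covariance of sqrt(N)(theta1-hat - theta1).
# All blocks are estimated by outer products of per-contribution scores,
# obtained analytically from the expected complete-data log-likelihood via
# the Oakes identity (the derivative of the observed log-likelihood equals
# the derivative of Q at fixed posteriors).
#
# Free coordinates: omega enters through its M-1 log-ratio coordinates
# alpha_m = log(omega_m / omega_1), and each row of Pi through its T-1
# log-ratio coordinates, so the information matrices are full rank.
#
# Score aggregation. Groups are the independent replicates, so summing
# score contributions within groups before the outer product is always
# valid ("group"); but inverting a d-dimensional outer product built from
# only J group rows carries an inverse-Wishart-type small-sample bias of
# order J / (J - d - 1), severe for the step-1 information (d = 35 in the
# packaged simulation design). Per-unit rows ("unit") avoid that bias and
# are accurate for unit-level parameter blocks (Gamma, Phi), whose
# within-group score correlations are weak, but they destroy the
# information of purely group-level parameters (the omega log-odds, whose
# per-unit score fragments are perfectly correlated within a group). The
# default ("hybrid") therefore assembles each block at the finest valid
# level: unit rows for Gamma x Gamma, Gamma x Phi and Phi x Phi, group
# rows for every block involving omega (or, in step 1, Pi).

theta2_names <- function(M, T, K, covnames) {
  g <- character(0)
  for (m in seq_len(M)) for (t in seq_len(T)[-1L]) for (k in seq_len(K)) {
    g <- c(g, sprintf("W%d:X%d:%s", m, t, covnames[k]))
  }
  a <- if (M > 1L) sprintf("logit(omega%d)", 2:M) else character(0)
  c(g, a)
}

# Analytic per-contribution scores at (theta1, theta2) with the given
# posteriors: s_gamma (N x M(T-1)K, unit rows), s_alpha (J x (M-1), group
# rows; the omega term of the CDLL is indexed by groups only), and
# s_phi (N x HT, unit rows).
score_contributions <- function(gamma, omega, phi, post, data, design) {
  T <- ncol(phi)
  M <- length(omega)
  K <- design$K
  N <- data$N
  grp <- data$group
  u <- post$u
  v <- post$v
  s_gamma <- matrix(0, N, M * (T - 1L) * K)
  col <- 0L
  for (m in seq_len(M)) {
    p_m <- exp(log_class_probs_m(gamma, m, design$Z, T))     # N x T
    resid <- slice_m(v, m) - u[grp, m] * p_m                 # N x T
    for (t in seq_len(T)[-1L]) for (k in seq_len(K)) {
      col <- col + 1L
      s_gamma[, col] <- resid[, t] * design$Z[, k]
    }
  }
  s_alpha <- if (M > 1L) {
    sweep(u[, -1L, drop = FALSE], 2L, omega[-1L], "-")       # J x (M-1)
  } else {
    matrix(0, data$J, 0L)
  }
  covn <- if (!is.null(design$names)) design$names else paste0("z", seq_len(K))
  list(s_gamma = s_gamma, s_alpha = s_alpha,
       s_phi = phi_scores(sum_over_m(v), phi, data),
       names = theta2_names(M, T, K, covn))
}

# Phi scores: vbar_ijt (y_ijh - phi_ht) / {phi_ht (1 - phi_ht)}, N x HT,
# column order t-major (h fastest), matching as.vector(phi).
phi_scores <- function(vmarg, phi, data) {
  T <- ncol(phi)
  phi_c <- clip_prob(phi)
  s_phi <- matrix(0, data$N, data$H * T)
  for (t in seq_len(T)) {
    block <- sweep(data$Y, 2L, phi_c[, t], "-")
    block <- sweep(block, 2L, phi_c[, t] * (1 - phi_c[, t]), "/")
    s_phi[, ((t - 1L) * data$H + 1L):(t * data$H)] <- vmarg[, t] * block
  }
  s_phi
}

# Score rows at a single aggregation level, used by the finite-difference
# checks and the pure "unit"/"group" modes. At unit level the group-level
# omega score is split evenly over the group's units so that unit rows sum
# to the group score.
score_rows <- function(sc, data, aggregate) {
  grp <- data$group
  if (aggregate == "group") {
    S2 <- cbind(rowsum(sc$s_gamma, grp, reorder = FALSE), sc$s_alpha)
    S1 <- rowsum(sc$s_phi, grp, reorder = FALSE)
  } else {
    S2 <- cbind(sc$s_gamma,
                sc$s_alpha[grp, , drop = FALSE] / data$group_sizes[grp])
    S1 <- sc$s_phi
  }
  colnames(S2) <- sc$names
  list(S2 = S2, S1 = S1)
}

# Assemble (I22, I21), 1/N-scaled, at the requested aggregation.
information_blocks <- function(sc, data, aggregate = c("hybrid", "unit", "group")) {
  aggregate <- match.arg(aggregate)
  N <- data$N
  if (aggregate != "hybrid") {
    S <- score_rows(sc, data, aggregate)
    I22 <- crossprod(S$S2) / N
    I21 <- crossprod(S$S2, S$S1) / N
  } else {
    grp <- data$group
    g_grp <- rowsum(sc$s_gamma, grp, reorder = FALSE)
    phi_grp <- rowsum(sc$s_phi, grp, reorder = FALSE)
    I22 <- rbind(
      cbind(crossprod(sc$s_gamma),          crossprod(g_grp, sc$s_alpha)),
      cbind(crossprod(sc$s_alpha, g_grp),   crossprod(sc$s_alpha))) / N
    I21 <- rbind(crossprod(sc$s_gamma, sc$s_phi),
                 crossprod(sc$s_alpha, phi_grp)) / N
    dimnames(I22) <- list(sc$names, sc$names)
  }
  I22 <- (I22 + t(I22)) / 2
  dimnames(I22) <- list(sc$names, sc$names)
  list(I22 = I22, I21 = I21)
}

# Asymptotic covariance of sqrt(N)(theta1-hat - theta1) from the step-1
# fit: the Phi block of the inverse outer-product information of the full
# step-1 parameter vector (free omega, free Pi rows, vec(Phi)).
sigma11 <- function(step1, data, aggregate = c("hybrid", "unit", "group")) {
  aggregate <- match.arg(aggregate)
  # Unlike I22, the full step-1 information mixes many unit-level (Phi)
  # and group-level (omega, Pi) coordinates; a mixed-level block assembly
  # is not a Gram matrix and goes indefinite at small J, and its inverse
  # then explodes. Unit-level rows give a true (always PSD) Gram matrix
  # and calibrated corrections, so "hybrid" resolves to "unit" here.
  if (aggregate == "hybrid") aggregate <- "unit"
  phi <- step1$phi
  pi <- step1$pi
  omega <- step1$omega
  post <- step1$posteriors
  T <- ncol(phi)
  M <- length(omega)
  grp <- data$group
  u <- post$u
  v <- post$v
  n_alpha <- M - 1L
  n_beta <- M * (T - 1L)
  n_phi <- data$H * T
  s_alpha <- if (M > 1L) {
    sweep(u[, -1L, drop = FALSE], 2L, omega[-1L], "-")       # J rows
  } else matrix(0, data$J, 0L)
  # Pi scores in log-ratio coordinates: v_ijtm - u_jm pi_t|m per unit
  s_beta <- matrix(0, data$N, n_beta)
  col <- 0L
  for (m in seq_len(M)) {
    vm <- slice_m(v, m)
    for (t in seq_len(T)[-1L]) {
      col <- col + 1L
      s_beta[, col] <- vm[, t] - u[grp, m] * pi[m, t]
    }
  }
  s_phi <- phi_scores(sum_over_m(v), phi, data)
  # the group-level outer product needs J >= parameter count
  d1 <- n_alpha + n_beta + n_phi
  if (aggregate == "group" && data$J < d1) aggregate <- "unit"
  S <- if (aggregate == "group") {
    cbind(s_alpha, rowsum(s_beta, grp, reorder = FALSE),
          rowsum(s_phi, grp, reorder = FALSE))
  } else {
    cbind(s_alpha[grp, , drop = FALSE] / data$group_sizes[grp],
          s_beta, s_phi)
  }
  I_full <- crossprod(S) / data$N
  I_full <- (I_full + t(I_full)) / 2
  I_inv <- inv_or_ginv(I_full, "step-1 information")
  idx <- (n_alpha + n_beta + 1L):(n_alpha + n_beta + n_phi)
  I_inv[idx, idx, drop = FALSE]
}

inv_or_ginv <- function(X, what) {
  X <- (X + t(X)) / 2
  out <- tryCatch(solve(X), error = function(e) NULL)
  if (is.null(out)) {
    warning(sprintf("%s is numerically singular; using a pseudo-inverse", what))
    out <- MASS_ginv(X)
  }
  (out + t(out)) / 2
}

# Assemble the corrected covariance V = V2 + V1 and the per-coefficient
# standard errors: corrected = sqrt(diag(V)/N), naive = sqrt(diag(V2)/N).
corrected_vcov <- function(I22, I21, Sigma11, N) {
  V2 <- inv_or_ginv(I22, "I22")
  V1 <- V2 %*% I21 %*% Sigma11 %*% t(I21) %*% V2
  V1 <- (V1 + t(V1)) / 2
  V <- V2 + V1
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("corrected covariance matrix is not positive semidefinite")
  }
  dimnames(V) <- dimnames(I22)
  dimnames(V2) <- dimnames(I22)
  list(V = V, V2 = V2, V1 = V1,
       se_corrected = sqrt(pmax(diag(V), 0) / N),
       se_naive = sqrt(pmax(diag(V2), 0) / N))
}

# Full-information SEs for the one-step estimator: outer products of the
# scores of the complete parameter vector (Gamma, alpha, Phi) at the MLE,
# assembled with the same block structure as the two-step information.
onestep_vcov <- function(gamma, omega, phi, post, data, design,
                         aggregate = "hybrid") {
  sc <- score_contributions(gamma, omega, phi, post, data, design)
  if (aggregate != "hybrid") {
    S <- score_rows(sc, data, aggregate)
    I_full <- crossprod(cbind(S$S2, S$S1)) / data$N
  } else {
    grp <- data$group
    g_grp <- rowsum(sc$s_gamma, grp, reorder = FALSE)
    phi_grp <- rowsum(sc$s_phi, grp, reorder = FALSE)
    S_u <- cbind(sc$s_gamma, sc$s_phi)                       # unit blocks
    I_uu <- crossprod(S_u)
    S_ug <- cbind(g_grp, phi_grp)
    I_ua <- crossprod(S_ug, sc$s_alpha)
    d_u <- ncol(S_u)
    d_g <- ncol(sc$s_alpha)
    d_gam <- ncol(sc$s_gamma)
    I_full <- matrix(0, d_u + d_g, d_u + d_g)
    I_full[seq_len(d_u), seq_len(d_u)] <- I_uu
    I_full[seq_len(d_u), d_u + seq_len(d_g)] <- I_ua
    I_full[d_u + seq_len(d_g), seq_len(d_u)] <- t(I_ua)
    I_full[d_u + seq_len(d_g), d_u + seq_len(d_g)] <- crossprod(sc$s_alpha)
    # reorder to (gamma, alpha, phi)
    ord <- c(seq_len(d_gam), d_u + seq_len(d_g),
             (d_gam + 1L):d_u)
    I_full <- I_full[ord, ord] / data$N
  }
  I_full <- (I_full + t(I_full)) / 2
  I_inv <- inv_or_ginv(I_full, "one-step information")
  d2 <- ncol(sc$s_gamma) + ncol(sc$s_alpha)
  V <- I_inv[seq_len(d2), seq_len(d2), drop = FALSE]
  dimnames(V) <- list(sc$names, sc$names)
  list(V = V, se = sqrt(pmax(diag(V), 0) / data$N))
}
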