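# Independent brute-force oracles: likelihood and posteriors by exhaustive
# enumeration over all joint latent configurations (W_j, X_1j, ..., X_njj).
# Deliberately naive (no log tricks, no factorization of the X-sum) so they
# share nothing with the package implementation; only usable when
# M * T^n_j is small.

# class_prob_fun(i, m) must return the length-T vector P(X_i = t | W = m)
# for global unit index i (constant in i for the unconditional model).
oracle_group_quantities <- function(Y, units, omega, class_prob_fun, phi) {
  T <- ncol(phi)
  M <- length(omega)
  n <- length(units)
  configs <- as.matrix(expand.grid(rep(list(seq_len(T)), n)))
  lik <- 0
  u <- numeric(M)
  v <- array(0, c(n, T, M))
  for (m in seq_len(M)) {
    for (r in seq_len(nrow(configs))) {
      x <- configs[r, ]
      p <- omega[m]
      for (a in seq_len(n)) {
        i <- units[a]
        t <- x[a]
        p <- p * class_prob_fun(i, m)[t] *
          prod(phi[, t]^Y[i, ] * (1 - phi[, t])^(1 - Y[i, ]))
      }
      lik <- lik + p
      u[m] <- u[m] + p
      for (a in seq_len(n)) v[a, x[a], m] <- v[a, x[a], m] + p
    }
  }
  list(lik = lik, u = u / lik, v = v / lik)
}

oracle_loglik <- function(Y, group, omega, class_prob_fun, phi) {
  sum(vapply(seq_len(max(group)), function(j) {
    log(oracle_group_quantities(Y, which(group == j), omega,
                                class_prob_fun, phi)$lik)
  }, numeric(1L)))
}

oracle_measurement_loglik <- function(Y, group, phi, pi, omega) {
  pi <- rbind(pi)
  oracle_loglik(Y, group, omega, function(i, m) pi[m, ], phi)
}

oracle_structural_loglik <- function(Y, group, phi, gamma, omega, Z) {
  T <- ncol(phi)
  pfun <- function(i, m) {
    G <- matrix(gamma[m, , ], T - 1, dim(gamma)[3])
    e <- exp(c(0, G %*% Z[i, ]))
    e / sum(e)
  }
  oracle_loglik(Y, group, omega, pfun, phi)
}

# Joint posteriors by enumeration, returned in the package's layout.
oracle_posteriors <- function(Y, group, omega, class_prob_fun, phi) {
  J <- max(group)
  M <- length(omega)
  T <- ncol(phi)
  u <- matrix(0, J, M)
  v <- array(0, c(nrow(Y), T, M))
  for (j in seq_len(J)) {
    units <- which(group == j)
    q <- oracle_group_quantities(Y, units, omega, class_prob_fun, phi)
    u[j, ] <- q$u
    v[units, , ] <- q$v
  }
  list(u = u, v = v)
}

# Tiny random model parameters and data, reproducible.
rand_params <- function(H, T, M, seed = 1) {
  set.seed(seed)
  phi <- matrix(runif(H * T, 0.15, 0.85), H, T)
  pi <- matrix(rexp(M * T), M, T)
  pi <- pi / rowSums(pi)
  omega <- rexp(M)
  omega <- omega / sum(omega)
  list(phi = phi, pi = pi, omega = omega)
}

rand_items <- function(N, H, seed = 1) {
  set.seed(seed)
  matrix(rbinom(N * H, 1, runif(N * H, 0.2, 0.8)), N, H)
}

# Small dataset drawn from a known unconditional model.
small_mlca_data <- function(J = 6, n_j = 4, H = 5, T = 2, M = 2, seed = 1) {
  pars <- rand_params(H, T, M, seed)
  set.seed(seed + 100)
  W <- sample.int(M, J, replace = TRUE, prob = pars$omega)
  group <- rep(seq_len(J), each = n_j)
  X <- vapply(group, function(j) sample.int(T, 1, prob = pars$pi[W[j], ]),
              integer(1))
  prob <- t(pars$phi)[X, , drop = FALSE]      # prob[i, h] = phi[h, X_i]
  Y <- matrix(rbinom(J * n_j * H, 1, prob), J * n_j, H)
  list(data = mlca_data(Y, group), pars = pars, W = W, X = X)
}

item_formula <- function(H) {
  stats::as.formula(paste0("cbind(", paste0("y", seq_len(H), collapse = ","),
                           ") ~ z"))
}
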