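# Core likelihood machinery: multinomial-logit class probabilities,
# measurement and structural log-likelihoods against enumeration oracles,
# parameter counting, identification checks.

test_that("multinomial-logit class probabilities match direct arithmetic", {
  # all-zero coefficients: symmetry
  expect_equal(class_probs(matrix(0, 2, 2), c(1, 0.3)), rep(1 / 3, 3))
  # intercept-only with log-ratio coefficients recovers the probabilities
  p <- c(0.5, 0.3, 0.2)
  g <- cbind(log(p[-1] / p[1]))
  expect_equal(class_probs(g, 1), p, tolerance = 1e-12)
  # hand evaluation: softmax of (0, 0.85, 1.38)
  e <- exp(c(0, 0.85, 1.38))
  expect_equal(class_probs(cbind(c(0.85, 1.38)), 1), e / sum(e),
               tolerance = 1e-12)
  # overflow-prone predictors stay finite and normalized
  p_big <- class_probs(cbind(c(900, 1000), c(1, -1)), c(1, 2))
  expect_true(all(is.finite(p_big)) && abs(sum(p_big) - 1) < 1e-12)
})

test_that("measurement log-likelihood collapses to independent Bernoulli when T = M = 1", {
  Y <- rand_items(20, 4, seed = 2)
  d <- mlca_data(Y, rep(1:4, each = 5))
  phi <- matrix(runif(4, 0.2, 0.8), 4, 1)
  ll <- loglik_measurement(phi, matrix(1, 1, 1), 1, d)
  ll_bern <- sum(Y %*% log(phi) + (1 - Y) %*% log(1 - phi))
  expect_equal(ll, ll_bern, tolerance = 1e-10)
})

test_that("measurement log-likelihood matches exhaustive enumeration", {
  for (seed in 1:3) {
    sm <- small_mlca_data(J = 3, n_j = 3, H = 4, T = 2, M = 2, seed = seed)
    p <- rand_params(4, 2, 2, seed + 50)
    ll <- loglik_measurement(p$phi, p$pi, p$omega, sm$data)
    ll_oracle <- oracle_measurement_loglik(sm$data$Y, sm$data$group,
                                           p$phi, p$pi, p$omega)
    expect_equal(ll, ll_oracle, tolerance = 1e-10)
  }
})

test_that("both log-likelihoods are invariant under consistent label permutations", {
  sm <- small_mlca_data(J = 4, n_j = 3, H = 5, T = 3, M = 2, seed = 9)
  p <- rand_params(5, 3, 2, seed = 77)
  ll <- loglik_measurement(p$phi, p$pi, p$omega, sm$data)
  pt <- c(3, 1, 2)                                   # low-class permutation
  pm <- c(2, 1)                                      # high-class permutation
  ll_perm <- loglik_measurement(p$phi[, pt], p$pi[pm, pt], p$omega[pm],
                                sm$data)
  expect_equal(ll, ll_perm, tolerance = 1e-10)
})

test_that("structural log-likelihood matches enumeration and reduces to measurement form", {
  sm <- small_mlca_data(J = 3, n_j = 3, H = 4, T = 3, M = 2, seed = 4)
  p <- rand_params(4, 3, 2, seed = 5)
  set.seed(11)
  z <- rnorm(sm$data$N)
  design <- structure(list(Z = cbind(1, z), K = 2L,
                           roles = c("intercept", "low_level"),
                           names = c("(Intercept)", "z")),
                      class = "mlca_design")
  gamma <- array(rnorm(2 * 2 * 2, sd = 0.5), c(2, 2, 2))
  ll <- loglik_structural(gamma, p$omega, p$phi, sm$data, design)
  ll_oracle <- oracle_structural_loglik(sm$data$Y, sm$data$group, p$phi,
                                        gamma, p$omega, design$Z)
  expect_equal(ll, ll_oracle, tolerance = 1e-10)

  # zero slopes: equals the measurement log-likelihood at the implied Pi
  gamma0 <- gamma
  gamma0[, , 2] <- 0
  pi_implied <- t(vapply(1:2, function(m)
    class_probs(matrix(gamma0[m, , ], 2, 2), c(1, 0)), numeric(3)))
  expect_equal(loglik_structural(gamma0, p$omega, p$phi, sm$data, design),
               loglik_measurement(p$phi, pi_implied, p$omega, sm$data),
               tolerance = 1e-10)

  # a zero covariate column with zero coefficients changes nothing
  design3 <- design
  design3$Z <- cbind(design$Z, 0)
  design3$K <- 3L
  gamma3 <- array(0, c(2, 2, 3))
  gamma3[, , 1:2] <- gamma
  expect_equal(loglik_structural(gamma3, p$omega, p$phi, sm$data, design3),
               ll, tolerance = 1e-12)
})

test_that("parameter count follows the stated counting rule", {
  expect_identical(npar_mlca(12, 4, 3), 59L)
  expect_identical(npar_mlca(1, 1, 1), 1L)
  expect_identical(npar_mlca(10, 3, 2, K = 2, with_covariates = TRUE), 39L)
})

test_that("identification report flags the stated failure modes", {
  d <- small_mlca_data(J = 4, n_j = 4, H = 5, T = 3, M = 2, seed = 3)$data
  # duplicated Pi rows: rank < M
  phi <- matrix(seq(0.1, 0.9, length.out = 15), 5, 3)
  pi_bad <- rbind(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2))
  rep_bad <- check_identification(phi, pi_bad, d)
  expect_false(rep_bad$A2)
  # equal response probabilities for item 1 in two classes
  phi_bad <- phi
  phi_bad[1, 2] <- phi_bad[1, 1]
  rep_a1 <- check_identification(phi_bad, rbind(c(0.6, 0.3, 0.1),
                                                c(0.1, 0.3, 0.6)), d)
  expect_false(rep_a1$A1[1])
  expect_true(all(rep_a1$A1[-1]))
  # the simulation truth satisfies the rank and dimension conditions; the
  # strict per-item condition (A1) is violated by design (pairs of classes
  # share response probabilities on half the items), which the report
  # surfaces without blocking anything
  ds <- mlca_sim_design(36)
  sim <- mlca_sim_data(ds, n_j = 100, J = 5, seed = 1)
  md <- mlca_data(sim$data[, paste0("y", 1:10)], sim$data$group)
  pi_true <- t(vapply(1:2, function(m)
    class_probs(matrix(ds$gamma[m, , ], 2, 2), c(1, 0)), numeric(3)))
  rep_ok <- check_identification(ds$phi, pi_true, md)
  expect_true(rep_ok$A2 && rep_ok$M_le_T && rep_ok$min_group_ok)
  expect_false(all(rep_ok$A1))
  # with fully distinct per-item probabilities every condition passes
  phi_dist <- matrix(seq(0.05, 0.95, length.out = 30), 10, 3)
  rep_all <- check_identification(phi_dist, pi_true, md)
  expect_true(rep_all$identified)
})
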