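# Step-1 EM: upward-downward posteriors against the enumeration oracle,
# closed-form M-step, the EM decomposition identity, monotonicity, and
# parameter recovery on simulated data.

estep1 <- mlcastep:::estep_measurement
mstep1 <- mlcastep:::mstep_measurement

test_that("upward-downward posteriors equal brute-force joint posteriors", {
  for (seed in 1:3) {
    sm <- small_mlca_data(J = 2, n_j = 3, H = 4, T = 2, M = 2, seed = seed)
    p <- rand_params(4, 2, 2, seed + 10)
    post <- estep1(p$phi, p$pi, p$omega, sm$data)
    oracle <- oracle_posteriors(sm$data$Y, sm$data$group, p$omega,
                                function(i, m) p$pi[m, ], p$phi)
    expect_equal(post$u, oracle$u, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(post$v, oracle$v, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("posterior invariants hold and degenerate dimensions collapse correctly", {
  sm <- small_mlca_data(J = 4, n_j = 5, H = 4, T = 3, M = 2, seed = 7)
  p <- rand_params(4, 3, 2, seed = 8)
  post <- estep1(p$phi, p$pi, p$omega, sm$data)
  expect_equal(rowSums(post$u), rep(1, sm$data$J), tolerance = 1e-10)
  vsum <- apply(post$v, 1, sum)
  expect_equal(vsum, rep(1, sm$data$N), tolerance = 1e-10)
  for (m in 1:2) {
    expect_equal(rowSums(post$q[, , m]), rep(1, sm$data$N), tolerance = 1e-10)
    expect_equal(post$v[, , m], post$q[, , m] * post$u[sm$data$group, m],
                 tolerance = 1e-12)
  }
  # M = 1: group posterior degenerate, v reduces to single-level posteriors
  p1 <- rand_params(4, 3, 1, seed = 9)
  post1 <- estep1(p1$phi, p1$pi, 1, sm$data)
  expect_equal(post1$u, matrix(1, sm$data$J, 1))
  # T = 1: q is identically 1 and v_ij1m = u_jm
  pT1 <- rand_params(4, 1, 2, seed = 10)
  postT1 <- estep1(pT1$phi, pT1$pi, pT1$omega, sm$data)
  expect_equal(postT1$q[, 1, ], matrix(1, sm$data$N, 2))
  expect_equal(postT1$v[, 1, ], postT1$u[sm$data$group, ])
})

test_that("M-step returns the complete-data MLE under hard posteriors", {
  sm <- small_mlca_data(J = 6, n_j = 4, H = 5, T = 2, M = 2, seed = 3)
  d <- sm$data
  # hard posteriors at the generating memberships
  u <- matrix(0, d$J, 2); u[cbind(1:d$J, sm$W)] <- 1
  v <- array(0, c(d$N, 2, 2))
  v[cbind(1:d$N, sm$X, sm$W[d$group])] <- 1
  q <- v
  for (m in 1:2) q[, , m] <- v[, , m] # unused by mstep
  upd <- mstep1(list(u = u, v = v, q = q), d)
  expect_equal(upd$omega, tabulate(sm$W, 2) / d$J, tolerance = 1e-9)
  for (t in 1:2) {
    idx <- sm$X == t
    expect_equal(upd$phi[, t], colMeans(d$Y[idx, , drop = FALSE]),
                 tolerance = 1e-9)
  }
  expect_equal(rowSums(upd$pi), c(1, 1), tolerance = 1e-12)
  # uniform posteriors: omega uniform, Pi rows uniform, Phi columns equal
  uu <- matrix(0.5, d$J, 2)
  vv <- array(0.25, c(d$N, 2, 2))
  upd_u <- mstep1(list(u = uu, v = vv, q = vv), d)
  expect_equal(upd_u$omega, c(0.5, 0.5))
  expect_equal(upd_u$pi, matrix(0.5, 2, 2))
  expect_equal(upd_u$phi[, 1], colMeans(d$Y), tolerance = 1e-12)
  expect_equal(upd_u$phi[, 1], upd_u$phi[, 2], tolerance = 1e-12)
})

test_that("EM decomposition holds: loglik = Q + posterior entropy", {
  sm <- small_mlca_data(J = 5, n_j = 4, H = 5, T = 3, M = 2, seed = 12)
  p <- rand_params(5, 3, 2, seed = 13)
  post <- estep1(p$phi, p$pi, p$omega, sm$data)
  Q <- mlcastep:::expected_cdll(p$phi, p$pi, p$omega, post, sm$data)
  H <- mlcastep:::posterior_entropy(post, sm$data)
  expect_equal(Q + H, post$loglik, tolerance = 1e-10)
  # hard posteriors: Q equals the complete-data log-likelihood
  d <- sm$data
  u <- matrix(0, d$J, 2); u[cbind(1:d$J, sm$W)] <- 1
  v <- array(0, c(d$N, 3, 2))
  v[cbind(1:d$N, sm$X, sm$W[d$group])] <- 1
  hard <- list(u = u, v = v, q = v)
  Qh <- mlcastep:::expected_cdll(p$phi, p$pi, p$omega, hard, d)
  cdll <- sum(log(p$omega[sm$W])) +
    sum(log(p$pi[cbind(sm$W[d$group], sm$X)])) +
    sum(d$Y * t(log(p$phi)[, sm$X]) + (1 - d$Y) * t(log(1 - p$phi)[, sm$X]))
  expect_equal(Qh, cdll, tolerance = 1e-10)
})

test_that("one E+M cycle leaves the complete-data MLE of deterministic data fixed", {
  # deterministic items: classes perfectly separated
  Y <- rbind(matrix(rep(c(1, 1, 1, 0), 6), 6, 4, byrow = TRUE),
             matrix(rep(c(0, 0, 0, 1), 6), 6, 4, byrow = TRUE))
  d <- mlca_data(Y, rep(1:4, each = 3))
  phi <- pmin(pmax(cbind(c(1, 1, 1, 0), c(0, 0, 0, 1)), 1e-6), 1 - 1e-6)
  pi <- rbind(c(1 - 1e-6, 1e-6), c(1e-6, 1 - 1e-6))
  omega <- c(0.5, 0.5)
  post <- estep1(phi, pi, omega, d)
  upd <- mstep1(post, d)
  expect_equal(upd$phi, phi, tolerance = 1e-5)
  expect_equal(upd$omega, omega, tolerance = 1e-5)
})

test_that("EM is monotone and T = M = 1 reduces to item means in one iteration", {
  sm <- small_mlca_data(J = 8, n_j = 6, H = 6, T = 3, M = 2, seed = 20)
  fit <- fit_measurement(sm$data, T = 3, M = 2,
                         control = mlca_control(n_starts = 2, seed = 20))
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_true(fit$converged)
  expect_equal(sum(fit$omega), 1, tolerance = 1e-12)
  expect_equal(rowSums(fit$pi), rep(1, 2), tolerance = 1e-12)
  # closed form at T = M = 1
  fit11 <- fit_measurement(sm$data, T = 1, M = 1,
                           control = mlca_control(n_starts = 1, seed = 1))
  expect_equal(drop(fit11$phi), colMeans(sm$data$Y), tolerance = 1e-9)
})

test_that("step-1 recovers the generating measurement parameters", {
  ds <- mlca_sim_design(36)                  # large separation, n_j = 500
  sim <- mlca_sim_data(ds, J = 50, seed = 99)
  md <- mlca_data(sim$data[, paste0("y", 1:10)], sim$data$group)
  fit <- fit_measurement(md, T = 3, M = 2,
                         control = mlca_control(n_starts = 1, seed = 99))
  # canonical order matches the truth's profile ordering
  expect_lt(mean(abs(fit$phi - ds$phi)), 0.03)
})

test_that("measurement estimates tighten as the number of groups grows", {
  ds <- mlca_sim_design(35)                  # n_j = 100, large separation
  errs <- vapply(c(10, 60), function(J) {
    sim <- mlca_sim_data(ds, J = J, seed = 500 + J)
    md <- mlca_data(sim$data[, paste0("y", 1:10)], sim$data$group)
    fit <- fit_measurement(md, T = 3, M = 2,
                           control = mlca_control(n_starts = 1, seed = J))
    pi_true <- rbind(
      class_probs(matrix(ds$gamma[1, , ], 2, 2), c(1, 0)),
      class_probs(matrix(ds$gamma[2, , ], 2, 2), c(1, 0)))
    # the high-class label is arbitrary when omega is (0.5, 0.5)
    min(mean(abs(fit$pi - pi_true)), mean(abs(fit$pi[2:1, ] - pi_true)))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})
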