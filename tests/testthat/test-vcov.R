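# Pseudo-ML variance correction: analytic scores against finite
# differences, information-block structure, and the corrected covariance.

# finite differences of the per-group log-likelihood contributions
group_loglik_contribs <- function(gamma, omega, phi, d, design) {
  A <- matrix(0, d$N, length(omega))
  logB <- mlcastep:::item_logdens(d$Y, phi)
  for (m in seq_along(omega)) {
    x <- logB + mlcastep:::log_class_probs_m(gamma, m, design$Z, ncol(phi))
    A[, m] <- mlcastep:::row_logsumexp(x)
  }
  C <- rowsum(A, d$group, reorder = FALSE)
  lj <- sweep(C, 2, log(omega), "+")
  mlcastep:::row_logsumexp(lj)
}

fd_scores <- function(f, x0, h = 1e-6) {
  vapply(seq_along(x0), function(k) {
    xp <- x0; xp[k] <- xp[k] + h
    xm <- x0; xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(length(f(x0))))
}

test_that("analytic Oakes-identity scores match central finite differences", {
  ds <- mlca_sim_design(33)
  sim <- mlca_sim_data(ds, n_j = 20, J = 15, seed = 3)
  d <- mlca_data(sim$data[, paste0("y", 1:10)], sim$data$group)
  design <- structure(list(Z = cbind(1, sim$data$z), K = 2L,
                           roles = c("intercept", "low_level"),
                           names = c("(Intercept)", "z")),
                      class = "mlca_design")
  # evaluate at a non-stationary, interior parameter point
  gamma <- ds$gamma * 0.8
  omega <- c(0.45, 0.55)
  phi <- pmin(pmax(ds$phi, 0.12), 0.88)
  post <- mlcastep:::estep_structural(gamma, omega, phi, d, design)
  sc0 <- mlcastep:::score_contributions(gamma, omega, phi, post, d, design)
  sc <- mlcastep:::score_rows(sc0, d, "group")
  # theta2 block: perturb (vec(Gamma), alpha) jointly
  theta2_to_pars <- function(th) {
    g <- gamma
    i <- 0
    for (m in 1:2) for (t in 1:2) for (k in 1:2) {
      i <- i + 1; g[m, t, k] <- th[i]
    }
    a <- th[9]
    om <- c(1, exp(a)); om <- om / sum(om)
    list(gamma = g, omega = om)
  }
  # parameter vector in the score's ordering (m outer, t middle, k inner)
  th0 <- numeric(9)
  i <- 0
  for (m in 1:2) for (t in 1:2) for (k in 1:2) {
    i <- i + 1; th0[i] <- gamma[m, t, k]
  }
  th0[9] <- log(omega[2] / omega[1])
  f2 <- function(th) {
    p <- theta2_to_pars(th)
    group_loglik_contribs(p$gamma, p$omega, phi, d, design)
  }
  fd2 <- fd_scores(f2, th0)
  expect_equal(dim(fd2), dim(sc$S2))
  expect_lt(max(abs(fd2 - sc$S2)) / max(1, max(abs(fd2))), 1e-4)
  # theta1 block: perturb phi entries (a representative subset)
  f1 <- function(ph) {
    group_loglik_contribs(gamma, omega, matrix(ph, 10, 3), d, design)
  }
  fd1 <- fd_scores(f1, as.vector(phi))
  expect_lt(max(abs(fd1 - sc$S1)) / max(1, max(abs(fd1))), 1e-4)
})

test_that("theta2 score vanishes at the two-step solution but theta1 score does not", {
  ds <- mlca_sim_design(35)
  sim <- mlca_sim_data(ds, J = 40, seed = 9)
  fit <- mlca(item_formula(10), data = sim$data, group = "group",
              nclass = 3, nclass_high = 2,
              control = mlca_control(n_starts = 1, seed = 9, tol = 1e-10))
  sc <- mlcastep:::score_rows(
    mlcastep:::score_contributions(
      fit$structural$gamma, fit$structural$omega, fit$measurement$phi,
      fit$posteriors, fit$data, fit$design),
    fit$data, "group")
  expect_lt(max(abs(colSums(sc$S2))), 1e-3 * fit$dims$N^0.5)
  # the theta1 (Phi) total score is generally nonzero once covariates enter
  expect_gt(max(abs(colSums(sc$S1))), 1e-4)
})

test_that("information blocks are PSD, symmetric, and invariant to data doubling", {
  ds <- mlca_sim_design(35)
  sim <- mlca_sim_data(ds, J = 25, seed = 21)
  fit <- mlca(item_formula(10), data = sim$data, group = "group",
              nclass = 3, nclass_high = 2,
              control = mlca_control(n_starts = 1, seed = 21))
  I22 <- fit$vcov_parts$I22
  expect_equal(I22, t(I22), tolerance = 1e-10)
  expect_true(min(eigen(I22, symmetric = TRUE, only.values = TRUE)$values)
              > -1e-10)
  # doubling the dataset leaves the 1/N-scaled outer product unchanged
  dat2 <- sim$data
  dat2$group <- dat2$group + max(sim$data$group)
  doubled <- rbind(sim$data, dat2)
  d2 <- mlca_data(doubled[, paste0("y", 1:10)], doubled$group)
  design2 <- structure(list(Z = cbind(1, doubled$z), K = 2L,
                            roles = c("intercept", "low_level"),
                            names = c("(Intercept)", "z")),
                       class = "mlca_design")
  post2 <- mlcastep:::estep_structural(fit$structural$gamma,
                                       fit$structural$omega,
                                       fit$measurement$phi, d2, design2)
  sc2 <- mlcastep:::score_contributions(
    fit$structural$gamma, fit$structural$omega, fit$measurement$phi,
    post2, d2, design2)
  I22_2 <- mlcastep:::information_blocks(sc2, d2, "hybrid")$I22
  expect_equal(unname(I22_2), unname(I22), tolerance = 1e-8)
})

test_that("corrected covariance dominates the naive one and I21 = 0 collapses V to V2", {
  ds <- mlca_sim_design(35)
  sim <- mlca_sim_data(ds, J = 40, seed = 33)
  fit <- mlca(item_formula(10), data = sim$data, group = "group",
              nclass = 3, nclass_high = 2,
              control = mlca_control(n_starts = 1, seed = 33))
  vp <- fit$vcov_parts
  # V - V2 = V1 is PSD
  expect_true(min(eigen(vp$V1, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-8)
  expect_true(all(fit$se_corrected >= fit$se_naive - 1e-12))
  # I21 = 0 reduces the correction to nothing
  vc0 <- mlcastep:::corrected_vcov(vp$I22, 0 * vp$I21, vp$Sigma11,
                                   fit$dims$N)
  expect_equal(vc0$V, vp$V2, tolerance = 1e-12)
})

test_that("step-1 covariance shrinks at rate 1/N and matches the single-level collapse", {
  # single-level collapse: with M = 1 the model is an ordinary latent class
  # model; compare against an independently coded single-level information
  ds <- mlca_sim_design(35)
  sim <- mlca_sim_data(ds, n_j = 40, J = 25, seed = 44)
  d <- mlca_data(sim$data[, paste0("y", 1:10)], sim$data$group)
  ctrl <- mlca_control(n_starts = 1, seed = 44, tol = 1e-10)
  step1 <- fit_measurement(d, T = 3, M = 1, control = ctrl)
  S11 <- mlcastep:::sigma11(step1, d, aggregate = "unit")
  # independent single-level outer-product information for (pi, Phi)
  phi <- step1$phi; pi <- drop(step1$pi)
  B <- exp(mlcastep:::item_logdens(d$Y, phi))
  po <- sweep(B, 2, pi, "*"); po <- po / rowSums(po)
  s_beta <- po[, -1, drop = FALSE] - rep(1, d$N) %o% pi[-1]
  s_phi <- matrix(0, d$N, 30)
  for (t in 1:3) {
    s_phi[, (t - 1) * 10 + 1:10] <-
      po[, t] * sweep(d$Y, 2, phi[, t]) /
      rep(phi[, t] * (1 - phi[, t]), each = d$N)
  }
  I_ref <- crossprod(cbind(s_beta, s_phi)) / d$N
  S11_ref <- solve(I_ref)[-(1:2), -(1:2)]
  expect_equal(unname(S11), unname(S11_ref), tolerance = 1e-6)
  # 1/N rate: SEs (sqrt(diag(Sigma11)/N)) shrink roughly as sqrt(1/4) when
  # N quadruples
  sim_big <- mlca_sim_data(ds, n_j = 40, J = 100, seed = 45)
  d_big <- mlca_data(sim_big$data[, paste0("y", 1:10)], sim_big$data$group)
  step1_big <- fit_measurement(d_big, T = 3, M = 1, control = ctrl)
  S11_big <- mlcastep:::sigma11(step1_big, d_big, aggregate = "unit")
  ratio <- median(diag(S11_big) / diag(S11))
  expect_lt(abs(ratio - 1), 0.5)   # Sigma11 is N-free; diag stays stable
})
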