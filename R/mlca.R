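#' Multilevel latent class models with covariates
#'
#' Fits a multilevel latent class model for binary items: low-level units
#' (individuals) carry a latent class \eqn{X_{ij}} with \eqn{T} categories
#' measured by \eqn{H} binary items, high-level units (groups) carry a
#' latent class \eqn{W_j} with \eqn{M} categories acting as a categorical
#' random effect, and covariates enter a multinomial logistic model for
#' \eqn{X_{ij}} given \eqn{W_j}, with coefficients specific to the
#' high-level class.
#'
#' Three estimators are available. \code{"twostep"} (the default) first
#' fits the measurement model without covariates by maximum likelihood,
#' then maximizes the pseudo log-likelihood of the full model over the
#' structural parameters with the item-response probabilities fixed;
#' standard errors are corrected for the first-step estimation via pseudo-ML
#' theory. \code{"onestep"} maximizes the joint likelihood over all
#' parameters simultaneously (the statistical benchmark). \code{"twostage"}
#' builds the measurement model in three sub-steps (single-level fit, class
#' probabilities with responses fixed, responses with class probabilities
#' fixed) before the structural step; only naive standard errors are
#' reported for it.
#'
#' @param formula a two-sided formula whose left side is the item matrix,
#'   e.g. \code{cbind(y1, y2, ..., yH) ~ z1 + z2}; the right side gives the
#'   covariates of the structural model (\code{~ 1} for none).
#' @param data a data frame containing the items, covariates and group
#'   identifier.
#' @param group the grouping variable: a column name in \code{data} or a
#'   vector of group labels.
#' @param nclass number of low-level latent classes \eqn{T}.
#' @param nclass_high number of high-level latent classes \eqn{M}.
#' @param method estimation strategy: \code{"twostep"}, \code{"onestep"} or
#'   \code{"twostage"}.
#' @param control an \code{\link{mlca_control}} list.
#' @param se logical; compute standard errors (default \code{TRUE}).
#' @param score_aggregate how score contributions enter the outer-product
#'   information matrices: \code{"hybrid"} (the default: per-unit rows for
#'   the unit-level parameter blocks, per-group rows for every block
#'   involving the group-level class probabilities), \code{"unit"} or
#'   \code{"group"} (all rows at one level). Pure group rows respect the
#'   independence structure but their inverted outer products are badly
#'   biased unless the number of groups is much larger than the parameter
#'   count; pure unit rows destroy the information of group-level
#'   parameters.
#' @return An object of class \code{"mlca"}; see Details. Its main
#'   components are \code{measurement} (\code{phi}, \code{pi},
#'   \code{omega} from the measurement fit), \code{structural}
#'   (\code{gamma}, \code{omega}), \code{coefficients} (named vector of
#'   structural coefficients and free high-class log-odds),
#'   \code{se_corrected}, \code{se_naive}, \code{vcov_parts}, \code{loglik},
#'   \code{posteriors} and \code{diagnostics}.
#' @seealso \code{\link{summary.mlca}}, \code{\link{mlca_select}},
#'   \code{\link{mlca_sim_study}}
#' @examples
#' design <- mlca_sim_design(31)            # small simulated setting
#' dat <- mlca_sim_data(design, n_j = 30, J = 20, seed = 7)
#' fit <- mlca(cbind(y1, y2, y3, y4, y5, y6, y7, y8, y9, y10) ~ z,
#'             data = dat$data, group = "group", nclass = 3,
#'             nclass_high = 2,
#'             control = mlca_control(n_starts = 1, seed = 7))
#' summary(fit)
#' @export
mlca <- function(formula, data, group, nclass, nclass_high = 1L,
                 method = c("twostep", "onestep", "twostage"),
                 control = mlca_control(), se = TRUE,
                 score_aggregate = c("hybrid", "unit", "group")) {
  method <- match.arg(method)
  score_aggregate <- match.arg(score_aggregate)
  cl <- match.call()
  grp <- if (is.character(group) && length(group) == 1L) data[[group]] else group
  items <- stats::model.response(stats::model.frame(
    stats::update(formula, . ~ 1), data = data, na.action = stats::na.fail))
  mdata <- mlca_data(items, grp)
  design <- build_design(formula[-2L], data, mdata)
  T <- as.integer(nclass)
  M <- as.integer(nclass_high)
  fit <- switch(method,
    twostep = fit_twostep(mdata, design, T, M, control, se, score_aggregate),
    onestep = fit_onestep(mdata, design, T, M, control, se, score_aggregate),
    twostage = fit_twostage(mdata, design, T, M, control, se, score_aggregate))
  fit$call <- cl
  fit$formula <- formula
  fit$method <- method
  fit$dims <- list(H = mdata$H, T = T, M = M, K = design$K,
                   N = mdata$N, J = mdata$J)
  fit$data <- mdata
  fit$design <- design
  class(fit) <- "mlca"
  fit
}

# Named coefficient vector (vec(Gamma) then free log-odds of omega).
theta2_vector <- function(gamma, omega, covnames) {
  M <- dim(gamma)[1L]
  Tm1 <- dim(gamma)[2L]
  K <- dim(gamma)[3L]
  g <- numeric(0)
  for (m in seq_len(M)) for (t in seq_len(Tm1)) for (k in seq_len(K)) {
    g <- c(g, gamma[m, t, k])
  }
  a <- if (M > 1L) log(omega[-1L] / omega[1L]) else numeric(0)
  stats::setNames(c(g, a), theta2_names(M, Tm1 + 1L, K, covnames))
}

fit_twostep <- function(mdata, design, T, M, control, se, aggregate) {
  t0 <- proc.time()[3L]
  step1 <- fit_measurement(mdata, T, M, control)
  t1 <- proc.time()[3L]
  init <- init_from_step1(step1, design$K)
  step2 <- fit_structural(mdata, design, step1$phi, M, control, init)
  t2 <- proc.time()[3L]
  out <- list(
    measurement = list(phi = step1$phi, pi = step1$pi, omega = step1$omega),
    structural = list(gamma = step2$gamma, omega = step2$omega),
    coefficients = theta2_vector(step2$gamma, step2$omega, design$names),
    loglik = step2$loglik, loglik_step1 = step1$loglik,
    posteriors = step2$posteriors, posteriors_step1 = step1$posteriors,
    step1 = step1, step2 = step2,
    diagnostics = list(
      converged = c(step1 = step1$converged, step2 = step2$converged),
      n_iter = c(step1 = step1$n_iter, step2 = step2$n_iter),
      wall_time = c(step1 = t1 - t0, step2 = t2 - t1))
  )
  if (se) {
    sc <- score_contributions(step2$gamma, step2$omega, step1$phi,
                              step2$posteriors, mdata, design)
    blocks <- information_blocks(sc, mdata, aggregate)
    S11 <- sigma11(step1, mdata, aggregate)
    vc <- corrected_vcov(blocks$I22, blocks$I21, S11, mdata$N)
    out$vcov_parts <- c(vc, list(I22 = blocks$I22, I21 = blocks$I21,
                                 Sigma11 = S11))
    out$se_corrected <- stats::setNames(vc$se_corrected, names(out$coefficients))
    out$se_naive <- stats::setNames(vc$se_naive, names(out$coefficients))
  }
  out
}

fit_onestep <- function(mdata, design, T, M, control, se, aggregate) {
  t0 <- proc.time()[3L]
  # initialized from a completed two-step fit for stability and
  # label consistency with the stepwise estimators
  base <- fit_twostep(mdata, design, T, M, control, se = FALSE, aggregate)
  gamma <- base$structural$gamma
  omega <- base$structural$omega
  phi <- base$measurement$phi
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  post <- NULL
  for (k in seq_len(control$max_iter)) {
    post <- estep_structural(gamma, omega, phi, mdata, design)
    trace <- c(trace, post$loglik)
    if (em_converged(post$loglik, ll_old, control$tol)) {
      converged <- TRUE
      break
    }
    ll_old <- post$loglik
    omega <- clip_simplex_vec(colSums(post$u) / nrow(post$u))
    vmarg <- sum_over_m(post$v)
    denom <- pmax(colSums(vmarg), .PROB_EPS)
    phi <- crossprod(mdata$Y, vmarg) / rep(denom, each = mdata$H)
    phi <- matrix(clip_prob(phi), mdata$H, T)
    if (T > 1L) {
      for (m in seq_len(M)) {
        W <- slice_m(post$v, m)
        G0 <- matrix(gamma[m, , ], T - 1L, design$K)
        gamma[m, , ] <- wml_fit(design$Z, W, G0)$G
      }
    }
  }
  if (!converged) warning("one-step EM did not converge within max_iter")
  t1 <- proc.time()[3L]
  out <- list(
    measurement = list(phi = phi, pi = base$measurement$pi,
                       omega = base$measurement$omega),
    structural = list(gamma = gamma, omega = omega),
    coefficients = theta2_vector(gamma, omega, design$names),
    loglik = post$loglik, loglik_step1 = base$loglik_step1,
    loglik_trace = trace,
    posteriors = post,
    diagnostics = list(converged = c(onestep = converged),
                       n_iter = c(onestep = length(trace)),
                       wall_time = c(onestep = t1 - t0))
  )
  if (se) {
    vc <- onestep_vcov(gamma, omega, phi, post, mdata, design, aggregate)
    out$vcov_parts <- vc
    out$se_corrected <- stats::setNames(vc$se, names(out$coefficients))
    out$se_naive <- out$se_corrected  # full-information ML: no correction
  }
  out
}

fit_twostage <- function(mdata, design, T, M, control, se, aggregate) {
  t0 <- proc.time()[3L]
  # Stage 1: single-level T-class fit for an initial Phi
  s1 <- fit_single_level(mdata, T, control)
  phi <- s1$phi
  # initial (omega, Pi) from the hierarchical K-modes initialization
  km <- kmodes_binary(mdata$Y, M, seed = control$seed,
                      n_init = control$kmodes_n_init)
  hi <- init_high_level(km$cluster, mdata, M)
  lo <- init_low_level(mdata, T, hi$W_tilde, M, control)
  omega <- hi$omega0
  pi <- lo$pi0
  # Stage 2a: multilevel EM with Phi fixed, updating (omega, Pi)
  ll_old <- -Inf
  for (k in seq_len(control$max_iter)) {
    post <- estep_measurement(phi, pi, omega, mdata)
    if (em_converged(post$loglik, ll_old, control$tol)) break
    ll_old <- post$loglik
    upd <- mstep_measurement(post, mdata)
    pi <- upd$pi; omega <- upd$omega            # Phi not updated
  }
  # Stage 2b: multilevel EM with (omega, Pi) fixed, updating Phi
  ll_old <- -Inf
  for (k in seq_len(control$max_iter)) {
    post <- estep_measurement(phi, pi, omega, mdata)
    if (em_converged(post$loglik, ll_old, control$tol)) break
    ll_old <- post$loglik
    upd <- mstep_measurement(post, mdata)
    phi <- upd$phi                              # (omega, Pi) not updated
  }
  ord <- reorder_classes(phi, pi, omega)
  phi <- ord$phi; pi <- ord$pi; omega <- ord$omega
  stage1 <- list(phi = phi, pi = pi, omega = omega,
                 posteriors = estep_measurement(phi, pi, omega, mdata))
  stage1$loglik <- stage1$posteriors$loglik
  t1 <- proc.time()[3L]
  # Stage 3 = step 2 of the two-step estimator with this Phi
  class(stage1) <- "mlca_step1"
  init <- init_from_step1(stage1, design$K)
  step2 <- fit_structural(mdata, design, phi, M, control, init)
  t2 <- proc.time()[3L]
  out <- list(
    measurement = list(phi = phi, pi = pi, omega = omega),
    structural = list(gamma = step2$gamma, omega = step2$omega),
    coefficients = theta2_vector(step2$gamma, step2$omega, design$names),
    loglik = step2$loglik, loglik_step1 = stage1$loglik,
    posteriors = step2$posteriors,
    step1 = stage1, step2 = step2,
    diagnostics = list(
      converged = c(stage12 = TRUE, step2 = step2$converged),
      n_iter = c(step2 = step2$n_iter),
      wall_time = c(stages = t1 - t0, step2 = t2 - t1))
  )
  if (se) {
    # corrected SEs are not available for the two-stage estimator
    # (conditioning on multiple interleaved sub-steps); naive only
    sc <- score_contributions(step2$gamma, step2$omega, phi,
                              step2$posteriors, mdata, design)
    I22 <- information_blocks(sc, mdata, aggregate)$I22
    V2 <- inv_or_ginv(I22, "I22")
    out$vcov_parts <- list(V2 = V2, I22 = I22)
    out$se_naive <- stats::setNames(sqrt(pmax(diag(V2), 0) / mdata$N),
                                    names(out$coefficients))
    out$se_corrected <- rep(NA_real_, length(out$coefficients))
  }
  out
}
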