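# Synthetic-data generator for the Monte Carlo evaluation of the
# estimators, and the study driver computing bias, Monte Carlo SDs,
# relative efficiency and confidence interval coverage.
#
# The generating model has M = 2 high-level classes, T = 3 low-level
# classes and H = 10 binary items. Low-level class profiles: class 1 scores
# 1 on every item with probability phi_level, class 2 on the last five
# items only, class 3 on none (probability 1 - phi_level everywhere).
# One standard-normal covariate enters the multinomial logit for X with
# slopes (-0.25, -0.25) in high-level class 1 and (0.25, 0.25) in class 2;
# the random intercepts are (-0.85, -1.38 | 0.85, 1.38) under moderate
# high-level separation and (-1.38, -2.07 | 1.38, 2.07) under large
# separation. High-level class sizes are (0.5, 0.5).

#' Monte Carlo simulation design
#'
#' Maps a condition number (1..36) to the crossed design over low-level
#' sample size (100 or 500 units per group), high-level sample size (30, 50
#' or 100 groups), low-level class separation (response probabilities 0.7,
#' 0.8 or 0.9 for the most likely responses) and high-level separation
#' (moderate or large random intercepts).
#'
#' @param condition integer in 1..36.
#' @return A list of class \code{"mlca_sim_design"} with the condition's
#'   dimensions and the true parameter values: \code{n_j}, \code{J},
#'   \code{phi_level}, \code{ll_separation}, \code{hl_separation},
#'   \code{phi} (\eqn{10 \times 3}), \code{gamma} (\eqn{2 \times 2 \times
#'   2} array over high class, low class 2..3, and (intercept, slope)),
#'   \code{omega} and the dimensions \code{H}, \code{T}, \code{M}.
#' @export
mlca_sim_design <- function(condition) {
  condition <- as.integer(condition)
  if (condition < 1L || condition > 36L) stop("condition must be in 1..36")
  i <- condition - 1L
  hl_sep <- if (i %/% 18L == 0L) "moderate" else "large"
  ll_sep <- c("small", "moderate", "large")[(i %% 18L) %/% 6L + 1L]
  J <- c(30L, 50L, 100L)[(i %% 6L) %/% 2L + 1L]
  n_j <- c(100L, 500L)[i %% 2L + 1L]
  phi_level <- c(small = 0.7, moderate = 0.8, large = 0.9)[[ll_sep]]
  phi <- cbind(rep(phi_level, 10L),
               c(rep(1 - phi_level, 5L), rep(phi_level, 5L)),
               rep(1 - phi_level, 10L))
  ints <- if (hl_sep == "moderate") {
    rbind(c(-0.85, -1.38), c(0.85, 1.38))
  } else {
    rbind(c(-1.38, -2.07), c(1.38, 2.07))
  }
  gamma <- array(0, c(2L, 2L, 2L))      # m, t-1, (intercept, slope)
  gamma[, , 1L] <- ints
  gamma[1L, , 2L] <- -0.25
  gamma[2L, , 2L] <- 0.25
  structure(list(condition = condition, n_j = n_j, J = J,
                 phi_level = phi_level, ll_separation = ll_sep,
                 hl_separation = hl_sep,
                 phi = phi, gamma = gamma, omega = c(0.5, 0.5),
                 H = 10L, T = 3L, M = 2L),
            class = "mlca_sim_design")
}

# Core generator: given parameters and a covariate design, draw W, X, Y.
draw_mlca <- function(phi, gamma, omega, Z, group) {
  J <- max(group)
  N <- nrow(Z)
  T <- ncol(phi)
  W <- sample.int(length(omega), J, replace = TRUE, prob = omega)
  X <- integer(N)
  for (m in seq_along(omega)) {
    idx <- which(W[group] == m)
    if (!length(idx)) next
    p <- exp(log_class_probs_m(gamma, m, Z[idx, , drop = FALSE], T))
    cum <- p
    for (t in seq_len(T)[-1L]) cum[, t] <- cum[, t - 1L] + p[, t]
    u <- stats::runif(length(idx))
    X[idx] <- 1L + rowSums(u > cum[, -T, drop = FALSE])
  }
  Y <- matrix(0L, N, nrow(phi))
  for (t in seq_len(T)) {
    idx <- which(X == t)
    if (!length(idx)) next
    Y[idx, ] <- matrix(stats::rbinom(length(idx) * nrow(phi), 1L,
                                     rep(phi[, t], each = length(idx))),
                       length(idx), nrow(phi))
  }
  list(Y = Y, X = X, W = W)
}

#' Generate one data set from a simulation design
#'
#' Draws group classes \eqn{W_j} from \eqn{\omega}, a standard-normal
#' covariate \eqn{z_{ij}}, low-level classes from the multinomial logit at
#' the design's coefficients, and items from the class-conditional Bernoulli
#' profiles. Bit-reproducible given \code{seed}.
#'
#' @param design an \code{\link{mlca_sim_design}} (or a compatible list with
#'   \code{phi}, \code{gamma}, \code{omega}).
#' @param n_j,J optional overrides of the design's group size and number of
#'   groups (used for reduced desk-scale runs).
#' @param seed integer seed.
#' @return A list with \code{data} (data frame with \code{group}, \code{z}
#'   and items \code{y1..yH}) and \code{truth} (\code{phi}, \code{gamma},
#'   \code{omega}, and the latent \code{W}, \code{X} actually drawn).
#' @export
mlca_sim_data <- function(design, n_j = design$n_j, J = design$J, seed = 1L) {
  set.seed(seed)
  N <- n_j * J
  group <- rep(seq_len(J), each = n_j)
  z <- stats::rnorm(N)
  Z <- cbind(1, z)
  sim <- draw_mlca(design$phi, design$gamma, design$omega, Z, group)
  df <- data.frame(group = group, z = z)
  items <- as.data.frame(sim$Y)
  colnames(items) <- paste0("y", seq_len(ncol(sim$Y)))
  list(data = cbind(df, items),
       truth = list(phi = design$phi, gamma = design$gamma,
                    omega = design$omega, W = sim$W, X = sim$X))
}

# Match estimated high-level classes to the truth by the structural
# intercepts (the low-level classes are already canonically ordered by the
# response-probability profiles). Returns the permutation p with
# estimated class p[m] playing the role of true class m.
align_high_classes <- function(gamma_hat, gamma_true) {
  M <- dim(gamma_true)[1L]
  perms <- permutations_of(M)
  costs <- vapply(perms, function(p) {
    sum((gamma_hat[p, , 1L] - gamma_true[, , 1L])^2)
  }, numeric(1L))
  perms[[which.min(costs)]]
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    sub <- permutations_of(n - 1L)
    out <- c(out, lapply(sub, function(p) c(i, setdiff(seq_len(n), i)[p])))
  }
  out
}

#' Monte Carlo study of the estimators
#'
#' Repeatedly generates data from the stated simulation conditions, fits
#' the requested estimators, and aggregates per-coefficient bias, Monte
#' Carlo standard deviation, relative SD with respect to the one-step
#' estimator (when fitted), 95\% confidence interval coverage and mean wall
#' time. Coverage uses the corrected standard errors for the two-step
#' estimator, the full-information standard errors for the one-step
#' estimator, and the naive standard errors for the two-stage estimator.
#' Estimated classes are aligned with the generating values (low level by
#' the canonical response-profile ordering, high level by matching the
#' structural intercepts) before metrics are computed.
#'
#' @param conditions integer vector of condition numbers (1..36).
#' @param estimators subset of \code{c("twostep", "onestep", "twostage")}.
#' @param n_reps number of Monte Carlo replicates per condition.
#' @param seed integer seed; replicate r of condition c uses seed
#'   \code{seed + 1000 * c + r}.
#' @param n_j,J optional overrides of group size / number of groups.
#' @param control an \code{\link{mlca_control}} list used for every fit;
#'   the default uses the single hierarchical initialization.
#' @param ci_level confidence level of the coverage intervals.
#' @return A list of class \code{"mlca_sim_study"} with \code{estimates}
#'   (one row per replicate, estimator and coefficient: estimate, SE,
#'   coverage indicator, wall time), \code{metrics} (aggregated), and
#'   \code{n_failed} (count of excluded failed fits).
#' @export
mlca_sim_study <- function(conditions, estimators = "twostep",
                           n_reps = 100L, seed = 1L,
                           n_j = NULL, J = NULL,
                           control = mlca_control(n_starts = 1L),
                           ci_level = 0.95) {
  estimators <- match.arg(estimators,
                          c("twostep", "onestep", "twostage"),
                          several.ok = TRUE)
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  rows <- list()
  n_failed <- 0L
  for (cond in conditions) {
    design <- mlca_sim_design(cond)
    nj_use <- if (is.null(n_j)) design$n_j else n_j
    J_use <- if (is.null(J)) design$J else J
    for (r in seq_len(n_reps)) {
      rep_seed <- seed + 1000L * cond + r
      sim <- mlca_sim_data(design, n_j = nj_use, J = J_use, seed = rep_seed)
      fml <- stats::as.formula(paste0(
        "cbind(", paste0("y", 1:design$H, collapse = ","), ") ~ z"))
      ctrl <- control
      ctrl$seed <- rep_seed
      for (est in estimators) {
        fit <- tryCatch(
          mlca(fml, data = sim$data, group = "group", nclass = design$T,
               nclass_high = design$M, method = est, control = ctrl),
          error = function(e) NULL)
        if (is.null(fit)) {
          n_failed <- n_failed + 1L
          next
        }
        p <- align_high_classes(fit$structural$gamma, design$gamma)
        se_vec <- if (est == "twostage") fit$se_naive else fit$se_corrected
        for (m in seq_len(design$M)) for (t in 2:design$T) {
          nm <- sprintf("W%d:X%d:z", m, t)
          # estimated class p[m] corresponds to true class m
          nm_hat <- sprintf("W%d:X%d:z", p[m], t)
          truth <- design$gamma[m, t - 1L, 2L]
          estv <- unname(fit$coefficients[nm_hat])
          sev <- unname(se_vec[nm_hat])
          rows[[length(rows) + 1L]] <- data.frame(
            condition = cond, estimator = est, rep = r, coef = nm,
            truth = truth, estimate = estv, se = sev,
            covered = as.integer(is.finite(sev) &&
                                   abs(estv - truth) <= zq * sev),
            wall_time = sum(fit$diagnostics$wall_time))
        }
      }
    }
  }
  estimates <- do.call(rbind, rows)
  metrics <- aggregate_study(estimates)
  structure(list(estimates = estimates, metrics = metrics,
                 n_failed = n_failed, ci_level = ci_level),
            class = "mlca_sim_study")
}

aggregate_study <- function(est) {
  key <- interaction(est$condition, est$estimator, est$coef, drop = TRUE)
  agg <- do.call(rbind, lapply(split(est, key), function(d) {
    data.frame(condition = d$condition[1L], estimator = d$estimator[1L],
               coef = d$coef[1L], truth = d$truth[1L],
               n_reps = nrow(d),
               mean_estimate = mean(d$estimate),
               bias = mean(d$estimate) - d$truth[1L],
               mc_sd = stats::sd(d$estimate),
               mean_se = mean(d$se, na.rm = TRUE),
               coverage = 100 * mean(d$covered),
               mean_wall_time = mean(d$wall_time))
  }))
  rownames(agg) <- NULL
  # relative Monte Carlo SD with respect to the one-step estimator
  agg$rel_sd_vs_onestep <- NA_real_
  for (i in seq_len(nrow(agg))) {
    ref <- agg$estimator == "onestep" & agg$condition == agg$condition[i] &
      agg$coef == agg$coef[i]
    if (any(ref)) agg$rel_sd_vs_onestep[i] <- agg$mc_sd[i] / agg$mc_sd[ref][1L]
  }
  agg
}

#' @export
print.mlca_sim_study <- function(x, digits = 3L, ...) {
  cat(sprintf("Monte Carlo study: %d replicate-level rows, %d failed fits\n\n",
              nrow(x$estimates), x$n_failed))
  tab <- x$metrics
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab)
  invisible(x)
}
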