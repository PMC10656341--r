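# Information criteria, entropy-based class separation, and class
# enumeration for the multilevel latent class model.

#' Information criteria for latent class enumeration
#'
#' Computes AIC, the standard BIC with the penalty scaled by the number of
#' low-level units \eqn{N}, and the group-level BIC with the penalty scaled
#' by the number of high-level units \eqn{J} (the sample size that governs
#' the accumulation of information about group-level structure).
#'
#' @param loglik maximized log-likelihood.
#' @param npar number of free parameters.
#' @param N number of low-level units.
#' @param J number of high-level units.
#' @return A named vector with \code{AIC}, \code{BIC} and \code{BIC_J}.
#' @export
mlca_ic <- function(loglik, npar, N, J) {
  stopifnot(N >= 1, J >= 1)
  c(AIC = -2 * loglik + 2 * npar,
    BIC = -2 * loglik + npar * log(N),
    BIC_J = -2 * loglik + npar * log(J))
}

#' Entropy-based R-squared for class separation
#'
#' One minus the ratio of the mean posterior entropy to the entropy of the
#' marginal class distribution: 1 for perfectly separated (degenerate)
#' posteriors, 0 when posteriors carry no information beyond the marginal.
#' At the high level the group posteriors \eqn{P(W_j \mid Y_j)} are used;
#' at the low level the unit-level marginal posteriors of \eqn{X_{ij}}.
#'
#' @param posterior matrix of posterior class probabilities, one row per
#'   unit (low level) or group (high level), rows summing to 1.
#' @return A value in \eqn{[0, 1]}; a degenerate marginal distribution
#'   (a single occupied class) is defined to give 1.
#' @export
entropy_rsq <- function(posterior) {
  posterior <- rbind(posterior)
  marg <- colMeans(posterior)
  h_marg <- -sum(xlogx(marg))
  if (h_marg <= 0) return(1)
  h_post <- mean(-rowSums(xlogx(posterior)))
  max(0, min(1, 1 - h_post / h_marg))
}

# Entropy R2 at both levels from a fitted measurement model.
entropy_rsq_levels <- function(post) {
  c(low = entropy_rsq(sum_over_m(post$v)),
    high = entropy_rsq(post$u))
}

#' Select the numbers of latent classes
#'
#' Enumerates candidate numbers of low-level classes \eqn{T} and high-level
#' classes \eqn{M} for the unconditional multilevel latent class model,
#' either over the full grid of \code{(T, M)} pairs or by the hierarchical
#' procedure: (1) fit single-level models (\eqn{M = 1}) and choose \eqn{T};
#' (2) with \eqn{T} fixed, fit multilevel models and choose \eqn{M}; (3)
#' with \eqn{M} fixed, re-choose \eqn{T}. Selection minimizes the stated
#' criterion among converged fits; by default the group-level BIC is used
#' when comparing values of \eqn{M} and the standard BIC when comparing
#' values of \eqn{T} (pass a single criterion to override both).
#'
#' @param data an \code{\link{mlca_data}} object (or a data frame together
#'   with \code{items} and \code{group} column names).
#' @param T_range,M_range candidate values of \eqn{T} and \eqn{M}.
#' @param strategy \code{"hierarchical"} or \code{"grid"}.
#' @param criterion \code{"AIC"}, \code{"BIC"} or \code{"BIC_J"}, or
#'   \code{NULL} (the default) for the per-level default above.
#' @param control an \code{\link{mlca_control}} list.
#' @param items,group column names, used when \code{data} is a data frame.
#' @return A list of class \code{"mlca_select"} with \code{table} (one row
#'   per fitted model: T, M, loglik, npar, AIC, BIC, BIC_J, entropy R2 at
#'   both levels, convergence flag) and the chosen \code{T} and \code{M}.
#' @export
mlca_select <- function(data, T_range, M_range,
                        strategy = c("hierarchical", "grid"),
                        criterion = NULL, control = mlca_control(),
                        items = NULL, group = NULL) {
  strategy <- match.arg(strategy)
  if (!inherits(data, "mlca_data")) {
    data <- mlca_data(data[, items, drop = FALSE], data[[group]])
  }
  if (!is.null(criterion)) {
    criterion <- match.arg(criterion, c("AIC", "BIC", "BIC_J"))
  }
  crit_T <- if (is.null(criterion)) "BIC" else criterion
  crit_M <- if (is.null(criterion)) "BIC_J" else criterion
  rows <- list()
  fit_one <- function(T, M) {
    key <- sprintf("T%d_M%d", T, M)
    if (!is.null(rows[[key]])) return(rows[[key]])
    fit <- tryCatch(fit_measurement(data, T, M, control),
                    error = function(e) NULL)
    row <- if (is.null(fit)) {
      data.frame(T = T, M = M, loglik = NA_real_, npar = NA_integer_,
                 AIC = NA_real_, BIC = NA_real_, BIC_J = NA_real_,
                 entropy_R2_low = NA_real_, entropy_R2_high = NA_real_,
                 converged = FALSE)
    } else {
      np <- npar_mlca(data$H, T, M)
      ic <- mlca_ic(fit$loglik, np, data$N, data$J)
      er <- entropy_rsq_levels(fit$posteriors)
      data.frame(T = T, M = M, loglik = fit$loglik, npar = np,
                 AIC = ic[["AIC"]], BIC = ic[["BIC"]], BIC_J = ic[["BIC_J"]],
                 entropy_R2_low = er[["low"]], entropy_R2_high = er[["high"]],
                 converged = fit$converged)
    }
    rows[[key]] <<- row
    row
  }
  pick <- function(T_vals, M_vals, crit) {
    tab <- do.call(rbind, lapply(seq_along(T_vals), function(i)
      fit_one(T_vals[i], M_vals[i])))
    ok <- which(tab$converged & is.finite(tab[[crit]]))
    if (!length(ok)) stop("no converged fits among the candidates")
    tab[ok[which.min(tab[[crit]][ok])], c("T", "M")]
  }
  if (strategy == "grid") {
    grid <- expand.grid(T = T_range, M = M_range)
    best <- pick(grid$T, grid$M, crit_M)
  } else {
    p1 <- pick(T_range, rep(1L, length(T_range)), crit_T)      # choose T
    p2 <- pick(rep(p1$T, length(M_range)), M_range, crit_M)    # choose M
    p3 <- pick(T_range, rep(p2$M, length(T_range)), crit_T)    # re-check T
    best <- data.frame(T = p3$T, M = p2$M)
  }
  table <- do.call(rbind, rows)
  table <- table[order(table$T, table$M), ]
  rownames(table) <- NULL
  structure(list(table = table, T = best$T, M = best$M,
                 strategy = strategy),
            class = "mlca_select")
}

#' @export
print.mlca_select <- function(x, digits = 2L, ...) {
  cat(sprintf("Class enumeration (%s strategy): chosen T = %d, M = %d\n\n",
              x$strategy, x$T, x$M))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab)
  invisible(x)
}
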