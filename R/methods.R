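# S3 methods for fitted "mlca" objects.

#' @export
print.mlca <- function(x, digits = 3L, ...) {
  d <- x$dims
  cat(sprintf("Multilevel latent class model (%s estimator)\n", x$method))
  cat(sprintf("  %d items, T = %d low-level classes, M = %d high-level classes\n",
              d$H, d$T, d$M))
  cat(sprintf("  N = %d units in J = %d groups\n", d$N, d$J))
  cat(sprintf("  log-likelihood: %.3f\n", x$loglik))
  cat("\nStructural coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Summary of a fitted multilevel latent class model
#'
#' @param object a fitted \code{\link{mlca}} object.
#' @param ... unused.
#' @return An object of class \code{"summary.mlca"} containing the
#'   coefficient table (estimate, naive SE, corrected SE where available,
#'   z value and p value based on the corrected SE), the estimated class
#'   sizes and item-response probabilities.
#' @export
summary.mlca <- function(object, ...) {
  se_c <- object$se_corrected
  se_n <- object$se_naive
  if (is.null(se_c)) se_c <- rep(NA_real_, length(object$coefficients))
  if (is.null(se_n)) se_n <- rep(NA_real_, length(object$coefficients))
  se_test <- ifelse(is.na(se_c), se_n, se_c)
  z <- object$coefficients / se_test
  tab <- cbind(Estimate = object$coefficients,
               `SE (naive)` = se_n,
               `SE (corrected)` = se_c,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(call = object$call, method = object$method,
                 dims = object$dims, coefficients = tab,
                 phi = object$measurement$phi,
                 pi = object$measurement$pi,
                 omega = object$structural$omega,
                 loglik = object$loglik,
                 diagnostics = object$diagnostics),
            class = "summary.mlca")
}

#' @export
print.summary.mlca <- function(x, digits = 3L, ...) {
  cat(sprintf("Multilevel latent class model (%s estimator)\n\n", x$method))
  cat("Coefficients (multinomial logit for X given W; class X1 reference):\n")
  stats::printCoefmat(x$coefficients, digits = digits, na.print = "-",
                      P.values = TRUE, has.Pvalue = TRUE)
  cat("\nHigh-level class sizes (omega):\n")
  print(round(x$omega, digits))
  cat("\nItem-response probabilities (phi, items x classes):\n")
  print(round(x$phi, digits))
  cat(sprintf("\nlog-likelihood: %.3f\n", x$loglik))
  invisible(x)
}

#' @export
coef.mlca <- function(object, ...) object$coefficients

#' @export
vcov.mlca <- function(object, type = c("corrected", "naive"), ...) {
  type <- match.arg(type)
  vp <- object$vcov_parts
  if (is.null(vp)) stop("model was fitted with se = FALSE")
  N <- object$dims$N
  if (type == "corrected") {
    if (is.null(vp$V)) stop("corrected covariance not available for this estimator")
    vp$V / N
  } else {
    vp$V2 / N
  }
}

#' @export
logLik.mlca <- function(object, ...) {
  d <- object$dims
  structure(object$loglik,
            df = npar_mlca(d$H, d$T, d$M, d$K, with_covariates = TRUE),
            nobs = d$N, class = "logLik")
}

#' Posterior class membership probabilities
#'
#' @param object a fitted \code{\link{mlca}} object.
#' @param type \code{"low"} for unit-level marginal posteriors of the
#'   low-level class (\eqn{N \times T}, in the original row order of the
#'   input data), \code{"high"} for group-level posteriors (\eqn{J \times
#'   M}), or \code{"joint"} for the \eqn{N \times T \times M} joint array.
#' @param ... unused.
#' @export
predict.mlca <- function(object, type = c("low", "high", "joint"), ...) {
  type <- match.arg(type)
  post <- object$posteriors
  if (type == "high") {
    out <- post$u
    rownames(out) <- as.character(object$data$group_labels)
    return(out)
  }
  if (type == "joint") return(post$v)
  vmarg <- sum_over_m(post$v)
  out <- matrix(NA_real_, object$dims$N, object$dims$T)
  out[object$data$orig_order, ] <- vmarg    # undo canonical reordering
  colnames(out) <- paste0("X", seq_len(object$dims$T))
  out
}

#' @export
plot.mlca <- function(x, ...) {
  phi <- x$measurement$phi
  graphics::matplot(seq_len(nrow(phi)), phi, type = "b", pch = 16, lty = 1,
                    xlab = "Item", ylab = "P(Y = 1 | X = t)",
                    ylim = c(0, 1), ...)
  graphics::legend("topright", legend = paste0("X", seq_len(ncol(phi))),
                   col = seq_len(ncol(phi)), lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Simulate item responses from a fitted model
#'
#' Draws new data sets from the fitted multilevel latent class model at the
#' estimated parameters, re-using the observed group sizes and covariates.
#'
#' @param object a fitted \code{\link{mlca}} object.
#' @param nsim number of data sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of \code{nsim} data frames with group identifier,
#'   covariates and items.
#' @export
simulate.mlca <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$dims
  md <- object$data
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    sim <- draw_mlca(phi = object$measurement$phi,
                     gamma = object$structural$gamma,
                     omega = object$structural$omega,
                     Z = object$design$Z, group = md$group)
    df <- data.frame(group = md$group_labels[md$group])
    df <- cbind(df, as.data.frame(object$design$Z[, -1L, drop = FALSE]))
    colnames(df)[-1L] <- object$design$names[-1L]
    items <- as.data.frame(sim$Y)
    colnames(items) <- paste0("y", seq_len(d$H))
    out[[r]] <- cbind(df, items)
  }
  if (nsim == 1L) out[[1L]] else out
}
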