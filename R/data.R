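#' Assemble a multilevel item-response data set
#'
#' Validates and canonicalizes the unit-level data used throughout the
#' package: an \code{N x H} matrix of strictly binary (0/1) item responses
#' together with a group identifier mapping each low-level unit (row) to one
#' of \code{J} high-level units. Rows are reordered so that units of the same
#' group are contiguous and groups are numbered \code{1..J} in order of first
#' appearance; the permutation applied is retained so results can be mapped
#' back to the original row order.
#'
#' @param items matrix or data frame of 0/1 item responses, one row per
#'   low-level unit, one column per item.
#' @param group vector of group labels, one per row of \code{items}.
#' @return An object of class \code{"mlca_data"}: a list with components
#'   \code{Y} (integer matrix), \code{group} (integer vector in \code{1..J}),
#'   \code{group_sizes}, \code{N}, \code{H}, \code{J}, \code{group_labels}
#'   (original labels in canonical order) and \code{orig_order} (row indices
#'   of the input giving the canonical order).
#' @export
mlca_data <- function(items, group) {
  Y <- as.matrix(items)
  if (!is.numeric(Y)) storage.mode(Y) <- "numeric"
  if (anyNA(Y) || !all(Y == 0 | Y == 1)) {
    stop("item responses must be strictly 0 or 1 with no missing values")
  }
  if (length(group) != nrow(Y)) {
    stop("'group' must have one entry per row of 'items'")
  }
  labels <- unique(group)
  gid <- match(group, labels)
  ord <- order(gid)          # stable: within-group original order preserved
  Y <- Y[ord, , drop = FALSE]
  gid <- gid[ord]
  storage.mode(Y) <- "integer"
  sizes <- as.integer(tabulate(gid, nbins = length(labels)))
  if (any(sizes == 0L)) stop("every group must contain at least one unit")
  structure(list(
    Y = Y, group = gid, group_sizes = sizes,
    N = nrow(Y), H = ncol(Y), J = length(labels),
    group_labels = labels, orig_order = ord
  ), class = "mlca_data")
}

# Build the covariate design from a model formula RHS, aligned with an
# mlca_data object (same canonical row order). First column is the
# intercept; full column rank is required for identification of the
# structural model. Columns constant within every group are flagged as
# high-level covariates.
build_design <- function(formula, data, mdata) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  Z <- stats::model.matrix(attr(mf, "terms"), mf)
  if (nrow(Z) != mdata$N) stop("covariate design and items have different lengths")
  if (colnames(Z)[1L] != "(Intercept)") {
    stop("the structural model must include an intercept")
  }
  Z <- Z[mdata$orig_order, , drop = FALSE]
  if (qr(Z)$rank < ncol(Z)) stop("covariate design is rank deficient")
  roles <- vapply(seq_len(ncol(Z)), function(k) {
    if (k == 1L) return("intercept")
    rng <- tapply(Z[, k], mdata$group, function(v) max(v) - min(v))
    if (all(rng < 1e-12)) "high_level" else "low_level"
  }, character(1L))
  structure(list(Z = Z, K = ncol(Z), roles = roles,
                 names = colnames(Z)), class = "mlca_design")
}

# Intercept-only design for models without covariates.
null_design <- function(mdata) {
  Z <- matrix(1, mdata$N, 1L, dimnames = list(NULL, "(Intercept)"))
  structure(list(Z = Z, K = 1L, roles = "intercept", names = "(Intercept)"),
            class = "mlca_design")
}
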