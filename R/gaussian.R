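# Gaussian model container and numerical guards shared by all estimators.

#' Multivariate Gaussian model over a named variable set
#'
#' Container for the mean vector and covariance matrix on which all
#' information measures in this package are computed. Covariances are
#' validated for symmetry (within 1e-10) and positive semi-definiteness
#' (smallest eigenvalue no smaller than -1e-10 times the largest).
#'
#' @param variables character vector of unique variable (gene) names.
#' @param mean numeric mean vector, one entry per variable.
#' @param covariance symmetric numeric matrix, variables x variables.
#' @param preprocessing optional list recording how the model was obtained
#'   (see [fit_gaussian()]); stored verbatim.
#'
#' @return An object of class `gaussian_model`: a list with elements
#'   `variables`, `mean`, `covariance`, `preprocessing` and a logical flag
#'   `rank_deficient` set when the covariance is numerically singular.
#' @export
#' @examples
#' m <- gaussian_model(c("X", "Y"), c(0, 0), diag(2))
#' mi(m, "X", "Y")  # 0: independent variables
gaussian_model <- function(variables, mean, covariance, preprocessing = list()) {
  variables <- as.character(variables)
  if (anyDuplicated(variables)) {
    stop("duplicate variable names: ",
         paste(unique(variables[duplicated(variables)]), collapse = ", "))
  }
  p <- length(variables)
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  if (length(mean) != p || !all(dim(covariance) == p)) {
    stop("mean/covariance dimensions do not match the ", p, " variables")
  }
  if (!all(is.finite(mean)) || !all(is.finite(covariance))) {
    stop("non-finite entries in mean or covariance")
  }
  if (max(abs(covariance - t(covariance))) > 1e-10) {
    stop("covariance is not symmetric (tolerance 1e-10)")
  }
  covariance <- (covariance + t(covariance)) / 2
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (p > 0 && min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("covariance is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  }
  dimnames(covariance) <- list(variables, variables)
  names(mean) <- variables
  structure(
    list(variables = variables, mean = mean, covariance = covariance,
         preprocessing = preprocessing,
         rank_deficient = p > 0 && min(ev) <= 1e-12 * max(abs(ev), 1)),
    class = "gaussian_model"
  )
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat("Gaussian model over", length(x$variables), "variables:",
      paste(utils::head(x$variables, 6), collapse = ", "),
      if (length(x$variables) > 6) "..." else "", "\n")
  if (isTRUE(x$rank_deficient)) cat("  (rank-deficient covariance)\n")
  invisible(x)
}

#' Fit a Gaussian model to an expression matrix
#'
#' Computes the sample mean and sample covariance (denominator m - 1) of a
#' genes x samples expression matrix, optionally after a natural-log
#' transform and/or per-gene standardization. Log transformation of
#' expression values is the usual route to approximate normality for
#' intensity-scale data; it requires strictly positive values unless a
#' pseudocount is supplied.
#'
#' @param expr numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene IDs) and at least 2 columns.
#' @param log_transform logical; take `log(expr + pseudocount)` first.
#' @param pseudocount nonnegative value added before the log transform.
#' @param standardize logical; center and scale each gene to unit variance
#'   after any log transform.
#'
#' @return A [gaussian_model()] whose `preprocessing` element records the
#'   options used and the sample count.
#' @export
#' @examples
#' x <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("G", 1:4), NULL))
#' fit_gaussian(x)
fit_gaussian <- function(expr, log_transform = FALSE, pseudocount = 0,
                         standardize = FALSE) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) {
    rownames(expr) <- paste0("G", seq_len(nrow(expr)))
  }
  if (ncol(expr) < 2) stop("at least 2 samples are required, got ", ncol(expr))
  if (!is.numeric(expr)) stop("expression matrix must be numeric")
  bad <- which(!is.finite(expr), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    g <- rownames(expr)[bad[1, 1]]
    s <- if (is.null(colnames(expr))) bad[1, 2] else colnames(expr)[bad[1, 2]]
    stop("non-finite expression value for gene ", g, ", sample ", s)
  }
  if (log_transform) {
    if (pseudocount < 0) stop("pseudocount must be nonnegative")
    shifted <- expr + pseudocount
    if (any(shifted <= 0)) {
      bad <- which(shifted <= 0, arr.ind = TRUE)
      stop("log transform of non-positive value for gene ",
           rownames(expr)[bad[1, 1]], " (add a pseudocount)")
    }
    expr <- log(shifted)
  }
  if (standardize) {
    sds <- apply(expr, 1, stats::sd)
    if (any(sds == 0)) {
      stop("cannot standardize constant gene ",
           rownames(expr)[which(sds == 0)[1]])
    }
    expr <- (expr - rowMeans(expr)) / sds
  }
  gaussian_model(
    variables = rownames(expr),
    mean = rowMeans(expr),
    covariance = stats::cov(t(expr)),
    preprocessing = list(log_transform = log_transform,
                         pseudocount = pseudocount,
                         standardize = standardize,
                         n_samples = ncol(expr))
  )
}

# --- internal numerical machinery -----------------------------------------

# Determinant floor and condition-number ceiling for the degeneracy policy.
.DET_FLOOR <- 1e-300
.COND_MAX <- 1e12

.logdet <- function(S) {
  if (length(S) == 0) return(0)
  d <- determinant(S, logarithm = TRUE)
  if (d$sign <= 0) stop("covariance submatrix has non-positive determinant")
  as.numeric(d$modulus)
}

# Apply the degeneracy policy to a covariance (sub)matrix: in strict mode a
# near-singular matrix is an error; in lenient mode (default) a small ridge
# lambda*I with lambda = 1e-10 * trace/dim is added, with a warning, so that
# near-duplicate expression profiles remain computable.
.guard_cov <- function(S, degeneracy = c("lenient", "strict"), context = "model") {
  degeneracy <- match.arg(degeneracy)
  n <- nrow(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  degenerate <- min(ev) <= 0 ||
    prod(ev) < .DET_FLOOR ||
    max(ev) / max(min(ev), .Machine$double.xmin) > .COND_MAX
  if (degenerate) {
    if (degeneracy == "strict") {
      stop("degenerate covariance (", context,
           "): determinant below floor or condition number above 1e12")
    }
    lambda <- 1e-10 * sum(diag(S)) / n
    warning("near-singular covariance (", context, "); added ridge ",
            format(lambda, digits = 3), " to the diagonal", call. = FALSE)
    S <- S + diag(lambda, n)
  }
  S
}

# Extract and guard the covariance over `vars` (in the given order).
.cov_subset <- function(model, vars, degeneracy = "lenient") {
  stopifnot(inherits(model, "gaussian_model"))
  missing <- setdiff(vars, model$variables)
  if (length(missing) > 0) {
    stop("variables not in model: ", paste(missing, collapse = ", "))
  }
  .guard_cov(model$covariance[vars, vars, drop = FALSE], degeneracy,
             context = paste(vars, collapse = ","))
}

# Marginal Gaussian model over a subset of variables, preserving order.
.marginal <- function(model, vars) {
  gaussian_model(vars, model$mean[vars],
                 model$covariance[vars, vars, drop = FALSE],
                 preprocessing = model$preprocessing)
}

# Validate an (x, y | z) query against the model.
.check_query <- function(model, x, y, z) {
  stopifnot(inherits(model, "gaussian_model"))
  if (identical(x, y)) stop("x and y must differ")
  if (x %in% z || y %in% z) stop("x and y must not appear in z")
  if (anyDuplicated(z)) stop("duplicate conditioning variables")
  missing <- setdiff(c(x, y, z), model$variables)
  if (length(missing) > 0) {
    stop("variables not in model: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

# Analytic information quantities are nonnegative; tiny float negatives are
# clamped, anything beyond -1e-12 signals an internal inconsistency.
.clamp0 <- function(v, what) {
  if (v < -1e-12) {
    stop("internal inconsistency: ", what, " evaluated to ", format(v))
  }
  max(v, 0)
}
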