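# Closed-form Gaussian information measures: MI, CMI, causal strength and
# CMI2 (conditional mutual inclusive information), plus the interventional
# construction and Gaussian KL divergence that define CMI2 and serve as its
# independent oracle.
#
# All quantities are in nats (natural logarithm throughout).

#' Gaussian mutual information
#'
#' MI(X, Y) for a multivariate Gaussian model, from the covariance
#' determinants: `0.5 * log(|C(X)| |C(Y)| / |C(X,Y)|)`. Zero iff X and Y are
#' uncorrelated; for unit variances and correlation rho this equals
#' `-0.5 * log(1 - rho^2)`.
#'
#' @param model a [gaussian_model()].
#' @param x,y distinct variable names present in the model.
#' @param degeneracy `"lenient"` (near-singular covariances are ridged with a
#'   warning) or `"strict"` (error).
#' @return Nonnegative mutual information in nats.
#' @export
#' @examples
#' S <- matrix(c(1, .6, .6, 1), 2, 2)
#' m <- gaussian_model(c("X", "Y"), c(0, 0), S)
#' mi(m, "X", "Y")  # -0.5 * log(1 - 0.36)
mi <- function(model, x, y, degeneracy = c("lenient", "strict")) {
  degeneracy <- match.arg(degeneracy)
  .check_query(model, x, y, character())
  S <- .cov_subset(model, c(x, y), degeneracy)
  .clamp0(0.5 * (log(S[1, 1]) + log(S[2, 2]) - .logdet(S)), "MI")
}

#' Gaussian conditional mutual information
#'
#' CMI(X; Y | Z) from covariance determinants:
#' `0.5 * log(|C(X,Z)| |C(Y,Z)| / (|C(Z)| |C(X,Y,Z)|))`. Z may contain one or
#' more variables (the order of the CMI is `length(z)`); an empty Z reduces
#' to [mi()] (zero-order case). Zero iff X and Y are conditionally
#' independent given Z under the Gaussian model.
#'
#' @inheritParams mi
#' @param z character vector of conditioning variable names (possibly empty),
#'   disjoint from `x` and `y`.
#' @return Nonnegative conditional mutual information in nats.
#' @export
cmi <- function(model, x, y, z = character(), degeneracy = c("lenient", "strict")) {
  degeneracy <- match.arg(degeneracy)
  .check_query(model, x, y, z)
  if (length(z) == 0) return(mi(model, x, y, degeneracy))
  S <- .cov_subset(model, c(x, y, z), degeneracy)
  iz <- 2 + seq_along(z)
  val <- 0.5 * (.logdet(S[c(1, iz), c(1, iz), drop = FALSE]) +
                .logdet(S[c(2, iz), c(2, iz), drop = FALSE]) -
                .logdet(S[iz, iz, drop = FALSE]) -
                .logdet(S))
  .clamp0(val, "CMI")
}

#' Interventional Gaussian distribution for a severed edge
#'
#' Builds the joint distribution obtained by deleting the directed edge
#' from one endpoint to the other: for direction `"x->y"` the result is
#' `P(x, z) * integral P(y | z, x') P(x') dx'`, i.e. the (x, z) marginal is
#' preserved exactly and y's conditional given z becomes the original
#' conditional averaged over the severed parent's marginal. For a
#' multivariate Gaussian the result is again Gaussian with the same mean;
#' only y's covariances change, and in the result x and y are conditionally
#' independent given z.
#'
#' @inheritParams cmi
#' @param direction `"x->y"` (sever the edge into y) or `"y->x"`.
#' @return A [gaussian_model()] over `c(x, y, z)` in that order.
#' @export
interventional_model <- function(model, x, y, z = character(),
                                 direction = c("x->y", "y->x"),
                                 degeneracy = c("lenient", "strict")) {
  direction <- match.arg(direction)
  degeneracy <- match.arg(degeneracy)
  .check_query(model, x, y, z)
  vars <- c(x, y, z)
  S <- .cov_subset(model, vars, degeneracy)
  if (direction == "x->y") {
    Snew <- .sever_cov(S, src = 1L, tgt = 2L)
  } else {
    Snew <- .sever_cov(S, src = 2L, tgt = 1L)
  }
  gaussian_model(vars, model$mean[vars], Snew,
                 preprocessing = model$preprocessing)
}

# Moment-space edge severing: regression of the target on (source, z) with
# the source coefficient's contribution replaced by the source's marginal
# variability, decoupled from the observed source. Returns the new
# covariance in the same variable order.
.sever_cov <- function(S, src, tgt) {
  n <- nrow(S)
  zi <- setdiff(seq_len(n), c(src, tgt))
  idx <- c(src, zi)
  B <- solve(S[idx, idx, drop = FALSE], S[idx, tgt])
  bsrc <- B[1]
  bz <- B[-1]
  resid_var <- S[tgt, tgt] - sum(S[idx, tgt] * B)
  s2 <- resid_var + bsrc^2 * S[src, src]
  Snew <- S
  if (length(zi) > 0) {
    Szz <- S[zi, zi, drop = FALSE]
    ctz <- as.numeric(Szz %*% bz)
    Snew[tgt, zi] <- ctz
    Snew[zi, tgt] <- ctz
    cts <- sum(bz * S[zi, src])
    Snew[tgt, src] <- cts
    Snew[src, tgt] <- cts
    Snew[tgt, tgt] <- s2 + sum(bz * ctz)
  } else {
    Snew[tgt, src] <- 0
    Snew[src, tgt] <- 0
    Snew[tgt, tgt] <- s2
  }
  (Snew + t(Snew)) / 2
}

#' Kullback-Leibler divergence between two Gaussian models
#'
#' Closed-form KL divergence `D_KL(p || q)` between multivariate normals on
#' the same variables in the same order:
#' `0.5 * (tr(Sq^-1 Sp) - n + (mq - mp)' Sq^-1 (mq - mp) + log|Sq| - log|Sp|)`.
#'
#' @param p,q [gaussian_model()] objects with identical variable vectors.
#' @return Nonnegative divergence in nats; 0 iff `p` and `q` coincide.
#' @export
kl_gaussian <- function(p, q) {
  stopifnot(inherits(p, "gaussian_model"), inherits(q, "gaussian_model"))
  if (!identical(p$variables, q$variables)) {
    stop("models must share the same variables in the same order")
  }
  n <- length(p$variables)
  Sp <- p$covariance
  Sq <- q$covariance
  Qi <- tryCatch(solve(Sq), error = function(e) {
    stop("q covariance is singular: ", conditionMessage(e))
  })
  d <- q$mean - p$mean
  val <- 0.5 * (sum(Qi * Sp) - n +
                as.numeric(crossprod(d, Qi %*% d)) +
                .logdet(Sq) - .logdet(Sp))
  .clamp0(val, "KL divergence")
}

#' Directional causal strength
#'
#' The KL divergence from the joint distribution to the interventional
#' distribution with the edge severed in the given direction:
#' `C_{X->Y} = D_KL(P || P_{X->Y})`. Unlike [mi()]/[cmi()]/[cmi2()] the
#' measure is asymmetric in (x, y) in general.
#'
#' @inheritParams interventional_model
#' @return Nonnegative causal strength in nats.
#' @export
causal_strength <- function(model, x, y, z = character(),
                            direction = c("x->y", "y->x"),
                            degeneracy = c("lenient", "strict")) {
  direction <- match.arg(direction)
  degeneracy <- match.arg(degeneracy)
  .check_query(model, x, y, z)
  p <- .marginal(model, c(x, y, z))
  q <- interventional_model(model, x, y, z, direction, degeneracy)
  kl_gaussian(p, q)
}

#' Conditional mutual inclusive information (CMI2)
#'
#' The average of the two KL divergences between the joint distribution and
#' the interventional distributions in which the x->y, respectively y->x,
#' edge is severed:
#' `CMI2(X; Y | Z) = (D_KL(P || P_{X->Y}) + D_KL(P || P_{Y->X})) / 2`.
#'
#' CMI2 decomposes as CMI plus two nonnegative KL terms, so it is never
#' smaller than CMI and coincides with it when Z is independent of (X, Y).
#' Where CMI collapses to zero when a conditioning gene's expression is
#' nearly identical to x or y (the redundant-conditioner failure mode), the
#' extra terms keep CMI2 bounded away from zero. With an empty Z the measure
#' reduces exactly to [mi()] (MI is the zero-order CMI2).
#'
#' This function evaluates a closed form derived from the Gaussian
#' interventional factorization `P(x,z) q(y|z)`: the severed joint's
#' precision matrix and log-determinant are written directly in terms of the
#' full precision matrix and the (x, z) marginal, so no generic KL call is
#' made. [cmi2_oracle()] computes the same quantity through the explicit
#' interventional construction and is the reference the closed form is
#' validated against.
#'
#' @inheritParams cmi
#' @return Nonnegative CMI2 in nats; always `>= cmi(model, x, y, z)` up to
#'   float rounding.
#' @export
#' @examples
#' # near-redundant conditioner: CMI collapses, CMI2 does not
#' f <- fixture_triples("redundant-conditioner")
#' cmi(f$model, "X", "Y", "Z")
#' cmi2(f$model, "X", "Y", "Z")
cmi2 <- function(model, x, y, z = character(),
                 degeneracy = c("lenient", "strict")) {
  degeneracy <- match.arg(degeneracy)
  .check_query(model, x, y, z)
  S <- .cov_subset(model, c(x, y, z), degeneracy)
  val <- 0.5 * (.kl_severed(S, src = 1L, tgt = 2L) +
                .kl_severed(S, src = 2L, tgt = 1L))
  .clamp0(val, "CMI2")
}

# Precision-space closed form for D_KL(P || P_{src->tgt}).
#
# The severed joint factorizes as P(src, z) * q(tgt | z), where q averages
# the original conditional of tgt over the source's marginal. Hence its
# precision K has K[src,tgt] = 0, the (src, z) block of the (src,z) marginal
# precision, and a rank-structured (tgt, z) contribution from the averaged
# conditional; its log-determinant is log|Sigma_1| + log(s2) with s2 the
# averaged conditional variance. Means are unchanged, so
#   KL = 0.5 * (tr(K S) - n + log|Sigma_1| + log(s2) - log|S|).
.kl_severed <- function(S, src, tgt) {
  n <- nrow(S)
  zi <- setdiff(seq_len(n), c(src, tgt))
  L <- solve(S)                              # full precision
  S1 <- S[c(src, zi), c(src, zi), drop = FALSE]
  P1 <- solve(S1)                            # (src, z) marginal precision
  beta <- -L[tgt, c(src, zi)] / L[tgt, tgt]  # regression coefs of tgt on (src, z)
  s2 <- 1 / L[tgt, tgt] + beta[1]^2 * S[src, src]
  K <- matrix(0, n, n)
  K[c(src, zi), c(src, zi)] <- P1
  K[tgt, tgt] <- 1 / s2
  if (length(zi) > 0) {
    bz <- beta[-1]
    K[tgt, zi] <- -bz / s2
    K[zi, tgt] <- -bz / s2
    K[zi, zi] <- K[zi, zi] + tcrossprod(bz) / s2
  }
  0.5 * (sum(K * S) - n + .logdet(S1) + log(s2) - .logdet(S))
}

#' Interventional-construction oracle for CMI2
#'
#' Computes CMI2 as the average of the two directional causal strengths,
#' each obtained through the explicit [interventional_model()] construction
#' followed by the generic [kl_gaussian()] closed form -- a route that shares
#' no linear-algebra shortcut with [cmi2()]. This is the normative
#' definition; the production closed form is validated against it.
#'
#' @inheritParams cmi
#' @return Nonnegative CMI2 in nats.
#' @export
cmi2_oracle <- function(model, x, y, z = character(),
                        degeneracy = c("lenient", "strict")) {
  degeneracy <- match.arg(degeneracy)
  0.5 * (causal_strength(model, x, y, z, "x->y", degeneracy) +
         causal_strength(model, x, y, z, "y->x", degeneracy))
}

#' Absolute (partial) correlation measure
#'
#' The pcalg-style baseline plug-in for the inference engine: with an empty
#' conditioning set, the absolute Pearson correlation; otherwise the
#' absolute partial correlation of x and y given z, computed from the
#' precision matrix of the (x, y, z) covariance.
#'
#' @inheritParams cmi
#' @return Value in [0, 1].
#' @export
partial_correlation <- function(model, x, y, z = character(),
                                degeneracy = c("lenient", "strict")) {
  degeneracy <- match.arg(degeneracy)
  .check_query(model, x, y, z)
  S <- .cov_subset(model, c(x, y, z), degeneracy)
  if (length(z) == 0) {
    return(abs(S[1, 2]) / sqrt(S[1, 1] * S[2, 2]))
  }
  P <- solve(S)
  min(abs(-P[1, 2] / sqrt(P[1, 1] * P[2, 2])), 1)
}
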