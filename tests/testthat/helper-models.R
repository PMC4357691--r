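# Shared fixtures: random SPD covariances and Gaussian models built in code.

rspd <- function(n, jitter = 0.5) {
  A <- matrix(stats::rnorm(n * n), n)
  S <- crossprod(A) + diag(n) * jitter
  dimnames(S) <- list(paste0("V", seq_len(n)), paste0("V", seq_len(n)))
  S
}

random_model <- function(n, jitter = 0.5) {
  gaussian_model(paste0("V", seq_len(n)), stats::rnorm(n), rspd(n, jitter))
}

# Correlation-matrix model over X, Y, Z with unit variances.
cor_model <- function(rxy, rxz, ryz) {
  S <- matrix(c(1, rxy, rxz,
                rxy, 1, ryz,
                rxz, ryz, 1), 3, 3)
  gaussian_model(c("X", "Y", "Z"), c(0, 0, 0), S)
}

# Group mutual information computed directly from determinants; independent
# arithmetic used to cross-check the cmi() chain rule.
group_mi <- function(S, ia, ib) {
  lg <- function(idx) as.numeric(determinant(S[idx, idx, drop = FALSE])$modulus)
  0.5 * (lg(ia) + lg(ib) - lg(c(ia, ib)))
}

# Gaussian log density for the Monte-Carlo KL oracle.
gauss_logdens <- function(X, mean, S) {
  n <- ncol(X)
  ch <- chol(S)
  D <- forwardsolve(t(ch), t(X) - mean)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(D^2))
}
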