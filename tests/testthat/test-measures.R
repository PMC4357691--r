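# Closed-form Gaussian information measures and the interventional/KL
# machinery that defines CMI2.

test_that("mi matches the bivariate closed form and is symmetric", {
  m <- cor_model(0.6, 0, 0)
  expect_equal(mi(m, "X", "Y"), -0.5 * log(1 - 0.36), tolerance = 1e-12)
  expect_equal(mi(m, "X", "Y"), 0.22314355131420976, tolerance = 1e-10)
  expect_equal(mi(gaussian_model(c("X", "Y"), c(0, 0), diag(2)), "X", "Y"), 0)
  set.seed(21)
  for (k in 1:20) {
    mm <- random_model(4)
    expect_equal(mi(mm, "V1", "V3"), mi(mm, "V3", "V1"), tolerance = 1e-12)
  }
})

test_that("cmi vanishes on a Gaussian Markov chain and factorizes under block independence", {
  chain <- cor_model(0.64, 0.8, 0.8)  # X - Z - Y with rho_xz = rho_zy = 0.8
  expect_equal(cmi(chain, "X", "Y", "Z"), 0, tolerance = 1e-12)
  # Z independent of (X, Y): determinants factorize, cmi == mi
  m <- cor_model(0.6, 0, 0)
  expect_equal(cmi(m, "X", "Y", "Z"), mi(m, "X", "Y"), tolerance = 1e-12)
})

test_that("cmi obeys the chain rule against brute-force group MI", {
  set.seed(31)
  for (k in 1:25) {
    n <- sample(3:6, 1)
    S <- rspd(n)
    m <- gaussian_model(paste0("V", 1:n), rep(0, n), S)
    z <- 2 + seq_len(sample(seq_len(n - 2), 1))
    expect_equal(cmi(m, "V1", "V2", paste0("V", z)),
                 group_mi(S, 1, c(2, z)) - group_mi(S, 1, z),
                 tolerance = 1e-10)
  }
})

test_that("measure queries are validated", {
  m <- random_model(4)
  expect_error(mi(m, "V1", "V1"), "differ")
  expect_error(cmi(m, "V1", "V2", c("V2", "V3")), "must not appear")
  expect_error(cmi(m, "V1", "V2", c("V3", "V3")), "duplicate")
  expect_error(cmi(m, "V1", "V9"), "not in model")
})

test_that("interventional model preserves the (x, z) marginal and cuts the partial covariance", {
  set.seed(41)
  for (k in 1:10) {
    m <- random_model(4)
    q <- interventional_model(m, "V1", "V2", c("V3", "V4"))
    # P(x, z) factor untouched: sub-covariance equal exactly
    keep <- c("V1", "V3", "V4")
    expect_equal(q$covariance[keep, keep], m$covariance[keep, keep],
                 tolerance = 1e-13)
    expect_equal(q$mean, m$mean[c("V1", "V2", "V3", "V4")])
    # given z, x and y are uncorrelated in the severed joint
    S <- q$covariance
    pc <- S["V1", "V2"] -
      S["V1", c("V3", "V4")] %*%
      solve(S[c("V3", "V4"), c("V3", "V4")], S[c("V3", "V4"), "V2"])
    expect_equal(as.numeric(pc), 0, tolerance = 1e-10)
  }
})

test_that("interventional model is the identity for mutually independent variables", {
  m <- gaussian_model(c("X", "Y", "Z"), c(1, 2, 3), diag(c(1, 2, 3)))
  q <- interventional_model(m, "X", "Y", "Z")
  expect_equal(q$covariance, m$covariance)
  expect_equal(q$mean, m$mean)
})

test_that("kl_gaussian closed form: identity, 1-D shift, nonnegativity", {
  m <- random_model(3)
  expect_equal(kl_gaussian(m, m), 0)
  p <- gaussian_model("X", 0, matrix(1))
  q <- gaussian_model("X", 1, matrix(1))
  expect_equal(kl_gaussian(p, q), 0.5, tolerance = 1e-12)
  set.seed(51)
  for (k in 1:20) expect_gte(kl_gaussian(random_model(3), random_model(3)), 0)
  expect_error(kl_gaussian(p, random_model(2)), "same variables")
})

test_that("kl_gaussian agrees with a Monte-Carlo estimate of E_p[ln p - ln q]", {
  skip_if_not_installed("MASS")
  set.seed(61)
  p <- random_model(3)
  q <- random_model(3)
  kl <- kl_gaussian(p, q)
  draws <- MASS::mvrnorm(2e5, p$mean, p$covariance)
  lr <- gauss_logdens(draws, p$mean, p$covariance) -
        gauss_logdens(draws, q$mean, q$covariance)
  expect_lt(abs(kl - mean(lr)), 3 * sd(lr) / sqrt(length(lr)))
})

test_that("causal strength is zero under independence and positive for a direct edge", {
  ind <- gaussian_model(c("X", "Y", "Z"), rep(0, 3), diag(3))
  expect_equal(causal_strength(ind, "X", "Y", "Z", "x->y"), 0)
  expect_equal(causal_strength(ind, "X", "Y", "Z", "y->x"), 0)
  # y = x + noise, z independent
  m <- cor_model(1 / sqrt(2), 0, 0)
  expect_gt(causal_strength(m, "X", "Y", "Z", "x->y"), 0.1)
})

test_that("causal strength decomposes as CMI plus a conditional KL correction", {
  # C_{X->Y} = CMI(X;Y|Z) + D_KL(P(Y|Z) || P_{X->Y}(Y|Z)); the second term is
  # the expected KL between the two conditional laws of Y given Z.
  set.seed(71)
  for (k in 1:10) {
    m <- random_model(3)
    S <- m$covariance
    q <- interventional_model(m, "V1", "V2", "V3")
    Sq <- q$covariance[c("V1", "V2", "V3"), c("V1", "V2", "V3")]
    v1 <- S["V2", "V2"] - S["V2", "V3"]^2 / S["V3", "V3"]
    b1 <- S["V2", "V3"] / S["V3", "V3"]
    v2 <- Sq["V2", "V2"] - Sq["V2", "V3"]^2 / Sq["V3", "V3"]
    b2 <- Sq["V2", "V3"] / Sq["V3", "V3"]
    cond_kl <- 0.5 * (log(v2 / v1) - 1 +
                      (v1 + (b1 - b2)^2 * S["V3", "V3"]) / v2)
    expect_equal(causal_strength(m, "V1", "V2", "V3", "x->y"),
                 cmi(m, "V1", "V2", "V3") + cond_kl,
                 tolerance = 1e-10)
  }
})

test_that("cmi2 equals cmi and mi when the conditioner is independent of the pair", {
  m <- cor_model(0.6, 0, 0)
  expect_equal(cmi2(m, "X", "Y", "Z"), cmi(m, "X", "Y", "Z"), tolerance = 1e-12)
  expect_equal(cmi2(m, "X", "Y", "Z"), mi(m, "X", "Y"), tolerance = 1e-12)
})

test_that("cmi2 reduces to mi with an empty conditioning set (zero order)", {
  set.seed(81)
  for (k in 1:10) {
    m <- random_model(3)
    expect_equal(cmi2(m, "V1", "V2"), mi(m, "V1", "V2"), tolerance = 1e-12)
  }
})

test_that("cmi2 stays large under a near-redundant conditioner where cmi collapses", {
  m <- cor_model(0.8, 0.8 * 0.999, 0.999)
  expect_lt(cmi(m, "X", "Y", "Z"), 0.01)
  expect_gt(cmi2(m, "X", "Y", "Z"), 0.1)
  expect_equal(cmi2(m, "X", "Y", "Z"), cmi2_oracle(m, "X", "Y", "Z"),
               tolerance = 1e-8)
})

test_that("cmi2 closed form matches the interventional oracle", {
  set.seed(91)
  for (k in 1:100) {
    n <- sample(3:6, 1)
    m <- random_model(n)
    nz <- sample(seq_len(min(3, n - 2)), 1)
    z <- paste0("V", 2 + seq_len(nz))
    expect_equal(cmi2(m, "V1", "V2", z), cmi2_oracle(m, "V1", "V2", z),
                 tolerance = 1e-8)
    # oracle is by definition the average of the two causal strengths
    expect_equal(cmi2_oracle(m, "V1", "V2", z),
                 0.5 * (causal_strength(m, "V1", "V2", z, "x->y") +
                        causal_strength(m, "V1", "V2", z, "y->x")),
                 tolerance = 1e-12)
  }
})

test_that("cmi2, cmi and mi are symmetric in (x, y) and scale invariant", {
  set.seed(101)
  for (k in 1:15) {
    m <- random_model(4)
    z <- c("V3", "V4")
    expect_equal(cmi2(m, "V1", "V2", z), cmi2(m, "V2", "V1", z),
                 tolerance = 1e-12)
    expect_equal(cmi(m, "V1", "V2", z), cmi(m, "V2", "V1", z),
                 tolerance = 1e-12)
    # rescale one variable: information measures must not move
    s <- runif(1, 0.1, 10)
    S2 <- m$covariance
    S2["V1", ] <- S2["V1", ] * s
    S2[, "V1"] <- S2[, "V1"] * s
    mu2 <- m$mean
    mu2["V1"] <- mu2["V1"] * s
    m2 <- gaussian_model(m$variables, mu2, S2)
    expect_equal(mi(m2, "V1", "V2"), mi(m, "V1", "V2"), tolerance = 1e-10)
    expect_equal(cmi(m2, "V1", "V2", z), cmi(m, "V1", "V2", z),
                 tolerance = 1e-10)
    expect_equal(cmi2(m2, "V1", "V2", z), cmi2(m, "V1", "V2", z),
                 tolerance = 1e-10)
  }
})

test_that("cmi2 dominates cmi, with equality under block independence of z", {
  set.seed(111)
  for (k in 1:50) {
    m <- random_model(4)
    z <- c("V3", "V4")
    expect_gte(cmi2(m, "V1", "V2", z) - cmi(m, "V1", "V2", z), -1e-10)
  }
  # block-diagonal between {x, y} and z
  Sxy <- rspd(2)
  Sz <- rspd(2)
  S <- rbind(cbind(Sxy, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), Sz))
  m <- gaussian_model(paste0("V", 1:4), rep(0, 4), S)
  expect_equal(cmi2(m, "V1", "V2", c("V3", "V4")),
               cmi(m, "V1", "V2", c("V3", "V4")), tolerance = 1e-10)
})

test_that("partial correlation plug-in matches cov2cor arithmetic", {
  set.seed(121)
  m <- random_model(4)
  R <- stats::cov2cor(m$covariance)
  expect_equal(partial_correlation(m, "V1", "V2"), abs(R["V1", "V2"]),
               tolerance = 1e-12)
  P <- solve(m$covariance)
  expect_equal(partial_correlation(m, "V1", "V2", c("V3", "V4")),
               abs(-P[1, 2] / sqrt(P[1, 1] * P[2, 2])), tolerance = 1e-12)
})
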