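# Linear-Gaussian structural equation simulator. Each gene is a weighted
# sum of its DAG parents plus independent Gaussian noise, so the implied
# joint distribution is exactly multivariate normal and the population
# covariance is available in closed form -- the regime in which the Gaussian
# estimators have analytic ground truth.

# Run expr with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards. No hidden global state leaks.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("a single finite numeric seed is required")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Construct a linear-Gaussian DAG model
#'
#' Low-level constructor; most users will call [random_dag()] or
#' [fixture_triples()]. Genes are taken to be listed in topological order,
#' and `weights[i, j]` is the coefficient of parent gene i in the structural
#' equation of child gene j, so the weight matrix must be strictly upper
#' triangular in that order.
#'
#' @param genes character vector of unique gene names, in topological order.
#' @param weights numeric genes x genes matrix of edge coefficients,
#'   nonzero only for `i < j` (parent before child).
#' @param noise_sd positive noise standard deviation, recycled per gene.
#' @return An object of class `dag_model`.
#' @export
dag_model <- function(genes, weights, noise_sd = 1) {
  genes <- as.character(genes)
  n <- length(genes)
  if (anyDuplicated(genes)) stop("duplicate gene names")
  weights <- as.matrix(weights)
  if (!all(dim(weights) == n)) stop("weights must be ", n, " x ", n)
  if (any(weights[lower.tri(weights, diag = TRUE)] != 0)) {
    stop("weights must be strictly upper triangular in topological order")
  }
  noise_sd <- rep_len(as.numeric(noise_sd), n)
  if (any(!is.finite(noise_sd)) || any(noise_sd <= 0)) {
    stop("noise_sd must be positive and finite")
  }
  dimnames(weights) <- list(genes, genes)
  names(noise_sd) <- genes
  structure(list(genes = genes, weights = weights, noise_sd = noise_sd,
                 topological_order = genes),
            class = "dag_model")
}

#' @export
print.dag_model <- function(x, ...) {
  cat("Linear-Gaussian DAG:", length(x$genes), "genes,",
      sum(x$weights != 0), "edges\n")
  invisible(x)
}

#' Sample a random DAG
#'
#' Genes are placed in a fixed topological order and each forward pair
#' (i before j) becomes an edge independently with probability
#' `edge_density`. Edge weights are uniform on +-[0.5, 1] (sign chosen at
#' random), a range that keeps signal comparable to the unit-variance noise.
#'
#' @param n number of genes (>= 2).
#' @param edge_density probability in [0, 1] of including each forward pair.
#' @param seed RNG seed (required; the draw is reproducible per seed).
#' @param noise_sd per-gene noise standard deviation (default 1).
#' @return A [dag_model()].
#' @export
#' @examples
#' d <- random_dag(10, 0.25, seed = 1)
#' nrow(dag_edges(d))
random_dag <- function(n, edge_density, seed, noise_sd = 1) {
  if (n < 2) stop("n must be at least 2")
  if (edge_density < 0 || edge_density > 1) {
    stop("edge_density must be in [0, 1]")
  }
  .with_seed(seed, {
    genes <- sprintf("G%d", seq_len(n))
    W <- matrix(0, n, n)
    up <- which(upper.tri(W))
    present <- up[stats::runif(length(up)) < edge_density]
    W[present] <- stats::runif(length(present), 0.5, 1) *
      sample(c(-1, 1), length(present), replace = TRUE)
    dag_model(genes, W, noise_sd)
  })
}

#' Edges (skeleton) of a DAG model
#'
#' @param dag a [dag_model()].
#' @return data.frame with columns `gene_a`, `gene_b` (parent, child) and
#'   `weight`.
#' @export
dag_edges <- function(dag) {
  stopifnot(inherits(dag, "dag_model"))
  idx <- which(dag$weights != 0, arr.ind = TRUE)
  data.frame(gene_a = dag$genes[idx[, 1]],
             gene_b = dag$genes[idx[, 2]],
             weight = dag$weights[idx],
             stringsAsFactors = FALSE)
}

#' Population covariance of a linear-Gaussian DAG
#'
#' For weight matrix W (parents in rows) and noise variances D, the implied
#' covariance is `(I - W')^-1 D (I - W')^-T`, the exact second moment of the
#' structural equations. Used as the closed-form oracle for the simulator
#' and to build population [gaussian_model()]s.
#'
#' @param dag a [dag_model()].
#' @return Symmetric covariance matrix with gene dimnames.
#' @export
dag_covariance <- function(dag) {
  stopifnot(inherits(dag, "dag_model"))
  n <- length(dag$genes)
  A <- solve(diag(n) - t(dag$weights))
  S <- A %*% diag(dag$noise_sd^2, n) %*% t(A)
  dimnames(S) <- list(dag$genes, dag$genes)
  (S + t(S)) / 2
}

#' Population Gaussian model of a DAG
#'
#' @param dag a [dag_model()].
#' @return A zero-mean [gaussian_model()] with the exact
#'   [dag_covariance()].
#' @export
dag_gaussian <- function(dag) {
  gaussian_model(dag$genes, rep(0, length(dag$genes)), dag_covariance(dag),
                 preprocessing = list(population = TRUE))
}

#' Simulate expression data from a DAG model
#'
#' Draws m independent samples: each gene is computed in topological order
#' as the weighted sum of its parents plus Gaussian noise.
#'
#' @param dag a [dag_model()].
#' @param m number of samples (>= 2).
#' @param seed RNG seed (required).
#' @return Numeric genes x samples matrix with gene rownames and sample
#'   colnames `S1..Sm`.
#' @export
simulate_expression <- function(dag, m, seed) {
  stopifnot(inherits(dag, "dag_model"))
  if (m < 2) stop("m must be at least 2")
  n <- length(dag$genes)
  .with_seed(seed, {
    E <- matrix(stats::rnorm(m * n), m, n) %*% diag(dag$noise_sd, n)
    X <- matrix(0, m, n)
    for (j in seq_len(n)) {
      X[, j] <- X %*% dag$weights[, j] + E[, j]
    }
    expr <- t(X)
    dimnames(expr) <- list(dag$genes, sprintf("S%d", seq_len(m)))
    expr
  })
}

#' Population fixtures for the three canonical triple-gene scenarios
#'
#' Returns the exact population model (and generating DAG) for the three
#' situations that separate MI, CMI and CMI2 as association measures:
#'
#' * `"independent-pair"`: X regulates Y directly (correlation 0.8); Z is an
#'   unconnected gene. All three measures agree.
#' * `"mediated-chain"`: X regulates Y only through Z (X -> Z -> Y, each
#'   link correlation 0.8). MI overestimates the X-Y association; CMI and
#'   CMI2 both vanish.
#' * `"redundant-conditioner"`: X regulates Y directly (correlation 0.8) and
#'   Z tracks Y almost perfectly (correlation 0.999). Conditioning on Z
#'   drives CMI to ~0 -- the underestimation failure -- while CMI2 stays
#'   bounded away from zero.
#'
#' All variances are 1 so the covariances are correlations.
#'
#' @param scenario one of `"independent-pair"`, `"mediated-chain"`,
#'   `"redundant-conditioner"`.
#' @return list with elements `model` (population [gaussian_model()] over
#'   X, Y, Z) and `dag` (the generating [dag_model()]).
#' @export
fixture_triples <- function(scenario = c("independent-pair", "mediated-chain",
                                         "redundant-conditioner")) {
  scenario <- match.arg(scenario)
  w <- 0.8                      # link correlation for unit-variance nodes
  sd_w <- sqrt(1 - w^2)         # child noise sd keeping unit variance
  near <- 0.999                 # redundant conditioner's correlation with Y
  dag <- switch(scenario,
    "independent-pair" = {
      W <- matrix(0, 3, 3)
      W[1, 2] <- w              # X -> Y
      dag_model(c("X", "Y", "Z"), W, c(1, sd_w, 1))
    },
    "mediated-chain" = {
      # topological order X, Z, Y
      W <- matrix(0, 3, 3)
      W[1, 2] <- w              # X -> Z
      W[2, 3] <- w              # Z -> Y
      dag_model(c("X", "Z", "Y"), W, c(1, sd_w, sd_w))
    },
    "redundant-conditioner" = {
      W <- matrix(0, 3, 3)
      W[1, 2] <- w              # X -> Y
      W[2, 3] <- near           # Y -> Z (Z nearly duplicates Y)
      dag_model(c("X", "Y", "Z"), W, c(1, sd_w, sqrt(1 - near^2)))
    })
  model <- dag_gaussian(dag)
  model <- .marginal(model, c("X", "Y", "Z"))
  list(model = model, dag = dag)
}
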