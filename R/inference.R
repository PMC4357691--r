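# Path-consistency network inference engine. Starting from the complete
# graph, edges are deleted by conditional-independence tests of increasing
# order: order 0 uses MI, order L >= 1 scores every size-L conditioning set
# drawn from the pair's common neighbours and aggregates (max by default).
# The measure is pluggable: CMI2 (default), CMI (PCA-CMI style), or
# absolute partial correlation (pcalg style).

#' Inference configuration
#'
#' @param theta nonnegative independence threshold in nats (for the
#'   `"pcor"` measure, on the correlation scale). An aggregated score below
#'   `theta` deletes the edge. Default 0.03.
#' @param max_order maximum conditioning-set size L, or `Inf` for no cap
#'   (the engine always stops at `n - 2`). For networks above ~100 genes an
#'   explicit `max_order = 1` keeps the enumeration tractable.
#' @param aggregation how the scores over the `choose(T, L)` conditioning
#'   sets of a pair are combined: `"max"` (default) or `"gmean"`
#'   (geometric mean).
#' @param measure association measure: `"cmi2"`, `"cmi"` or `"pcor"`.
#' @param log_transform,pseudocount,standardize preprocessing passed to
#'   [fit_gaussian()].
#' @param degeneracy near-singular covariance policy, see [mi()].
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(theta = 0.03, max_order = Inf,
                             aggregation = c("max", "gmean"),
                             measure = c("cmi2", "cmi", "pcor"),
                             log_transform = FALSE, pseudocount = 0,
                             standardize = FALSE,
                             degeneracy = c("lenient", "strict")) {
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0) {
    stop("theta must be a single nonnegative number")
  }
  if (!(is.infinite(max_order) || (max_order >= 0 && max_order == floor(max_order)))) {
    stop("max_order must be a nonnegative integer or Inf")
  }
  structure(list(theta = theta, max_order = max_order,
                 aggregation = match.arg(aggregation),
                 measure = match.arg(measure),
                 log_transform = log_transform, pseudocount = pseudocount,
                 standardize = standardize,
                 degeneracy = match.arg(degeneracy)),
            class = "inference_config")
}

#' Common-neighbour conditioning candidates for a pair
#'
#' Genes adjacent to both endpoints of a currently present edge, excluding
#' the endpoints themselves, in the network's gene order (deterministic).
#' Their number is the T of the order-L enumeration `choose(T, L)`.
#'
#' @param net a `grn_network` from [infer_network()].
#' @param i,j gene names of an adjacent pair.
#' @return Character vector (possibly empty) of candidate gene names.
#' @export
pair_conditioning_candidates <- function(net, i, j) {
  stopifnot(inherits(net, "grn_network"))
  ii <- match(i, net$genes)
  jj <- match(j, net$genes)
  if (is.na(ii) || is.na(jj)) stop("unknown gene name")
  if (!net$adjacency[ii, jj]) stop("pair ", i, "-", j, " is not adjacent")
  net$genes[net$adjacency[ii, ] & net$adjacency[jj, ]]
}

#' Aggregate conditioning-set scores
#'
#' Combines the measure values obtained over all conditioning sets of one
#' pair at one order into the single score that is compared with theta:
#' the maximum (default), or the geometric mean (0 if any value is 0).
#'
#' @param values nonempty numeric vector of nonnegative scores.
#' @param mode `"max"` or `"gmean"`.
#' @return Single aggregated score.
#' @export
aggregate_condition_score <- function(values, mode = c("max", "gmean")) {
  mode <- match.arg(mode)
  if (length(values) == 0) stop("cannot aggregate an empty score list")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("scores must be finite and nonnegative")
  }
  if (mode == "max") return(max(values))
  if (any(values == 0)) return(0)
  exp(mean(log(values)))
}

# Measure dispatch: order-0 scores use MI (the zero-order CMI2/CMI) or the
# absolute correlation for the pcor baseline.
.measure_fun <- function(measure) {
  switch(measure,
         cmi2 = cmi2,
         cmi = cmi,
         pcor = partial_correlation)
}

#' Infer a gene regulatory network by path consistency
#'
#' Runs the iterative edge-deletion scheme on a genes x samples expression
#' matrix. Order 0 scores every pair of the complete graph with the
#' zero-order measure and deletes pairs below `theta`. At each order
#' L >= 1, every surviving pair with at least L common neighbours is scored
#' over all `choose(T, L)` conditioning sets; the aggregated score (see
#' [aggregate_condition_score()]) decides deletion. Within an order, all
#' tests are evaluated against the graph as it stood at the start of the
#' order and deletions are applied at order end, so the result does not
#' depend on pair iteration order. The loop ends when an order (L >= 1)
#' deletes nothing, when no pair has enough common neighbours, or when
#' `max_order` is reached.
#'
#' @param expr numeric genes x samples matrix (rownames = gene IDs), or the
#'   path handling of [read_expression()] upstream.
#' @param config an [inference_config()].
#' @param model optionally, a pre-fitted [gaussian_model()] (e.g. a
#'   population model); when supplied, `expr` is ignored.
#' @return An object of class `grn_network`: list with `genes`, logical
#'   symmetric `adjacency`, matrices `scores` and `decision_order` (per
#'   unordered pair: the last aggregated score computed and the order at
#'   which it was decided), the final order `order`, and the `config`.
#' @export
#' @examples
#' f <- fixture_triples("mediated-chain")
#' x <- simulate_expression(f$dag, m = 1000, seed = 7)
#' net <- infer_network(x, inference_config(theta = 0.05))
#' edge_table(net)
infer_network <- function(expr, config = inference_config(), model = NULL) {
  stopifnot(inherits(config, "inference_config"))
  if (is.null(model)) {
    model <- fit_gaussian(expr, log_transform = config$log_transform,
                          pseudocount = config$pseudocount,
                          standardize = config$standardize)
  }
  genes <- model$variables
  n <- length(genes)
  if (n < 2) stop("at least 2 genes are required")
  msr <- .measure_fun(config$measure)
  zero_order <- if (config$measure == "pcor") partial_correlation else mi

  adj <- matrix(TRUE, n, n, dimnames = list(genes, genes))
  diag(adj) <- FALSE
  scores <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  orders <- matrix(NA_integer_, n, n, dimnames = list(genes, genes))

  final_order <- 0L
  L <- -1L
  repeat {
    L <- L + 1L
    if (L > config$max_order || L > n - 2) {
      final_order <- max(L - 1L, 0L)
      break
    }
    adj0 <- adj
    tested_any <- FALSE
    deleted_any <- FALSE
    pairs <- which(upper.tri(adj0) & adj0, arr.ind = TRUE)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]
      j <- pairs[k, 2]
      if (L == 0L) {
        val <- zero_order(model, genes[i], genes[j],
                          degeneracy = config$degeneracy)
      } else {
        cand <- which(adj0[i, ] & adj0[j, ])
        if (length(cand) < L) next
        # combn(x, m) with scalar x means seq_len(x); force the set meaning
        sets <- if (length(cand) == L) matrix(cand, ncol = 1)
                else utils::combn(cand, L)
        vals <- apply(sets, 2, function(K) {
          msr(model, genes[i], genes[j], genes[K],
              degeneracy = config$degeneracy)
        })
        val <- aggregate_condition_score(vals, config$aggregation)
      }
      tested_any <- TRUE
      scores[i, j] <- scores[j, i] <- val
      orders[i, j] <- orders[j, i] <- L
      if (val < config$theta) {
        adj[i, j] <- adj[j, i] <- FALSE
        deleted_any <- TRUE
      }
    }
    if (L > 0L && !tested_any) {
      final_order <- L - 1L
      break
    }
    final_order <- L
    # order 0 always advances; thereafter a no-change order terminates
    if (L > 0L && !deleted_any) break
  }

  structure(list(genes = genes, adjacency = adj, scores = scores,
                 decision_order = orders, order = final_order,
                 config = config, model = model),
            class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  n <- length(x$genes)
  cat("Inferred network:", n, "genes,",
      sum(x$adjacency[upper.tri(x$adjacency)]), "of", choose(n, 2),
      "edges retained (measure =", x$config$measure,
      ", theta =", x$config$theta, ", final order =", x$order, ")\n")
  invisible(x)
}

#' Edge table of an inferred network
#'
#' One row per unordered gene pair ever tested, with the last score
#' computed for it, whether the edge was retained, and the order at which
#' the decision was made. Pairs are in canonical (lexicographic) order.
#'
#' @param net a `grn_network`.
#' @return data.frame with columns `gene_a`, `gene_b`, `score`, `present`,
#'   `decision_order`.
#' @export
edge_table <- function(net) {
  stopifnot(inherits(net, "grn_network"))
  idx <- which(upper.tri(net$adjacency), arr.ind = TRUE)
  a <- net$genes[idx[, 1]]
  b <- net$genes[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  df <- data.frame(gene_a = a, gene_b = b,
                   score = net$scores[idx],
                   present = net$adjacency[idx],
                   decision_order = net$decision_order[idx],
                   stringsAsFactors = FALSE)
  df[order(df$gene_a, df$gene_b), , drop = FALSE]
}

#' Rank all gene pairs by association score
#'
#' Ranks every pair tested by the engine by its final score, descending,
#' with ties broken lexicographically. Removed edges keep the score at
#' which they were removed, so a single run supports threshold-sweep ROC
#' analysis against a gold standard.
#'
#' @param net a `grn_network`.
#' @return data.frame as [edge_table()], sorted by decreasing `score`.
#' @export
edge_ranking <- function(net) {
  df <- edge_table(net)
  df <- df[order(-df$score, df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}
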