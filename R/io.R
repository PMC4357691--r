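# Readers and writers for the plain-text formats the package exchanges:
# tab-separated expression matrices (genes x samples, header row of sample
# IDs, first column of gene IDs), DREAM-style gold-standard edge lists, and
# the scored edge-list TSV the inference engine emits.

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample IDs and a first column of gene IDs; all
#' remaining cells numeric and finite. With `transpose = TRUE` the file is
#' read as samples x genes (first column sample IDs, header gene IDs) and
#' transposed into the canonical genes x samples orientation.
#'
#' @param path file path.
#' @param transpose logical; set for samples-in-rows dialects.
#' @return Numeric genes x samples matrix with dimnames.
#' @export
read_expression <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expression file needs an ID column plus data columns")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate IDs in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric or missing value at row ID '", ids[bad[1, 1]],
         "', column '", colnames(vals)[bad[1, 2]], "'")
  }
  dimnames(num) <- list(ids, colnames(vals))
  m <- if (transpose) t(num) else num
  if (anyDuplicated(rownames(m))) stop("duplicate gene IDs")
  if (anyDuplicated(colnames(m))) stop("duplicate sample IDs")
  m
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written with 17 significant digits so a write/read round trip
#' is lossless at double precision.
#'
#' @param expr numeric genes x samples matrix with dimnames.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix must have gene rownames and sample colnames")
  }
  header <- paste(c("gene", colnames(expr)), collapse = "\t")
  rows <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i], sprintf("%.17g", expr[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a DREAM-style gold-standard edge list
#'
#' Two or three tab-separated columns: regulator, target, and an optional
#' 0/1 indicator. Rows with indicator 1 (or no indicator) are positive
#' edges; rows with 0 are explicit known negatives. Directions are
#' collapsed to unordered pairs; a pair listed both as positive and as
#' negative is a contradiction error.
#'
#' @param path file path.
#' @return An object of class `gold_standard`: list with data.frames
#'   `edges` (positive pairs, canonical order) and `negatives`, plus the
#'   `genes` universe mentioned in the file.
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) stop("gold-standard file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pos <- character()
  neg <- character()
  genes <- character()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2 || length(f) > 3) {
      stop("line ", k, ": expected 2 or 3 tab-separated columns")
    }
    if (f[1] == f[2]) stop("line ", k, ": self-edge ", f[1])
    lab <- if (length(f) == 3) f[3] else "1"
    if (!lab %in% c("0", "1")) {
      stop("line ", k, ": third column must be 0 or 1, got '", lab, "'")
    }
    key <- .pair_key(f[1], f[2])
    genes <- c(genes, f[1], f[2])
    if (lab == "1") pos <- c(pos, key) else neg <- c(neg, key)
  }
  pos <- unique(pos)
  neg <- unique(neg)
  both <- intersect(pos, neg)
  if (length(both) > 0) {
    stop("contradictory gold-standard rows for pair(s): ",
         paste(gsub("\r", "-", both), collapse = ", "))
  }
  split_keys <- function(keys) {
    if (length(keys) == 0) {
      return(data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(gene_a = vapply(parts, `[`, "", 1),
               gene_b = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  }
  structure(list(edges = split_keys(pos), negatives = split_keys(neg),
                 genes = unique(genes)),
            class = "gold_standard")
}

#' Write a gold-standard edge list
#'
#' @param gold a `gold_standard`, or a data.frame of positive edges.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_gold_standard <- function(gold, path) {
  if (!inherits(gold, "gold_standard")) {
    gold <- list(edges = as.data.frame(gold, stringsAsFactors = FALSE),
                 negatives = data.frame(gene_a = character(),
                                        gene_b = character()))
  }
  lines <- c(
    if (nrow(gold$edges) > 0)
      paste(gold$edges[[1]], gold$edges[[2]], "1", sep = "\t"),
    if (nrow(gold$negatives) > 0)
      paste(gold$negatives[[1]], gold$negatives[[2]], "0", sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write an inferred network as a scored edge-list TSV
#'
#' Emits one row per tested gene pair (canonical order) with score, presence
#' flag and decision order, preceded by `#`-comment header lines recording
#' the threshold, measure, aggregation, final order and package version, so
#' the file is self-describing.
#'
#' @param net a `grn_network`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "grn_network"))
  df <- edge_table(net)
  header <- c(
    sprintf("# theta=%.17g", net$config$theta),
    sprintf("# measure=%s", net$config$measure),
    sprintf("# aggregation=%s", net$config$aggregation),
    sprintf("# order=%d", net$order),
    sprintf("# version=%s", as.character(utils::packageVersion("cmi2ni"))),
    paste(c("gene_a", "gene_b", "score", "present", "decision_order"),
          collapse = "\t")
  )
  rows <- sprintf("%s\t%s\t%.17g\t%d\t%d", df$gene_a, df$gene_b, df$score,
                  as.integer(df$present), df$decision_order)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a scored edge-list TSV
#'
#' @param path a file written by [write_edge_list()].
#' @return data.frame in [edge_table()] layout; the `#`-comment metadata is
#'   attached as the `"meta"` attribute (named character vector).
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- character()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[kv[1]] <- kv[2]
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          header = TRUE, stringsAsFactors = FALSE)
  needed <- c("gene_a", "gene_b", "score", "present", "decision_order")
  if (!all(needed %in% names(df))) {
    stop("edge list is missing columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  df$present <- as.logical(df$present)
  attr(df, "meta") <- meta
  df
}

#' Write evaluation metrics as JSON and/or TSV
#'
#' @param m a `grn_metrics` object.
#' @param json_path optional JSON output path.
#' @param tsv_path optional TSV output path.
#' @return Invisibly, the metric list that was written.
#' @export
write_metrics <- function(m, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(m, "grn_metrics"))
  out <- list(tp = m$counts$tp, fp = m$counts$fp, tn = m$counts$tn,
              fn = m$counts$fn, mode = m$counts$mode,
              tpr = m$tpr, fpr = m$fpr, ppv = m$ppv, acc = m$acc,
              mcc = m$mcc)
  if (!is.null(json_path)) {
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(tsv_path)) {
    vals <- vapply(out, function(v) {
      if (is.numeric(v) && is.na(v)) "undefined" else as.character(v)
    }, character(1))
    writeLines(c(paste(names(out), collapse = "\t"),
                 paste(vals, collapse = "\t")), tsv_path)
  }
  invisible(out)
}

#' Write ROC curve points as TSV
#'
#' @param roc a `roc_curve` from [roc_auc()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  lines <- c(sprintf("# auc=%s",
                     if (is.na(roc$auc)) "undefined"
                     else sprintf("%.17g", roc$auc)),
             "fpr\ttpr",
             sprintf("%.17g\t%.17g", roc$points$fpr, roc$points$tpr))
  writeLines(lines, path)
  invisible(path)
}
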