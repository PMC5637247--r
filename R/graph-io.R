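#' Read a gene expression matrix from TSV
#'
#' Expects a tab-separated file whose first row is a header of sample ids and
#' whose first column holds gene symbols. Returns a tibble with a `gene`
#' column followed by one numeric column per sample. Duplicate gene rows are
#' collapsed by keeping the row with the highest variance (the standard
#' microarray collapse heuristic); the collapse is reported via a message.
#'
#' @param path Path to the TSV file.
#' @param drop_missing If `TRUE`, rows containing missing values are dropped
#'   (with a message); if `FALSE` (default) such rows are an error.
#' @return A tibble (`gene` + sample columns) with at least 3 sample columns.
#' @export
read_expression_matrix <- function(path, drop_missing = FALSE) {
  lines <- readLines(path)
  if (length(lines) < 2) abort("expression file has no data rows")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) abort("line 1: malformed header (no sample columns)")
  samples <- header[-1]
  if (length(samples) >= 2 && header[[1]] != "" && anyDuplicated(samples) == 0 &&
      !any(samples == "")) {
    # header of form <gene-col-name> <sample ids...>
  } else if (anyDuplicated(samples) > 0 || any(samples == "")) {
    abort("line 1: malformed header (duplicate or empty sample ids)")
  }
  n_samp <- length(samples)
  if (n_samp < 3) {
    abort(sprintf("only %d sample columns; at least 3 are required", n_samp))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != n_samp + 1)) {
    bad <- which(nf != n_samp + 1)[1]
    abort(sprintf("line %d: expected %d fields, found %d",
                  bad + 1L, n_samp + 1L, nf[bad]))
  }
  genes <- vapply(fields, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(genes), ncol = n_samp)
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]][-1]))
    miss_txt <- fields[[i]][-1] %in% c("", "NA", "na", "NaN")
    if (anyNA(v) && any(is.na(v) & !miss_txt)) {
      j <- which(is.na(v) & !miss_txt)[1]
      abort(sprintf("line %d, column %d ('%s'): non-numeric value '%s'",
                    i + 1L, j + 1L, samples[j], fields[[i]][j + 1L]))
    }
    vals[i, ] <- v
  }
  if (anyNA(vals)) {
    bad_rows <- which(apply(vals, 1, anyNA))
    if (!drop_missing) {
      abort(sprintf(paste0("line %d: missing values (set drop_missing = TRUE ",
                           "to drop such rows)"), bad_rows[1] + 1L))
    }
    inform(sprintf("dropping %d gene row(s) with missing values",
                   length(bad_rows)))
    vals <- vals[-bad_rows, , drop = FALSE]
    genes <- genes[-bad_rows]
  }
  if (length(genes) == 0) abort("no complete gene rows after filtering")
  if (anyDuplicated(genes) > 0) {
    rv <- apply(vals, 1, var)
    keep <- rep(TRUE, length(genes))
    for (g in unique(genes[duplicated(genes)])) {
      idx <- which(genes == g)
      keep[idx] <- FALSE
      keep[idx[which.max(rv[idx])]] <- TRUE
    }
    inform(sprintf(
      "collapsed %d duplicated gene symbol(s), keeping the highest-variance row",
      sum(!keep)))
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  out <- as_tibble(as.data.frame(vals))
  names(out) <- samples
  bind_cols(tibble(gene = genes), out)
}

# numeric matrix view of an expression tibble (genes x samples)
expr_values <- function(expr) {
  stopifnot(is.data.frame(expr), "gene" %in% names(expr))
  m <- as.matrix(expr[setdiff(names(expr), "gene")])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene
  m
}

#' Write an expression tibble to TSV
#'
#' Inverse of [read_expression_matrix()] for well-formed inputs.
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param path Output path.
#' @export
write_expression_matrix <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weighted edge list from TSV
#'
#' Expects three tab-separated columns: `gene_a`, `gene_b`, `weight`. A header
#' row is auto-detected by a non-numeric third field. Duplicated unordered
#' pairs must agree in weight within 1e-9; self-loops and negative weights
#' are rejected.
#'
#' @param path Path to the TSV file.
#' @return An `iw_network` (see [gene_network()]).
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("edge-list file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    bad <- which(lengths(fields) < 3)[1]
    abort(sprintf("line %d: expected 3 tab-separated fields", bad))
  }
  first_w <- suppressWarnings(as.numeric(fields[[1]][3]))
  if (is.na(first_w)) fields <- fields[-1]  # header row
  if (length(fields) == 0) abort("edge-list file has no data rows")
  w <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(w)) {
    abort(sprintf("line %d: non-numeric weight", which(is.na(w))[1]))
  }
  gene_network(tibble(
    from = vapply(fields, `[[`, character(1), 1L),
    to = vapply(fields, `[[`, character(1), 2L),
    weight = w))
}

#' Write a weighted network to TSV or GraphML
#'
#' The TSV dialect is bit-stable: one edge per unordered pair, rows sorted
#' lexicographically by (min node, max node), weights printed with 10
#' significant digits, so `read_edge_list(write_network(net))` returns the
#' same edge set with weights equal within 1e-9. GraphML output (via igraph)
#' carries the weight as an edge attribute for generic graph tools.
#'
#' @param net An `iw_network`.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  net <- gene_network(net, nodes = attr(net, "nodes"))
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("from\tto\tweight", con)
    if (nrow(net) > 0) {
      writeLines(sprintf("%s\t%s\t%.10g", net$from, net$to, net$weight), con)
    }
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member genes. Member lists are deduplicated; sets left without genes
#' are dropped with a warning; a pathway name appearing twice with different
#' members is an error (identical duplicates are collapsed).
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `pathway`, `gene` (one row per membership),
#'   with set descriptions in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("GMT file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    abort(sprintf("line %d: fewer than 2 tab-separated fields",
                  which(lengths(fields) < 2)[1]))
  }
  names_ <- vapply(fields, `[[`, character(1), 1L)
  descs <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- lengths(members) == 0
  if (any(empty)) {
    warn(sprintf("dropping %d empty gene set(s): %s", sum(empty),
                 paste(names_[empty], collapse = ", ")))
    names_ <- names_[!empty]; descs <- descs[!empty]
    members <- members[!empty]
  }
  if (anyDuplicated(names_) > 0) {
    for (nm in unique(names_[duplicated(names_)])) {
      idx <- which(names_ == nm)
      sets <- lapply(members[idx], sort)
      if (!all(vapply(sets[-1], identical, logical(1), sets[[1]]))) {
        abort(sprintf("duplicate pathway name '%s' with different members", nm))
      }
    }
    keep <- !duplicated(names_)
    names_ <- names_[keep]; descs <- descs[keep]; members <- members[keep]
  }
  if (length(names_) == 0) abort("GMT file contains no nonempty gene sets")
  gene_sets(setNames(members, names_), descriptions = setNames(descs, names_))
}

#' Build a gene-set collection tibble
#'
#' @param x A named list of character vectors (pathway id -> gene symbols).
#' @param descriptions Optional named character vector of set descriptions.
#' @return A tibble with columns `pathway`, `gene`; pathway order follows `x`.
#' @export
gene_sets <- function(x, descriptions = NULL) {
  stopifnot(is.list(x), !is.null(names(x)), all(nzchar(names(x))))
  if (anyDuplicated(names(x)) > 0) abort("duplicate pathway names")
  x <- lapply(x, function(g) unique(as.character(g)))
  if (any(lengths(x) == 0)) abort("empty gene sets are not allowed")
  out <- tibble(
    pathway = factor(rep(names(x), lengths(x)), levels = names(x)),
    gene = unlist(x, use.names = FALSE))
  out$pathway <- as.character(out$pathway)
  attr(out, "pathway_order") <- names(x)
  attr(out, "descriptions") <- descriptions
  class(out) <- c("iw_genesets", class(as_tibble(tibble())))
  out
}

# named list view; pathway order = first appearance / original order
geneset_list <- function(sets) {
  ord <- attr(sets, "pathway_order") %||% unique(sets$pathway)
  split(sets$gene, factor(sets$pathway, levels = ord))
}

#' Write a gene-set collection to GMT
#'
#' @param sets Collection as returned by [gene_sets()] or [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lst <- geneset_list(sets)
  descs <- attr(sets, "descriptions")
  lines <- vapply(names(lst), function(nm) {
    d <- if (!is.null(descs) && nm %in% names(descs)) descs[[nm]] else "na"
    paste(c(nm, d, lst[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
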