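#' Read a PPI scaffold from a delimited edge list
#'
#' Reads a 2- or 3-column tab/space-delimited edge list (gene A, gene B,
#' optional confidence score), applies the confidence cutoff, removes
#' self-loops, and collapses duplicate edges in either orientation.  Gene
#' identifiers are bare symbol strings, matched case-sensitively; no alias
#' mapping is attempted.
#'
#' Edges without a score column pass any cutoff, so unscored (e.g. synthetic)
#' graphs flow through the same reader.
#'
#' @param path path to the edge-list file.
#' @param confidence_cutoff minimum retained score, in \[0, 1\].
#' @param verbose log retained node/edge counts to stderr.
#'
#' @return An undirected simple \code{igraph} with named vertices; the node
#'   set is the union of retained edge endpoints.
#' @export
read_scaffold <- function(path, confidence_cutoff = 0.9, verbose = FALSE) {
  stopifnot(confidence_cutoff >= 0, confidence_cutoff <= 1)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty scaffold file: ", path)
  fields <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(fields)
  # tolerate a header line (non-numeric score field, or recognised column names)
  start <- 1L
  header_names <- c("gene_a", "gene_b", "protein1", "protein2", "source",
                    "target", "node1", "node2", "from", "to")
  if ((nf[1] >= 3L && is.na(suppressWarnings(as.numeric(fields[[1]][3])))) ||
      any(tolower(fields[[1]][1:2]) %in% header_names)) start <- 2L
  bad <- which(nf[start:length(nf)] < 2L) + start - 1L
  if (length(bad)) stop("malformed edge list line ", bad[1], " in ", path)
  a <- vapply(fields[start:length(fields)], `[`, "", 1L)
  b <- vapply(fields[start:length(fields)], `[`, "", 2L)
  score <- vapply(fields[start:length(fields)], function(f) {
    if (length(f) >= 3L) f[3] else NA_character_
  }, "")
  sc <- suppressWarnings(as.numeric(score))
  badsc <- which(!is.na(score) & is.na(sc))
  if (length(badsc)) stop("non-numeric score on line ", badsc[1] + start - 1L, " in ", path)
  keep <- is.na(sc) | sc >= confidence_cutoff
  keep <- keep & a != b
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) stop("scaffold is empty after confidence filtering at ",
                            confidence_cutoff)
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[!dup]; hi <- hi[!dup]
  g <- graph_from_edgelist(cbind(lo, hi), directed = FALSE)
  if (verbose) {
    message(sprintf("scaffold: %d nodes, %d edges (cutoff %.2f)",
                    vcount(g), ecount(g), confidence_cutoff))
  }
  g
}

#' Write a scaffold as a 2-column TSV edge list
#'
#' @param scaffold an undirected \code{igraph} with named vertices.
#' @param path output path.
#' @export
write_scaffold <- function(scaffold, path) {
  el <- as_edgelist(scaffold)
  lo <- pmin(el[, 1], el[, 2]); hi <- pmax(el[, 1], el[, 2])
  ord <- order(lo, hi)
  write.table(data.frame(gene_a = lo[ord], gene_b = hi[ord]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an expression cohort
#'
#' Holds a gene-by-sample matrix of normalised (VST-like) expression values
#' together with an ordinal group label (e.g. age in months) per sample.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample IDs).
#' @param groups vector of group labels, named by sample ID or in column order.
#'
#' @return A list of class \code{"expr_cohort"} with elements \code{values}
#'   and \code{groups} (named by sample).
#' @export
expression_cohort <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in expression matrix: ",
         rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene %s, sample %s",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values))
      stop("groups must be named by sample ID or match the sample count")
    names(groups) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing)) stop("missing group label for sample ", missing[1])
  structure(list(values = values, groups = groups[colnames(values)]),
            class = "expr_cohort")
}

#' @export
print.expr_cohort <- function(x, ...) {
  cat(sprintf("expr_cohort: %d genes x %d samples, groups: %s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$groups), collapse = ", ")))
  invisible(x)
}

#' Read an expression matrix with a sample-group sidecar
#'
#' The expression file is a TSV with gene symbols in the first column and a
#' header row of sample IDs.  Group labels come from a two-column sidecar TSV
#' (sample, group).
#'
#' @param path expression TSV.
#' @param groups_path sidecar TSV mapping sample ID to group label.
#' @return An \code{\link{expression_cohort}}.
#' @export
read_expression <- function(path, groups_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stop("duplicated gene row in ", path, ": ", genes[duplicated(genes)][1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    mn <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
    bad <- which(is.na(mn) & !is.na(m))
    if (length(bad)) {
      r <- (bad[1] - 1L) %% nrow(m) + 1L
      cc <- (bad[1] - 1L) %/% nrow(m) + 1L
      stop(sprintf("non-numeric expression value at row %d, column %d of %s",
                   r, cc + 1L, path))
    }
    m <- mn
    colnames(m) <- colnames(tab)[-1]
  }
  rownames(m) <- genes
  gr <- read.delim(groups_path, stringsAsFactors = FALSE)
  groups <- setNames(gr[[2]], as.character(gr[[1]]))
  expression_cohort(m, groups)
}

#' Write an expression cohort to TSV (plus group sidecar)
#'
#' @param cohort an \code{expr_cohort}.
#' @param path expression output TSV.
#' @param groups_path group sidecar output TSV.
#' @export
write_expression <- function(cohort, path, groups_path) {
  df <- data.frame(gene = rownames(cohort$values), cohort$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(cohort$groups),
                         group = unname(cohort$groups)),
              groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a condition gene set mapped to the scaffold
#'
#' Deduplicates the input symbols and intersects them with the scaffold's
#' nodes; proximity analysis operates only on mapped genes, so off-network
#' symbols are dropped (and counted).
#'
#' @param genes character vector of gene symbols.
#' @param scaffold scaffold \code{igraph}.
#' @param name condition name.
#'
#' @return Character vector of class \code{"gene_set"} with attributes
#'   \code{name} and \code{n_dropped}.
#' @export
gene_set <- function(genes, scaffold, name = "condition") {
  genes <- unique(genes[nzchar(genes)])
  mapped <- intersect(genes, V(scaffold)$name)
  if (length(mapped) == 0L)
    stop("gene set '", name, "' has no genes on the scaffold")
  structure(mapped, class = "gene_set", name = name,
            n_dropped = length(genes) - length(mapped))
}

#' Read a one-gene-per-line condition gene set
#'
#' @param path text file, one symbol per line.
#' @param scaffold scaffold \code{igraph} used for mapping.
#' @param name condition name (default: file base name).
#' @return A \code{\link{gene_set}}.
#' @export
read_gene_set <- function(path, scaffold, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  genes <- trimws(readLines(path))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("empty gene set file: ", path)
  gene_set(genes, scaffold, name = name)
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d mapped genes (%d dropped)\n",
              attr(x, "name"), length(x), attr(x, "n_dropped")))
  invisible(x)
}

# shared TSV writer: fixed conventions so reruns are byte-identical
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
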