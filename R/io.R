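#' Read a gene expression matrix from a tab-separated file
#'
#' Expression files are plain TSV with a header row. In the default
#' `genes_rows` orientation the first column holds gene identifiers and the
#' remaining columns hold one sample each; `genes_cols` flips this (first
#' column holds sample identifiers, header names the genes).
#'
#' @param path Path to a TSV file.
#' @param orientation Either `"genes_rows"` (default) or `"genes_cols"`.
#' @return A numeric matrix, genes in rows and samples in columns, with
#'   unique gene identifiers as row names.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(data.frame(gene_id = c("G1", "G2"), s1 = c(1, 2), s2 = c(3, 4)),
#'             tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' read_expression(tf)
#' @export
read_expression <- function(path, orientation = c("genes_rows", "genes_cols")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || nrow(raw) < 1L)
    stop("expression file must have an id column plus at least one data column")
  ids <- raw[[1L]]
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(ids, colnames(raw)[-1L]))
  if (any(is.na(num))) {
    loc <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s'",
                 ids[loc[1L]], colnames(num)[loc[2L]]))
  }
  mat <- if (orientation == "genes_rows") num else t(num)
  dup <- unique(rownames(mat)[duplicated(rownames(mat))])
  if (length(dup))
    stop("duplicated gene identifiers: ", paste(dup, collapse = ", "))
  if (nrow(mat) < 2L) stop("need at least 2 genes, got ", nrow(mat))
  if (ncol(mat) < 2L) stop("need at least 2 samples, got ", ncol(mat))
  mat
}

#' Construct a network object over a fixed gene universe
#'
#' A `grn_network` is an undirected graph over an ordered gene panel,
#' stored as a two-column matrix of index pairs with `i < j`.
#'
#' @param gene_ids Character vector of unique gene identifiers.
#' @param edges Two-column integer matrix (or data frame) of gene index
#'   pairs; self-pairs are dropped, duplicates and reversed pairs collapsed.
#' @param votes Optional logical N x N matrix of per-gene directed calls
#'   made before symmetrisation (kept for auditing).
#' @return An object of class `grn_network`.
#' @export
grn_network <- function(gene_ids, edges = NULL, votes = NULL) {
  stopifnot(is.character(gene_ids), !anyDuplicated(gene_ids))
  n <- length(gene_ids)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "integer"
    if (ncol(edges) != 2L) stop("edges must have two columns")
    if (any(edges < 1L) || any(edges > n)) stop("edge index out of range")
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  colnames(edges) <- c("i", "j")
  structure(list(gene_ids = gene_ids, edges = edges, votes = votes),
            class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf("grn_network: %d genes, %d undirected edges\n",
              length(x$gene_ids), nrow(x$edges)))
  invisible(x)
}

#' Number of undirected edges in a network
#' @param net A `grn_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' Per-gene degree in the undirected edge set
#' @param net A `grn_network`.
#' @return Integer vector named by gene.
#' @export
degrees <- function(net) {
  d <- integer(length(net$gene_ids))
  if (nrow(net$edges)) {
    tab <- tabulate(c(net$edges[, 1L], net$edges[, 2L]),
                    nbins = length(net$gene_ids))
    d <- tab
  }
  names(d) <- net$gene_ids
  d
}

#' Read a gold-standard network
#'
#' Accepts the DREAM-style 3-column edge list (`geneA geneB {0,1}`), a
#' 2-column edge list (every row an edge), or a square adjacency matrix
#' with gene names on both margins. Direction is collapsed: `(A,B,1)` and
#' `(B,A,1)` yield a single unordered edge; rows labelled 0 are ignored.
#' Adjacency inputs are binarised at `> 0`; an asymmetric adjacency is
#' symmetrised by logical OR with a warning.
#'
#' @param path Path to a TSV file.
#' @param gene_ids Ordered gene panel the network indexes into.
#' @return A `grn_network`.
#' @export
read_gold_standard <- function(path, gene_ids) {
  if (!file.exists(path)) stop("gold-standard file not found: ", path)
  n <- length(gene_ids)
  lines <- readLines(path)
  # tolerate the header row write_network emits
  if (length(lines) && grepl("^gene_a\t", lines[1L]))
    lines <- lines[-1L]
  if (!length(lines)) return(grn_network(gene_ids))
  tab <- utils::read.delim(text = lines, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  # edge lists have 2-3 columns with gene names in the first two; anything
  # fully numeric and square (with or without name margins) is an adjacency
  edge_like <- ncol(tab) %in% c(2L, 3L) &&
    is.character(tab[[1L]]) && is.character(tab[[2L]]) &&
    all(tab[[1L]] %in% gene_ids | tab[[2L]] %in% gene_ids)
  if (edge_like) {
    a <- tab[[1L]]
    b <- tab[[2L]]
    lab <- if (ncol(tab) == 3L) as.numeric(tab[[3L]]) else rep(1, nrow(tab))
    unknown <- setdiff(unique(c(a, b)), gene_ids)
    if (length(unknown))
      stop("gold standard names genes absent from the panel: ",
           paste(unknown, collapse = ", "))
    keep <- lab != 0
    edges <- cbind(match(a[keep], gene_ids), match(b[keep], gene_ids))
    return(grn_network(gene_ids, edges))
  }
  if (is.character(tab[[1L]])) {
    # name margins: header row + row-name column
    adj <- as.matrix(utils::read.delim(path, header = TRUE, sep = "\t",
                                       row.names = 1L, check.names = FALSE))
  } else {
    adj <- as.matrix(tab)
  }
  if (!is.numeric(adj)) stop("could not parse gold standard as edge list ",
                             "or numeric adjacency matrix")
  if (nrow(adj) != ncol(adj)) stop("adjacency matrix is not square")
  if (nrow(adj) != n) stop("adjacency dimension ", nrow(adj),
                           " does not match panel size ", n)
  bin <- adj > 0
  if (!identical(bin, t(bin)) && !all(bin == t(bin))) {
    warning("adjacency not symmetric after binarisation; symmetrising by OR")
    bin <- bin | t(bin)
  }
  diag(bin) <- FALSE
  idx <- which(bin & upper.tri(bin), arr.ind = TRUE)
  grn_network(gene_ids, idx)
}

#' Write an inferred network to a DREAM-style edge list
#'
#' Each undirected edge becomes one row `geneA geneB weight`. When a score
#' matrix is supplied the weight is the symmetrised score
#' `max(MIP[i,j], MIP[j,i])`, otherwise 1. Rows are ordered by descending
#' weight then lexicographically, so output is diff-able.
#'
#' @param net A `grn_network`.
#' @param path Output file path.
#' @param scores Optional `rwr_scores` object (or plain score matrix).
#' @return The path, invisibly.
#' @export
write_network <- function(net, path, scores = NULL) {
  e <- net$edges
  ids <- net$gene_ids
  if (nrow(e) == 0L) {
    writeLines("gene_a\tgene_b\tweight", path)
    return(invisible(path))
  }
  w <- rep(1, nrow(e))
  if (!is.null(scores)) {
    mip <- if (inherits(scores, "rwr_scores")) scores$mip else scores
    w <- pmax(mip[e], mip[e[, c(2L, 1L), drop = FALSE]])
  }
  ord <- order(-w, ids[e[, 1L]], ids[e[, 2L]])
  df <- data.frame(gene_a = ids[e[ord, 1L]], gene_b = ids[e[ord, 2L]],
                   weight = signif(w[ord], 6L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("gene_a\tgene_b\tweight", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a metrics report as JSON
#'
#' @param report A `grn_metrics` object from [network_metrics()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(
    list(TP = report$counts$tp, FP = report$counts$fp,
         TN = report$counts$tn, FN = report$counts$fn,
         TPR = report$tpr, FPR = report$fpr,
         PPV = report$ppv, ACC = report$acc),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
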