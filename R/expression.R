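# Thresholded expression analysis of bulk and single-cell FPKM matrices.
# Positivity is inclusive: a gene is "expressed" in a cell when its FPKM is
# greater than or equal to the threshold (default 5 FPKM).

#' Read an FPKM expression matrix
#'
#' Dense format: a TSV with gene ids in the first column and one column per
#' sample/cell. Triplet format: a TSV with columns `gene`, `cell`, `fpkm`;
#' absent pairs are 0. Negative or missing values are rejected at ingestion.
#'
#' @param path Path to the file.
#' @param format `"dense"` or `"triplet"`.
#' @return Numeric matrix, genes in rows, cells in columns.
#' @export
read_expression_matrix <- function(path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "dense") {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "cell", "fpkm")
    if (!all(need %in% names(tab))) {
      stop("triplet file must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    genes <- unique(tab$gene)
    cells <- unique(tab$cell)
    m <- matrix(0, length(genes), length(cells),
                dimnames = list(genes, cells))
    m[cbind(match(tab$gene, genes), match(tab$cell, cells))] <- tab$fpkm
  }
  validate_expression_matrix(m)
}

validate_expression_matrix <- function(m) {
  if (anyNA(m)) stop("expression matrix contains missing values", call. = FALSE)
  if (any(m < 0)) stop("expression matrix contains negative FPKM", call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate cell ids", call. = FALSE)
  m
}

#' Binarize an expression matrix at a positivity threshold
#'
#' @param matrix Numeric gene-by-cell FPKM matrix.
#' @param threshold Positivity threshold in FPKM; a cell is positive for a
#'   gene when FPKM >= threshold (inclusive). Default 5.
#' @return A logical gene-by-cell matrix of class `binary_expression` with the
#'   threshold stored in attribute `"threshold"`.
#' @export
binarize <- function(matrix, threshold = 5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  validate_expression_matrix(matrix)
  b <- matrix >= threshold
  structure(b, threshold = threshold,
            class = c("binary_expression", class(b)))
}

check_genes <- function(binary, genes) {
  missing <- setdiff(genes, rownames(binary))
  if (length(missing) > 0L) {
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Prevalence of a gene across cells
#'
#' @param binary A `binary_expression` matrix.
#' @param gene Gene id.
#' @return Percentage (0-100) of cells positive for the gene.
#' @export
prevalence <- function(binary, gene) {
  check_genes(binary, gene)
  100 * mean(binary[gene, ])
}

#' Conditional coexpression fraction
#'
#' Fraction of `gene_a`-positive cells that are also positive for `gene_b`,
#' as a percentage. Asymmetric by design: conditioning is on `gene_a`. When no
#' cell is positive for `gene_a` the fraction is undefined and `NA` is
#' returned with a warning.
#'
#' @param binary A `binary_expression` matrix.
#' @param gene_a Conditioning gene.
#' @param gene_b Target gene.
#' @return Percentage in \[0, 100\], or `NA`.
#' @export
coexpression_fraction <- function(binary, gene_a, gene_b) {
  check_genes(binary, c(gene_a, gene_b))
  a <- binary[gene_a, ]
  if (!any(a)) {
    warning("no cell is positive for '", gene_a,
            "': coexpression fraction undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(a & binary[gene_b, ]) / sum(a)
}

#' Genes expressed above a mean-FPKM threshold in a cell group
#'
#' Defines the "expressed" gene set of a lineage or cell group: genes whose
#' mean FPKM over the group is at or above the threshold. The result feeds
#' [screen_proteome] as its expression restriction.
#'
#' @param matrix Numeric gene-by-cell FPKM matrix.
#' @param group_cells Character vector of cell ids (must be columns of
#'   `matrix`); must be non-empty.
#' @param threshold Mean-FPKM threshold (default 5).
#' @return Character vector of gene ids.
#' @export
expressed_gene_set <- function(matrix, group_cells = colnames(matrix),
                               threshold = 5) {
  validate_expression_matrix(matrix)
  if (length(group_cells) == 0L) stop("empty cell group", call. = FALSE)
  missing <- setdiff(group_cells, colnames(matrix))
  if (length(missing) > 0L) {
    stop("cell(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  means <- rowMeans(matrix[, group_cells, drop = FALSE])
  rownames(matrix)[means >= threshold]
}

#' Build a coexpression network from binarized expression
#'
#' An undirected edge joins genes `a` and `b` when the smaller of the two
#' conditional coexpression fractions, `min(coexpr(a|b), coexpr(b|a))`,
#' expressed as a fraction in \[0, 1\], is at or above `edge_threshold`; the
#' edge weight is that minimum. Genes with zero positive cells have undefined
#' fractions and get no edges.
#'
#' @param binary A `binary_expression` matrix.
#' @param gene_list Genes to include as nodes (default: all).
#' @param edge_threshold Minimum mutual conditional fraction in \[0, 1\]
#'   required for an edge (default 0.5).
#' @return An [igraph::graph] with vertex attribute `name` and edge attribute
#'   `weight`.
#' @export
build_network <- function(binary, gene_list = rownames(binary),
                          edge_threshold = 0.5) {
  check_genes(binary, gene_list)
  stopifnot(edge_threshold >= 0, edge_threshold <= 1)
  sub <- binary[gene_list, , drop = FALSE]
  npos <- rowSums(sub)
  joint <- sub %*% t(sub)          # joint positive-cell counts
  n <- length(gene_list)
  edges <- data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (n >= 2L) {
    idx <- which(upper.tri(joint), arr.ind = TRUE)
    a <- idx[, 1L]; b <- idx[, 2L]
    ok <- npos[a] > 0 & npos[b] > 0
    a <- a[ok]; b <- b[ok]
    w <- pmin(joint[cbind(a, b)] / npos[a], joint[cbind(a, b)] / npos[b])
    keep <- w >= edge_threshold
    edges <- data.frame(from = gene_list[a[keep]], to = gene_list[b[keep]],
                        weight = w[keep], stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = gene_list))
  g
}

#' Write a coexpression network as edge-list TSV and GraphML
#'
#' @param graph An igraph graph from [build_network].
#' @param prefix Output path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>.graphml`.
#' @return Invisibly, the two paths written.
#' @export
write_network <- function(graph, prefix) {
  edges <- igraph::as_data_frame(graph, what = "edges")
  tsv <- paste0(prefix, "_edges.tsv")
  gml <- paste0(prefix, ".graphml")
  write.table(edges, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  igraph::write_graph(graph, gml, format = "graphml")
  invisible(c(tsv, gml))
}
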