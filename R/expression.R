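#' Single-cell expression containers
#'
#' An `expr_matrix` holds a dense cells x genes matrix of non-negative
#' expression values (raw or normalized counts) together with per-cell
#' metadata (`cell_id`, and optionally `cluster`, `subject`, `group`).
#' [binarize()] produces a `binary_matrix` that keeps both the 0/1 states and
#' the source continuous values; the continuous values feed the group
#' contrast statistics later in the pipeline.
#'
#' @param values Numeric matrix, cells in rows, genes in columns. Column
#'   names are gene symbols (uppercased); row names are cell ids.
#' @param metadata Optional data frame with a `cell_id` column matching the
#'   row names, plus any of `cluster`, `subject`, `group`.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, metadata = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be >= 0", call. = FALSE)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("cell", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    stop("gene symbols required as column names", call. = FALSE)
  }
  colnames(values) <- toupper(colnames(values))
  if (anyDuplicated(colnames(values))) {
    stop("duplicate gene symbols in matrix", call. = FALSE)
  }
  if (is.null(metadata)) {
    metadata <- tibble::tibble(cell_id = rownames(values))
  } else {
    metadata <- tibble::as_tibble(metadata)
    stopifnot("cell_id" %in% names(metadata))
    metadata$cell_id <- as.character(metadata$cell_id)
    if (!all(rownames(values) %in% metadata$cell_id)) {
      stop("metadata does not cover all cells", call. = FALSE)
    }
    metadata <- metadata[match(rownames(values), metadata$cell_id), ]
  }
  structure(list(values = values, metadata = metadata), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " cells x ", ncol(x$values),
      " genes\n", sep = "")
  invisible(x)
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat("<binary_matrix> ", nrow(x$states), " cells x ", ncol(x$states),
      " genes (method: ", attr(x, "method"), ")\n", sep = "")
  invisible(x)
}

#' Load a single-cell expression matrix from disk
#'
#' Supports MatrixMarket triplets with `features`/`barcodes` sidecars (the
#' 10x convention, genes x cells on disk) and dense CSV/TSV with a header of
#' gene names and one row per cell.
#'
#' @param path Matrix file (`.mtx`, `.csv`, or `.tsv`).
#' @param format `"mtx"` or `"csv"`; guessed from the extension by default.
#' @param features,barcodes Sidecar paths for MTX input; default to
#'   `features.tsv` / `barcodes.tsv` next to the matrix.
#' @param orientation On-disk orientation, `"genes_by_cells"` (10x default
#'   for MTX) or `"cells_by_genes"`.
#' @param metadata Optional path to a metadata CSV keyed by `cell_id`, or a
#'   data frame.
#' @return An [expr_matrix()].
#' @export
load_expression <- function(path,
                            format = c("auto", "mtx", "csv"),
                            features = NULL, barcodes = NULL,
                            orientation = NULL, metadata = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "csv"
  }
  if (format == "mtx") {
    if (is.null(orientation)) orientation <- "genes_by_cells"
    dir <- dirname(path)
    if (is.null(features)) features <- file.path(dir, "features.tsv")
    if (is.null(barcodes)) barcodes <- file.path(dir, "barcodes.tsv")
    m <- as.matrix(Matrix::readMM(path))
    feat <- readr::read_tsv(features, col_names = FALSE,
                            show_col_types = FALSE)
    bc <- readr::read_tsv(barcodes, col_names = FALSE, show_col_types = FALSE)
    genes <- if (ncol(feat) >= 2) toupper(feat[[2]]) else toupper(feat[[1]])
    cells <- bc[[1]]
    if (orientation == "genes_by_cells") m <- t(m)
    if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      stop("matrix is ", nrow(m), " x ", ncol(m), " after orientation but ",
           "sidecars give ", length(cells), " barcodes and ", length(genes),
           " features", call. = FALSE)
    }
    genes <- make.unique(genes)
    dimnames(m) <- list(cells, genes)
  } else {
    if (is.null(orientation)) orientation <- "cells_by_genes"
    tab <- readr::read_delim(path, show_col_types = FALSE)
    first_chr <- !is.numeric(tab[[1]])
    ids <- if (first_chr) as.character(tab[[1]]) else NULL
    if (first_chr) tab <- tab[, -1]
    m <- as.matrix(tab)
    if (!is.null(ids)) rownames(m) <- ids
    if (orientation == "genes_by_cells") m <- t(m)
  }
  if (!is.null(metadata) && !is.data.frame(metadata)) {
    metadata <- readr::read_csv(metadata, show_col_types = FALSE)
  }
  expr_matrix(m, metadata)
}

#' Quality-control filtering of cells and genes
#'
#' Cells expressing fewer than `min_genes` genes, more than `max_genes`
#' genes, or with more than `max_mito_frac` of their counts coming from
#' mitochondrial genes are removed first; genes detected (value > 0) in fewer
#' than `min_cells_per_gene` of the surviving cells are then removed.
#'
#' @param m An [expr_matrix()].
#' @param min_genes,max_genes Per-cell detected-gene bounds (defaults 200 and
#'   2500).
#' @param max_mito_frac Maximum mitochondrial fraction (default 0.05).
#' @param min_cells_per_gene Minimum cells a gene must be detected in
#'   (default 3).
#' @param mito_prefix Gene-symbol prefix marking mitochondrial genes.
#' @param verbose Log the filter report.
#' @return A filtered [expr_matrix()].
#' @export
qc_filter <- function(m, min_genes = 200, max_genes = 2500,
                      max_mito_frac = 0.05, min_cells_per_gene = 3,
                      mito_prefix = "MT-", verbose = TRUE) {
  v <- m$values
  detected <- rowSums(v > 0)
  mito <- startsWith(colnames(v), toupper(mito_prefix))
  tot <- rowSums(v)
  mito_frac <- ifelse(tot > 0, rowSums(v[, mito, drop = FALSE]) / tot, 0)
  keep_cells <- detected >= min_genes & detected <= max_genes &
    mito_frac <= max_mito_frac
  if (!any(keep_cells)) {
    stop("qc_filter removed every cell; review thresholds", call. = FALSE)
  }
  v2 <- v[keep_cells, , drop = FALSE]
  keep_genes <- colSums(v2 > 0) >= min_cells_per_gene
  v2 <- v2[, keep_genes, drop = FALSE]
  if (verbose) {
    message("qc_filter: cells ", nrow(v), " -> ", nrow(v2),
            "; genes ", ncol(v), " -> ", ncol(v2))
  }
  expr_matrix(v2, m$metadata[keep_cells, ])
}

#' Binarize an expression matrix
#'
#' Converts expression values to the presence/absence states the Boolean
#' models are trained on. Default is the nonzero indicator (state 1 iff
#' value > 0), exploiting the bimodal, dropout-heavy nature of scRNA-seq;
#' fixed-threshold and per-gene median-of-nonzero thresholds are available as
#' alternatives. The continuous matrix is retained alongside the states.
#'
#' @param m An [expr_matrix()].
#' @param method `"nonzero"` (default), `"threshold"`, or `"median"`.
#' @param threshold Cutoff for `method = "threshold"` (state 1 iff value > t).
#' @return A `binary_matrix`: list with `states` (0/1 matrix), `continuous`
#'   (the source values), and `metadata`.
#' @export
binarize <- function(m, method = c("nonzero", "threshold", "median"),
                     threshold = 0) {
  method <- match.arg(method)
  v <- m$values
  if (any(v < 0)) stop("negative expression values", call. = FALSE)
  states <- switch(method,
    nonzero = (v > 0),
    threshold = (v > threshold),
    median = {
      med <- apply(v, 2, function(col) {
        nz <- col[col > 0]
        if (!length(nz)) Inf else median(nz)
      })
      sweep(v, 2, med, `>`)
    }
  )
  storage.mode(states) <- "integer"
  structure(
    list(states = states, continuous = v, metadata = m$metadata),
    class = "binary_matrix", method = method
  )
}

#' Subset cells by cluster and contrast groups
#'
#' @param b A `binary_matrix` (or [expr_matrix()]).
#' @param cluster Cluster label to keep (requires a `cluster` metadata
#'   column); `NULL` keeps all clusters.
#' @param groups Optional pair of group labels defining the contrast.
#' @param verbose Log group sizes.
#' @return The subsetted object, same class as the input.
#' @export
subset_cells <- function(b, cluster = NULL, groups = NULL, verbose = TRUE) {
  meta <- b$metadata
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(cluster)) {
    if (!"cluster" %in% names(meta)) stop("no cluster metadata", call. = FALSE)
    if (!cluster %in% meta$cluster) {
      stop("cluster '", cluster, "' not present in metadata", call. = FALSE)
    }
    keep <- keep & meta$cluster == cluster
  }
  if (!is.null(groups)) {
    stopifnot(length(groups) == 2, "group" %in% names(meta))
    keep <- keep & meta$group %in% groups
    for (g in groups) {
      n_g <- sum(keep & meta$group == g)
      if (n_g == 0) stop("group '", g, "' has no cells in subset",
                         call. = FALSE)
      if (verbose) message("group ", g, ": ", n_g, " cells")
    }
  }
  if (!any(keep)) stop("subset is empty", call. = FALSE)
  if (inherits(b, "binary_matrix")) {
    structure(
      list(states = b$states[keep, , drop = FALSE],
           continuous = b$continuous[keep, , drop = FALSE],
           metadata = meta[keep, ]),
      class = "binary_matrix", method = attr(b, "method")
    )
  } else {
    expr_matrix(b$values[keep, , drop = FALSE], meta[keep, ])
  }
}

#' Write binary states as a plain TSV of 0/1 values
#'
#' @param b A `binary_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binary_tsv <- function(b, path) {
  df <- tibble::as_tibble(b$states)
  df <- dplyr::bind_cols(tibble::tibble(cell_id = rownames(b$states)), df)
  readr::write_tsv(df, path)
  invisible(path)
}
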