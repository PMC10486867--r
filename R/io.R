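#' Coerce and validate a cell x gene UMI count matrix
#'
#' All of the package works on sparse cell x gene matrices of non-negative
#' integer UMI counts, with unique gene names as column names and unique cell
#' barcodes as row names. Duplicate gene names are disambiguated
#' deterministically by appending ".1", ".2", ...
#'
#' @param counts a matrix or `Matrix::sparseMatrix`, cells in rows.
#' @param gene_names,barcodes optional character vectors overriding dimnames.
#' @return A `dgCMatrix` with validated dimnames.
#' @export
as_count_matrix <- function(counts, gene_names = NULL, barcodes = NULL) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(counts, "dMatrix")   # pattern/logical -> numeric
  counts <- methods::as(methods::as(counts, "CsparseMatrix"),
                        "generalMatrix")
  v <- counts@x
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers")
  }
  if (!is.null(gene_names)) colnames(counts) <- gene_names
  if (!is.null(barcodes)) rownames(counts) <- barcodes
  if (is.null(colnames(counts)) && ncol(counts) > 0) {
    colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  }
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    rownames(counts) <- paste0("cell", seq_len(nrow(counts)))
  }
  if (anyDuplicated(colnames(counts))) {
    colnames(counts) <- make.unique(colnames(counts), sep = ".")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("cell barcodes must be unique")
  }
  if (length(colnames(counts)) != ncol(counts) ||
      length(rownames(counts)) != nrow(counts)) {
    stop("dimension / name-list length mismatch")
  }
  counts
}

read_lines_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    readLines(con)
  } else {
    readLines(path)
  }
}

first_existing <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Read a 10x Genomics triplet-format count matrix
#'
#' Reads a directory holding a MatrixMarket `matrix.mtx(.gz)` plus
#' `barcodes.tsv(.gz)` and either `genes.tsv(.gz)` (v2) or
#' `features.tsv(.gz)` (v3), or a path directly to the `.mtx` file with its
#' sidecars alongside. 10x stores genes x cells; the result is transposed so
#' that rows are cells.
#'
#' @param path directory or `.mtx`/`.mtx.gz` file path.
#' @return A cell x gene `dgCMatrix` (see [as_count_matrix()]).
#' @export
read_10x <- function(path) {
  if (dir.exists(path)) {
    mtx <- first_existing(path, c("matrix.mtx", "matrix.mtx.gz"))
    if (is.null(mtx)) stop("no matrix.mtx[.gz] found in ", path)
  } else {
    mtx <- path
    path <- dirname(path)
  }
  genes_f <- first_existing(path, c("features.tsv", "features.tsv.gz",
                                    "genes.tsv", "genes.tsv.gz"))
  bc_f <- first_existing(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  if (is.null(genes_f) || is.null(bc_f)) {
    stop("missing features/genes or barcodes TSV next to ", mtx)
  }
  m <- read_mm(mtx)
  genes_tab <- utils::read.table(text = read_lines_maybe_gz(genes_f),
                                 sep = "\t", header = FALSE,
                                 stringsAsFactors = FALSE, quote = "",
                                 comment.char = "")
  # v2/v3 carry (id, symbol[, type]); prefer the symbol column when present
  gene_names <- if (ncol(genes_tab) >= 2) genes_tab[[2]] else genes_tab[[1]]
  barcodes <- read_lines_maybe_gz(bc_f)
  if (nrow(m) == length(gene_names) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)                    # 10x orientation: genes x cells
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(gene_names))) {
    stop(sprintf(
      "matrix is %d x %d but there are %d genes and %d barcodes",
      nrow(m), ncol(m), length(gene_names), length(barcodes)))
  }
  as_count_matrix(m, gene_names = gene_names, barcodes = barcodes)
}

read_mm <- function(path) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = ".mtx")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(read_lines_maybe_gz(path), tmp)
    path <- tmp
  }
  Matrix::readMM(path)
}

#' Write a count matrix in 10x triplet format
#'
#' Writes `matrix.mtx`, `barcodes.tsv` and both `genes.tsv` (v2) so the
#' directory round-trips through [read_10x()]. Genes are stored as rows, the
#' 10x convention.
#'
#' @param counts cell x gene count matrix.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_10x <- function(counts, dir) {
  counts <- as_count_matrix(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(counts), file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(id = colnames(counts), symbol = colnames(counts)),
    file.path(dir, "genes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a dense TSV count matrix (first column barcodes, header gene names)
#' @param path TSV file.
#' @return A cell x gene `dgCMatrix`.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.table(text = read_lines_maybe_gz(path), sep = "\t",
                           header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  as_count_matrix(as.matrix(tab))
}

#' QC parameters for cell filtering
#'
#' Defaults follow common scRNA-seq practice: drop cells with fewer than 200
#' detected genes, more than 2500 detected genes, or more than 5% of UMIs on
#' mitochondrial genes (matched case-insensitively by name prefix).
#'
#' @param min_genes,max_genes bounds on the number of detected (count > 0)
#'   genes; a cell is kept when its detected-gene count is in
#'   `[min_genes, max_genes]`.
#' @param max_mito_frac maximum mitochondrial UMI fraction, in `[0, 1]`.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_genes = 200L, max_genes = 2500L,
                      max_mito_frac = 0.05, mito_prefix = "MT-") {
  if (min_genes > max_genes) stop("min_genes must be <= max_genes")
  if (max_mito_frac < 0 || max_mito_frac > 1) {
    stop("max_mito_frac must be in [0, 1]")
  }
  structure(list(min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 max_mito_frac = max_mito_frac,
                 mito_prefix = mito_prefix),
            class = "qc_params")
}

#' Filter cells by detected genes and mitochondrial fraction
#'
#' Removal conditions are strict (a cell is removed when it has strictly
#' fewer than `min_genes` detected genes, strictly more than `max_genes`, or
#' a mitochondrial fraction strictly above `max_mito_frac`), so the kept
#' interval is closed. Idempotent.
#'
#' @param counts cell x gene count matrix.
#' @param params a [qc_params()] object.
#' @return The subset of rows (cells) passing QC.
#' @export
qc_filter <- function(counts, params = qc_params()) {
  counts <- as_count_matrix(counts)
  stopifnot(inherits(params, "qc_params"))
  detected <- Matrix::rowSums(counts > 0)
  total <- Matrix::rowSums(counts)
  mito <- startsWith(toupper(colnames(counts)), toupper(params$mito_prefix))
  mito_umis <- if (any(mito)) {
    Matrix::rowSums(counts[, mito, drop = FALSE])
  } else {
    numeric(nrow(counts))
  }
  mito_frac <- ifelse(total > 0, mito_umis / total, 0)
  keep <- detected >= params$min_genes & detected <= params$max_genes &
    mito_frac <= params$max_mito_frac
  counts[keep, , drop = FALSE]
}

#' Normalize UMI counts to per-cell gene proportions
#'
#' Divides each cell's counts by its total so rows lie on the simplex;
#' all-zero cells stay all-zero and are flagged in the `"zero_cells"`
#' attribute.
#'
#' @param counts cell x gene count matrix.
#' @return A dense cell x gene matrix of proportions with attribute
#'   `zero_cells` (integer row indices of all-zero cells).
#' @export
normalize_proportions <- function(counts) {
  counts <- as_count_matrix(counts)
  total <- Matrix::rowSums(counts)
  zero <- as.integer(which(total == 0))
  scale <- ifelse(total > 0, 1 / total, 0)
  props <- as.matrix(Matrix::Diagonal(x = scale) %*% counts)
  dimnames(props) <- dimnames(counts)
  attr(props, "zero_cells") <- zero
  props
}
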