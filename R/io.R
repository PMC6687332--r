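#' Read a genes x cells UMI count matrix
#'
#' Two on-disk dialects are supported: `mtx_triplet` (a directory holding
#' `matrix.mtx` in MatrixMarket coordinate format plus `genes.tsv` and
#' `barcodes.tsv` sidecars, the 10x-style triplet layout) and `csv` (a dense
#' matrix with gene identifiers in the first column and barcodes as header).
#'
#' @param path directory (mtx_triplet) or file (csv).
#' @param format one of `"mtx_triplet"`, `"csv"`.
#' @return sparse dgCMatrix with gene rownames and barcode colnames.
#' @export
read_counts <- function(path, format = c("mtx_triplet", "csv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf)) if (!file.exists(f)) stop("missing file: ", f)
    .check_mtx_entries(mtx)
    m <- Matrix::readMM(mtx)
    genes <- read.delim(gf, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    barcodes <- read.delim(bf, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    if (nrow(m) != length(genes))
      stop("dimension mismatch: matrix.mtx has ", nrow(m), " rows but ",
           gf, " lists ", length(genes), " genes")
    if (ncol(m) != length(barcodes))
      stop("dimension mismatch: matrix.mtx has ", ncol(m), " columns but ",
           bf, " lists ", length(barcodes), " barcodes")
    dimnames(m) <- list(genes, barcodes)
    m <- as(m, "CsparseMatrix")
  } else {
    df <- read.csv(path, row.names = 1L, check.names = FALSE)
    m <- as(as.matrix(df), "CsparseMatrix")
  }
  validate_counts(m)
  m
}

# a MatrixMarket coordinate file must hold exactly as many entry lines as
# its size line declares; readMM silently tolerates truncation
.check_mtx_entries <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  declared <- NA_integer_
  entries <- 0L
  repeat {
    chunk <- readLines(con, n = 65536L)
    if (!length(chunk)) break
    chunk <- chunk[!startsWith(chunk, "%") & nzchar(chunk)]
    if (is.na(declared) && length(chunk)) {
      declared <- as.integer(strsplit(trimws(chunk[1L]), "\\s+")[[1L]][3L])
      chunk <- chunk[-1L]
    }
    entries <- entries + length(chunk)
  }
  if (is.na(declared)) stop("invalid MatrixMarket header in ", path)
  if (entries != declared)
    stop(path, " declares ", declared, " nonzero entries but contains ",
         entries)
  invisible(TRUE)
}

#' Write a count matrix
#'
#' @param counts genes x cells matrix with dimnames.
#' @param path output directory (mtx_triplet) or file (csv).
#' @param format one of `"mtx_triplet"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("mtx_triplet", "csv")) {
  format <- match.arg(format)
  validate_counts(counts)
  if (format == "mtx_triplet") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    Matrix::writeMM(as(as(counts, "CsparseMatrix"), "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(counts), file.path(path, "genes.tsv"))
    writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
  } else {
    write.csv(as.matrix(counts), path, quote = FALSE)
  }
  invisible(path)
}

#' Validate the count-matrix contract
#'
#' @param counts genes x cells matrix.
#' @return `counts`, invisibly; errors on duplicate identifiers, negative or
#'   non-integral entries.
#' @export
validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry gene rownames and barcode colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell barcodes")
  x <- if (methods::is(counts, "sparseMatrix")) counts@x else as.vector(counts)
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be nonnegative integers")
  invisible(counts)
}

#' Read / write the per-cell annotation table
#'
#' TSV with fixed column order: barcode, condition, cluster, then any QC
#' columns present (umi_total, mito_fraction, qc_pass).
#'
#' @param cells data.frame with at least barcode, condition, cluster.
#' @param path file path.
#' @return the table (read) or `path` invisibly (write).
#' @export
write_cell_table <- function(cells, path) {
  lead <- c("barcode", "condition", "cluster")
  stopifnot(all(lead %in% names(cells)))
  rest <- intersect(c("umi_total", "mito_fraction", "qc_pass"), names(cells))
  write.table(cells[, c(lead, rest)], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  cells <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("barcode", "condition", "cluster") %in% names(cells)))
  if ("qc_pass" %in% names(cells)) cells$qc_pass <- as.logical(cells$qc_pass)
  cells
}
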