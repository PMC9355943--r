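#' Read a MatrixMarket triplet with gene/barcode sidecar files
#'
#' Reads the droplet-pipeline convention of a sparse counts matrix stored as a
#' MatrixMarket coordinate file plus one-entry-per-line gene and barcode label
#' files.
#'
#' @param matrix_path path to the .mtx coordinate file.
#' @param genes_path path to the gene id file (one id per line).
#' @param barcodes_path path to the barcode/observation id file.
#' @return ExpressionMatrix with \code{layer = "counts"}.
#' @export
read_mtx_triplet <- function(matrix_path, genes_path, barcodes_path) {
  values <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  barcodes <- readLines(barcodes_path)
  if (nrow(values) != length(genes))
    stop("format error: matrix has ", nrow(values), " rows but ",
         length(genes), " gene labels")
  if (ncol(values) != length(barcodes))
    stop("format error: matrix has ", ncol(values), " columns but ",
         length(barcodes), " barcode labels")
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("format error: duplicate gene ids: ", paste(dup, collapse = ", "))
  expression_matrix(methods::as(values, "CsparseMatrix"), genes, barcodes,
                    layer = "counts")
}

#' Write an ExpressionMatrix as a MatrixMarket triplet
#'
#' Only nonzero entries are written. The integer dialect is the default for
#' counts; requesting it with non-integer values is an error.
#'
#' @param m ExpressionMatrix with \code{layer = "counts"}.
#' @param out_prefix path prefix; writes \code{<prefix>.mtx},
#'   \code{<prefix>.genes.txt}, \code{<prefix>.barcodes.txt}.
#' @param integer write the integer MatrixMarket dialect (default TRUE).
#' @return invisibly, a named character vector of the three paths written.
#' @export
write_mtx_triplet <- function(m, out_prefix, integer = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stop("write_mtx_triplet requires a counts layer")
  v <- methods::as(methods::as(m$values, "CsparseMatrix"), "TsparseMatrix")
  i <- methods::slot(v, "i") + 1L
  j <- methods::slot(v, "j") + 1L
  x <- methods::slot(v, "x")
  keep <- x != 0
  i <- i[keep]; j <- j[keep]; x <- x[keep]
  if (integer && any(x != round(x)))
    stop("format error: non-integer values with integer dialect requested")
  field <- if (integer) "integer" else "real"
  paths <- c(matrix = paste0(out_prefix, ".mtx"),
             genes = paste0(out_prefix, ".genes.txt"),
             barcodes = paste0(out_prefix, ".barcodes.txt"))
  # column-major order, the convention CellRanger-style writers follow
  ord <- order(j, i)
  body <- if (integer)
    sprintf("%d %d %d", i[ord], j[ord], as.integer(round(x[ord])))
  else sprintf("%d %d %.10g", i[ord], j[ord], x[ord])
  writeLines(c(sprintf("%%%%MatrixMarket matrix coordinate %s general", field),
               sprintf("%d %d %d", nrow(v), ncol(v), length(i)), body),
             paths["matrix"])
  writeLines(m$gene_ids, paths["genes"])
  writeLines(m$obs_ids, paths["barcodes"])
  invisible(paths)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated as
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate genes within
#' a set are collapsed (first occurrence kept); set order follows the file.
#'
#' @param path GMT file path.
#' @return a \code{GeneSetCollection}: named list of sets, each a list with
#'   \code{description} and \code{genes}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in seq_along(lines)) {
    fields <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("format error: line ", ln, " has fewer than 3 tab-separated fields")
    name <- fields[[1]]
    if (name %in% names(sets))
      stop("format error: duplicate set name '", name, "' at line ", ln)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("format error: set '", name, "' at line ", ln, " has no genes")
    sets[[name]] <- list(description = fields[[2]], genes = genes)
  }
  structure(sets, class = "GeneSetCollection")
}

#' Write a GMT gene-set collection
#' @param collection GeneSetCollection or a named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    if (is.character(s)) s <- list(description = "", genes = s)
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read and validate a bulk sample metadata table
#'
#' Expects a delimited table with header containing \code{sample_id} and any
#' of the phenotype/covariate columns \code{steatosis},
#' \code{lobular_inflammation} (ordinal grades 0-2), \code{fibrosis} (0/1),
#' \code{bmi}, \code{age}, \code{sex}. Ordinal phenotypes are validated
#' against their grade ranges; rows with missing covariates are flagged in the
#' \code{incomplete} attribute.
#'
#' @param path TSV/CSV path (delimiter sniffed from the header line).
#' @return data.frame keyed by \code{sample_id} (also rownames).
#' @export
read_sample_metadata <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicated sample_id: ", paste(dup, collapse = ", "))
  ranges <- list(steatosis = 0:2, lobular_inflammation = 0:2, fibrosis = 0:1)
  for (col in intersect(names(ranges), names(df))) {
    v <- df[[col]]
    bad <- !is.na(v) & !(v %in% ranges[[col]])
    if (any(bad))
      stop("validation error: ", col, " must be encoded as ",
           paste(ranges[[col]], collapse = ", "), "; offending sample(s): ",
           paste(df$sample_id[bad], collapse = ", "))
  }
  covars <- intersect(c("bmi", "age", "sex"), names(df))
  incomplete <- df$sample_id[rowSums(is.na(df[, covars, drop = FALSE])) > 0]
  rownames(df) <- df$sample_id
  attr(df, "incomplete") <- incomplete
  df
}

#' Write a sample metadata table as TSV
#' @param meta data.frame with sample_id column.
#' @param path output path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
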