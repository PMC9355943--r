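#' Construct an ExpressionMatrix
#'
#' The central container of the pipeline: a genes x observations matrix of
#' counts or transformed values, with ordered gene and observation identifiers
#' and an optional per-observation metadata table (donor, cell type, phenotype
#' grades, covariates).
#'
#' @param values numeric matrix or sparse \code{Matrix} (rows = genes,
#'   columns = observations).
#' @param gene_ids character vector of unique gene identifiers, one per row.
#'   Defaults to \code{rownames(values)}.
#' @param obs_ids character vector of unique observation identifiers, one per
#'   column. Defaults to \code{colnames(values)}.
#' @param obs_meta optional \code{data.frame} keyed by observation id (either
#'   rownames or an \code{obs_id} column); reordered to match \code{obs_ids}.
#' @param layer one of \code{"counts"}, \code{"lognorm"}, \code{"scaled"};
#'   records which transformation the values carry. Counts must be
#'   non-negative.
#' @return An object of class \code{ExpressionMatrix}: a list with elements
#'   \code{values}, \code{gene_ids}, \code{obs_ids}, \code{obs_meta},
#'   \code{layer}.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              obs_ids = colnames(values), obs_meta = NULL,
                              layer = c("counts", "lognorm", "scaled")) {
  layer <- match.arg(layer)
  if (is.null(gene_ids) || is.null(obs_ids))
    stop("gene_ids and obs_ids are required (or set dimnames on 'values')")
  gene_ids <- as.character(gene_ids)
  obs_ids <- as.character(obs_ids)
  if (nrow(values) != length(gene_ids))
    stop("row count (", nrow(values), ") != length(gene_ids) (",
         length(gene_ids), ")")
  if (ncol(values) != length(obs_ids))
    stop("column count (", ncol(values), ") != length(obs_ids) (",
         length(obs_ids), ")")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  dup <- obs_ids[duplicated(obs_ids)]
  if (length(dup))
    stop("duplicate observation ids: ", paste(unique(dup), collapse = ", "))
  if (layer == "counts" && min_value(values) < 0)
    stop("counts layer must be non-negative")
  dimnames(values) <- list(gene_ids, obs_ids)
  if (!is.null(obs_meta)) {
    obs_meta <- as.data.frame(obs_meta)
    key <- if ("obs_id" %in% names(obs_meta)) as.character(obs_meta$obs_id)
           else if ("sample_id" %in% names(obs_meta))
             as.character(obs_meta$sample_id)
           else rownames(obs_meta)
    if (!all(obs_ids %in% key))
      stop("obs_meta does not cover all observations")
    obs_meta <- obs_meta[match(obs_ids, key), , drop = FALSE]
    rownames(obs_meta) <- obs_ids
  }
  structure(list(values = values, gene_ids = gene_ids, obs_ids = obs_ids,
                 obs_meta = obs_meta, layer = layer),
            class = "ExpressionMatrix")
}

min_value <- function(x) {
  if (inherits(x, "sparseMatrix")) {
    v <- methods::slot(methods::as(x, "CsparseMatrix"), "x")
    min(c(0, v))
  } else min(x)
}

#' @exportS3Method base::print
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d observations [%s]\n",
              length(x$gene_ids), length(x$obs_ids), x$layer))
  if (!is.null(x$obs_meta))
    cat("  obs_meta columns:", paste(names(x$obs_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by gene and/or observation identifiers
#'
#' Order of the supplied identifiers is respected; metadata rows follow the
#' observations.
#'
#' @param m ExpressionMatrix.
#' @param genes,obs character vectors of identifiers to keep (default: all).
#' @return ExpressionMatrix.
#' @export
em_subset <- function(m, genes = NULL, obs = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  genes <- if (is.null(genes)) m$gene_ids else as.character(genes)
  obs <- if (is.null(obs)) m$obs_ids else as.character(obs)
  bad <- setdiff(genes, m$gene_ids)
  if (length(bad)) stop("unknown genes: ", paste(bad[1:min(5, length(bad))],
                                                 collapse = ", "))
  bad <- setdiff(obs, m$obs_ids)
  if (length(bad)) stop("unknown observations: ",
                        paste(bad[1:min(5, length(bad))], collapse = ", "))
  expression_matrix(m$values[genes, obs, drop = FALSE], genes, obs,
                    if (!is.null(m$obs_meta)) m$obs_meta[obs, , drop = FALSE],
                    layer = m$layer)
}

#' Dense numeric matrix of an ExpressionMatrix
#' @param m ExpressionMatrix.
#' @return base numeric matrix (genes x observations).
#' @export
em_dense <- function(m) as.matrix(m$values)
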