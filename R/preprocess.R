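#' Quality-control filter on cells
#'
#' Keeps cells whose detected-gene count lies in [min_genes, max_genes] and
#' whose mitochondrial count fraction is at most max_mito_frac. Genes and the
#' order of surviving cells are unchanged.
#'
#' @param m counts ExpressionMatrix.
#' @param min_genes,max_genes bounds on the number of genes with nonzero
#'   counts per cell.
#' @param max_mito_frac maximum fraction of counts on mitochondrial genes.
#' @param mito_prefix gene-id prefix identifying mitochondrial genes.
#' @return filtered ExpressionMatrix.
#' @export
qc_filter_cells <- function(m, min_genes = 200, max_genes = 6000,
                            max_mito_frac = 0.2, mito_prefix = "MT-") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stop("qc_filter_cells requires a counts layer")
  detected <- Matrix::colSums(m$values > 0)
  totals <- Matrix::colSums(m$values)
  mito <- startsWith(m$gene_ids, mito_prefix)
  mito_frac <- if (any(mito))
    Matrix::colSums(m$values[mito, , drop = FALSE]) / pmax(totals, 1)
  else rep(0, length(totals))
  keep <- detected >= min_genes & detected <= max_genes &
    mito_frac <= max_mito_frac
  if (!any(keep)) stop("no cells survive QC thresholds")
  em_subset(m, obs = m$obs_ids[keep])
}

#' Log-normalize single-cell counts
#'
#' Per cell: value -> log1p(value * target_sum / cell_total), with target_sum
#' the median cell total (overridable).
#'
#' @param m counts ExpressionMatrix.
#' @param target_sum scaling target; default the median of cell totals.
#' @return lognorm-layer ExpressionMatrix (dense).
#' @export
normalize_log <- function(m, target_sum = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stop("normalize_log requires a counts layer")
  totals <- Matrix::colSums(m$values)
  if (any(totals == 0))
    stop("cell(s) with zero total count: ",
         paste(utils::head(m$obs_ids[totals == 0], 5), collapse = ", "),
         " (QC-filter first)")
  if (is.null(target_sum)) target_sum <- stats::median(totals)
  v <- em_dense(m)
  v <- log1p(sweep(v, 2, target_sum / totals, `*`))
  expression_matrix(v, m$gene_ids, m$obs_ids, m$obs_meta, layer = "lognorm")
}

#' Median-of-ratios normalization for bulk counts
#'
#' The DESeq-style size factor: per sample, the median over
#' all-samples-nonzero genes of count / geometric-mean-across-samples; values
#' are divided by the sample's factor.
#'
#' @param m counts ExpressionMatrix (genes x samples).
#' @return list with \code{expr} (normalized ExpressionMatrix, counts layer
#'   semantics retained as normalized counts) and \code{size_factors}.
#' @export
normalize_median_of_ratios <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts")
    stop("normalize_median_of_ratios requires a counts layer")
  v <- em_dense(m)
  all_nonzero <- rowSums(v == 0) == 0
  if (!any(all_nonzero))
    stop("no gene has nonzero counts in all samples")
  loggeo <- rowMeans(log(v[all_nonzero, , drop = FALSE]))
  sf <- apply(v[all_nonzero, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - loggeo)))
  norm <- sweep(v, 2, sf, `/`)
  out <- expression_matrix(norm, m$gene_ids, m$obs_ids, m$obs_meta,
                           layer = "counts")
  list(expr = out, size_factors = stats::setNames(sf, m$obs_ids))
}

#' Z-score genes within batches
#'
#' Per gene, within each batch (donor): subtract the batch mean and divide by
#' the batch SD; genes constant within a batch become 0 there. This removes
#' donor differences in average and variance before network construction.
#'
#' @param m lognorm ExpressionMatrix.
#' @param batch_labels one label per observation (defaults to
#'   \code{obs_meta$donor}).
#' @return scaled-layer ExpressionMatrix.
#' @export
scale_within_batch <- function(m, batch_labels = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm") stop("scale_within_batch requires a lognorm layer")
  if (is.null(batch_labels)) batch_labels <- m$obs_meta$donor
  if (is.null(batch_labels)) stop("no batch labels supplied or in obs_meta")
  if (length(batch_labels) != length(m$obs_ids))
    stop("batch_labels length mismatch")
  tab <- table(batch_labels)
  if (any(tab < 2))
    stop("batch(es) with a single observation: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  v <- em_dense(m)
  for (b in names(tab)) {
    idx <- which(batch_labels == b)
    sub <- v[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sd <- apply(sub, 1, stats::sd)
    sub <- (sub - mu) / ifelse(sd == 0, 1, sd)
    sub[sd == 0, ] <- 0
    v[, idx] <- sub
  }
  expression_matrix(v, m$gene_ids, m$obs_ids, m$obs_meta, layer = "scaled")
}

#' Select highly variable genes
#'
#' Top n genes by variance of log-normalized expression; ties broken by gene
#' id order.
#'
#' @param m lognorm ExpressionMatrix.
#' @param n_top number of genes to return.
#' @return character vector of gene ids, ranked.
#' @export
select_hvgs <- function(m, n_top) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm") stop("select_hvgs requires a lognorm layer")
  if (n_top > length(m$gene_ids))
    stop("n_top exceeds the number of genes")
  vars <- apply(em_dense(m), 1, stats::var)
  ord <- order(-vars, m$gene_ids)
  m$gene_ids[ord][seq_len(n_top)]
}

#' Cluster cells by PCA, k-nearest-neighbour graph and Louvain communities
#'
#' PCA on the scaled matrix, a symmetrized unweighted kNN graph on the PC
#' scores, and modularity-based (Louvain) community detection with a
#' resolution parameter. Deterministic given the seed.
#'
#' @param m scaled ExpressionMatrix.
#' @param n_pcs number of principal components.
#' @param k_neighbors neighbours per cell.
#' @param resolution Louvain resolution.
#' @param seed integer seed.
#' @return a \code{ClusterResult}: list with \code{labels} (named integer
#'   vector, dense ids from 0), \code{params}, \code{modularity}.
#' @export
cluster_cells <- function(m, n_pcs = 20, k_neighbors = 15, resolution = 1,
                          seed = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "scaled") stop("cluster_cells requires a scaled layer")
  n_cells <- length(m$obs_ids)
  if (k_neighbors >= n_cells) stop("k_neighbors must be below the cell count")
  scores <- pca_scores(em_dense(m), n_pcs)
  g <- knn_graph(scores, k_neighbors)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(comm)) - 1L
  names(labels) <- m$obs_ids
  structure(list(labels = labels,
                 params = list(n_pcs = n_pcs, k_neighbors = k_neighbors,
                               resolution = resolution, seed = seed),
                 modularity = max(igraph::modularity(comm))),
            class = "ClusterResult")
}

#' @exportS3Method base::print
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d cells, %d clusters, modularity %.3f\n",
              length(x$labels), length(unique(x$labels)), x$modularity))
  invisible(x)
}

pca_scores <- function(v, n_pcs) {
  # cells x genes; centre only (genes already scaled upstream)
  n_pcs <- min(n_pcs, nrow(v) - 1L, ncol(v))
  p <- stats::prcomp(t(v), center = TRUE, scale. = FALSE, rank. = n_pcs)
  p$x
}

knn_graph <- function(scores, k) {
  d <- as.matrix(stats::dist(scores))
  n <- nrow(d)
  nbr <- t(apply(d, 1, function(row) order(row)[2:(k + 1)]))
  edges <- cbind(rep(seq_len(n), each = k), as.integer(t(nbr)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Annotate clusters by nearest reference centroid
#'
#' Each cluster's mean log-normalized profile is compared with each reference
#' centroid by Spearman correlation over the shared genes; the best centroid
#' labels the cluster, or "Unknown" when the best correlation is below
#' \code{min_corr}.
#'
#' @param m lognorm ExpressionMatrix.
#' @param cluster_labels named vector, obs_id -> cluster id.
#' @param centroids matrix genes x cell types
#'   (see \code{\link{reference_centroids}}).
#' @param min_corr minimum Spearman correlation to accept a label.
#' @param min_shared_genes floor on the gene overlap (default 50).
#' @return named character vector, cluster id -> label.
#' @export
annotate_nearest_centroid <- function(m, cluster_labels, centroids,
                                      min_corr = 0.5, min_shared_genes = 50) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm")
    stop("annotate_nearest_centroid requires a lognorm layer")
  shared <- intersect(m$gene_ids, rownames(centroids))
  if (length(shared) < min_shared_genes)
    stop("gene overlap with centroids (", length(shared),
         ") below the floor of ", min_shared_genes)
  v <- em_dense(m)[shared, , drop = FALSE]
  cents <- centroids[shared, , drop = FALSE]
  cl <- cluster_labels[m$obs_ids]
  out <- character(0)
  for (k in sort(unique(cl))) {
    prof <- rowMeans(v[, cl == k, drop = FALSE])
    cors <- apply(cents, 2, function(cent)
      stats::cor(prof, cent, method = "spearman"))
    out[as.character(k)] <- if (max(cors) < min_corr) "Unknown"
                            else colnames(cents)[which.max(cors)]
  }
  out
}

#' Subset cells and re-run the clustering pipeline
#'
#' Restricts to the requested cell types, re-selects highly variable genes,
#' recomputes PCA and re-clusters — the standard subcluster analysis of a
#' heterogeneous population (e.g. macrophages or stellate cells).
#'
#' @param m lognorm ExpressionMatrix (full dataset).
#' @param labels named vector obs_id -> cell-type label.
#' @param target_types labels to keep.
#' @param n_hvgs,n_pcs,k_neighbors,resolution,seed clustering parameters.
#' @param batch_labels optional batch labels for the subset scaling (defaults
#'   to the subset's obs_meta donor).
#' @return ClusterResult on the subset.
#' @export
subset_and_recluster <- function(m, labels, target_types, n_hvgs = 500,
                                 n_pcs = 20, k_neighbors = 15, resolution = 1,
                                 seed = 1, batch_labels = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  keep <- m$obs_ids[labels[m$obs_ids] %in% target_types]
  if (!length(keep)) stop("no cells with the target type(s)")
  if (length(keep) <= k_neighbors)
    stop("subset smaller than k_neighbors")
  sub <- em_subset(m, obs = keep)
  hvgs <- select_hvgs(sub, min(n_hvgs, length(sub$gene_ids)))
  sub <- em_subset(sub, genes = hvgs)
  if (is.null(batch_labels) && !is.null(sub$obs_meta$donor))
    batch_labels <- sub$obs_meta$donor
  scaled <- if (is.null(batch_labels)) {
    v <- em_dense(sub)
    mu <- rowMeans(v); sd <- apply(v, 1, stats::sd)
    v <- (v - mu) / ifelse(sd == 0, 1, sd); v[sd == 0, ] <- 0
    expression_matrix(v, sub$gene_ids, sub$obs_ids, sub$obs_meta, "scaled")
  } else scale_within_batch(sub, batch_labels)
  cluster_cells(scaled, n_pcs = n_pcs, k_neighbors = k_neighbors,
                resolution = resolution, seed = seed)
}

#' Fraction of cells positive for two genes
#'
#' Counts cells where both genes exceed the threshold — e.g. the fraction of
#' TREM2+CD9+ macrophages.
#'
#' @param m counts ExpressionMatrix.
#' @param gene_a,gene_b gene ids.
#' @param threshold count threshold (default 0: any expression).
#' @return list with \code{count}, \code{total}, \code{fraction}.
#' @export
fraction_double_positive <- function(m, gene_a, gene_b, threshold = 0) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts")
    stop("fraction_double_positive requires a counts layer")
  for (g in c(gene_a, gene_b))
    if (!g %in% m$gene_ids) stop("gene absent from the matrix: ", g)
  a <- as.numeric(m$values[gene_a, ])
  b <- as.numeric(m$values[gene_b, ])
  count <- sum(a > threshold & b > threshold)
  total <- length(a)
  list(count = count, total = total, fraction = count / total)
}
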