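#' Upper-tail hypergeometric overlap test
#'
#' Tests whether the overlap k between a module and a gene set is larger than
#' expected when the set is drawn from a finite universe: p = P(X >= k) for
#' X ~ Hypergeometric(N = |universe|, K = |set|, n = |module|). Genes outside
#' the universe are dropped with a warning.
#'
#' @param module_genes character vector.
#' @param set_genes character vector.
#' @param universe character vector of all eligible genes.
#' @return list with \code{k}, \code{n} (module size in universe), \code{K}
#'   (set size in universe), \code{N}, \code{p}, \code{overlap} (gene ids).
#' @export
hypergeometric_test <- function(module_genes, set_genes, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  mg <- unique(module_genes); sg <- unique(set_genes)
  out_m <- setdiff(mg, universe); out_s <- setdiff(sg, universe)
  if (length(out_m) || length(out_s))
    log_msg("dropping ", length(out_m) + length(out_s),
            " gene(s) outside the universe", level = "WARN")
  mg <- intersect(mg, universe); sg <- intersect(sg, universe)
  overlap <- intersect(mg, sg)
  k <- length(overlap)
  N <- length(universe); K <- length(sg); n <- length(mg)
  p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n,
                                        lower.tail = FALSE)
  list(k = k, n = n, K = K, N = N, p = min(p, 1), overlap = sort(overlap))
}

#' Map a candidate gene list onto modules
#'
#' One hypergeometric test per module against the candidate list, BH-adjusted
#' across modules; overlapping genes reported per module.
#'
#' @param module_set ModuleSet.
#' @param candidate_genes character vector (e.g. GWAS effector genes).
#' @param universe gene universe; default: all genes that entered module
#'   discovery (modules plus background).
#' @return EnrichmentResult data.frame: module, k, n, K, N, p, p_adj,
#'   significant, overlap (comma-separated).
#' @export
enrich_candidates <- function(module_set, candidate_genes, universe = NULL) {
  if (is.null(universe))
    universe <- c(unlist(lapply(module_set$modules, `[[`, "genes"),
                         use.names = FALSE), module_set$background)
  universe <- unique(universe)
  if (!length(intersect(candidate_genes, universe)))
    stop("candidate list is disjoint from the universe")
  rows <- lapply(names(module_set$modules), function(mid) {
    ht <- hypergeometric_test(module_set$modules[[mid]]$genes,
                              candidate_genes, universe)
    data.frame(module = mid, k = ht$k, n = ht$n, K = ht$K, N = ht$N,
               p = ht$p, overlap = paste(ht$overlap, collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < 0.05
  out <- out[, c("module", "k", "n", "K", "N", "p", "p_adj", "significant",
                 "overlap")]
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Gene-set enrichment of one module against a GMT collection
#'
#' Sets are intersected with the universe and filtered to sizes in
#' [min_set, max_set]; one hypergeometric test per retained set with BH
#' adjustment across sets.
#'
#' @param module GeneModule or character vector of genes.
#' @param collection GeneSetCollection (see \code{\link{read_gmt}}) or a
#'   named list of character vectors.
#' @param universe gene universe.
#' @param min_set,max_set size bounds after universe intersection (defaults
#'   5, 500).
#' @return EnrichmentResult data.frame sorted by p_adj (empty, with a logged
#'   reason, if no set survives filtering).
#' @export
enrich_genesets <- function(module, collection, universe, min_set = 5,
                            max_set = 500) {
  genes <- if (inherits(module, "GeneModule")) module$genes else module
  universe <- unique(universe)
  sets <- lapply(collection, function(s) {
    g <- if (is.list(s)) s$genes else s
    intersect(unique(g), universe)
  })
  sizes <- lengths(sets)
  keep <- sizes >= min_set & sizes <= max_set
  if (!any(keep)) {
    log_msg("no gene set within size bounds after universe intersection",
            level = "WARN")
    out <- data.frame(set = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0),
                      overlap = character(0))
    class(out) <- c("EnrichmentResult", "data.frame")
    return(out)
  }
  sets <- sets[keep]
  rows <- lapply(names(sets), function(nm) {
    ht <- hypergeometric_test(genes, sets[[nm]], universe)
    data.frame(set = nm, k = ht$k, n = ht$n, K = ht$K, N = ht$N, p = ht$p,
               overlap = paste(ht$overlap, collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < 0.05
  out <- out[order(out$p_adj, out$p, out$set),
             c("set", "k", "n", "K", "N", "p", "p_adj", "significant",
               "overlap")]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Pairwise module-overlap proportion matrix
#'
#' Entry (row r, column c) is the proportion of module c's genes shared with
#' module r: |genes_c \eqn{\cap} genes_r| / |genes_c|. The diagonal is fixed
#' at 0 and rows/columns are ordered by average-linkage hierarchical
#' clustering of the symmetrized matrix.
#'
#' @param module_sets one ModuleSet or a list of ModuleSets (e.g. one per
#'   cell type).
#' @return square numeric matrix with ordered module ids as dimnames.
#' @export
module_overlap_matrix <- function(module_sets) {
  if (inherits(module_sets, "ModuleSet")) module_sets <- list(module_sets)
  mods <- unlist(lapply(module_sets, `[[`, "modules"), recursive = FALSE)
  ids <- vapply(mods, `[[`, "", "module_id")
  if (anyDuplicated(ids))
    stop("duplicate module ids across the supplied sets")
  names(mods) <- ids
  if (length(mods) < 2) stop("need at least 2 modules")
  n <- length(mods)
  ov <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in ids) for (c in ids)
    if (r != c)
      ov[r, c] <- length(intersect(mods[[c]]$genes, mods[[r]]$genes)) /
        length(mods[[c]]$genes)
  sym <- (ov + t(ov)) / 2
  ord <- stats::hclust(stats::as.dist(1 - sym), method = "average")$order
  ov[ord, ord]
}

#' Genes belonging to at least k of the given modules
#'
#' The cross-module shared-gene extraction: e.g. all genes in at least three
#' of four oxidative-phosphorylation-correlated modules.
#'
#' @param modules list of GeneModule (or character vectors).
#' @param k membership threshold, 1 <= k <= length(modules).
#' @return sorted character vector.
#' @export
genes_in_at_least_k <- function(modules, k) {
  if (k < 1 || k > length(modules))
    stop("k must lie in [1, ", length(modules), "]")
  gl <- lapply(modules, function(m)
    unique(if (inherits(m, "GeneModule")) m$genes else m))
  counts <- table(unlist(gl))
  sort(names(counts)[counts >= k])
}
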