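#' Pairwise gene-gene correlation matrix
#'
#' @param m scaled or lognorm ExpressionMatrix (genes x observations), or a
#'   plain genes x observations matrix.
#' @param method "pearson" or "spearman".
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   genes get correlation 0 against everything (with a warning).
#' @export
pairwise_correlation <- function(m, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- if (inherits(m, "ExpressionMatrix")) {
    if (!m$layer %in% c("scaled", "lognorm"))
      stop("pairwise_correlation requires a scaled or lognorm layer")
    em_dense(m)
  } else as.matrix(m)
  if (ncol(v) < 30)
    stop("need at least 30 observations for a usable correlation network")
  sds <- apply(v, 1, stats::sd)
  const <- sds == 0
  cc <- suppressWarnings(stats::cor(t(v), method = method))
  if (any(const)) {
    log_msg("zero-variance gene(s) set to correlation 0: ",
            paste(utils::head(rownames(v)[const], 5), collapse = ", "),
            level = "WARN")
    cc[const, ] <- 0
    cc[, const] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Soft-thresholded adjacency
#'
#' @param corr correlation matrix.
#' @param power soft-thresholding exponent (>= 1).
#' @param network_type "unsigned" (|r|^power) or "signed-hybrid"
#'   (negative correlations clipped to 0 before raising to the power).
#' @return adjacency matrix in [0,1] with zero diagonal.
#' @export
adjacency <- function(corr, power, network_type = c("signed-hybrid",
                                                    "unsigned")) {
  network_type <- match.arg(network_type)
  if (power < 1) stop("power must be >= 1")
  a <- switch(network_type,
              unsigned = abs(corr)^power,
              `signed-hybrid` = pmax(corr, 0)^power)
  diag(a) <- 0
  a
}

scale_free_fit <- function(k, n_breaks = 10) {
  # discretized degree distribution; signed R^2 is positive for a decreasing
  # (scale-free-like) log-log relation
  k <- k[k > 0]
  if (!length(k)) return(list(r2 = NA_real_, slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = n_breaks + 1)
  breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  dk <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[ok] / sum(freq[ok])) ~ log10(dk[ok]))
  list(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]))
}

#' Choose the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the connectivity distribution is binned on the
#' log-log scale and a line fitted; the signed fit index is
#' \eqn{-sign(slope) R^2}, so a decreasing (scale-free-like) degree
#' distribution scores positive. The chosen power is the smallest one
#' reaching \code{r2_target}, else the best-scoring one with a warning.
#'
#' @param corr correlation matrix.
#' @param powers ascending grid of candidate powers (default 1:20).
#' @param r2_target signed R^2 threshold (default 0.8).
#' @param network_type passed to \code{\link{adjacency}}.
#' @return a \code{SoftPowerFit}: list with \code{fit_table} (power, signed
#'   R^2, slope, mean connectivity) and \code{chosen_power}.
#' @export
pick_soft_power <- function(corr, powers = 1:20, r2_target = 0.8,
                            network_type = "signed-hybrid") {
  if (is.unsorted(powers)) stop("powers must be an ascending grid")
  rows <- lapply(powers, function(b) {
    a <- adjacency(corr, b, network_type)
    k <- rowSums(a)
    if (all(k == 0)) stop("all genes disconnected at power ", b)
    sf <- scale_free_fit(k)
    data.frame(power = b,
               signed_r2 = if (is.na(sf$r2)) NA_real_
                           else -sign(sf$slope) * sf$r2,
               slope = sf$slope, mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  # a non-positive target imposes no constraint: the smallest power wins
  hit <- if (r2_target <= 0) seq_len(nrow(tab))
         else which(!is.na(tab$signed_r2) & tab$signed_r2 >= r2_target)
  chosen <- if (length(hit)) tab$power[hit[1]] else {
    log_msg("no power reaches signed R^2 ", r2_target,
            "; taking the best-fitting power", level = "WARN")
    tab$power[which.max(tab$signed_r2)]
  }
  structure(list(fit_table = tab, chosen_power = chosen),
            class = "SoftPowerFit")
}

#' @exportS3Method base::print
print.SoftPowerFit <- function(x, ...) {
  cat("SoftPowerFit: chosen power", x$chosen_power, "\n")
  print(x$fit_table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Topological overlap matrix
#'
#' \eqn{TOM_{ij} = (\sum_u a_{iu} a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 -
#' a_{ij})} with k the row sums; the diagonal is defined as 1.
#'
#' @param adj adjacency matrix with entries in [0,1] and zero diagonal.
#' @return TOM similarity matrix in [0,1].
#' @export
tom_similarity <- function(adj) {
  if (min(adj) < 0 || max(adj) > 1)
    stop("adjacency entries must lie in [0,1]")
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  # clamp tiny numerical overshoot
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  (tom + t(tom)) / 2
}

new_gene_module <- function(module_id, genes, cell_type = NA_character_,
                            kim = NULL, kim_norm = NULL, eigengene = NULL) {
  structure(list(module_id = module_id, cell_type = cell_type,
                 genes = genes, kim = kim, kim_norm = kim_norm,
                 eigengene = eigengene),
            class = "GeneModule")
}

#' @exportS3Method base::print
print.GeneModule <- function(x, ...) {
  cat(sprintf("GeneModule %s (%s): %d genes\n", x$module_id,
              ifelse(is.na(x$cell_type), "-", x$cell_type), length(x$genes)))
  invisible(x)
}

new_module_set <- function(modules, background, provenance = list()) {
  structure(list(modules = modules, background = background,
                 provenance = provenance),
            class = "ModuleSet")
}

#' @exportS3Method base::print
print.ModuleSet <- function(x, ...) {
  cat(sprintf("ModuleSet: %d modules, %d background genes\n",
              length(x$modules), length(x$background)))
  for (m in x$modules)
    cat(sprintf("  %s: %d genes\n", m$module_id, length(m$genes)))
  invisible(x)
}

#' Detect modules from a TOM by hierarchical tree cutting
#'
#' Average-linkage clustering on 1 - TOM, a static cut at the given quantile
#' of the merge heights, and a minimum-size filter; genes in clusters below
#' the minimum become background. Modules are numbered by decreasing size.
#'
#' @param tom TOM similarity matrix with gene dimnames.
#' @param min_size minimum module size (default 10).
#' @param cut_quantile quantile of merge heights at which to cut (default
#'   0.99).
#' @param cell_type optional tag carried into the modules.
#' @return ModuleSet (kIM filled from the supplied TOM; eigengenes unset).
#' @export
detect_modules <- function(tom, min_size = 10, cut_quantile = 0.99,
                           cell_type = NA_character_) {
  genes <- rownames(tom)
  if (is.null(genes)) stop("tom must carry gene dimnames")
  if (length(genes) < min_size)
    return(new_module_set(list(), genes))
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  h <- stats::quantile(tree$height, cut_quantile, names = FALSE)
  cl <- stats::cutree(tree, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  modules <- list()
  for (i in seq_along(keep)) {
    g <- genes[cl == as.integer(keep[i])]
    mid <- paste0("M", i)
    kim <- compute_kim(tom, g)
    modules[[mid]] <- new_gene_module(mid, g, cell_type,
                                      kim = kim$raw, kim_norm = kim$normalized)
  }
  background <- setdiff(genes, unlist(lapply(modules, `[[`, "genes")))
  new_module_set(modules, background,
                 provenance = list(cell_type = cell_type,
                                   min_size = min_size,
                                   cut_quantile = cut_quantile))
}

#' Intramodular connectivity (kIM)
#'
#' A gene's summed TOM similarity to the other members of its module —
#' the centrality weight used for module activity.
#'
#' @param tom TOM matrix with gene dimnames.
#' @param genes module gene ids (length >= 2).
#' @return list with \code{raw} and \code{normalized} (sums to 1) named
#'   vectors.
#' @export
compute_kim <- function(tom, genes) {
  if (length(genes) < 2) stop("singleton module: kIM undefined")
  missing <- setdiff(genes, rownames(tom))
  if (length(missing))
    stop("gene(s) absent from TOM: ", paste(missing, collapse = ", "))
  sub <- tom[genes, genes, drop = FALSE]
  diag(sub) <- 0
  raw <- rowSums(sub)
  total <- sum(raw)
  normalized <- if (total > 0) raw / total
                else stats::setNames(rep(1 / length(raw), length(raw)),
                                     names(raw))
  list(raw = raw, normalized = normalized)
}

#' Module eigengene
#'
#' First principal component of the observations x genes submatrix (genes
#' standardized), scaled to unit variance and sign-oriented so that its
#' correlation with the module's mean standardized expression is
#' non-negative.
#'
#' @param m ExpressionMatrix (any non-counts layer) or plain matrix
#'   (genes x observations).
#' @param genes module gene ids (>= 2 present).
#' @return numeric vector, one score per observation.
#' @export
module_eigengene <- function(m, genes) {
  v <- if (inherits(m, "ExpressionMatrix")) em_dense(m) else as.matrix(m)
  genes <- intersect(genes, rownames(v))
  if (length(genes) < 2) stop("need >= 2 module genes present")
  x <- v[genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (all(sds == 0)) stop("all-constant module submatrix")
  x <- (x - rowMeans(x)) / ifelse(sds == 0, 1, sds)
  x[sds == 0, ] <- 0
  sv <- svd(t(x), nu = 1, nv = 0)
  score <- sv$u[, 1]
  score <- score / stats::sd(score)
  ref <- colMeans(x)
  orient <- stats::cor(score, ref)
  if (!is.na(orient) && orient < 0) score <- -score
  stats::setNames(score, colnames(v))
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively merges the module pair with the highest eigengene correlation
#' while it exceeds \code{merge_corr}; eigengenes (and kIM when a TOM is
#' supplied) are recomputed after each merge. Ties break by module order.
#'
#' @param m expression used for eigengenes (scaled layer or matrix).
#' @param module_set ModuleSet.
#' @param merge_corr correlation threshold (default 0.85).
#' @param tom optional TOM for kIM recomputation.
#' @return ModuleSet.
#' @export
merge_modules <- function(m, module_set, merge_corr = 0.85, tom = NULL) {
  mods <- module_set$modules
  if (length(mods) < 2) return(fill_module_stats(m, module_set, tom))
  repeat {
    eig <- vapply(mods, function(mod) module_eigengene(m, mod$genes),
                  numeric(obs_count(m)))
    cc <- stats::cor(eig)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[best[1], best[2]] <= merge_corr) break
    i <- min(best); j <- max(best)
    mods[[i]]$genes <- c(mods[[i]]$genes, mods[[j]]$genes)
    mods[[j]] <- NULL
    if (length(mods) < 2) break
  }
  out <- new_module_set(mods, module_set$background, module_set$provenance)
  fill_module_stats(m, out, tom)
}

obs_count <- function(m)
  if (inherits(m, "ExpressionMatrix")) length(m$obs_ids) else ncol(m)

fill_module_stats <- function(m, module_set, tom = NULL) {
  for (mid in names(module_set$modules)) {
    mod <- module_set$modules[[mid]]
    mod$eigengene <- module_eigengene(m, mod$genes)
    if (!is.null(tom)) {
      kim <- compute_kim(tom, mod$genes)
      mod$kim <- kim$raw
      mod$kim_norm <- kim$normalized
    }
    module_set$modules[[mid]] <- mod
  }
  module_set
}

#' Quality-control filter on modules
#'
#' Retains modules with at least \code{min_size} genes and mean
#' gene-eigengene correlation (kME) at least \code{min_mean_kme}; genes of
#' dropped modules return to the background.
#'
#' @param m expression used for kME (scaled layer or matrix).
#' @param module_set ModuleSet with eigengenes filled.
#' @param min_size minimum size (default 10).
#' @param min_mean_kme minimum mean kME (default 0.3).
#' @return ModuleSet.
#' @export
qc_modules <- function(m, module_set, min_size = 10, min_mean_kme = 0.3) {
  v <- if (inherits(m, "ExpressionMatrix")) em_dense(m) else as.matrix(m)
  keep <- list()
  dropped <- character(0)
  for (mid in names(module_set$modules)) {
    mod <- module_set$modules[[mid]]
    if (is.null(mod$eigengene)) mod$eigengene <- module_eigengene(m, mod$genes)
    kme <- apply(v[mod$genes, , drop = FALSE], 1, function(row)
      suppressWarnings(stats::cor(row, mod$eigengene)))
    if (length(mod$genes) >= min_size &&
        mean(kme, na.rm = TRUE) >= min_mean_kme) keep[[mid]] <- mod
    else dropped <- c(dropped, mod$genes)
  }
  new_module_set(keep, union(module_set$background, dropped),
                 module_set$provenance)
}

#' Robust consensus module discovery (rWGCNA)
#'
#' The full network stage for one cell type: the soft power is chosen once on
#' the full data; \code{B_net} resamples of \code{resample_frac} of the
#' observations (without replacement) each yield a TOM; the consensus TOM is
#' the elementwise median; modules are detected on the consensus, merged by
#' eigengene correlation and quality-filtered. Deterministic given
#' \code{cfg$seed_net}.
#'
#' @param m scaled ExpressionMatrix for one cell type (>= 100 observations).
#' @param cfg \code{\link{pipeline_config}}.
#' @param cell_type tag recorded in the modules (defaults to the single
#'   cell_type in obs_meta, if any).
#' @return list with \code{module_set}, \code{power_fit} (SoftPowerFit) and
#'   \code{consensus_tom}.
#' @export
consensus_modules <- function(m, cfg = pipeline_config(),
                              cell_type = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "scaled") stop("consensus_modules requires a scaled layer")
  n <- length(m$obs_ids)
  if (n < 100) stop("need >= 100 observations for consensus networks")
  n_res <- ceiling(cfg$resample_frac * n)
  if (n_res > n) stop("resample size exceeds the number of observations")
  if (is.null(cell_type))
    cell_type <- if (!is.null(m$obs_meta$cell_type) &&
                     length(unique(m$obs_meta$cell_type)) == 1)
      unique(m$obs_meta$cell_type) else NA_character_
  corr_full <- pairwise_correlation(m, cfg$cor_method)
  fit <- pick_soft_power(corr_full, cfg$powers, cfg$r2_target,
                         cfg$network_type)
  v <- em_dense(m)
  n_genes <- nrow(v)
  set.seed(cfg$seed_net)
  toms <- array(0, dim = c(n_genes, n_genes, cfg$B_net))
  for (b in seq_len(cfg$B_net)) {
    idx <- sample(n, n_res)
    cc <- pairwise_correlation(v[, idx, drop = FALSE], cfg$cor_method)
    toms[, , b] <- tom_similarity(adjacency(cc, fit$chosen_power,
                                            cfg$network_type))
  }
  cons <- apply(toms, c(1, 2), stats::median)
  dimnames(cons) <- list(m$gene_ids, m$gene_ids)
  ms <- detect_modules(cons, cfg$min_module_size, cfg$cut_quantile, cell_type)
  ms <- merge_modules(m, ms, cfg$merge_corr, tom = cons)
  ms <- qc_modules(m, ms, cfg$min_module_size, cfg$min_mean_kme)
  ms <- fill_module_stats(m, ms, tom = cons)
  # stable, size-ordered ids after merging/QC
  ord <- order(-vapply(ms$modules, function(x) length(x$genes), integer(1)))
  mods <- ms$modules[ord]
  renamed <- list()
  for (i in seq_along(mods)) {
    mid <- if (is.na(cell_type)) paste0("M", i)
           else sprintf("M-%s-%d", cell_type, i)
    mods[[i]]$module_id <- mid
    renamed[[mid]] <- mods[[i]]
  }
  ms$modules <- renamed
  ms$provenance <- list(cell_type = cell_type,
                        chosen_power = fit$chosen_power,
                        B_net = cfg$B_net, resample_frac = cfg$resample_frac,
                        seed = cfg$seed_net,
                        network_type = cfg$network_type)
  list(module_set = ms, power_fit = fit, consensus_tom = cons)
}

#' Serialize a ModuleSet as JSON
#'
#' @param module_set ModuleSet.
#' @param path output path.
#' @export
write_module_set_json <- function(module_set, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for JSON serialization")
  payload <- list(
    provenance = module_set$provenance,
    background = module_set$background,
    modules = lapply(unname(module_set$modules), function(mod) list(
      module_id = mod$module_id,
      cell_type = mod$cell_type,
      genes = mod$genes,
      kim = as.list(round(mod$kim, 10)),
      kim_norm = as.list(round(mod$kim_norm, 10)))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export a ModuleSet as GMT
#'
#' @param module_set ModuleSet.
#' @param path output path.
#' @export
module_set_to_gmt <- function(module_set, path) {
  sets <- lapply(module_set$modules, function(mod)
    list(description = paste0("cell_type=",
                              ifelse(is.na(mod$cell_type), "NA",
                                     mod$cell_type)),
         genes = mod$genes))
  names(sets) <- vapply(module_set$modules, `[[`, "", "module_id")
  write_gmt(sets, path)
}
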