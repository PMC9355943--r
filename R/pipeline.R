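#' Run the full synthetic-data pipeline end to end
#'
#' The `run-all` entry point: simulates a case single-cell dataset with
#' planted modules, a healthy reference, a bulk cohort and a candidate gene
#' list; preprocesses (QC, log-normalization, per-donor scaling); discovers
#' consensus modules per cell type; tests preservation in the reference;
#' projects module activity into the bulk cohort and associates it with
#' inflammation and fibrosis under covariate adjustment; and maps the
#' candidate genes onto the modules. All stage outputs are written as
#' plain-text files under \code{out_dir} (deterministic for fixed seeds).
#'
#' @param sim_cfg \code{\link{sim_config}} for the generators.
#' @param cfg \code{\link{pipeline_config}} for the analysis stages.
#' @param out_dir output directory (created if needed); NULL to skip writing.
#' @param n_candidates size of the simulated candidate gene list.
#' @param candidates_planted named vector, module -> planted candidate count
#'   (default: 8 in the first module).
#' @return list with all intermediate and final results (truth, module_sets,
#'   preservation, association, enrichment, activity, fractions of
#'   double-positive marker cells are left to the caller).
#' @export
run_pipeline <- function(sim_cfg = sim_config(), cfg = pipeline_config(),
                         out_dir = NULL, n_candidates = 215,
                         candidates_planted = NULL) {
  sc <- simulate_sc_dataset(sim_cfg)
  reference <- simulate_reference_dataset(sim_cfg, sc$truth)
  bulk <- simulate_bulk_dataset(sim_cfg, sc$truth)

  filtered <- qc_filter_cells(sc$expr, cfg$min_genes, cfg$max_genes,
                              cfg$max_mito_frac, cfg$mito_prefix)
  lognorm <- normalize_log(filtered)
  scaled <- scale_within_batch(lognorm)

  cell_types <- unique(scaled$obs_meta$cell_type)
  module_sets <- list()
  toms <- list()
  for (ct in cell_types) {
    obs <- scaled$obs_ids[scaled$obs_meta$cell_type == ct]
    if (length(obs) < 100) {
      log_msg("cell type ", ct, " has ", length(obs),
              " cells; skipping module discovery", level = "WARN")
      next
    }
    sub <- em_subset(scaled, obs = obs)
    hvgs <- select_hvgs(em_subset(lognorm, obs = obs),
                        min(cfg$n_hvgs, length(sub$gene_ids)))
    sub <- em_subset(sub, genes = sort(hvgs))
    res <- consensus_modules(sub, cfg, cell_type = ct)
    module_sets[[ct]] <- res$module_set
    toms[[ct]] <- res$consensus_tom
  }

  ref_lognorm <- normalize_log(qc_filter_cells(
    reference, cfg$min_genes, cfg$max_genes, cfg$max_mito_frac,
    cfg$mito_prefix))
  preservation <- list()
  for (ct in names(module_sets)) {
    obs <- ref_lognorm$obs_ids[ref_lognorm$obs_meta$cell_type == ct]
    if (length(obs) < 50) next
    preservation[[ct]] <- preservation_table(
      module_sets[[ct]], em_subset(ref_lognorm, obs = obs),
      M_perm = cfg$M_perm, seed = cfg$seed_perm)
  }

  bulk_norm <- normalize_median_of_ratios(bulk$expr)
  all_modules <- unlist(lapply(module_sets, `[[`, "modules"),
                        recursive = FALSE)
  names(all_modules) <- vapply(all_modules, `[[`, "", "module_id")
  association <- NULL
  activity <- NULL
  if (length(all_modules)) {
    activity <- activity_matrix(bulk_norm$expr, all_modules)
    association <- associate_modules(activity, bulk$meta,
                                     phenotypes = c("lobular_inflammation",
                                                    "fibrosis"),
                                     B_assoc = cfg$B_assoc,
                                     seed = cfg$seed_assoc)
  }

  if (is.null(candidates_planted) && length(all_modules))
    candidates_planted <- stats::setNames(8L, names(all_modules)[1])
  cand <- NULL; cand_enrich <- NULL
  if (length(all_modules)) {
    cand <- simulate_candidate_genes(sc$truth, n_candidates,
                                     candidates_planted,
                                     seed = sim_cfg$seed + 3L)
    merged <- new_module_set(all_modules,
                             Reduce(intersect,
                                    lapply(module_sets, `[[`, "background")))
    cand_enrich <- enrich_candidates(merged, cand$genes)
  }

  overlap <- if (length(all_modules) >= 2)
    module_overlap_matrix(module_sets) else NULL

  out <- list(sim_cfg = sim_cfg, cfg = cfg, truth = cand$truth %||% sc$truth,
              sc = sc$expr, lognorm = lognorm, scaled = scaled,
              reference = reference, bulk = bulk,
              module_sets = module_sets, consensus_toms = toms,
              preservation = preservation, activity = activity,
              association = association,
              candidates = cand$genes, candidate_enrichment = cand_enrich,
              overlap = overlap)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_config(out$sim_cfg, fp("sim_config.txt"))
  write_config(out$cfg, fp("pipeline_config.txt"))
  for (ct in names(out$module_sets)) {
    write_module_set_json(out$module_sets[[ct]],
                          fp(paste0("modules_", ct, ".json")))
    module_set_to_gmt(out$module_sets[[ct]], fp(paste0("modules_", ct,
                                                       ".gmt")))
  }
  tsv <- function(df, name) if (!is.null(df))
    utils::write.table(format(as.data.frame(df), digits = 10), fp(name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (ct in names(out$preservation))
    tsv(out$preservation[[ct]], paste0("preservation_", ct, ".tsv"))
  tsv(out$association, "association.tsv")
  tsv(out$candidate_enrichment, "candidate_enrichment.tsv")
  if (!is.null(out$activity)) {
    act <- data.frame(sample_id = rownames(out$activity),
                      round(out$activity, 10), check.names = FALSE)
    utils::write.table(act, fp("activity.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(out$overlap)) {
    ov <- data.frame(module = rownames(out$overlap),
                     round(out$overlap, 10), check.names = FALSE)
    utils::write.table(ov, fp("module_overlap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$candidates))
    writeLines(out$candidates, fp("candidate_genes.txt"))
  invisible(out_dir)
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovered module membership against the planted truth.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in [-1, 1] (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Planted vs recovered module labels for a gene list
#'
#' Helper that turns a ground truth and a recovered ModuleSet into parallel
#' label vectors over the analysed genes (background = "bg"), restricted to
#' one cell type.
#'
#' @param truth ground truth from \code{\link{simulate_sc_dataset}}.
#' @param module_set recovered ModuleSet.
#' @param genes gene ids analysed (default: modules + background of the set).
#' @param cell_type cell type whose planted modules to compare against
#'   (default "CT1").
#' @return list with \code{truth_labels} and \code{found_labels}.
#' @export
module_recovery_labels <- function(truth, module_set, genes = NULL,
                                   cell_type = "CT1") {
  if (is.null(genes))
    genes <- c(unlist(lapply(module_set$modules, `[[`, "genes"),
                      use.names = FALSE), module_set$background)
  tl <- stats::setNames(rep("bg", length(genes)), genes)
  for (mod in truth$modules)
    if (mod$cell_type == cell_type) {
      g <- intersect(mod$genes, genes)
      tl[g] <- mod$module_id
    }
  fl <- stats::setNames(rep("bg", length(genes)), genes)
  for (mod in module_set$modules) {
    g <- intersect(mod$genes, genes)
    fl[g] <- mod$module_id
  }
  list(truth_labels = tl, found_labels = fl)
}
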