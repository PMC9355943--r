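#' Simulation configuration
#'
#' Parameters of the synthetic single-cell / bulk generator. Defaults describe
#' the scaled-down study design the package is validated on: 10 donors
#' contributing 200 cells each for one cell type (2,000 cells), 600 genes with
#' five planted co-expression modules of 30 genes, strong module factors
#' (\code{factor_sd = 2}) against modest gene-level noise, donor batch effects
#' on both the log-mean and the dispersion, and a bulk cohort of 184 samples
#' (mirroring a 160-case / 24-control design) whose first planted module
#' responds to lobular inflammation at 0.5 SD of activity per grade and whose
#' second responds to fibrosis at 0.5 SD.
#'
#' @param ... name = value overrides; unknown names are an error.
#' @return a classed list of simulation settings.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_donors = 10L, n_cell_types = 1L, cells_per_donor = 200L,
    n_genes = 600L, n_modules_per_type = 5L, module_size = 30L,
    factor_sd = 2, noise_sd = 0.3,
    library_size_mean = 2000, lib_sdlog = 0.3, nb_dispersion = 0.3,
    donor_shift_sd = 0.3, donor_disp_range = c(0.8, 1.25),
    n_bulk_samples = 184L, bulk_library_size = 2e5, bulk_dispersion = 0.05,
    phenotype_effect_grid = NULL,
    covariate_effects = c(bmi = 0.1, age = 0.1, sex = 0.1),
    frac_modules_preserved = 0.9,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown sim config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$module_size < 3)
    stop("config error: module_size must be at least 3 (modules undetectable)")
  if (cfg$module_size * cfg$n_modules_per_type > cfg$n_genes)
    stop("config error: module_size x n_modules_per_type exceeds n_genes")
  for (f in c("n_donors", "n_cell_types", "cells_per_donor", "n_genes",
              "n_modules_per_type", "n_bulk_samples"))
    if (cfg[[f]] < 1) stop("config error: ", f, " must be positive")
  structure(cfg, class = "coexmod_sim_config")
}

# Deterministic block allocation: within a cell type, modules occupy
# consecutive disjoint gene blocks; blocks rotate across cell types so
# different types get (mostly) different modules when space allows.
plant_modules <- function(cfg) {
  capacity <- cfg$n_genes %/% cfg$module_size
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  modules <- list()
  for (t in seq_len(cfg$n_cell_types)) {
    ct <- paste0("CT", t)
    for (j in seq_len(cfg$n_modules_per_type)) {
      slot <- ((t - 1L) * cfg$n_modules_per_type + (j - 1L)) %% capacity
      genes <- gene_ids[(slot * cfg$module_size + 1L):
                        ((slot + 1L) * cfg$module_size)]
      mid <- sprintf("M-%s-%d", ct, j)
      loadings <- stats::runif(cfg$module_size, 0.7, 1.3)
      names(loadings) <- genes
      modules[[mid]] <- list(module_id = mid, cell_type = ct,
                             genes = genes, loadings = loadings)
    }
  }
  modules
}

#' Simulate a single-cell dataset with planted co-expression modules
#'
#' Generative model, per cell type: each planted module m has a latent
#' per-cell factor f ~ N(0, factor_sd); the log-mean of gene g in cell c is
#' baseline_g + loading_g * f + donor shift + N(0, noise_sd); counts are
#' negative binomial with log-normal cell library-size scaling and a
#' donor-specific dispersion multiplier. Background genes carry no factor and
#' are independent given the library size. The returned ground truth records
#' module memberships, loadings, batch parameters, the preservation flags
#' used by \code{\link{simulate_reference_dataset}}, and the phenotype slope
#' grid used by \code{\link{simulate_bulk_dataset}}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{expr} (counts ExpressionMatrix; obs_meta has
#'   \code{donor} and \code{cell_type}) and \code{truth} (ground-truth
#'   record).
#' @export
simulate_sc_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "coexmod_sim_config"))
  set.seed(cfg$seed)
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  base <- stats::rnorm(cfg$n_genes, log(3), 1)
  names(base) <- gene_ids
  modules <- plant_modules(cfg)
  donors <- sprintf("D%02d", seq_len(cfg$n_donors))
  batch <- data.frame(
    donor = donors,
    shift = stats::rnorm(cfg$n_donors, 0, cfg$donor_shift_sd),
    disp_mult = stats::runif(cfg$n_donors, cfg$donor_disp_range[1],
                             cfg$donor_disp_range[2]))
  n_mod <- length(modules)
  n_pres <- round(cfg$frac_modules_preserved * n_mod)
  preserved <- stats::setNames(rep(FALSE, n_mod), names(modules))
  if (n_pres > 0)
    preserved[sample(names(modules), n_pres)] <- TRUE

  phen <- c("steatosis", "lobular_inflammation", "fibrosis")
  slopes <- cfg$phenotype_effect_grid
  if (is.null(slopes)) {
    slopes <- matrix(0, n_mod, 3, dimnames = list(names(modules), phen))
    slopes[1, "lobular_inflammation"] <- 0.5
    if (n_mod >= 2) slopes[2, "fibrosis"] <- 0.5
  } else {
    slopes <- as.matrix(slopes)
    if (!all(rownames(slopes) %in% names(modules)) ||
        !all(colnames(slopes) %in% phen))
      stop("config error: phenotype_effect_grid must be modules x phenotypes")
    full <- matrix(0, n_mod, 3, dimnames = list(names(modules), phen))
    full[rownames(slopes), colnames(slopes)] <- slopes
    slopes <- full
  }
  if (!all(is.finite(slopes))) stop("config error: slopes must be finite")

  truth <- structure(list(
    modules = modules,
    module_table = data.frame(
      module_id = names(modules),
      cell_type = vapply(modules, `[[`, "", "cell_type"),
      size = lengths(lapply(modules, `[[`, "genes")),
      row.names = NULL),
    background = setdiff(gene_ids,
                         unique(unlist(lapply(modules, `[[`, "genes")))),
    base_log_mean = base,
    phenotype_slopes = slopes,
    batch_params = batch,
    preserved_in_reference = preserved,
    candidate_gene_truth = integer(0),
    factor_sd = cfg$factor_sd, noise_sd = cfg$noise_sd
  ), class = "coexmod_truth")

  sim <- draw_sc_counts(cfg, truth, destroyed = character(0),
                        cell_prefix = "C")
  list(expr = sim, truth = truth)
}

# Shared count-drawing engine for the case and reference datasets. Modules in
# `destroyed` lose their factor entirely: their genes revert to plain
# background behaviour, and the displaced loadings are re-attached to random
# background genes, each driven by its own independent per-gene factor, so no
# gene-gene correlation survives anywhere.
draw_sc_counts <- function(cfg, truth, destroyed, cell_prefix) {
  gene_ids <- names(truth$base_log_mean)
  n_genes <- length(gene_ids)
  donors <- truth$batch_params$donor
  cells_ct <- cfg$n_donors * cfg$cells_per_donor
  cell_types <- unique(vapply(truth$modules, `[[`, "", "cell_type"))
  if (!length(cell_types)) cell_types <- "CT1"

  # displaced loadings from destroyed modules go to random background genes
  solo <- list()   # gene -> loading driven by an independent factor
  for (mid in destroyed) {
    mod <- truth$modules[[mid]]
    for (g in mod$genes) solo[[g]] <- unname(mod$loadings[g])
    recipients <- sample(truth$background,
                         min(length(mod$genes), length(truth$background)))
    for (k in seq_along(recipients))
      solo[[recipients[k]]] <- unname(mod$loadings[k])
  }

  blocks <- list(); metas <- list()
  for (ct in cell_types) {
    donor_of <- rep(donors, each = cfg$cells_per_donor)
    n_cells <- length(donor_of)
    eta <- matrix(truth$base_log_mean, n_genes, n_cells,
                  dimnames = list(gene_ids, NULL))
    eta <- eta + matrix(rep(truth$batch_params$shift,
                            each = cfg$cells_per_donor),
                        n_genes, n_cells, byrow = TRUE)
    ct_modules <- Filter(function(m) m$cell_type == ct, truth$modules)
    for (mod in ct_modules) {
      if (mod$module_id %in% destroyed) next
      f <- stats::rnorm(n_cells, 0, cfg$factor_sd)
      eta[mod$genes, ] <- eta[mod$genes, ] + outer(mod$loadings, f)
    }
    for (g in names(solo))
      eta[g, ] <- eta[g, ] + solo[[g]] * stats::rnorm(n_cells, 0, cfg$factor_sd)
    if (cfg$noise_sd > 0)
      eta <- eta + matrix(stats::rnorm(n_genes * n_cells, 0, cfg$noise_sd),
                          n_genes, n_cells)
    lib <- stats::rlnorm(n_cells, log(cfg$library_size_mean), cfg$lib_sdlog)
    # scale so a cell's expected total matches its drawn library size
    mu <- exp(eta)
    mu <- sweep(mu, 2, lib / colSums(mu), `*`)
    size <- 1 / (cfg$nb_dispersion *
                 rep(truth$batch_params$disp_mult, each = cfg$cells_per_donor))
    counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu,
                                    size = rep(size, each = n_genes)),
                     n_genes, n_cells)
    blocks[[ct]] <- counts
    metas[[ct]] <- data.frame(donor = donor_of,
                              cell_type = rep(ct, n_cells))
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, metas)
  obs_ids <- sprintf("%s%05d", cell_prefix, seq_len(ncol(counts)))
  meta$obs_id <- obs_ids
  expression_matrix(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "CsparseMatrix"),
                    gene_ids, obs_ids, meta, layer = "counts")
}

#' Simulate a healthy reference single-cell dataset
#'
#' Re-draws donors and cells under the same gene baselines. Modules flagged
#' \code{preserved_in_reference} in the ground truth keep their shared latent
#' factor; non-preserved modules have their co-expression destroyed (their
#' loadings are re-attached to independent per-gene factors and redistributed
#' over background genes).
#'
#' @param cfg the \code{\link{sim_config}} used for the case dataset.
#' @param truth ground truth from \code{\link{simulate_sc_dataset}}.
#' @return counts ExpressionMatrix.
#' @export
simulate_reference_dataset <- function(cfg, truth) {
  stopifnot(inherits(truth, "coexmod_truth"))
  set.seed(cfg$seed + 1L)
  # new donors for the reference cohort
  truth$batch_params$shift <- stats::rnorm(cfg$n_donors, 0, cfg$donor_shift_sd)
  truth$batch_params$disp_mult <- stats::runif(cfg$n_donors,
                                               cfg$donor_disp_range[1],
                                               cfg$donor_disp_range[2])
  destroyed <- names(truth$preserved_in_reference)[
    !truth$preserved_in_reference]
  draw_sc_counts(cfg, truth, destroyed = destroyed, cell_prefix = "R")
}

#' Simulate a bulk RNA-seq cohort with phenotype-linked module activity
#'
#' Per sample, ordinal phenotypes (lobular inflammation 0-2, fibrosis 0-1,
#' steatosis 0-2) and covariates (BMI, age, sex) are drawn; each planted
#' module's latent activity is slope x phenotype + covariate terms + Gaussian
#' noise, with the residual SD budgeted so total activity SD is ~1 and the
#' slopes are in SD-of-activity units. Module gene means are modulated by
#' loading x activity on the log scale; counts are negative binomial.
#'
#' @param cfg \code{\link{sim_config}}.
#' @param truth ground truth from \code{\link{simulate_sc_dataset}}.
#' @return list with \code{expr} (counts ExpressionMatrix), \code{meta}
#'   (sample metadata conforming to \code{\link{read_sample_metadata}}), and
#'   \code{activity} (latent module activities, samples x modules).
#' @export
simulate_bulk_dataset <- function(cfg, truth) {
  stopifnot(inherits(truth, "coexmod_truth"))
  set.seed(cfg$seed + 2L)
  n <- cfg$n_bulk_samples
  ids <- sprintf("S%03d", seq_len(n))
  meta <- data.frame(
    sample_id = ids,
    steatosis = sample(0:2, n, TRUE, prob = c(0.3, 0.4, 0.3)),
    lobular_inflammation = sample(0:2, n, TRUE, prob = c(0.35, 0.4, 0.25)),
    fibrosis = stats::rbinom(n, 1, 0.4),
    bmi = round(stats::rnorm(n, 43.4, 7.4), 1),
    age = round(stats::rnorm(n, 44, 7.5)),
    sex = sample(c("F", "M"), n, TRUE))
  cov_scaled <- cbind(bmi = as.numeric(scale(meta$bmi)),
                      age = as.numeric(scale(meta$age)),
                      sex = as.numeric(meta$sex == "M"))
  ce <- cfg$covariate_effects
  modules <- truth$modules
  slopes <- truth$phenotype_slopes
  phen_mat <- cbind(steatosis = meta$steatosis,
                    lobular_inflammation = meta$lobular_inflammation,
                    fibrosis = meta$fibrosis)
  activity <- matrix(0, n, length(modules),
                     dimnames = list(ids, names(modules)))
  for (mid in names(modules)) {
    sys <- as.numeric(phen_mat %*% slopes[mid, ]) +
      as.numeric(cov_scaled %*% ce[colnames(cov_scaled)])
    resid_sd <- sqrt(max(0.05, 1 - stats::var(sys)))
    activity[, mid] <- sys + stats::rnorm(n, 0, resid_sd)
  }
  gene_ids <- names(truth$base_log_mean)
  eta <- matrix(truth$base_log_mean, length(gene_ids), n,
                dimnames = list(gene_ids, NULL))
  for (mid in names(modules)) {
    mod <- modules[[mid]]
    eta[mod$genes, ] <- eta[mod$genes, ] + outer(mod$loadings, activity[, mid])
  }
  eta <- eta + matrix(stats::rnorm(length(eta), 0, 0.1), nrow(eta), ncol(eta))
  lib <- stats::rlnorm(n, log(cfg$bulk_library_size), 0.1)
  mu <- exp(eta)
  mu <- sweep(mu, 2, lib / colSums(mu), `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$bulk_dispersion),
                   nrow(mu), ncol(mu))
  expr <- expression_matrix(counts, gene_ids, ids, meta, layer = "counts")
  list(expr = expr, meta = meta, activity = activity)
}

#' Simulate a candidate gene list with planted module enrichment
#'
#' Emulates a GWAS effector-gene list: a chosen number of members of selected
#' modules plus uniformly drawn background genes, for validating the
#' hypergeometric mapping of candidate genes onto modules.
#'
#' @param truth ground truth from \code{\link{simulate_sc_dataset}}.
#' @param n_total total number of candidate genes.
#' @param planted_per_module named integer vector, module_id -> number of that
#'   module's genes to plant (may be empty).
#' @param seed integer seed.
#' @return list with \code{genes} (character vector, length n_total) and
#'   \code{truth} with \code{candidate_gene_truth} updated.
#' @export
simulate_candidate_genes <- function(truth, n_total, planted_per_module =
                                       integer(0), seed = 1L) {
  stopifnot(inherits(truth, "coexmod_truth"))
  set.seed(seed)
  planted_per_module <- unlist(planted_per_module)
  if (length(planted_per_module)) {
    bad <- setdiff(names(planted_per_module), names(truth$modules))
    if (length(bad)) stop("unknown module(s): ", paste(bad, collapse = ", "))
  }
  planted <- character(0)
  for (mid in names(planted_per_module)) {
    k <- planted_per_module[[mid]]
    g <- truth$modules[[mid]]$genes
    if (k > length(g))
      stop("config error: requested ", k, " planted genes but module ", mid,
           " has only ", length(g))
    planted <- c(planted, sample(g, k))
  }
  planted <- unique(planted)
  if (n_total < length(planted))
    stop("config error: n_total smaller than the planted gene count")
  pool <- setdiff(names(truth$base_log_mean), planted)
  filler <- sample(pool, n_total - length(planted))
  truth$candidate_gene_truth <- vapply(
    names(truth$modules),
    function(mid) sum(planted %in% truth$modules[[mid]]$genes), integer(1))
  list(genes = c(planted, filler), truth = truth)
}

#' Reference centroids from a labelled dataset
#'
#' Mean log-normalized profile per cell type, for nearest-centroid
#' annotation.
#'
#' @param m lognorm-layer ExpressionMatrix whose obs_meta has a
#'   \code{cell_type} column.
#' @return matrix genes x cell types.
#' @export
reference_centroids <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"), m$layer == "lognorm")
  ct <- m$obs_meta$cell_type
  if (is.null(ct)) stop("obs_meta must have a cell_type column")
  v <- em_dense(m)
  cents <- vapply(unique(ct), function(k) rowMeans(v[, ct == k, drop = FALSE]),
                  numeric(nrow(v)))
  colnames(cents) <- unique(ct)
  if (any(colSums(abs(cents)) == 0)) stop("all-zero centroid")
  cents
}
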