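#' Pipeline configuration
#'
#' Collects every tunable of the downstream stages with its default. Any
#' subset can be overridden via \code{...}; unknown names are an error so
#' typos do not silently fall back to defaults. Every stochastic stage has its
#' own integer seed so stages can be re-run in isolation.
#'
#' @param ... name = value overrides of the defaults listed below.
#' @return a classed list of settings.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # QC (droplet-data conventions; grade-school knobs, all config-exposed)
    min_genes = 200L, max_genes = 6000L, max_mito_frac = 0.2,
    mito_prefix = "MT-",
    # preprocessing
    n_hvgs = 500L, n_pcs = 20L, k_neighbors = 15L, resolution = 1,
    min_corr = 0.5,
    # network construction
    powers = 1:20, r2_target = 0.8, network_type = "signed-hybrid",
    cor_method = "pearson",
    # module detection
    min_module_size = 10L, cut_quantile = 0.99, merge_corr = 0.85,
    min_mean_kme = 0.3,
    # robustness / inference
    B_net = 20L, resample_frac = 0.8, B_assoc = 1999L, M_perm = 999L,
    # enrichment
    min_set = 5L, max_set = 500L,
    # seeds (one per stochastic stage)
    seed_cluster = 1L, seed_net = 2L, seed_assoc = 3L, seed_perm = 4L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  counts <- c("B_net", "B_assoc", "M_perm", "min_module_size", "n_hvgs",
              "n_pcs", "k_neighbors")
  for (f in counts) if (cfg[[f]] < 1) stop(f, " must be strictly positive")
  seeds <- grep("^seed_", names(cfg), value = TRUE)
  for (f in seeds) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] != round(cfg[[f]]))
      stop(f, " must be an integer seed")
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  structure(cfg, class = "coexmod_config")
}

#' @exportS3Method base::print
print.coexmod_config <- function(x, ...) {
  cat("coexmod pipeline configuration:\n")
  for (nm in names(x))
    cat(sprintf("  %-16s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

#' Write a resolved configuration as a flat key-value document
#'
#' Every run logs its resolved configuration (including all seeds) so the run
#' is reproducible from the log alone.
#'
#' @param cfg coexmod_config or sim_config.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(nm)
    paste0(nm, " = ", paste(format(cfg[[nm]], digits = 15), collapse = " ")),
    character(1))
  writeLines(lines, path)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' ignored. Values are type-converted (integer/double/logical/character).
#'
#' @param path file path.
#' @return named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    p <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(p) < 2) stop("malformed config line: ", ln)
    val <- trimws(paste(p[-1], collapse = "="))
    val <- strsplit(val, "[[:space:]]+")[[1]]
    val <- utils::type.convert(val, as.is = TRUE)
    out[[trimws(p[1])]] <- val
  }
  out
}

log_msg <- function(..., level = "INFO") {
  opt <- getOption("coexmod.log_level", "INFO")
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3, QUIET = 4)
  if (levels[[level]] >= levels[[opt]])
    message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}
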