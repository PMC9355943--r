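#' Module activity: weighted mean of scaled module gene expression
#'
#' Each module gene is z-scored across the observations of the target
#' dataset; the activity of an observation is the kIM-weighted mean of those
#' z-scores (weights renormalized over the genes actually present). The raw
#' activity has mean 0 over the scaling population; a unit-variance
#' standardization is returned alongside for regression.
#'
#' @param m ExpressionMatrix (lognorm for single-cell, normalized counts for
#'   bulk — z-scoring happens here) or plain genes x observations matrix.
#' @param module GeneModule (with kim weights) or a character vector of genes
#'   (uniform weights).
#' @param weights "kim" (default) or "uniform".
#' @return list with \code{raw} and \code{standardized} named numeric
#'   vectors, plus \code{genes_used}.
#' @export
module_activity <- function(m, module, weights = c("kim", "uniform")) {
  weights <- match.arg(weights)
  v <- if (inherits(m, "ExpressionMatrix")) {
    x <- em_dense(m)
    if (m$layer == "counts") x <- log1p(x)
    x
  } else as.matrix(m)
  genes <- if (inherits(module, "GeneModule")) module$genes else module
  present <- intersect(genes, rownames(v))
  missing <- setdiff(genes, present)
  if (length(present) < 2)
    stop("fewer than 2 module genes present; missing: ",
         paste(missing, collapse = ", "))
  if (length(missing))
    log_msg("dropping ", length(missing), " module gene(s) absent from the ",
            "target data", level = "WARN")
  w <- if (weights == "kim" && inherits(module, "GeneModule") &&
           !is.null(module$kim_norm)) module$kim_norm[present]
       else stats::setNames(rep(1, length(present)), present)
  if (any(w < 0)) stop("kIM weights must be non-negative")
  w <- w / sum(w)
  x <- v[present, , drop = FALSE]
  mu <- rowMeans(x)
  sds <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sds == 0, 1, sds)
  z[sds == 0, ] <- 0
  raw <- as.numeric(crossprod(z, w))
  names(raw) <- colnames(v)
  s <- stats::sd(raw)
  standardized <- if (s > 0) raw / s else raw
  list(raw = raw, standardized = standardized, genes_used = present)
}

#' Activity of every module of a ModuleSet
#'
#' @param m target ExpressionMatrix.
#' @param module_set ModuleSet (or list of GeneModule).
#' @param weights passed to \code{\link{module_activity}}.
#' @param standardized return the unit-variance column (default TRUE).
#' @return observations x modules matrix.
#' @export
activity_matrix <- function(m, module_set, weights = "kim",
                            standardized = TRUE) {
  mods <- if (inherits(module_set, "ModuleSet")) module_set$modules
          else module_set
  cols <- lapply(mods, function(mod) {
    a <- module_activity(m, mod, weights)
    if (standardized) a$standardized else a$raw
  })
  out <- do.call(cbind, cols)
  colnames(out) <- vapply(mods, function(mod)
    if (inherits(mod, "GeneModule")) mod$module_id else "module", "")
  out
}

#' Permutation test of module co-expression preservation
#'
#' Observed statistic: mean off-diagonal pairwise correlation among the
#' module's genes in the reference dataset. Null: the same statistic for
#' size-matched random gene sets drawn from the reference-expressed genes.
#' Empirical p = (1 + #\{null >= observed\}) / (M_perm + 1).
#'
#' @param module GeneModule or character vector of genes.
#' @param reference lognorm ExpressionMatrix (>= 50 observations) or matrix.
#' @param M_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param min_genes minimum module genes present in the reference (default
#'   5); fewer returns NULL with a logged reason (module skipped).
#' @return list with \code{observed}, \code{null_mean}, \code{null_sd},
#'   \code{z}, \code{p}, \code{n_genes}; or NULL if skipped.
#' @export
preservation_test <- function(module, reference, M_perm = 999, seed = 1,
                              min_genes = 5) {
  v <- if (inherits(reference, "ExpressionMatrix")) {
    if (reference$layer == "counts")
      stop("normalize the reference before preservation testing")
    em_dense(reference)
  } else as.matrix(reference)
  if (ncol(v) < 50) stop("reference needs >= 50 observations")
  genes <- if (inherits(module, "GeneModule")) module$genes else module
  mid <- if (inherits(module, "GeneModule")) module$module_id else "module"
  expressed <- rownames(v)[apply(v, 1, stats::sd) > 0]
  present <- intersect(genes, expressed)
  if (length(present) < min_genes) {
    log_msg("module ", mid, " skipped: only ", length(present),
            " genes present in the reference", level = "WARN")
    return(NULL)
  }
  mean_offdiag_cor <- function(g) {
    cc <- suppressWarnings(stats::cor(t(v[g, , drop = FALSE])))
    mean(cc[upper.tri(cc)], na.rm = TRUE)
  }
  observed <- mean_offdiag_cor(present)
  set.seed(seed)
  null <- vapply(seq_len(M_perm), function(i)
    mean_offdiag_cor(sample(expressed, length(present))), numeric(1))
  p <- (1 + sum(null >= observed)) / (M_perm + 1)
  list(module_id = mid, observed = observed, null_mean = mean(null),
       null_sd = stats::sd(null), z = (observed - mean(null)) / stats::sd(null),
       p = p, n_genes = length(present))
}

#' Preservation of every module in a reference dataset
#'
#' @param module_set ModuleSet.
#' @param reference lognorm ExpressionMatrix.
#' @param M_perm,seed,min_genes see \code{\link{preservation_test}}.
#' @return data.frame (one row per tested module) with BH-adjusted p; skipped
#'   modules are absent, listed in the \code{skipped} attribute.
#' @export
preservation_table <- function(module_set, reference, M_perm = 999, seed = 1,
                               min_genes = 5) {
  rows <- list(); skipped <- character(0)
  for (mid in names(module_set$modules)) {
    res <- preservation_test(module_set$modules[[mid]], reference,
                             M_perm = M_perm, seed = seed + match(
                               mid, names(module_set$modules)),
                             min_genes = min_genes)
    if (is.null(res)) skipped <- c(skipped, mid)
    else rows[[mid]] <- as.data.frame(res)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out$p_adj <- bh_adjust(out$p)
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  out
}

#' Ordinary least squares with intercept
#'
#' @param y response (standardized module activity).
#' @param X data.frame or matrix of predictors (phenotype first).
#' @return named coefficient vector (including the intercept).
#' @export
fit_linear_model <- function(y, X) {
  X <- as.matrix(as.data.frame(X))
  if (length(y) <= ncol(X) + 1)
    stop("need n > number of predictors + 1")
  M <- cbind(`(Intercept)` = 1, X)
  qr_fit <- qr(M)
  if (qr_fit$rank < ncol(M))
    stop("rank-deficient design; collinear column(s): ",
         paste(setdiff(colnames(M), colnames(M)[qr_fit$pivot[
           seq_len(qr_fit$rank)]]), collapse = ", "))
  stats::setNames(as.numeric(qr.coef(qr_fit, y)), colnames(M))
}

#' Bootstrap percentile inference for one regression coefficient
#'
#' Rows of (y, X) are resampled with replacement B times; the model is refit
#' and the focal coefficient collected. CI bounds are the 2.5/97.5
#' percentiles; the two-sided p-value is the +1-corrected sign-count
#' \eqn{2 \min(\#\{b \le 0\}+1, \#\{b \ge 0\}+1)/(B+1)}, capped at 1.
#' Rank-deficient resamples are redrawn (error if more than 10\% redraws).
#'
#' @param y response.
#' @param X predictor data.frame/matrix; the focal coefficient is the first
#'   column (after the intercept).
#' @param B_assoc bootstrap replicates (>= 199; default 1999).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list with \code{beta} (full-data estimate), \code{ci_low},
#'   \code{ci_high}, \code{p_boot}, \code{B}, \code{n_redraws}.
#' @export
bootstrap_percentile <- function(y, X, B_assoc = 1999, seed = 1,
                                 conf = 0.95) {
  if (B_assoc < 199) stop("B_assoc must be >= 199")
  X <- as.matrix(as.data.frame(X))
  beta_hat <- fit_linear_model(y, X)[2]
  M <- cbind(1, X)
  n <- length(y)
  set.seed(seed)
  betas <- numeric(B_assoc)
  redraws <- 0
  for (b in seq_len(B_assoc)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      Mb <- M[idx, , drop = FALSE]
      fit <- qr(Mb)
      if (fit$rank == ncol(Mb)) break
      redraws <- redraws + 1
      if (redraws > 0.1 * B_assoc)
        stop("more than 10% of bootstrap resamples were rank-deficient")
    }
    betas[b] <- qr.coef(fit, y[idx])[2]
  }
  alpha <- 1 - conf
  ci <- stats::quantile(betas, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  p <- 2 * min(sum(betas <= 0) + 1, sum(betas >= 0) + 1) / (B_assoc + 1)
  list(beta = unname(beta_hat), ci_low = ci[1], ci_high = ci[2],
       p_boot = min(p, 1), B = B_assoc, n_redraws = redraws)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input order preserved.
#'
#' @param pvals numeric vector in [0,1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Associate module activity with histological phenotypes
#'
#' For every (module, phenotype) pair: OLS of standardized activity on the
#' numerically encoded phenotype plus covariates, bootstrap percentile CI and
#' p-value, and BH adjustment across modules within each phenotype. Samples
#' with missing covariates are dropped listwise per model.
#'
#' @param activity observations x modules matrix
#'   (see \code{\link{activity_matrix}}).
#' @param meta sample metadata keyed by rownames/sample_id.
#' @param phenotypes subset of c("steatosis", "lobular_inflammation",
#'   "fibrosis").
#' @param covariates covariate column names (default bmi, age, sex).
#' @param B_assoc bootstrap replicates (default 1999).
#' @param seed integer seed.
#' @return AssociationResult data.frame: module, phenotype, beta, ci_low,
#'   ci_high, p_boot, p_adj, significant, n.
#' @export
associate_modules <- function(activity, meta,
                              phenotypes = c("lobular_inflammation",
                                             "fibrosis"),
                              covariates = c("bmi", "age", "sex"),
                              B_assoc = 1999, seed = 1) {
  allowed <- c("steatosis", "lobular_inflammation", "fibrosis")
  if (!all(phenotypes %in% allowed))
    stop("phenotypes must be a subset of: ", paste(allowed, collapse = ", "))
  key <- if ("sample_id" %in% names(meta)) as.character(meta$sample_id)
         else rownames(meta)
  if (!all(rownames(activity) %in% key))
    stop("metadata does not cover all samples")
  meta <- meta[match(rownames(activity), key), , drop = FALSE]
  rows <- list()
  for (ph in phenotypes) {
    for (j in seq_len(ncol(activity))) {
      mid <- colnames(activity)[j]
      df <- data.frame(y = activity[, j], ph = as.numeric(meta[[ph]]))
      for (cv in covariates)
        df[[cv]] <- if (is.numeric(meta[[cv]])) meta[[cv]]
                    else as.numeric(factor(meta[[cv]])) - 1
      ok <- stats::complete.cases(df)
      if (sum(ok) < 20)
        stop("fewer than 20 complete samples for ", mid, " / ", ph)
      d <- df[ok, , drop = FALSE]
      X <- d[, -1, drop = FALSE]
      names(X)[1] <- ph
      bs <- bootstrap_percentile(d$y, X, B_assoc = B_assoc,
                                 seed = seed + 131 * j +
                                   7919 * match(ph, allowed))
      rows[[paste(mid, ph)]] <- data.frame(
        module = mid, phenotype = ph, beta = bs$beta, ci_low = bs$ci_low,
        ci_high = bs$ci_high, p_boot = bs$p_boot, n = sum(ok))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- NA_real_
  for (ph in phenotypes) {
    sel <- out$phenotype == ph
    out$p_adj[sel] <- bh_adjust(out$p_boot[sel])
  }
  out$significant <- out$p_adj < 0.05
  attr(out, "covariates") <- covariates
  class(out) <- c("AssociationResult", "data.frame")
  out
}

#' @exportS3Method base::print
print.AssociationResult <- function(x, digits = 3, ...) {
  cat("Module-phenotype associations (bootstrap percentile inference):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Summarize module activity by cell cluster
#'
#' Per (module, cluster): n, mean, median, quartiles, plus a specificity
#' score — the gap between the top and second cluster means in SD-of-activity
#' units.
#'
#' @param activity observations x modules matrix.
#' @param cluster_labels named vector covering all observations.
#' @return data.frame, one row per (module, cluster); per-module specificity
#'   in the \code{specificity} attribute.
#' @export
activity_by_cluster <- function(activity, cluster_labels) {
  labs <- cluster_labels[rownames(activity)]
  if (any(is.na(labs))) stop("cluster labels must cover all observations")
  rows <- list(); spec_score <- numeric(0)
  for (j in seq_len(ncol(activity))) {
    mid <- colnames(activity)[j]
    a <- activity[, j]
    means <- tapply(a, labs, mean)
    sdall <- stats::sd(a)
    top2 <- sort(means, decreasing = TRUE)[1:min(2, length(means))]
    spec_score[mid] <- if (length(top2) == 2 && sdall > 0)
      (top2[1] - top2[2]) / sdall else 0
    for (k in names(means)) {
      q <- stats::quantile(a[labs == k], c(0.25, 0.5, 0.75), names = FALSE)
      rows[[paste(mid, k)]] <- data.frame(
        module = mid, cluster = k, n = sum(labs == k),
        mean = means[[k]], q25 = q[1], median = q[2], q75 = q[3])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "specificity") <- spec_score
  out
}
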