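test_that("pairwise correlation matches the textbook formula", {
  set.seed(1)
  v <- matrix(rnorm(10 * 50), 10, 50,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  cc <- pairwise_correlation(v)
  oracle <- cor(t(v))
  expect_equal(cc, oracle, tolerance = 1e-12)
  expect_true(isSymmetric(cc))
  expect_equal(unname(diag(cc)), rep(1, 10))
  # duplicated gene and negated gene
  v2 <- rbind(v, dup = v[1, ], neg = -v[1, ])
  cc2 <- pairwise_correlation(v2)
  expect_equal(cc2["g01", "dup"], 1, tolerance = 1e-12)
  expect_equal(cc2["g01", "neg"], -1, tolerance = 1e-12)
  # zero-variance gene -> 0 with warning path
  v3 <- rbind(v, flat = rep(2, 50))
  cc3 <- pairwise_correlation(v3)
  expect_true(all(cc3["flat", colnames(cc3) != "flat"] == 0))
  expect_equal(cc3["flat", "flat"], 1)
  expect_error(pairwise_correlation(v[, 1:10]), "30 observations")
})

test_that("adjacency applies soft thresholding with clipping", {
  cc <- matrix(c(1, 0.5, -0.5, 0.5, 1, 0.2, -0.5, 0.2, 1), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  a_u <- adjacency(cc, 2, "unsigned")
  expect_equal(a_u["a", "b"], 0.25)
  expect_equal(a_u["a", "c"], 0.25)
  expect_equal(unname(diag(a_u)), rep(0, 3))
  a_s <- adjacency(cc, 2, "signed-hybrid")
  expect_equal(a_s["a", "c"], 0)
  expect_equal(a_s["a", "b"], 0.25)
  set.seed(2)
  r <- matrix(runif(64, -1, 1), 8); r <- (r + t(r)) / 2; diag(r) <- 1
  expect_equal(adjacency(r, 3, "unsigned"),
               {x <- abs(r)^3; diag(x) <- 0; x}, tolerance = 1e-15)
  expect_error(adjacency(cc, 2, "bogus"))
})

test_that("mean adjacency is non-increasing in the soft power", {
  set.seed(3)
  v <- matrix(rnorm(30 * 60), 30, 60,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  cc <- pairwise_correlation(v)
  means <- vapply(1:8, function(b) mean(adjacency(cc, b)), numeric(1))
  expect_true(all(diff(means) <= 1e-15))
})

test_that("scale-free fit scores an exact power law as 1", {
  # degrees drawn so that binned log-freq vs log-k is exactly linear
  k <- rep(2^(0:7), times = round(1000 * (2^(0:7))^-1.5))
  sf <- coexmod:::scale_free_fit(k, n_breaks = 8)
  expect_gt(sf$r2, 0.99)
  expect_lt(sf$slope, 0)
})

test_that("soft power selection honours the target and the grid", {
  set.seed(4)
  # correlated blocks give a usable degree spectrum
  f <- rnorm(100)
  v <- rbind(t(sapply(1:20, function(i) 0.9 * f + rnorm(100, 0, 0.6))),
             matrix(rnorm(40 * 100), 40, 100))
  rownames(v) <- sprintf("g%02d", 1:60)
  cc <- pairwise_correlation(v)
  fit <- pick_soft_power(cc, powers = 1:10, r2_target = 0)
  expect_equal(fit$chosen_power, 1)
  fit2 <- pick_soft_power(cc, powers = 1:10, r2_target = 0.8)
  expect_true(fit2$chosen_power %in% 1:10)
  tab <- fit2$fit_table
  # connectivity decreases with power
  expect_true(all(diff(tab$mean_k) < 0))
  # R^2 values match an independent histogram+regression oracle
  for (b in c(2, 5)) {
    a <- adjacency(cc, b)
    k <- rowSums(a); k <- k[k > 0]
    br <- seq(min(k), max(k), length.out = 11); br[11] <- br[11] + 1e-9
    bin <- cut(k, br, include.lowest = TRUE)
    fr <- tapply(k, bin, length); dk <- tapply(k, bin, mean)
    ok <- !is.na(fr) & fr > 0
    o <- summary(lm(log10(fr[ok] / sum(fr[ok])) ~ log10(dk[ok])))
    expect_equal(tab$signed_r2[tab$power == b],
                 -sign(coef(o)[2, 1]) * o$r.squared, tolerance = 1e-10)
  }
  expect_error(pick_soft_power(cc, powers = c(3, 1)), "ascending")
})

test_that("TOM matches hand-evaluated cases", {
  ones <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(ones) <- 0
  t1 <- tom_similarity(ones)
  expect_equal(t1["a", "b"], 1)
  half <- matrix(0.5, 3, 3, dimnames = dimnames(ones)); diag(half) <- 0
  t2 <- tom_similarity(half)
  expect_equal(t2["a", "b"], 0.5)  # (0.25 + 0.5) / (1 + 1 - 0.5)
  expect_equal(unname(diag(t2)), rep(1, 3))
  bad <- half; bad[1, 2] <- 1.4
  expect_error(tom_similarity(bad), "0,1")
})

test_that("TOM equals the brute-force triple loop and stays in [0,1]", {
  for (seed in 1:10) {
    a <- random_adjacency(12, seed = seed)
    tom <- tom_similarity(a)
    expect_lt(max(abs(tom - tom_bruteforce(a))), 1e-10)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_true(isSymmetric(tom))
  }
})

test_that("module detection separates perfect blocks", {
  n <- 40
  tom <- matrix(0, n, n,
                dimnames = list(sprintf("g%02d", 1:n),
                                sprintf("g%02d", 1:n)))
  tom[1:20, 1:20] <- 1
  tom[21:40, 21:40] <- 1
  ms <- detect_modules(tom, min_size = 10)
  expect_length(ms$modules, 2L)
  sizes <- sort(vapply(ms$modules, function(m) length(m$genes), integer(1)))
  expect_equal(unname(sizes), c(20L, 20L))
  expect_length(ms$background, 0L)
  # min_size above n: everything is background
  ms2 <- detect_modules(tom, min_size = 100)
  expect_length(ms2$modules, 0L)
  expect_length(ms2$background, n)
})

test_that("module detection recovers noisy planted blocks", {
  set.seed(7)
  n <- 90
  truth <- rep(1:3, each = 30)
  tom <- matrix(runif(n * n, 0, 0.15), n, n)
  for (b in 1:3)
    tom[truth == b, truth == b] <- runif(900, 0.5, 0.9)
  tom <- (tom + t(tom)) / 2; diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  # with no background genes most merge heights are within-block, so the
  # cut sits below the block-joining merges
  ms <- detect_modules(tom, min_size = 10, cut_quantile = 0.97)
  found <- setNames(rep("bg", n), rownames(tom))
  for (m in ms$modules) found[m$genes] <- m$module_id
  expect_gte(adjusted_rand_index(found, truth), 0.9)
})

test_that("eigengene matches an independent SVD route and orientation rule", {
  set.seed(8)
  f <- rnorm(80)
  x <- t(sapply(1:6, function(i) 1.2 * f + rnorm(80, 0, 0.4)))
  rownames(x) <- sprintf("g%d", 1:6)
  colnames(x) <- sprintf("c%02d", 1:80)
  e <- module_eigengene(x, rownames(x))
  expect_equal(sd(e), 1, tolerance = 1e-12)
  # power-iteration oracle on the standardized submatrix
  z <- t(scale(t(x)))
  cm <- crossprod(t(z))      # gene x gene
  v0 <- rep(1, 6)
  for (i in 1:500) { v0 <- cm %*% v0; v0 <- v0 / sqrt(sum(v0^2)) }
  score <- as.numeric(crossprod(z, v0))
  score <- score / sd(score)
  if (cor(score, colMeans(z)) < 0) score <- -score
  expect_equal(unname(e), score, tolerance = 1e-6)
  # orientation: correlation with module mean is non-negative either way
  e_flip <- module_eigengene(-x, rownames(x))
  zf <- t(scale(t(-x)))
  expect_gte(cor(e_flip, colMeans(zf)), 0)
  # identical genes: eigengene is the standardized common profile
  xx <- rbind(a = f, b = f)
  colnames(xx) <- sprintf("c%02d", 1:80)
  ei <- module_eigengene(xx, c("a", "b"))
  expect_equal(unname(ei), as.numeric(scale(f)), tolerance = 1e-8)
  expect_error(module_eigengene(matrix(1, 2, 10,
                                       dimnames = list(c("a", "b"), NULL)),
                                c("a", "b")), "constant")
})

test_that("kIM is the within-module TOM row sum", {
  a <- random_adjacency(15, seed = 9)
  tom <- tom_similarity(a)
  genes <- rownames(tom)[c(2, 5, 9, 12)]
  kim <- compute_kim(tom, genes)
  sub <- tom[genes, genes]; diag(sub) <- 0
  expect_equal(kim$raw, rowSums(sub), tolerance = 1e-12)
  expect_equal(sum(kim$normalized), 1, tolerance = 1e-12)
  # 2-gene module: both weights equal the pair TOM
  kim2 <- compute_kim(tom, rownames(tom)[1:2])
  expect_equal(unname(kim2$raw), rep(tom[1, 2], 2))
  # perfect block of size s: kIM = s - 1
  ones <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(ones) <- 0
  kb <- compute_kim(tom_similarity(ones), letters[1:4])
  expect_equal(unname(kb$raw), rep(3, 4))
  expect_error(compute_kim(tom, rownames(tom)[1]), "singleton")
})

test_that("modules with identical eigengenes merge; distinct ones do not", {
  set.seed(10)
  f1 <- rnorm(100); f2 <- rnorm(100)
  x <- rbind(t(sapply(1:8, function(i) f1 + rnorm(100, 0, 0.1))),
             t(sapply(1:8, function(i) f1 + rnorm(100, 0, 0.1))),
             t(sapply(1:8, function(i) f2 + rnorm(100, 0, 0.1))))
  rownames(x) <- sprintf("g%02d", 1:24)
  colnames(x) <- sprintf("c%03d", 1:100)
  ms <- coexmod:::new_module_set(
    list(M1 = coexmod:::new_gene_module("M1", rownames(x)[1:8]),
         M2 = coexmod:::new_gene_module("M2", rownames(x)[9:16]),
         M3 = coexmod:::new_gene_module("M3", rownames(x)[17:24])),
    character(0))
  merged <- merge_modules(x, ms, merge_corr = 0.85)
  expect_length(merged$modules, 2L)
  sizes <- sort(vapply(merged$modules, function(m) length(m$genes),
                       integer(1)))
  expect_equal(unname(sizes), c(8L, 16L))
  # unreachable threshold: identity
  same <- merge_modules(x, ms, merge_corr = 1.01)
  expect_length(same$modules, 3L)
})

test_that("module QC drops noise modules and keeps coherent ones", {
  set.seed(11)
  f <- rnorm(500)
  coher <- t(sapply(1:12, function(i) f + rnorm(500, 0, 0.5)))
  noise <- matrix(rnorm(12 * 500), 12, 500)
  x <- rbind(coher, noise)
  rownames(x) <- sprintf("g%02d", 1:24)
  colnames(x) <- sprintf("c%03d", 1:500)
  ms <- coexmod:::new_module_set(
    list(M1 = coexmod:::new_gene_module("M1", rownames(x)[1:12]),
         M2 = coexmod:::new_gene_module("M2", rownames(x)[13:24])),
    character(0))
  ms <- coexmod:::fill_module_stats(x, ms)
  out <- qc_modules(x, ms, min_size = 10, min_mean_kme = 0.3)
  expect_identical(names(out$modules), "M1")
  expect_setequal(out$background, rownames(x)[13:24])
  # vacuous thresholds: identity
  all_kept <- qc_modules(x, ms, min_size = 0, min_mean_kme = -1)
  expect_length(all_kept$modules, 2L)
})

test_that("degenerate consensus (B_net = 1, 100% resample) equals a single run", {
  cfg0 <- sim_config(n_genes = 150, n_modules_per_type = 2, module_size = 25,
                     cells_per_donor = 30, n_donors = 4, seed = 12)
  sim <- simulate_sc_dataset(cfg0)
  scaled <- scale_within_batch(normalize_log(sim$expr))
  cfg <- pipeline_config(B_net = 1L, resample_frac = 1)
  res <- consensus_modules(scaled, cfg)
  cc <- pairwise_correlation(scaled, "pearson")
  fit <- pick_soft_power(cc)
  tom <- tom_similarity(adjacency(cc, fit$chosen_power))
  expect_equal(unname(res$consensus_tom), unname(tom), tolerance = 1e-12)
  single <- detect_modules(tom, cfg$min_module_size, cfg$cut_quantile)
  expect_equal(sort(vapply(res$module_set$modules,
                           function(m) length(m$genes), integer(1))),
               sort(vapply(single$modules,
                           function(m) length(m$genes), integer(1))),
               ignore_attr = TRUE)
})

test_that("consensus of identical TOMs is that TOM (median identity)", {
  a <- random_adjacency(10, seed = 13)
  tom <- tom_similarity(a)
  stack <- array(rep(tom, 3), dim = c(10, 10, 3))
  cons <- apply(stack, c(1, 2), median)
  expect_equal(cons, unname(tom), tolerance = 1e-15)
})

test_that("consensus modules recover planted membership and are reproducible", {
  cfg0 <- sim_config(n_genes = 300, n_modules_per_type = 3, module_size = 30,
                     cells_per_donor = 80, n_donors = 10, seed = 14)
  sim <- simulate_sc_dataset(cfg0)
  scaled <- scale_within_batch(normalize_log(sim$expr))
  cfg <- pipeline_config(B_net = 10L)
  res <- consensus_modules(scaled, cfg, cell_type = "CT1")
  labs <- module_recovery_labels(sim$truth, res$module_set)
  ari <- adjusted_rand_index(labs$truth_labels, labs$found_labels)
  expect_gte(ari, 0.8)
  skip_if_not_installed("mclust")
  expect_equal(ari,
               mclust::adjustedRandIndex(labs$truth_labels,
                                         labs$found_labels),
               tolerance = 1e-12)
  res2 <- consensus_modules(scaled, cfg, cell_type = "CT1")
  expect_identical(lapply(res$module_set$modules, `[[`, "genes"),
                   lapply(res2$module_set$modules, `[[`, "genes"))
  expect_identical(res$consensus_tom, res2$consensus_tom)
})

test_that("consensus beats a single half-sample run on most replicates", {
  wins <- 0
  for (rep_i in 1:5) {
    cfg0 <- sim_config(n_genes = 200, n_modules_per_type = 2,
                       module_size = 25, cells_per_donor = 60, n_donors = 8,
                       factor_sd = 1, noise_sd = 0.6, seed = 100 + rep_i)
    sim <- simulate_sc_dataset(cfg0)
    scaled <- scale_within_batch(normalize_log(sim$expr))
    cfg <- pipeline_config(B_net = 8L, seed_net = rep_i)
    cons <- consensus_modules(scaled, cfg, cell_type = "CT1")
    labs <- module_recovery_labels(sim$truth, cons$module_set)
    ari_cons <- adjusted_rand_index(labs$truth_labels, labs$found_labels)
    # single run on a 50% subsample
    set.seed(rep_i)
    idx <- sample(length(scaled$obs_ids), length(scaled$obs_ids) %/% 2)
    sub <- em_subset(scaled, obs = scaled$obs_ids[idx])
    cc <- pairwise_correlation(sub)
    fit <- pick_soft_power(cc)
    tom <- tom_similarity(adjacency(cc, fit$chosen_power))
    ms <- detect_modules(tom, cfg$min_module_size, cfg$cut_quantile)
    labs2 <- module_recovery_labels(sim$truth, ms)
    ari_single <- adjusted_rand_index(labs2$truth_labels,
                                      labs2$found_labels)
    if (ari_cons >= ari_single) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
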