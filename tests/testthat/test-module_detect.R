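# Planted-block dissimilarity: two tight blocks far apart
block_dissim <- function(sizes = c(20, 20), within = 0.1, between = 0.9, jitter = 0,
                         seed = 1) {
  n <- sum(sizes)
  set.seed(seed)
  D <- matrix(between, n, n)
  start <- cumsum(c(1, sizes))
  for (b in seq_along(sizes)) {
    idx <- start[b]:(start[b + 1] - 1)
    D[idx, idx] <- within
  }
  if (jitter > 0) {
    J <- matrix(runif(n * n, -jitter, jitter), n, n)
    D <- D + (J + t(J)) / 2
  }
  diag(D) <- 0
  dimnames(D) <- list(paste0("G", 1:n), paste0("G", 1:n))
  D
}

test_that("average linkage merge heights match a naive agglomeration oracle", {
  set.seed(21)
  for (i in 1:5) {
    D <- matrix(runif(64), 8, 8)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    dimnames(D) <- list(paste0("G", 1:8), paste0("G", 1:8))
    tree <- linkage_tree(D)
    expect_equal(sort(tree$height), oracle_average_linkage_heights(D),
                 tolerance = 1e-12)
  }
})

test_that("two leaves merge at their distance; ties and reruns are deterministic", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tree <- linkage_tree(D)
  expect_equal(tree$height, 0.4)
  ## three equidistant leaves: reproducible regardless of tie order
  D3 <- matrix(0.3, 3, 3); diag(D3) <- 0
  dimnames(D3) <- list(letters[1:3], letters[1:3])
  t1 <- linkage_tree(D3); t2 <- linkage_tree(D3)
  expect_identical(t1$merge, t2$merge)
  expect_identical(t1$height, t2$height)
  ## invalid inputs
  Dbad <- D; Dbad[1, 2] <- Inf; Dbad[2, 1] <- Inf
  expect_error(linkage_tree(Dbad), "non-finite")
})

test_that("dynamic hybrid cut recovers planted blocks exactly (ARI = 1)", {
  D <- block_dissim(c(20, 20))
  tree <- linkage_tree(D)
  part <- cut_dynamic_hybrid(tree, D, cut_params(min_module_size = 5))
  truth <- rep(1:2, each = 20)
  expect_equal(part$n_modules, 2L)
  expect_equal(adjusted_rand_index(part$labels, setNames(truth, rownames(D))), 1)
  ## determinism
  part2 <- cut_dynamic_hybrid(tree, D, cut_params(min_module_size = 5))
  expect_identical(part$labels, part2$labels)
})

test_that("min_module_size above the gene count leaves everything unassigned", {
  D <- block_dissim(c(20, 20), seed = 4)
  tree <- linkage_tree(D)
  expect_warning(part <- cut_dynamic_hybrid(tree, D, cut_params(min_module_size = 50)),
                 "unassigned")
  expect_true(all(part$labels == 0L))
  expect_equal(part$n_modules, 0L)
})

test_that("deeper deep_split never yields fewer stage-1 branches", {
  spec <- synthetic_spec()
  ds <- simulate_dataset(spec, seed = 11)
  cm <- correlation_matrix(ds$expr, method = "bicor")
  tom <- tom_similarity(adjacency_matrix(cm))
  tree <- linkage_tree(tom$dissim)
  branches <- sapply(0:4, function(d) {
    cut_dynamic_hybrid(tree, tom$dissim, cut_params(deep_split = d))$n_stage1_branches
  })
  expect_true(all(diff(branches) >= 0))
})

test_that("module eigengenes have unit variance, member orientation, and rank-1 pve", {
  set.seed(31)
  ## rank-1 module: identical rows up to sign
  base <- rnorm(12)
  m <- rbind(A1 = base, A2 = 2 * base + 1, A3 = -base, B1 = rnorm(12), B2 = rnorm(12))
  colnames(m) <- paste0("S", 1:12)
  part <- list(labels = setNames(c(1L, 1L, 1L, 2L, 2L), rownames(m)))
  eg <- module_eigengenes(m, part$labels)
  expect_equal(sd(eg$me[, "ME1"]), 1)
  expect_equal(eg$pve[["ME1"]], 1, tolerance = 1e-12)
  expect_equal(abs(cor(eg$me[, "ME1"], base)), 1, tolerance = 1e-12)
  ## orientation: mean member correlation non-negative for all modules
  for (q in eg$modules) {
    mem <- names(part$labels)[part$labels == q]
    expect_gte(mean(cor(eg$me[, paste0("ME", q)], t(m[mem, ]))), 0)
  }
})

test_that("eigengene orientation and unit variance hold on random data", {
  set.seed(32)
  for (i in 1:10) {
    m <- matrix(rnorm(30 * 15), 30, 15,
                dimnames = list(paste0("G", 1:30), paste0("S", 1:15)))
    labels <- setNames(rep(1:3, each = 10), rownames(m))
    eg <- module_eigengenes(m, labels)
    expect_equal(unname(apply(eg$me, 2, sd)), rep(1, 3), tolerance = 1e-8)
    for (q in 1:3) {
      mem <- names(labels)[labels == q]
      expect_gte(mean(cor(eg$me[, paste0("ME", q)], t(m[mem, ]))), 0)
    }
    expect_true(all(eg$pve > 0 & eg$pve <= 1))
  }
})

test_that("pve approximates the mean squared member-eigengene correlation", {
  ## planted module with cor(gene, eigengene) = sqrt(0.64)
  spec <- synthetic_spec(n_samples = 200, module_sizes = c(30L),
                         rho = 0.64, rho_spread = 0, n_genes = 40,
                         driver_plan = data.frame(module = 1, cor = 0.5),
                         candidate_module = 1, candidate_rho = 0.64,
                         candidate_driver_cor = 0.4,
                         paired = FALSE, outlier_fraction = 0)
  pves <- replicate(10, {
    ds <- simulate_dataset(spec, seed = sample.int(1e6, 1))
    mem <- names(ds$truth$labels)[ds$truth$labels == 1L]
    labels <- setNames(rep(1L, length(mem)), mem)
    eg <- module_eigengenes(ds$expr[mem, ], labels)
    kme2 <- mean(cor(eg$me[, 1], t(ds$expr[mem, ]))^2)
    c(eg$pve[[1]], kme2)
  })
  set.seed(99)
  expect_lt(mean(abs(pves[1, ] - pves[2, ])), 0.05)
})

test_that("modules with identical eigengenes merge; distant ones do not", {
  set.seed(41)
  e1 <- rnorm(20); e2 <- rnorm(20)
  mk <- function(e, n, noise = 0.05) t(sapply(seq_len(n), function(i) e + rnorm(20, 0, noise)))
  m <- rbind(mk(e1, 5), mk(e1, 5), mk(e2, 5))
  rownames(m) <- paste0("G", 1:15)
  colnames(m) <- paste0("S", 1:20)
  part <- coexmod:::finish_partition(
    setNames(rep(1:3, each = 5), rownames(m)), cut_params(), 3L)
  merged <- merge_close_modules(m, part, 0.15)
  expect_equal(merged$partition$n_modules, 2L)
  expect_gt(merged$n_merges, 0L)
  ## the two same-eigengene modules became one
  l <- merged$partition$labels
  expect_equal(length(unique(l[paste0("G", 1:10)])), 1L)
  ## all pairwise distant -> unchanged
  m2 <- rbind(mk(e1, 5), mk(e2, 5))
  rownames(m2) <- paste0("H", 1:10); colnames(m2) <- paste0("S", 1:20)
  part2 <- coexmod:::finish_partition(
    setNames(rep(1:2, each = 5), rownames(m2)), cut_params(), 2L)
  merged2 <- merge_close_modules(m2, part2, 0.15)
  expect_equal(merged2$n_merges, 0L)
  expect_equal(merged2$partition$n_modules, 2L)
})

test_that("chained merging follows the closest-first rule on a 3-module fixture", {
  set.seed(42)
  base <- rnorm(40)
  ## three modules; 1 and 2 nearly share an eigengene, 3 is independent
  m <- rbind(t(replicate(6, base + rnorm(40, 0, 0.1))),
             t(replicate(6, base + rnorm(40, 0, 0.12))),
             t(replicate(6, rnorm(40))))
  rownames(m) <- paste0("G", 1:18); colnames(m) <- paste0("S", 1:40)
  part <- coexmod:::finish_partition(
    setNames(rep(1:3, each = 6), rownames(m)), cut_params(), 3L)
  eg <- module_eigengenes(m, part$labels)
  cors <- cor(eg$me)
  ## hand simulation of closest-first merging at threshold 0.15:
  ## only the high-correlation pair merges; module 3 stays
  stopifnot(sum(1 - cors[upper.tri(cors)] < 0.15) == 1)
  merged <- merge_close_modules(m, part, 0.15)
  expect_equal(merged$partition$n_modules, 2L)
  l <- merged$partition$labels
  expect_equal(length(unique(l[paste0("G", 1:12)])), 1L)
  expect_equal(length(unique(l[paste0("G", 13:18)])), 1L)
})

test_that("hub statistics order genes by intramodular connectivity", {
  set.seed(51)
  m <- matrix(rnorm(3 * 10), 3, 10, dimnames = list(c("a", "b", "c"), paste0("S", 1:10)))
  A <- matrix(c(0, 1.0, 0.8,
                1.0, 0, 0.5,
                0.8, 0.5, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  labels <- setNames(c(1L, 1L, 1L), c("a", "b", "c"))
  eg <- module_eigengenes(m, labels)
  st <- gene_module_stats(m, list(labels = labels), A, eg)
  ## kIM: a = 1.8, b = 1.5, c = 1.3 -> ranks 1, 2, 3
  expect_equal(st$kIM, c(1.8, 1.5, 1.3))
  expect_equal(st$hub_rank, 1:3)
  ## kME = 1 for a gene equal to its eigengene up to positive scaling
  me <- eg$me[, "ME1"]
  m2 <- rbind(m, d = 2 * me + 3)
  labels2 <- setNames(rep(1L, 4), rownames(m2))
  A2 <- rbind(cbind(A, d = 0.1), d = c(0.1, 0.1, 0.1, 0))
  rownames(A2)[4] <- "d"
  eg2 <- module_eigengenes(m2, labels2)
  st2 <- gene_module_stats(m2, list(labels = labels2), A2, eg2)
  expect_gt(st2$kME[st2$gene_id == "d"], 0.99)
})

test_that("top_hub_genes respects k and warns at the boundary", {
  spec <- synthetic_spec()
  ds <- simulate_dataset(spec, seed = 5)
  truth <- ds$truth$labels
  cm <- correlation_matrix(ds$expr[names(truth)[truth %in% c(4, 5)], ], method = "pearson")
  A <- adjacency_matrix(cm)
  labels <- truth[truth %in% c(4, 5)]
  eg <- module_eigengenes(ds$expr, labels)
  st <- gene_module_stats(ds$expr, list(labels = labels), A, eg)
  expect_length(top_hub_genes(st, 4, k = 10), 10L)
  expect_warning(all_of_5 <- top_hub_genes(st, 5, k = 120), "only")
  expect_length(all_of_5, sum(labels == 5))
})

test_that("module-trait correlation is exact for a trait equal to an eigengene", {
  spec <- synthetic_spec()
  ds <- simulate_dataset(spec, seed = 13)
  eg <- module_eigengenes(ds$expr, ds$truth$labels)
  traits <- data.frame(sample_id = rownames(eg$me),
                       self = eg$me[, "ME1"],
                       const = 1)
  expect_warning(mt <- module_trait_correlation(eg, traits), "constant")
  expect_equal(mt$r["ME1", "self"], 1, tolerance = 1e-12)
  expect_lt(mt$p["ME1", "self"], 1e-20)
  expect_true(all(is.na(mt$r[, "const"])))
})

test_that("permuted traits give small correlations and uniform p-values", {
  spec <- synthetic_spec()
  ds <- simulate_dataset(spec, seed = 19)
  eg <- module_eigengenes(ds$expr, ds$truth$labels)
  set.seed(77)
  ps <- replicate(200, {
    traits <- data.frame(sample_id = rownames(eg$me), perm = sample(ds$traits$driver))
    module_trait_correlation(eg, traits)$p["ME4", "perm"]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(median(abs(ps - 0.5)), 0.4)
})

test_that("ARI matches the contingency-table formula and its invariances", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  a <- c(1, 1, 1, 2, 2, 2); b <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b), tolerance = 1e-12)
  set.seed(61)
  for (i in 1:20) {
    x <- sample(0:3, 40, replace = TRUE)
    y <- sample(0:2, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), oracle_ari(x, y), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(a, a), 1)
})

test_that("hyperparameter sweep reports identical partitions as ARI 1", {
  D <- block_dissim(c(15, 15), jitter = 0.02, seed = 6)
  set.seed(62)
  expr <- matrix(rnorm(30 * 12), 30, 12, dimnames = list(rownames(D), paste0("S", 1:12)))
  grid <- data.frame(deep_split = c(2, 2), min_module_size = c(5, 5),
                     merge_threshold = c(0.15, 0.15), pam_stage = c(TRUE, TRUE))
  sw <- hyperparameter_sweep(expr, D, grid)
  expect_equal(sw$ari[1, 2], 1)
  expect_equal(sw$median_ari, 1)
  expect_error(hyperparameter_sweep(expr, D, grid[0, ]), "empty")
})
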