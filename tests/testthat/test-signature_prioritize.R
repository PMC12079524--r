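test_that("signature score hits exactly 1 and 0 at top and bottom rank placement", {
  set.seed(1)
  G <- 50; S <- 5
  m <- matrix(rnorm(G * 3), G, 3, dimnames = list(paste0("G", 1:G), paste0("S", 1:3)))
  ## force signature genes into the top S ranks of sample 1, bottom of sample 2
  sig <- paste0("G", 1:S)
  m[sig, 1] <- max(m[, 1]) + 1:S
  m[sig, 2] <- min(m[, 2]) - (1:S)
  sc <- signature_score(m, sig)
  expect_equal(sc$score[["S1"]], 1)
  expect_equal(sc$score[["S2"]], 0)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
})

test_that("signature score is bitwise invariant under per-sample monotone transforms", {
  set.seed(2)
  m <- matrix(rnorm(2000 * 20), 2000, 20,
              dimnames = list(paste0("G", 1:2000), paste0("S", 1:20)))
  sig <- sample(rownames(m), 19)
  base <- signature_score(m, sig)$score
  ## exp transform per sample
  expect_identical(round(signature_score(exp(m), sig)$score, 12), round(base, 12))
  ## a different strictly increasing transform per sample
  m2 <- m
  for (s in seq_len(ncol(m2))) m2[, s] <- s * m2[, s]^3 + atan(m2[, s])
  expect_identical(round(signature_score(m2, sig)$score, 12), round(base, 12))
})

test_that("random 19-gene signature on null data scores near 0.5", {
  set.seed(3)
  means <- replicate(20, {
    m <- matrix(rnorm(2000 * 100), 2000, 100,
                dimnames = list(paste0("G", 1:2000), paste0("S", 1:100)))
    mean(signature_score(m, sample(rownames(m), 19))$score)
  })
  expect_lt(abs(mean(means) - 0.5), 0.05)
})

test_that("signature scoring validates inputs", {
  m <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("G", 1:5), paste0("S", 1:4)))
  expect_error(signature_score(m, c("X1", "X2")), "no signature gene")
  expect_error(signature_score(m, rownames(m)), "all genes")
  expect_message(sc <- signature_score(m, c("G1", "G2", "X9")), "absent")
  expect_equal(sc$n_genes_used, 2L)
  expect_equal(sc$n_genes_missing, 1L)
})

test_that("a hub signature identical to the reference correlates at R = 1", {
  set.seed(4)
  m <- matrix(rnorm(200 * 30), 200, 30,
              dimnames = list(paste0("G", 1:200), paste0("S", 1:30)))
  sig <- paste0("G", 1:15)
  out <- validate_signature(m, list(M1 = sig, M2 = paste0("G", 100:120)), sig)
  expect_equal(out$R[out$module == "M1"], 1, tolerance = 1e-12)
  expect_equal(out$module[1], "M1")   # sorted by descending R
})

test_that("the module sharing the reference's latent factor ranks first in validation", {
  spec <- synthetic_spec(n_samples = 100, module_sizes = c(60L, 60L, 60L),
                         rho = c(0.65, 0.65, 0.65), rho_spread = 0.1,
                         n_genes = 600,
                         driver_plan = data.frame(module = 1, cor = 0.6),
                         candidate_module = 1, candidate_rho = 0.65,
                         candidate_driver_cor = 0.6 * sqrt(0.65),
                         paired = FALSE, outlier_fraction = 0)
  wins <- sapply(1:10, function(i) {
    val <- make_validation_cohort(spec, 100, seed = 40 + i, distort_genes = TRUE)
    labels <- val$truth$labels
    hubs <- lapply(1:3, function(q) names(labels)[labels == q][1:20])
    names(hubs) <- paste0("M", 1:3)
    ## reference signature: other members of module 1 (same latent factor)
    ref <- names(labels)[labels == 1L][31:50]
    out <- validate_signature(val$expr, hubs, ref)
    out$module[1] == "M1"
  })
  expect_gte(mean(wins), 0.9)
})

test_that("validation p-values are calibrated for permuted sample scores", {
  spec <- synthetic_spec(n_samples = 60, module_sizes = 40L, rho = 0.6,
                         rho_spread = 0.1, n_genes = 400,
                         driver_plan = data.frame(module = 1, cor = 0.6),
                         candidate_module = 1, candidate_rho = 0.6,
                         candidate_driver_cor = 0.6 * sqrt(0.6),
                         paired = FALSE, outlier_fraction = 0)
  ds <- simulate_dataset(spec, seed = 8)
  labels <- ds$truth$labels
  hub <- names(labels)[labels == 1L][1:20]
  bg <- grep("^BG_", names(labels), value = TRUE)[1:20]
  set.seed(9)
  ps <- replicate(200, {
    ## permuting the validation samples of one score vector breaks any real
    ## association; the correlation p should then be uniform
    perm <- ds$expr
    colnames(perm) <- sample(colnames(perm))
    base <- signature_score(ds$expr, hub)$score
    ref <- signature_score(perm, bg)$score[names(base)]
    cor.test(base, ref)$p.value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("candidate ranking screens by sign and significance and sorts by composite", {
  spec <- synthetic_spec()
  ds <- simulate_dataset(spec, seed = 3)
  cm <- correlation_matrix(ds$expr, method = "bicor")
  adj <- adjacency_matrix(cm)
  part <- list(labels = ds$truth$labels)
  eg <- module_eigengenes(ds$expr, ds$truth$labels)
  st <- gene_module_stats(ds$expr, part, adj, eg)
  case <- ds$traits$sample_id[ds$traits$condition == 1]
  tab <- rank_candidates(ds$expr, part, st, 2L, "DRIVER1",
                         direction = "negative", N = 10, sample_subset = case)
  ## eligibility rule: every top-N gene is negative and significant
  top <- tab[tab$top_n, ]
  expect_equal(nrow(top), 10L)
  expect_true(all(top$r_driver < 0 & top$p < 0.05))
  ## ineligible genes sit below all eligible ones regardless of hubness
  expect_true(max(tab$final_rank[tab$eligible]) < min(tab$final_rank[!tab$eligible]))
  ## final ranks are a permutation
  expect_setequal(tab$final_rank, seq_len(nrow(tab)))
  ## composite sorted among eligible
  expect_false(is.unsorted(tab$composite[tab$eligible]))
  ## q is the BH adjustment of p
  expect_equal(sort(tab$q), sort(oracle_bh(tab$p)), tolerance = 1e-12)
})

test_that("candidate ranking is invariant to gene order and positive rescaling", {
  spec <- synthetic_spec()
  ds <- simulate_dataset(spec, seed = 6)
  cm <- correlation_matrix(ds$expr, method = "bicor")
  adj <- adjacency_matrix(cm)
  part <- list(labels = ds$truth$labels)
  eg <- module_eigengenes(ds$expr, ds$truth$labels)
  st <- gene_module_stats(ds$expr, part, adj, eg)
  t1 <- rank_candidates(ds$expr, part, st, 2L, "DRIVER1")
  ## permute gene rows
  set.seed(7)
  perm <- sample(nrow(ds$expr))
  t2 <- rank_candidates(ds$expr[perm, ], part, st, 2L, "DRIVER1")
  expect_equal(t1$gene_id, t2$gene_id)
  expect_equal(t1$final_rank, t2$final_rank)
  ## positive rescaling of expression (gene-wise) leaves correlations intact
  sc <- ds$expr * 3.5
  t3 <- rank_candidates(sc, part, st, 2L, "DRIVER1")
  expect_equal(t1$r_driver, t3$r_driver, tolerance = 1e-12)
})

test_that("driver inside the module is excluded; boundary N warns", {
  spec <- synthetic_spec()
  ds <- simulate_dataset(spec, seed = 12)
  keep <- c(sprintf("M1_G%03d", 1:100), "DRIVER1")
  cm <- correlation_matrix(ds$expr[keep, ], method = "pearson")
  adj <- adjacency_matrix(cm)
  labels <- setNames(rep(1L, length(keep)), keep)  # driver clustered into module 1
  part <- list(labels = labels)
  eg <- module_eigengenes(ds$expr, labels)
  st <- gene_module_stats(ds$expr, part, adj, eg)
  expect_message(tab <- suppressWarnings(
    rank_candidates(ds$expr, part, st, 1L, "DRIVER1", direction = "positive",
                    N = 1000)), "module member")
  expect_false("DRIVER1" %in% tab$gene_id)
  expect_warning(rank_candidates(ds$expr, part, st, 1L, "DRIVER1",
                                 direction = "positive", N = 1000),
                 "flagging all")
})

test_that("paired t-test matches the closed form and its symmetries", {
  d <- c(1.0, 1.2, 0.8, 1.1, 0.9)
  expr <- rbind(g1 = c(d + 5, rep(5, 5)))
  colnames(expr) <- paste0("S", 1:10)
  traits <- data.frame(sample_id = colnames(expr),
                       condition = rep(c(1L, 0L), each = 5),
                       pair = rep(paste0("P", 1:5), 2))
  out <- paired_de_test(expr, traits)
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(abs(t_hand), 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(out$mean_diff, 1.0)
  expect_equal(out$direction, "up")
  ## swapping condition labels negates t, keeps p
  tr2 <- traits; tr2$condition <- 1L - tr2$condition
  out2 <- paired_de_test(expr, tr2)
  expect_equal(out2$t, -out$t, tolerance = 1e-12)
  expect_equal(out2$p, out$p, tolerance = 1e-12)
})

test_that("degenerate paired differences are flagged", {
  expr <- rbind(zero = rep(3, 8), shift = c(rep(4, 4), rep(3, 4)))
  colnames(expr) <- paste0("S", 1:8)
  traits <- data.frame(sample_id = colnames(expr),
                       condition = rep(c(1L, 0L), each = 4),
                       pair = rep(paste0("P", 1:4), 2))
  out <- paired_de_test(expr, traits)
  expect_equal(out$p[out$gene_id == "zero"], 1)
  expect_equal(out$t[out$gene_id == "zero"], 0)
  expect_true(out$degenerate[out$gene_id == "zero"])
  expect_equal(out$t[out$gene_id == "shift"], Inf)
  expect_true(out$degenerate[out$gene_id == "shift"])
  expect_equal(out$direction[out$gene_id == "shift"], "up")
})

test_that("hypergeometric ORA matches exhaustive enumeration", {
  universe <- paste0("G", 1:20)
  sets <- list(hit = paste0("G", 1:5))
  ## selection = the set itself: p = 1 / choose(20, 5)
  out <- ora_hypergeometric(paste0("G", 1:5), sets, universe)
  expect_equal(out$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(out$p, oracle_hyper_enum(20, 5, 5, 5), tolerance = 1e-12)
  ## partial overlap checked against enumeration
  out2 <- ora_hypergeometric(c("G1", "G2", "G10", "G11", "G12"), sets, universe)
  expect_equal(out2$overlap, 2L)
  expect_equal(out2$p, oracle_hyper_enum(20, 5, 5, 2), tolerance = 1e-12)
  ## zero overlap has p = 1
  out3 <- ora_hypergeometric(paste0("G", 10:14), sets, universe)
  expect_equal(out3$p, 1)
})

test_that("ORA applies BH across sets and polices the universe", {
  universe <- paste0("G", 1:100)
  sets <- list(a = paste0("G", 1:10), b = paste0("G", 11:20), c = paste0("G", 21:30))
  sel <- paste0("G", c(1:5, 11:15, 21:25))
  out <- ora_hypergeometric(sel, sets, universe)
  ## identical construction -> identical p -> identical q
  expect_equal(length(unique(round(out$p, 12))), 1L)
  expect_equal(length(unique(round(out$q, 12))), 1L)
  expect_equal(out$q, oracle_bh(out$p), tolerance = 1e-12)
  expect_warning(ora_hypergeometric(c(sel, "NOT_THERE"), sets, universe), "universe")
  expect_error(ora_hypergeometric(sel, sets, character(0)), "universe")
})

test_that("BH adjustment agrees with the step-up definition on random p-vectors", {
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})
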