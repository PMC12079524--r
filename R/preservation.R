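## Permutation module preservation across datasets: seven density and
## connectivity statistics per module with a random-gene-set null.

## correlation submatrix for a gene set under a network config
set_cor <- function(expr, genes, cfg) {
  correlation_matrix(expr[genes, , drop = FALSE], method = cfg$method,
                     min_pairs = cfg$min_pairs)$cor
}

## first-PC summary of a gene set in one dataset: pve and signed kME
set_pc_stats <- function(expr, genes) {
  X <- expr[genes, , drop = FALSE]
  sds <- apply(X, 1L, stats::sd)
  X <- X[sds > 0 & !is.na(sds), , drop = FALSE]
  if (nrow(X) < 2L) return(list(pve = NA_real_, kme = rep(NA_real_, length(genes))))
  Z <- t(scale(t(X)))
  sv <- svd(t(Z), nu = 1L, nv = 0L)
  v <- sv$u[, 1L]
  kme_sub <- as.numeric(stats::cor(v, t(Z)))
  if (mean(kme_sub) < 0) kme_sub <- -kme_sub
  kme <- rep(NA_real_, length(genes))
  kme[match(rownames(X), genes)] <- kme_sub
  list(pve = sv$d[1L]^2 / sum(sv$d^2), kme = kme)
}

## The seven preservation statistics of one gene set.
## s1 meanCor: mean intramodule correlation in the test data
## s2 meanAdj: mean intramodule adjacency in the test data
## s3 pve:     variance explained by the set's first PC in the test data
## s4 meanKME: mean |kME| in the test data
## s5 cor.kIM: rank correlation of intramodular connectivity, ref vs test
## s6 cor.kME: rank correlation of signed kME, ref vs test
## s7 cor.cor: rank correlation of the vectorized intramodule correlations
## The pattern-agreement statistics s5-s7 use Spearman correlation: under
## the random-gene-set null, a draw containing even two co-members of a
## strong module yields a two-point-leverage pattern whose Pearson
## correlation is near 1; rank correlation removes that leverage so the
## null honestly reflects "no reproducible connectivity pattern".
seven_stats <- function(ref_expr, test_expr, genes, cfg) {
  corR <- set_cor(ref_expr, genes, cfg)
  corT <- set_cor(test_expr, genes, cfg)
  ut <- upper.tri(corR)
  adjT <- if (cfg$network_type == "unsigned") abs(corT)^cfg$beta else
    ((1 + corT) / 2)^cfg$beta
  kimR <- rowSums(if (cfg$network_type == "unsigned") abs(corR)^cfg$beta else
    ((1 + corR) / 2)^cfg$beta) - 1
  kimT <- rowSums(adjT) - 1
  pcR <- set_pc_stats(ref_expr, genes)
  pcT <- set_pc_stats(test_expr, genes)
  c(meanCor = mean(corT[ut], na.rm = TRUE),
    meanAdj = mean(adjT[ut], na.rm = TRUE),
    pve = pcT$pve,
    meanKME = mean(abs(pcT$kme), na.rm = TRUE),
    cor.kIM = suppressWarnings(stats::cor(kimR, kimT, method = "spearman")),
    cor.kME = suppressWarnings(stats::cor(pcR$kme, pcT$kme, use = "complete.obs",
                                          method = "spearman")),
    cor.cor = suppressWarnings(stats::cor(corR[ut], corT[ut], use = "complete.obs",
                                          method = "spearman")))
}

#' Observed module preservation statistics
#'
#' Computes, per module, the seven preservation statistics comparing a
#' reference dataset (where the modules were defined) with a test dataset:
#' density in the test data (mean intramodule correlation, mean adjacency,
#' eigengene variance explained, mean |kME|) and connectivity-pattern
#' agreement between datasets (correlation of kIM, of kME, and of the
#' vectorized intramodule correlations). Statistics are computed on the gene
#' overlap of the two datasets; modules with less than `min_overlap_frac` of
#' their genes present in the test data (or fewer than 3 overlapping genes)
#' are skipped with a warning.
#'
#' @param ref_expr,test_expr expression matrices.
#' @param partition `cx_partition` from the reference dataset.
#' @param config a [network_config()].
#' @param min_overlap_frac minimum fraction of module genes that must be
#'   present in the test data.
#' @return matrix modules x 7 statistics; skipped modules are absent.
#' @export
preservation_stats <- function(ref_expr, test_expr, partition,
                               config = network_config(),
                               min_overlap_frac = 0.5) {
  labels <- part_labels(partition)
  mods <- sort(unique(labels[labels > 0L]))
  common <- intersect(rownames(ref_expr), rownames(test_expr))
  out <- list()
  for (q in mods) {
    genes <- names(labels)[labels == q]
    overlap <- intersect(genes, common)
    if (length(overlap) < 3L || length(overlap) < min_overlap_frac * length(genes)) {
      cx_warn("W_MODULE_SKIP",
              sprintf("module %d skipped: only %d/%d genes in test data",
                      q, length(overlap), length(genes)))
      next
    }
    out[[as.character(q)]] <- seven_stats(ref_expr, test_expr, overlap, config)
  }
  if (!length(out)) cx_stop("E_NO_MODULES", "no module has sufficient overlap")
  do.call(rbind, out)
}

#' Permutation test of module preservation
#'
#' For each module, the null distribution of the seven preservation
#' statistics is generated by drawing random gene sets of equal size
#' (without replacement) from the analyzed gene universe, one draw per
#' permutation shared across all seven statistics. Per statistic,
#' `Z = (obs - mean(null)) / sd(null)` and the one-sided permutation
#' p-value `p = (1 + #\{null >= obs\}) / (n_perm + 1)`. A module is called
#' significantly preserved when p < `alpha` for all seven statistics. The
#' composite `Zsummary` is the median of the density-statistic median
#' (s1-s4) and the connectivity-statistic median (s5-s7).
#'
#' @inheritParams preservation_stats
#' @param n_perm number of permutations (>= 20).
#' @param seed integer seed; the report is reproducible from it.
#' @param alpha per-statistic significance level for the preservation call.
#' @return list of class `cx_preservation`: `observed`, `z`, `p`,
#'   `zsummary`, `preserved` (logical per module), `n_perm`, `seed`,
#'   `module_sizes`.
#' @export
permutation_preservation <- function(ref_expr, test_expr, partition,
                                     config = network_config(), n_perm = 200L,
                                     seed = 1L, alpha = 0.05,
                                     min_overlap_frac = 0.5) {
  if (n_perm < 20L) cx_stop("E_NPERM", "n_perm must be >= 20")
  labels <- part_labels(partition)
  obs <- preservation_stats(ref_expr, test_expr, partition, config, min_overlap_frac)
  mods <- rownames(obs)
  common <- intersect(rownames(ref_expr), rownames(test_expr))
  universe <- common   # null sets are drawn from all analyzed genes
  sizes <- vapply(mods, function(q)
    length(intersect(names(labels)[labels == as.integer(q)], common)), integer(1))

  seeds <- derive_seeds(seed, length(mods))
  Zm <- Pm <- matrix(NA_real_, length(mods), ncol(obs),
                     dimnames = list(mods, colnames(obs)))
  zsum <- stats::setNames(numeric(length(mods)), mods)
  for (i in seq_along(mods)) {
    null <- with_seed(seeds[i], {
      t(vapply(seq_len(n_perm), function(p) {
        genes <- sample(universe, sizes[i])
        seven_stats(ref_expr, test_expr, genes, config)
      }, numeric(ncol(obs))))
    })
    mu <- colMeans(null, na.rm = TRUE)
    sdv <- apply(null, 2L, stats::sd, na.rm = TRUE)
    z <- (obs[i, ] - mu) / sdv
    z[!is.finite(z)] <- NA_real_
    if (any(sdv == 0, na.rm = TRUE)) {
      cx_warn("W_NULL_SD0", sprintf("module %s: degenerate null for %s; Z reported missing",
                                    mods[i], paste(colnames(obs)[sdv == 0], collapse = ",")))
    }
    p <- vapply(seq_len(ncol(obs)), function(j)
      (1 + sum(null[, j] >= obs[i, j], na.rm = TRUE)) / (n_perm + 1), numeric(1))
    Zm[i, ] <- z
    Pm[i, ] <- p
    zsum[i] <- stats::median(c(stats::median(z[1:4], na.rm = TRUE),
                               stats::median(z[5:7], na.rm = TRUE)))
  }
  structure(list(observed = obs, z = Zm, p = Pm, zsummary = zsum,
                 preserved = apply(Pm < alpha, 1L, all),
                 n_perm = as.integer(n_perm), seed = seed, alpha = alpha,
                 module_sizes = sizes),
            class = "cx_preservation")
}

#' @export
print.cx_preservation <- function(x, ...) {
  cat(sprintf("<cx_preservation> %d modules, %d permutations\n",
              nrow(x$observed), x$n_perm))
  cat(sprintf("preserved (all seven p < %.2f): %d/%d\n",
              x$alpha, sum(x$preserved), length(x$preserved)))
  invisible(x)
}
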