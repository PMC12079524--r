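## Hub statistics, module-trait correlation, partition agreement, and the
## tree-cut hyperparameter robustness sweep.

#' Per-gene module membership and connectivity statistics
#'
#' `kIM` is the intramodular connectivity (sum of adjacency to other members
#' of the gene's own module), `kME` the correlation of the gene with its own
#' module eigengene. Hub rank within a module orders by descending kIM, ties
#' by descending kME, then gene ID. Unassigned genes get `NA` statistics.
#'
#' @param expr expression matrix.
#' @param partition a `cx_partition`.
#' @param adj adjacency matrix over the same genes.
#' @param eigengenes a `cx_eigengenes` for the same partition (computed if
#'   missing).
#' @return data.frame (one row per gene): `gene_id`, `module`, `kIM`, `kME`,
#'   `hub_rank`.
#' @export
gene_module_stats <- function(expr, partition, adj, eigengenes = NULL) {
  labels <- part_labels(partition)
  genes <- names(labels)
  if (is.null(eigengenes)) eigengenes <- module_eigengenes(expr, partition)
  out <- data.frame(gene_id = genes, module = unname(labels),
                    kIM = NA_real_, kME = NA_real_, hub_rank = NA_integer_,
                    stringsAsFactors = FALSE)
  for (q in eigengenes$modules) {
    members <- genes[labels == q]
    idx <- match(members, genes)
    Aq <- adj[members, members, drop = FALSE]
    diag(Aq) <- 0
    kim <- rowSums(Aq)
    me <- eigengenes$me[, paste0("ME", q)]
    kme <- as.numeric(stats::cor(t(expr[members, , drop = FALSE]), me))
    ord <- order(-kim, -kme, members)
    rk <- integer(length(members)); rk[ord] <- seq_along(members)
    out$kIM[idx] <- kim
    out$kME[idx] <- kme
    out$hub_rank[idx] <- rk
  }
  out
}

#' Top hub genes of a module
#'
#' Returns the `k` top-ranked genes of a module by hub rank (kIM with kME
#' tie-break). If the module has fewer than `k` genes, all are returned with
#' a warning.
#'
#' @param stats data.frame from [gene_module_stats()].
#' @param module module label.
#' @param k number of hub genes (default 120).
#' @return character vector of gene IDs in hub-rank order.
#' @export
top_hub_genes <- function(stats, module, k = 120L) {
  sub <- stats[!is.na(stats$module) & stats$module == module & !is.na(stats$hub_rank), ]
  if (!nrow(sub)) cx_stop("E_NO_MODULE", sprintf("module %s not found", module))
  sub <- sub[order(sub$hub_rank), ]
  if (nrow(sub) < k) {
    cx_warn("W_FEW_HUBS", sprintf("module %s has only %d genes (< k = %d); returning all",
                                  module, nrow(sub), k))
    k <- nrow(sub)
  }
  sub$gene_id[seq_len(k)]
}

#' Module-trait correlations
#'
#' Pearson correlation (with asymptotic p) between each module eigengene and
#' each trait column over a stated sample subset. Categorical traits must be
#' numerically coded beforehand; constant traits give `NA` with a warning.
#'
#' @param eigengenes a `cx_eigengenes`.
#' @param traits trait data.frame (`sample_id` + numeric columns).
#' @param sample_subset optional character vector of sample IDs to use
#'   (default: all samples shared by eigengenes and traits).
#' @return list of class `cx_module_trait`: `r` and `p` (modules x traits),
#'   `n` (samples used), `samples`.
#' @export
module_trait_correlation <- function(eigengenes, traits, sample_subset = NULL) {
  samples <- intersect(rownames(eigengenes$me), traits$sample_id)
  if (!is.null(sample_subset)) samples <- intersect(samples, sample_subset)
  if (length(samples) < 4L) cx_stop("E_FEW_SAMPLES", "need >= 4 overlapping samples")
  me <- eigengenes$me[samples, , drop = FALSE]
  tr <- traits[match(samples, traits$sample_id), setdiff(colnames(traits), "sample_id"),
               drop = FALSE]
  num <- vapply(tr, is.numeric, logical(1))
  tr <- tr[, num, drop = FALSE]
  R <- matrix(NA_real_, ncol(me), ncol(tr), dimnames = list(colnames(me), colnames(tr)))
  P <- R
  for (j in seq_len(ncol(tr))) {
    y <- tr[[j]]
    if (length(unique(y[!is.na(y)])) < 2L) {
      cx_warn("W_CONSTANT_TRAIT", sprintf("trait '%s' is constant; correlation undefined",
                                          colnames(tr)[j]))
      next
    }
    r <- as.numeric(stats::cor(me, y, use = "pairwise.complete.obs"))
    nn <- colSums(!is.na(me) & !is.na(y))
    R[, j] <- r
    P[, j] <- cor_pvalue(r, nn)
  }
  structure(list(r = R, p = P, n = length(samples), samples = samples),
            class = "cx_module_trait")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement via the standard contingency-table formula.
#' Unassigned labels (0) are treated as their own class.
#'
#' @param a,b label vectors over the same elements (matched by names when
#'   both are named).
#' @return ARI in `[-1, 1]`; 1 means identical up to label permutation.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  if (length(a) != length(b)) cx_stop("E_ARI", "partitions must cover the same elements")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Tree-cut hyperparameter robustness sweep
#'
#' Runs the dynamic hybrid cut plus eigengene merging for every point of a
#' hyperparameter grid and reports module counts and sizes per point and the
#' pairwise adjusted Rand index between all resulting partitions (unassigned
#' treated as its own class) — the robustness summary for the module
#' structure.
#'
#' @param expr expression matrix (for eigengene merging).
#' @param dissim TOM dissimilarity matrix.
#' @param grid data.frame with columns `deep_split`, `min_module_size`,
#'   `merge_threshold`, `pam_stage` (see [default_sweep_grid()]).
#' @param tree optional precomputed [linkage_tree()] of `dissim`.
#' @param cut_height static cut fraction shared by all grid points.
#' @return list of class `cx_sweep`: `grid`, `labels` (matrix genes x
#'   points), `n_modules`, `sizes`, `ari` (pairwise matrix), `median_ari`.
#' @export
hyperparameter_sweep <- function(expr, dissim, grid = default_sweep_grid(),
                                 tree = NULL, cut_height = 0.99) {
  if (!nrow(grid)) cx_stop("E_GRID", "hyperparameter grid is empty")
  if (is.null(tree)) tree <- linkage_tree(dissim)
  labs <- matrix(NA_integer_, nrow(dissim), nrow(grid),
                 dimnames = list(rownames(dissim), NULL))
  n_modules <- integer(nrow(grid))
  sizes <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- cut_params(deep_split = grid$deep_split[i],
                    min_module_size = grid$min_module_size[i],
                    merge_threshold = grid$merge_threshold[i],
                    pam_stage = grid$pam_stage[i],
                    cut_height = cut_height)
    part <- cut_dynamic_hybrid(tree, dissim, p)
    if (part$n_modules > 1L) {
      part <- merge_close_modules(expr, part, p$merge_threshold)$partition
    }
    labs[, i] <- part$labels[rownames(dissim)]
    n_modules[i] <- part$n_modules
    sizes[[i]] <- part$sizes
  }
  np <- nrow(grid)
  ari <- diag(1, np)
  if (np > 1L) {
    for (i in seq_len(np - 1L)) {
      for (j in (i + 1L):np) {
        ari[i, j] <- ari[j, i] <- adjusted_rand_index(labs[, i], labs[, j])
      }
    }
  }
  structure(list(grid = grid, labels = labs, n_modules = n_modules,
                 sizes = sizes, ari = ari,
                 median_ari = stats::median(ari[upper.tri(ari)])),
            class = "cx_sweep")
}

#' Default hyperparameter sweep grid
#'
#' Deep split 1-3, minimum module size 20 and 30, merge threshold 0.15 and
#' 0.25, PAM stage on and off: 24 combinations spanning the tree-cut
#' hyperparameters whose robustness is being assessed.
#'
#' @return data.frame grid.
#' @export
default_sweep_grid <- function() {
  expand.grid(deep_split = 1:3,
              min_module_size = c(20L, 30L),
              merge_threshold = c(0.15, 0.25),
              pam_stage = c(TRUE, FALSE),
              KEEP.OUT.ATTRS = FALSE)
}
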