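## Module eigengenes: first principal component summaries of module
## expression, plus eigengene-based module merging.

#' Module eigengenes
#'
#' For each module, member gene rows are standardized (mean 0, sd 1 across
#' samples) and the module eigengene is the first right-singular-vector
#' score across samples, scaled to unit variance and sign-oriented so the
#' mean correlation with member genes is non-negative. The proportion of
#' member variance explained (`pve`) is the first squared singular value
#' over the total.
#'
#' @param expr expression matrix (genes x samples).
#' @param partition a `cx_partition` (or named integer label vector,
#'   0 = unassigned). Unassigned genes are ignored.
#' @return list of class `cx_eigengenes`: `me` (samples x modules matrix,
#'   columns `ME1..MEQ`), `pve` (named numeric), `modules` (labels),
#'   `dropped_genes` (constant genes excluded).
#' @export
module_eigengenes <- function(expr, partition) {
  labels <- part_labels(partition)
  labels <- labels[names(labels) %in% rownames(expr)]
  mods <- sort(unique(labels[labels > 0L]))
  if (!length(mods)) cx_stop("E_NO_MODULES", "partition has no modules")
  me <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), paste0("ME", mods)))
  pve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  dropped <- character(0)
  for (j in seq_along(mods)) {
    genes <- names(labels)[labels == mods[j]]
    X <- expr[genes, , drop = FALSE]
    sds <- apply(X, 1L, stats::sd)
    if (any(sds == 0 | is.na(sds))) {
      bad <- genes[sds == 0 | is.na(sds)]
      dropped <- c(dropped, bad)
      cx_warn("W_CONSTANT_IN_MODULE",
              sprintf("module %d: dropping %d constant gene(s) from its eigengene",
                      mods[j], length(bad)))
      X <- X[setdiff(genes, bad), , drop = FALSE]
    }
    if (nrow(X) < 2L) cx_stop("E_SMALL_MODULE",
                              sprintf("module %d has < 2 usable genes", mods[j]))
    Z <- t(scale(t(X)))                         # standardize gene rows
    sv <- svd(t(Z), nu = 1L, nv = 0L)           # samples x genes
    v <- sv$u[, 1L] * sv$d[1L]
    v <- v / stats::sd(v)                       # unit variance across samples
    if (mean(stats::cor(v, t(Z))) < 0) v <- -v  # orient toward members
    me[, j] <- v
    pve[j] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  structure(list(me = me, pve = pve, modules = mods, dropped_genes = dropped),
            class = "cx_eigengenes")
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity `1 - cor(ME_a, ME_b)` is below `merge_threshold`,
#' recomputing eigengenes after every merge, until no pair qualifies.
#' Modules are then relabeled by descending size.
#'
#' @param expr expression matrix.
#' @param partition a `cx_partition`.
#' @param merge_threshold eigengene dissimilarity threshold in (0, 1).
#' @return list: `partition` (relabeled `cx_partition`), `eigengenes`
#'   (recomputed for the final partition), `n_merges`.
#' @export
merge_close_modules <- function(expr, partition, merge_threshold = 0.15) {
  if (merge_threshold <= 0 || merge_threshold >= 1) {
    cx_stop("E_MERGE", "merge_threshold must be in (0,1)")
  }
  labels <- part_labels(partition)
  n_merges <- 0L
  repeat {
    mods <- sort(unique(labels[labels > 0L]))
    if (length(mods) < 2L) break
    eg <- module_eigengenes(expr, labels)
    d <- 1 - stats::cor(eg$me)
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)[1L, ]
    if (d[idx[1L], idx[2L]] >= merge_threshold) break
    a <- mods[min(idx)]; b <- mods[max(idx)]
    labels[labels == b] <- a
    n_merges <- n_merges + 1L
  }
  part <- finish_partition(labels, partition$params, partition$n_stage1_branches)
  list(partition = part,
       eigengenes = module_eigengenes(expr, part),
       n_merges = n_merges)
}
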