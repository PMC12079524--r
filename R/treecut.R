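## Dendrogram construction and adaptive (dynamic hybrid) tree cutting.

#' Average-linkage dendrogram from a dissimilarity matrix
#'
#' Standard agglomerative average linkage (UPGMA) on a symmetric
#' dissimilarity matrix with zero diagonal, via [stats::hclust()]. Ties in
#' the minimum pairwise dissimilarity are resolved deterministically by the
#' agglomeration order, so repeated runs on identical input give identical
#' trees.
#'
#' @param dissim symmetric dissimilarity matrix, zero diagonal, finite.
#' @return an `hclust` object.
#' @export
linkage_tree <- function(dissim) {
  if (!isSymmetric(unname(dissim))) cx_stop("E_DISSIM", "dissimilarity must be symmetric")
  if (any(!is.finite(dissim))) cx_stop("E_DISSIM", "non-finite dissimilarity")
  if (any(abs(diag(dissim)) > 1e-12)) cx_stop("E_DISSIM", "dissimilarity diagonal must be 0")
  stats::hclust(stats::as.dist(dissim), method = "average")
}

#' Tree-cut parameters
#'
#' @param deep_split split sensitivity, integer 0-4; larger values split the
#'   dendrogram more aggressively (see Details).
#' @param min_module_size smallest cluster kept as a module.
#' @param merge_threshold eigengene dissimilarity below which modules are
#'   merged, in (0, 1).
#' @param pam_stage if `TRUE`, unassigned genes are re-examined and joined to
#'   the nearest module when they are closer to it than to non-members and
#'   within the static cut height.
#' @param cut_height static cut as a fraction of the maximum merge height.
#'
#' @details
#' `deep_split` maps to a (core-scatter, gap) criterion pair; a candidate
#' branch only becomes its own module when its internal merge heights are
#' tight (scatter below the core-scatter limit) and it is well separated
#' from its sibling (normalized height gap above the gap limit). The five
#' constant pairs follow the dynamic-tree-cut convention:
#' core scatter limit 0.64, 0.73, 0.82, 0.91, 0.95 for `deep_split` 0-4 and
#' gap limit `(1 - core scatter limit) * 3/4`.
#'
#' @return list of class `cx_cut_params`.
#' @export
cut_params <- function(deep_split = 2L, min_module_size = 30L,
                       merge_threshold = 0.15, pam_stage = TRUE,
                       cut_height = 0.99) {
  if (!deep_split %in% 0:4) cx_stop("E_DS", "deep_split must be in 0..4")
  if (!is_count(min_module_size)) cx_stop("E_MINSIZE", "min_module_size must be a positive integer")
  if (merge_threshold <= 0 || merge_threshold >= 1) cx_stop("E_MERGE", "merge_threshold must be in (0,1)")
  if (cut_height <= 0 || cut_height > 1) cx_stop("E_CUTH", "cut_height must be in (0,1]")
  structure(list(deep_split = as.integer(deep_split),
                 min_module_size = as.integer(min_module_size),
                 merge_threshold = merge_threshold,
                 pam_stage = isTRUE(pam_stage),
                 cut_height = cut_height),
            class = "cx_cut_params")
}

## deep-split sensitivity constants (see ?cut_params)
DS_CORE_SCATTER <- c(0.64, 0.73, 0.82, 0.91, 0.95)
DS_MIN_GAP <- (1 - DS_CORE_SCATTER) * 3 / 4

## Ordered module color palette (assigned by descending module size; label 0
## is always "grey", the pseudo-module of unassigned genes).
MODULE_PALETTE <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                    "grey60", "lightgreen", "lightyellow", "royalblue",
                    "darkred", "darkgreen", "darkturquoise", "darkgrey",
                    "orange", "darkorange", "white", "skyblue", "saddlebrown",
                    "steelblue", "paleturquoise", "violet", "darkolivegreen",
                    "darkmagenta")

#' Module color names for numeric labels
#'
#' @param labels integer module labels, 0 = unassigned.
#' @return character vector of color names ("grey" for 0).
#' @export
module_colors <- function(labels) {
  cols <- c("grey", MODULE_PALETTE, paste0("module", seq_len(max(0, max(labels) - length(MODULE_PALETTE)))))
  cols[labels + 1L]
}

## Bottom-up node statistics for an hclust tree: subtree size, lowest
## internal merge height, parent links. Internal nodes are 1..n-1 (hclust
## merge rows), leaves are negative indices in merge.
tree_node_stats <- function(tree) {
  n <- length(tree$height) + 1L
  h <- tree$height
  size <- integer(n - 1L)
  hbase <- numeric(n - 1L)   # lowest internal merge height of the subtree
  parent <- integer(n - 1L)  # parent internal node, 0 = root
  leaf_attach <- numeric(n)  # height of the merge where each leaf enters
  for (i in seq_len(n - 1L)) {
    s <- 0L; hb <- h[i]
    for (child in tree$merge[i, ]) {
      if (child < 0) {
        s <- s + 1L
        leaf_attach[-child] <- h[i]
      } else {
        s <- s + size[child]
        hb <- min(hb, hbase[child])
        parent[child] <- i
      }
    }
    size[i] <- s; hbase[i] <- hb
  }
  list(n = n, h = h, size = size, hbase = hbase, parent = parent,
       leaf_attach = leaf_attach)
}

## Internal merge heights of the subtree rooted at internal node i.
node_internal_heights <- function(tree, i) {
  stack <- i
  out <- numeric(0)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, tree$height[nd])
    for (child in tree$merge[nd, ]) if (child > 0) stack <- c(stack, child)
  }
  out
}

## Leaves under internal node i (indices 1..n)
node_leaves <- function(tree, i) {
  stack <- i
  out <- integer(0)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (child in tree$merge[nd, ]) {
      if (child < 0) out <- c(out, -child) else stack <- c(stack, child)
    }
  }
  out
}

## Size of a branch's "core": the minimum module size plus the square root
## of the excess, following the dynamic-tree-cut convention. The core is the
## set of lowest merges, i.e. the tightest part of the branch; judging
## branches by their core makes the criteria robust to stragglers that
## attach near the top of a branch.
core_size <- function(branch_size, m) {
  min(branch_size, m + round(sqrt(max(branch_size - m, 0))))
}

#' Dynamic hybrid tree cut
#'
#' Two-stage adaptive cut of an average-linkage dendrogram built on
#' `1 - TOM` dissimilarities.
#'
#' Stage 1 cuts the tree at `hmin + cut_height * (hmax - hmin)` (a fraction
#' of the dendrogram height range) and recursively decomposes each branch
#' below the cut. Walking down a branch, singleton or sub-`min_module_size`
#' side-branches are peeled off; at the first merge whose two sides both
#' hold at least `min_module_size` leaves, the branch is split when both
#' sides look like module cores relative to the splitting height: the mean
#' height of a side's core merges must stay below the deep-split
#' core-scatter limit and the height gap between the split and the side's
#' core top must exceed the deep-split gap limit (both expressed as
#' fractions of the side's local height span). Splitting recurses into both
#' sides; genes peeled above an accepted split fall to the unassigned label
#' 0 ("grey"), as do branches smaller than `min_module_size`.
#'
#' Stage 2 (the PAM-like stage, when `pam_stage` is on) assigns each
#' unassigned gene to the module with the smallest average dissimilarity to
#' its members, provided that average is below the gene's average
#' dissimilarity to non-members, below the static cut height, and no larger
#' than the average intramodule dissimilarity of the module's loosest
#' member. The procedure is fully deterministic.
#'
#' @param tree `hclust` object from [linkage_tree()].
#' @param dissim the dissimilarity matrix the tree was built on.
#' @param params a [cut_params()] object.
#' @return list of class `cx_partition`: `labels` (named integer vector,
#'   0 = unassigned, 1..Q by descending size), `colors`, `sizes`,
#'   `n_modules`, `n_stage1_branches`, `params`.
#' @export
cut_dynamic_hybrid <- function(tree, dissim, params = cut_params()) {
  gene_ids <- tree$labels
  if (is.null(gene_ids)) gene_ids <- rownames(dissim)
  n <- length(tree$height) + 1L
  if (!is.null(rownames(dissim)) && !identical(rownames(dissim), gene_ids)) {
    dissim <- dissim[gene_ids, gene_ids]
  }
  m <- params$min_module_size
  if (m >= n) {
    cx_warn("W_ALL_GREY", "min_module_size >= number of genes; all genes unassigned")
    return(finish_partition(stats::setNames(integer(n), gene_ids), params, 0L))
  }
  st <- tree_node_stats(tree)
  max_scatter <- DS_CORE_SCATTER[params$deep_split + 1L]
  min_gap <- DS_MIN_GAP[params$deep_split + 1L]
  hmin <- min(st$h); hmax <- max(st$h)
  cut_h <- hmin + params$cut_height * (hmax - hmin)
  size_of <- function(node) if (node < 0) 1L else st$size[node]

  ## Is `child` an acceptable module core for a split at height h_split?
  ## Scatter: the child's core (lowest) merges must sit low within the local
  ## span. Gap: the split height must clear the top of the child's core by a
  ## clear fraction of the local span. Judging only the core makes both
  ## criteria robust to stragglers and trunk accretions that attach near the
  ## top of a branch; the price is that a structureless but tight branch
  ## whose merge heights carry metric jitter can occasionally be subdivided.
  core_ok <- function(child, h_split) {
    if (child < 0) return(FALSE)
    base <- st$hbase[child]
    span <- h_split - base
    if (span <= 0) return(FALSE)
    hs <- sort(node_internal_heights(tree, child))
    k <- max(1L, core_size(st$size[child], m) - 1L)
    core <- hs[seq_len(min(k, length(hs)))]
    scatter <- (mean(core) - base) / span
    gap <- (h_split - max(core)) / span
    scatter <= max_scatter && gap >= min_gap
  }

  ## recursive stage-1 decomposition of a branch rooted at `node`: walk down
  ## the trunk peeling sub-threshold side branches; split at the first merge
  ## where both sides are acceptable cores, else keep the branch whole.
  decompose <- function(node) {
    cur <- node
    while (cur > 0 && st$size[cur] >= 2L * m) {
      ch <- tree$merge[cur, ]
      big <- ch[which.max(c(size_of(ch[1L]), size_of(ch[2L])))]
      small <- setdiff(ch, big)[1L]
      if (size_of(small) >= m && core_ok(big, st$h[cur]) && core_ok(small, st$h[cur])) {
        return(c(decompose(big), decompose(small)))
      }
      if (size_of(big) < m) break
      cur <- big
    }
    list(node)   # no split found: the whole branch stays together
  }

  ## stage-1 roots: maximal internal nodes with height <= cut height
  roots <- which(st$h <= cut_h & (st$parent == 0L | st$h[pmax(st$parent, 1L)] > cut_h))
  clusters <- if (length(roots)) unlist(lapply(roots, decompose)) else integer(0)
  n_branches <- length(clusters)

  ## Trim each accepted branch by distance to its core. The core is the
  ## lowest-attaching core_size leaves; a leaf is kept when its average
  ## dissimilarity to the core stays clearly below background level --
  ## within three quarters of the span between the core members' median
  ## distance and the background (non-branch) median distance. Background
  ## genes accrete onto strong branches just below the static cut but
  ## remain much farther from the core than genuine members.
  trim_branch <- function(leaves) {
    k <- core_size(length(leaves), m)
    ord <- leaves[order(st$leaf_attach[leaves], leaves)]
    core <- ord[seq_len(k)]
    d_core <- rowMeans(dissim[, core, drop = FALSE])
    med_in <- stats::median(d_core[core])
    med_out <- stats::median(d_core[-leaves])
    thr <- med_in + 0.75 * (med_out - med_in)
    leaves[d_core[leaves] <= thr]
  }

  labels <- stats::setNames(integer(n), gene_ids)
  lab <- 0L
  for (node in clusters) {
    if (node < 0 || st$size[node] < m) next         # below minimum size
    keep <- trim_branch(node_leaves(tree, node))
    if (length(keep) < m) next
    lab <- lab + 1L
    labels[keep] <- lab
  }

  if (params$pam_stage && lab > 0L) {
    labels <- pam_assign(labels, dissim, cut_h)
  }
  finish_partition(labels, params, n_branches)
}

## Stage-2 PAM-like assignment of unassigned genes. A gene joins the module
## with the smallest average dissimilarity to its members, provided that
## average is (1) below the gene's average dissimilarity to non-members,
## (2) below the static cut height, and (3) not larger than the average
## intramodule dissimilarity of the module's loosest member -- the last
## guard keeps background genes, which sit only marginally closer to a
## strong module than to everything else, out of the modules.
pam_assign <- function(labels, dissim, max_dist) {
  mods <- sort(unique(labels[labels > 0L]))
  unass <- which(labels == 0L)
  if (!length(unass) || !length(mods)) return(labels)
  member <- sapply(mods, function(q) as.numeric(labels == q))  # n x Q
  sizes <- colSums(member)
  S <- dissim %*% member
  ## average dissimilarity from every gene to each module's members
  avg_mod <- S / matrix(sizes, nrow(dissim), length(mods), byrow = TRUE)
  ## loosest member per module: max average dissimilarity to co-members
  loosest <- vapply(seq_along(mods), function(j) {
    idx <- which(member[, j] == 1)
    max(S[idx, j] / (sizes[j] - 1L))
  }, numeric(1))
  tot <- rowSums(dissim)
  n <- nrow(dissim)
  new_labels <- labels
  for (g in unass) {
    q_idx <- which.min(avg_mod[g, ])
    d_mod <- avg_mod[g, q_idx]
    n_in <- sizes[q_idx]
    d_out <- (tot[g] - d_mod * n_in) / (n - 1L - n_in)   # excludes g itself (d_gg = 0)
    if (is.finite(d_out) && d_mod < d_out && d_mod <= max_dist &&
        d_mod <= loosest[q_idx]) {
      new_labels[g] <- mods[q_idx]
    }
  }
  new_labels
}

## Relabel modules 1..Q by descending size (ties by old label) and attach
## colors/sizes.
finish_partition <- function(labels, params, n_branches) {
  old <- sort(unique(labels[labels > 0L]))
  if (length(old)) {
    sz <- sapply(old, function(q) sum(labels == q))
    ord <- old[order(-sz, old)]
    remap <- stats::setNames(seq_along(ord), ord)
    labels[labels > 0L] <- remap[as.character(labels[labels > 0L])]
  }
  sizes <- if (length(old)) table(factor(labels[labels > 0L], levels = seq_along(old))) else table(integer(0))
  structure(list(labels = labels,
                 colors = stats::setNames(module_colors(labels), names(labels)),
                 sizes = as.integer(sizes),
                 n_modules = length(old),
                 n_stage1_branches = n_branches,
                 params = params),
            class = "cx_partition")
}

#' @export
print.cx_partition <- function(x, ...) {
  cat(sprintf("<cx_partition> %d modules over %d genes (%d unassigned)\n",
              x$n_modules, length(x$labels), sum(x$labels == 0L)))
  if (x$n_modules > 0) {
    cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  }
  invisible(x)
}
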