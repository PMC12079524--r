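## Differential co-expression between two conditions: does a module's
## correlation structure change between case and control samples?

module_diff_stat <- function(expr_a, expr_b, genes, method) {
  ca <- suppressWarnings(stats::cor(t(expr_a[genes, , drop = FALSE]),
                                    method = if (method == "spearman") "spearman" else "pearson"))
  cb <- suppressWarnings(stats::cor(t(expr_b[genes, , drop = FALSE]),
                                    method = if (method == "spearman") "spearman" else "pearson"))
  ca[is.na(ca)] <- 0; cb[is.na(cb)] <- 0
  d <- abs(ca - cb)
  diag(d) <- NA
  list(D = mean(d[upper.tri(d)]), d_gene = rowMeans(d, na.rm = TRUE))
}

#' Differential co-expression between two conditions
#'
#' For each module, the statistic `D = mean |cor_A(ij) - cor_B(ij)|` over
#' member pairs compares the intramodule correlation structure between the
#' two condition groups; per-gene statistics `d_i` average over each gene's
#' partners. Significance is assessed by condition-label permutation
#' (within-pair label swaps when pair IDs are supplied, respecting the
#' paired design), with `p = (1 + #\{null >= obs\}) / (n_perm + 1)`. A module
#' is called preserved across conditions when its p-value exceeds `alpha`.
#'
#' @param expr expression matrix.
#' @param traits trait table with `sample_id`, a binary `condition` column
#'   (0/1) and, for paired designs, a `pair` column.
#' @param partition `cx_partition` (or label vector).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param paired permute within pairs (requires a complete `pair` column).
#' @param method `"pearson"` or `"spearman"` for the condition-wise
#'   correlations.
#' @param alpha level for the "preserved across conditions" call.
#' @return list of class `cx_diffcoex`: `D` (per module), `p` (per module),
#'   `preserved`, `gene` (data.frame gene_id, module, d, p), `n_perm`,
#'   `seed`.
#' @export
diff_coexpression <- function(expr, traits, partition, n_perm = 200L, seed = 1L,
                              paired = TRUE, method = c("pearson", "spearman"),
                              alpha = 0.05) {
  method <- match.arg(method)
  labels <- part_labels(partition)
  samples <- intersect(colnames(expr), traits$sample_id)
  tr <- traits[match(samples, traits$sample_id), ]
  cond <- tr$condition
  if (!all(cond %in% c(0, 1))) cx_stop("E_CONDITION", "condition must be coded 0/1")
  if (sum(cond == 0) < 4L || sum(cond == 1) < 4L) {
    cx_stop("E_FEW_SAMPLES", "each condition needs >= 4 samples")
  }
  if (paired) {
    if (!"pair" %in% colnames(tr) || anyNA(tr$pair)) {
      cx_stop("E_UNPAIRED", "paired permutation requested but pair IDs are missing")
    }
    pair <- tr$pair
    if (!all(table(pair) == 2L)) cx_stop("E_UNPAIRED", "each pair must have exactly 2 samples")
  }
  expr <- expr[, samples, drop = FALSE]
  mods <- sort(unique(labels[labels > 0L]))
  mods <- mods[vapply(mods, function(q)
    sum(names(labels)[labels == q] %in% rownames(expr)) >= 3L, logical(1))]
  if (!length(mods)) cx_stop("E_NO_MODULES", "no module with >= 3 genes in the data")

  split_stat <- function(cvec) {
    a <- samples[cvec == 1]; b <- samples[cvec == 0]
    lapply(mods, function(q) {
      genes <- intersect(names(labels)[labels == q], rownames(expr))
      module_diff_stat(expr[, a, drop = FALSE], expr[, b, drop = FALSE], genes, method)
    })
  }

  obs <- split_stat(cond)
  D_obs <- vapply(obs, `[[`, numeric(1), "D")
  d_obs <- lapply(obs, `[[`, "d_gene")

  exceed_D <- numeric(length(mods))
  exceed_d <- lapply(d_obs, function(v) numeric(length(v)))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      cperm <- if (paired) {
        flip <- stats::setNames(sample(c(TRUE, FALSE), length(unique(pair)),
                                       replace = TRUE), unique(pair))
        ifelse(flip[pair], 1 - cond, cond)
      } else {
        sample(cond)
      }
      null <- split_stat(cperm)
      for (i in seq_along(mods)) {
        exceed_D[i] <- exceed_D[i] + (null[[i]]$D >= D_obs[i])
        exceed_d[[i]] <- exceed_d[[i]] + (null[[i]]$d_gene >= d_obs[[i]])
      }
    }
  })
  p_D <- (1 + exceed_D) / (n_perm + 1)
  gene_tab <- do.call(rbind, lapply(seq_along(mods), function(i) {
    genes <- intersect(names(labels)[labels == mods[i]], rownames(expr))
    data.frame(gene_id = genes, module = mods[i], d = d_obs[[i]],
               p = (1 + exceed_d[[i]]) / (n_perm + 1),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(D = stats::setNames(D_obs, mods),
                 p = stats::setNames(p_D, mods),
                 preserved = stats::setNames(p_D > alpha, mods),
                 gene = gene_tab, n_perm = as.integer(n_perm), seed = seed,
                 alpha = alpha),
            class = "cx_diffcoex")
}

#' @export
print.cx_diffcoex <- function(x, ...) {
  cat(sprintf("<cx_diffcoex> %d modules, %d permutations; preserved across conditions: %d/%d\n",
              length(x$D), x$n_perm, sum(x$preserved), length(x$preserved)))
  invisible(x)
}
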