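## Soft-threshold adjacency, scale-free topology fit and topological overlap.

#' Network configuration
#'
#' Bundles the parameters that define the weighted network: soft-threshold
#' power `beta` (default 8, the value at which the connectivity distribution
#' approximates scale-free topology on the motivating data), network type
#' (unsigned: `a = |r|^beta`; signed: `a = ((1 + r)/2)^beta`), correlation
#' method and the minimum pairwise-complete observations.
#'
#' @param beta positive integer soft-threshold power.
#' @param network_type `"unsigned"` or `"signed"`.
#' @param method correlation method passed to [correlation_matrix()].
#' @param min_pairs minimum pairwise-complete observations, >= 3.
#' @return list of class `cx_network_config`.
#' @export
network_config <- function(beta = 8L, network_type = c("unsigned", "signed"),
                           method = c("bicor", "pearson", "spearman"),
                           min_pairs = 5L) {
  network_type <- match.arg(network_type)
  method <- match.arg(method)
  if (!is_count(beta)) cx_stop("E_BETA", "beta must be a positive integer")
  if (min_pairs < 3L) cx_stop("E_MIN_PAIRS", "min_pairs must be >= 3")
  structure(list(beta = as.integer(beta), network_type = network_type,
                 method = method, min_pairs = as.integer(min_pairs)),
            class = "cx_network_config")
}

#' Soft-threshold adjacency from a correlation matrix
#'
#' Unsigned: `a_ij = |r_ij|^beta`; signed: `a_ij = ((1 + r_ij)/2)^beta`.
#' Missing correlations give adjacency 0 (counted). The diagonal is set to 0
#' so that row sums are the connectivity `k_i`.
#'
#' @param cor a `cx_correlation` object or a symmetric correlation matrix.
#' @param config a [network_config()].
#' @return symmetric adjacency matrix with zero diagonal; `attr(, "k")` holds
#'   connectivity, `attr(, "n_missing")` the count of missing correlations
#'   mapped to 0.
#' @export
adjacency_matrix <- function(cor, config = network_config()) {
  R <- if (inherits(cor, "cx_correlation")) cor$cor else cor
  n_missing <- sum(is.na(R))
  if (n_missing > 0L) {
    cx_log("info", "I_MISSING_COR",
           sprintf("%d missing correlation(s) mapped to adjacency 0", n_missing))
    R[is.na(R)] <- 0
  }
  A <- if (config$network_type == "unsigned") {
    abs(R)^config$beta
  } else {
    ((1 + R) / 2)^config$beta
  }
  diag(A) <- 0
  attr(A, "k") <- rowSums(A)
  attr(A, "n_missing") <- n_missing
  A
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins connectivities into `n_bins` equal-width bins and regresses
#' `log10(mean frequency)` on `log10(mean connectivity)` over non-empty bins.
#' The fit index is the coefficient of determination, flagged invalid when
#' the regression slope is non-negative (a scale-free degree distribution
#' must decay).
#'
#' @param k numeric vector of connectivities.
#' @param n_bins number of equal-width bins (default 10).
#' @return list: `fit` (R^2 in `[0,1]`), `slope`, `valid`, `mean_k`,
#'   `median_k`, `max_k`, `n_bins_used`.
#' @export
scale_free_index <- function(k, n_bins = 10L) {
  k <- k[is.finite(k)]
  out <- list(fit = NA_real_, slope = NA_real_, valid = FALSE,
              mean_k = mean(k), median_k = stats::median(k), max_k = max(k),
              n_bins_used = 0L)
  if (length(unique(k)) < 2L) {
    cx_warn("W_SF_DEGENERATE", "all connectivities identical; scale-free fit undefined")
    return(out)
  }
  if (length(unique(k)) < n_bins) {
    cx_warn("W_SF_FEW", "fewer distinct connectivities than bins; bins collapsed")
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  mean_k_bin <- tapply(k, bin, mean)
  freq_bin <- tapply(k, bin, length) / length(k)
  keep <- !is.na(mean_k_bin) & !is.na(freq_bin) & mean_k_bin > 0 & freq_bin > 0
  if (sum(keep) < 3L) {
    cx_warn("W_SF_DEGENERATE", "too few usable bins for a scale-free fit")
    return(out)
  }
  lx <- log10(mean_k_bin[keep])
  ly <- log10(freq_bin[keep])
  fit <- stats::lm(ly ~ lx)
  ## summary.lm warns on an exactly linear profile; a perfect fit is valid here
  out$fit <- suppressWarnings(summary(fit)$r.squared)
  out$slope <- unname(stats::coef(fit)[2L])
  out$valid <- is.finite(out$slope) && out$slope < 0
  out$n_bins_used <- sum(keep)
  out
}

#' Scale-free topology fit of an adjacency matrix
#'
#' @param adj adjacency matrix (see [adjacency_matrix()]).
#' @param n_bins number of connectivity bins.
#' @return see [scale_free_index()].
#' @export
scale_free_fit <- function(adj, n_bins = 10L) {
  k <- rowSums(adj) - diag(adj)
  scale_free_index(k, n_bins = n_bins)
}

#' Choose the soft-threshold power
#'
#' Evaluates the scale-free fit for each candidate power and returns the
#' smallest power whose valid fit reaches `target` (default R^2 = 0.8). If no
#' candidate reaches the target, the power with the best valid fit is
#' returned with a warning.
#'
#' @param cor a `cx_correlation` object or correlation matrix.
#' @param betas ascending vector of candidate powers.
#' @param config a [network_config()] (its `beta` is ignored).
#' @param target scale-free R^2 threshold.
#' @param n_bins connectivity bins for the fit.
#' @return list: `beta` (chosen power), `reached_target`, `table`
#'   (data.frame: beta, fit, slope, valid, mean_k, median_k, max_k).
#' @export
pick_soft_threshold <- function(cor, betas = c(1:10, 12, 14, 16, 18, 20),
                                config = network_config(), target = 0.8,
                                n_bins = 10L) {
  if (!length(betas)) cx_stop("E_BETAS", "candidate beta list is empty")
  if (is.unsorted(betas, strictly = TRUE)) cx_stop("E_BETAS", "betas must be ascending")
  rows <- lapply(betas, function(b) {
    cfg <- config
    cfg$beta <- as.integer(b)
    A <- adjacency_matrix(cor, cfg)
    f <- suppressWarnings(scale_free_fit(A, n_bins = n_bins))
    data.frame(beta = b, fit = f$fit, slope = f$slope, valid = f$valid,
               mean_k = f$mean_k, median_k = f$median_k, max_k = f$max_k)
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$valid & !is.na(tab$fit) & tab$fit >= target)
  if (length(ok)) {
    chosen <- tab$beta[ok[1L]]
    reached <- TRUE
  } else {
    vld <- which(tab$valid & !is.na(tab$fit))
    if (!length(vld)) vld <- which(!is.na(tab$fit))
    chosen <- tab$beta[vld[which.max(tab$fit[vld])]]
    reached <- FALSE
    cx_warn("W_SF_TARGET",
            sprintf("no power reached scale-free R^2 >= %.2f; using beta = %d (best fit)",
                    target, chosen))
  }
  list(beta = as.integer(chosen), reached_target = reached, table = tab)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` (u != i, j), `TOM_ii = 1`. Pairs with a zero
#' denominator (isolated pair) get TOM 0 by convention. The clustering
#' dissimilarity is `1 - TOM`.
#'
#' @param adj adjacency matrix with entries in `[0, 1]` (diagonal ignored).
#' @return list of class `cx_tom`: `tom` (similarity, unit diagonal) and
#'   `dissim` (`1 - tom`).
#' @export
tom_similarity <- function(adj) {
  A <- adj
  if (any(A < 0 | A > 1, na.rm = TRUE)) cx_stop("E_ADJ_RANGE", "adjacency entries must be in [0, 1]")
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A                       # diag(A)=0 makes this sum over u != i, j
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - A
  TOM <- (L + A) / denom
  zero <- denom <= 0
  if (any(zero)) {
    cx_log("info", "I_TOM_ISOLATED",
           sprintf("%d pair(s) with zero TOM denominator set to 0", sum(zero) / 2))
    TOM[zero] <- 0
  }
  TOM[TOM > 1] <- 1
  TOM[TOM < 0] <- 0
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(adj)
  structure(list(tom = TOM, dissim = 1 - TOM), class = "cx_tom")
}
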