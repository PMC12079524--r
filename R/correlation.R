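## Robust correlation for network construction.
##
## Biweight midcorrelation (bicor) follows the canonical definition:
##   u_i = (x_i - med(x)) / (9 * mad(x)),  with raw MAD (no 1.4826 consistency
##   constant -- the 9*mad denominator of the Tukey biweight uses the
##   unscaled median absolute deviation),
##   w_i = (1 - u_i^2)^2 * 1[|u_i| < 1],
##   x~_i = (x_i - med(x)) * w_i,
##   bicor(x, y) = sum(x~ y~) / sqrt(sum(x~^2) sum(y~^2)).
## Vectors with zero MAD cannot be weighted and fall back to Pearson-style
## mean centering with unit weights for that vector.

bicor_prepare <- function(x) {
  m <- stats::median(x)
  s <- stats::median(abs(x - m))          # raw MAD, no consistency constant
  if (s == 0) {
    mu <- mean(x)
    sdv <- stats::sd(x)
    if (is.na(sdv) || sdv == 0) return(NULL)   # constant vector
    d <- x - mu
  } else {
    u <- (x - m) / (9 * s)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    d <- (x - m) * w
  }
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) return(NULL)
  list(d = d, zero_mad = s == 0)
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation using Tukey biweights around the median, the
#' correlation measure used to define the co-expression network. Zero-MAD
#' vectors fall back to mean centering (Pearson behaviour) for that vector.
#'
#' @param x,y numeric vectors of equal length; pairs with missing values are
#'   dropped (pairwise-complete).
#' @return correlation in `[-1, 1]`; `NA` for constant input.
#' @export
bicor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  px <- bicor_prepare(x)
  py <- bicor_prepare(y)
  if (is.null(px) || is.null(py)) return(NA_real_)
  r <- sum(px$d * py$d) / (sqrt(sum(px$d^2)) * sqrt(sum(py$d^2)))
  max(-1, min(1, r))
}

cor_pvalue <- function(r, n) {
  ## two-sided p from the asymptotic t distribution of a correlation
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n > 2
  t_stat <- r[ok] * sqrt((n[ok] - 2) / pmax(1 - r[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(abs(t_stat), df = n[ok] - 2, lower.tail = FALSE)
  p <- pmin(p, 1)
  if (is.matrix(r)) dim(p) <- dim(r)
  p
}

#' Gene-gene correlation matrix
#'
#' Computes the symmetric correlation matrix between all gene rows of an
#' expression matrix, by biweight midcorrelation (default), Pearson, or
#' Spearman, with two-sided p-values from the asymptotic t distribution.
#' With missing data, correlations use pairwise-complete observations and
#' pairs with fewer than `min_pairs` complete observations are set to `NA`.
#'
#' @param expr expression matrix (genes x samples).
#' @param method `"bicor"`, `"pearson"` or `"spearman"`.
#' @param min_pairs minimum pairwise-complete observations, >= 3.
#' @return list of class `cx_correlation`: `cor` (symmetric, unit diagonal),
#'   `p` (two-sided p-values), `n` (pair counts), `method`,
#'   `n_insufficient` (pairs below `min_pairs`), `zero_mad_genes`.
#' @export
correlation_matrix <- function(expr, method = c("bicor", "pearson", "spearman"),
                               min_pairs = 5L) {
  method <- match.arg(method)
  if (min_pairs < 3L) cx_stop("E_MIN_PAIRS", "min_pairs must be >= 3")
  g <- rownames(expr)
  ns <- ncol(expr)
  zero_mad <- character(0)
  n_insufficient <- 0L

  if (!anyNA(expr)) {
    if (method == "bicor") {
      D <- matrix(0, nrow(expr), ns)
      const <- logical(nrow(expr))
      for (i in seq_len(nrow(expr))) {
        p <- bicor_prepare(expr[i, ])
        if (is.null(p)) { const[i] <- TRUE; next }
        if (p$zero_mad) zero_mad <- c(zero_mad, g[i])
        D[i, ] <- p$d / sqrt(sum(p$d^2))
      }
      R <- tcrossprod(D)
      R[R > 1] <- 1; R[R < -1] <- -1
      if (any(const)) {
        cx_warn("W_CONSTANT_GENE", sprintf("%d constant gene(s): correlation set to 0",
                                           sum(const)))
        R[const, ] <- 0; R[, const] <- 0
      }
      diag(R) <- 1
    } else {
      X <- if (method == "spearman") t(apply(expr, 1L, rank)) else expr
      sds <- apply(X, 1L, stats::sd)
      const <- is.na(sds) | sds == 0
      R <- suppressWarnings(stats::cor(t(X), method = "pearson"))
      if (any(const)) {
        cx_warn("W_CONSTANT_GENE", sprintf("%d constant gene(s): correlation set to 0",
                                           sum(const)))
        R[const, ] <- 0; R[, const] <- 0
      }
      R[is.na(R)] <- 0
      diag(R) <- 1
    }
    N <- matrix(ns, nrow(expr), nrow(expr))
    if (length(zero_mad)) {
      cx_log("info", "I_ZERO_MAD",
             sprintf("%d gene(s) with zero MAD fell back to mean centering",
                     length(zero_mad)))
    }
  } else {
    ## pairwise-complete path (small inputs; the loader drops very sparse rows)
    ng <- nrow(expr)
    R <- diag(1, ng)
    N <- matrix(ns, ng, ng)
    fun <- switch(method,
                  bicor = bicor,
                  pearson = function(x, y) {
                    ok <- stats::complete.cases(x, y)
                    if (sum(ok) < 3L) return(NA_real_)
                    suppressWarnings(stats::cor(x[ok], y[ok]))
                  },
                  spearman = function(x, y) {
                    ok <- stats::complete.cases(x, y)
                    if (sum(ok) < 3L) return(NA_real_)
                    suppressWarnings(stats::cor(x[ok], y[ok], method = "spearman"))
                  })
    for (i in seq_len(ng - 1L)) {
      for (j in (i + 1L):ng) {
        npair <- sum(stats::complete.cases(expr[i, ], expr[j, ]))
        N[i, j] <- N[j, i] <- npair
        if (npair < min_pairs) {
          n_insufficient <- n_insufficient + 1L
          R[i, j] <- R[j, i] <- NA_real_
          next
        }
        r <- fun(expr[i, ], expr[j, ])
        if (is.na(r)) r <- 0     # constant pair: correlation undefined
        R[i, j] <- R[j, i] <- r
      }
    }
    if (n_insufficient > 0L) {
      cx_warn("W_MIN_PAIRS",
              sprintf("%d gene pair(s) below min_pairs set to NA", n_insufficient))
    }
  }
  dimnames(R) <- list(g, g)
  P <- cor_pvalue(R, N)
  diag(P) <- NA_real_
  dimnames(P) <- dimnames(R)
  structure(list(cor = R, p = P, n = N, method = method,
                 n_insufficient = n_insufficient, zero_mad_genes = zero_mad),
            class = "cx_correlation")
}

#' @export
print.cx_correlation <- function(x, ...) {
  cat(sprintf("<cx_correlation> %d genes, method = %s\n", nrow(x$cor), x$method))
  invisible(x)
}
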