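## Factor-model synthetic expression generator with planted co-expression
## modules, a planted driver gene, and a planted candidate hub gene. Every
## planted quantity maps to a closed-form population target: member genes
## correlate sqrt(rho) with their module eigengene, the driver correlates
## c_q with the eigengene of module q, and the candidate's condition effect
## is an additive log2 shift.

#' Specification of a synthetic expression study
#'
#' Defaults emulate a scaled-down paired two-condition atherosclerosis
#' cohort: 2000 genes (5 modules of 200/100/80/60/40 members plus pure-noise
#' background, a driver gene, a candidate gene), 40 samples in 20
#' case/control pairs, a driver correlated +0.90 / -0.70 / +0.66 with the
#' eigengenes of modules 1-3, and a candidate hub in the anti-correlated
#' module 2 upregulated by 0.5 log2 units in the case condition.
#' Heavy-tailed contamination (the rationale for robust correlation) is off
#' by default; the documented outlier plan for robustness studies is 1% of
#' cells at 6 SD (see [inject_outliers()]).
#'
#' @param n_samples total number of samples (must be even when `paired`).
#' @param module_sizes integer vector of planted module sizes.
#' @param rho per-module mean signal share in `[0, 1]`; member gene `i`
#'   correlates `sqrt(rho_i)` with the module eigengene.
#' @param rho_spread within-module half-range of the signal share: member
#'   shares are evenly spaced over `rho +/- rho_spread`, giving each module
#'   a hub-to-periphery connectivity gradient as in real co-expression
#'   modules (the first member IDs are the hubs).
#' @param n_genes total gene count (background size is derived).
#' @param driver_plan data.frame with columns `module` and `cor`: target
#'   driver-eigengene correlations.
#' @param eigengene_structure `"coupled"` (default): eigengenes receive the
#'   smallest mutual correlations (`cor(e_q, e_r) = t c_q c_r` with minimal
#'   `t >= 0`) that make the joint driver-eigengene covariance positive
#'   semi-definite, so any plan with `|c_q| <= 1` is realizable while
#'   modules stay as uncorrelated as the plan permits (driver-associated
#'   modules in real plaque data are likewise inter-correlated); when
#'   `sum(c^2) <= 1` this reduces to exactly independent eigengenes.
#'   `"independent"` forces `t = 0` and errors when `sum(c^2) > 1`
#'   (unrealizable plan).
#' @param candidate_module module hosting the planted candidate.
#' @param candidate_rho candidate signal share (its hub strength).
#' @param candidate_driver_cor planted correlation between the candidate and
#'   the driver gene; must be jointly realizable with `candidate_rho` and
#'   the host module's driver loading (checked before sampling).
#' @param candidate_delta additive case-condition shift (log2 units) applied
#'   to the candidate.
#' @param paired paired two-condition design (case/control per pair).
#' @param pair_effect_sd standard deviation of the per-gene, per-pair shared
#'   random effect, folded inside the unit residual variance so population
#'   gene-eigengene correlations stay exactly `sqrt(rho)`.
#' @param outlier_fraction fraction of matrix cells replaced by outliers.
#' @param outlier_magnitude outlier magnitude in per-gene SD units.
#' @return list of class `cx_synth_spec`.
#' @export
synthetic_spec <- function(n_samples = 40L,
                           module_sizes = c(200L, 100L, 80L, 60L, 40L),
                           rho = seq(0.725, 0.575, length.out = 5),
                           rho_spread = 0.075,
                           n_genes = 2000L,
                           driver_plan = data.frame(module = 1:3,
                                                    cor = c(0.90, -0.70, 0.66)),
                           eigengene_structure = c("coupled", "independent"),
                           candidate_module = 2L,
                           candidate_rho = 0.9,
                           candidate_driver_cor = -0.75,
                           candidate_delta = 0.5,
                           paired = TRUE,
                           pair_effect_sd = 0.3,
                           outlier_fraction = 0,
                           outlier_magnitude = 6) {
  eigengene_structure <- match.arg(eigengene_structure)
  if (length(rho) != length(module_sizes)) {
    cx_stop("E_SPEC", "rho must have one entry per module")
  }
  if (any(rho - rho_spread < 0 | rho + rho_spread > 1)) {
    cx_stop("E_SPEC", "rho +/- rho_spread must stay in [0, 1]")
  }
  if (any(abs(driver_plan$cor) > 1)) cx_stop("E_SPEC", "driver correlations must be in [-1, 1]")
  if (eigengene_structure == "independent" && sum(driver_plan$cor^2) > 1) {
    cx_stop("E_DRIVER_PLAN",
            "unrealizable driver plan: sum of squared loadings exceeds 1 for independent eigengenes")
  }
  if (paired && n_samples %% 2L != 0L) cx_stop("E_SPEC", "paired design needs an even n_samples")
  n_special <- 2L  # driver + candidate
  n_background <- n_genes - sum(module_sizes) - n_special
  if (n_background < 0L) cx_stop("E_SPEC", "n_genes too small for the requested modules")
  if (!candidate_module %in% seq_along(module_sizes)) {
    cx_stop("E_SPEC", "candidate_module out of range")
  }
  if (candidate_rho < 0 || candidate_rho > 1) cx_stop("E_SPEC", "candidate_rho must be in [0, 1]")
  ## realizability of (driver, host eigengene, candidate) correlations
  c_host <- driver_plan$cor[match(candidate_module, driver_plan$module)]
  if (is.na(c_host)) c_host <- 0
  bound <- sqrt(pmax(0, (1 - c_host^2) * (1 - candidate_rho)))
  lo <- c_host * sqrt(candidate_rho) - bound
  hi <- c_host * sqrt(candidate_rho) + bound
  if (candidate_driver_cor < lo - 1e-12 || candidate_driver_cor > hi + 1e-12) {
    cx_stop("E_CAND_PLAN",
            sprintf("candidate_driver_cor must lie in [%.3f, %.3f] for this plan", lo, hi))
  }
  structure(list(n_samples = as.integer(n_samples), module_sizes = as.integer(module_sizes),
                 rho = rho, rho_spread = rho_spread,
                 n_genes = as.integer(n_genes), n_background = as.integer(n_background),
                 driver_plan = driver_plan, eigengene_structure = eigengene_structure,
                 candidate_module = as.integer(candidate_module),
                 candidate_rho = candidate_rho,
                 candidate_driver_cor = candidate_driver_cor,
                 candidate_delta = candidate_delta,
                 paired = isTRUE(paired), pair_effect_sd = pair_effect_sd,
                 outlier_fraction = outlier_fraction, outlier_magnitude = outlier_magnitude),
            class = "cx_synth_spec")
}

## Smallest eigengene coupling t such that the joint covariance of
## (driver z, e_1..e_Q) with cor(z, e_q) = c_q and cor(e_q, e_r) = t c_q c_r
## is positive semi-definite: (1 - t) * sum(c^2 / (1 - t c^2)) <= 1.
## t = 0 (independent eigengenes) works exactly when sum(c^2) <= 1.
min_coupling <- function(c_q) {
  cc <- c_q[c_q != 0]
  if (!length(cc) || sum(cc^2) <= 1) return(0)
  f <- function(t) (1 - t) * sum(cc^2 / (1 - t * cc^2)) - 1
  stats::uniroot(f, c(0, 1 - 1e-9), tol = 1e-12)$root
}

## Draw (driver z, eigengenes E) from the coupled Gaussian model.
draw_latents <- function(ns, c_q, t_couple) {
  Q <- length(c_q)
  S <- diag(1, Q + 1L)
  S[1L, -1L] <- S[-1L, 1L] <- c_q
  off <- t_couple * tcrossprod(c_q)
  diag(off) <- 1
  S[-1L, -1L] <- off
  ## guard tiny negative eigenvalues from the PSD boundary
  ev <- eigen(S, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  X <- matrix(stats::rnorm(ns * (Q + 1L)), ns) %*% L
  list(z = X[, 1L], E = X[, -1L, drop = FALSE])
}

## residual with per-pair shared component, standardized to unit variance so
## that cor(gene, eigengene) = sqrt(rho) holds exactly in population
synth_residual <- function(n_genes, n_samples, paired, tau, pair_id) {
  eps <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  if (paired && tau > 0) {
    n_pairs <- n_samples / 2L
    b <- matrix(stats::rnorm(n_genes * n_pairs), n_genes, n_pairs)
    eps <- (tau * b[, pair_id, drop = FALSE] + eps) / sqrt(1 + tau^2)
  }
  eps
}

#' Simulate a synthetic expression dataset
#'
#' Draws module eigengenes, member genes `x_i = sqrt(rho) e_q +
#' sqrt(1 - rho) eps_i`, pure-noise background genes, the planted driver and
#' candidate, applies the paired-condition shift and outlier contamination,
#' and returns the expression matrix together with the trait table and the
#' generating truth. Fully deterministic given the seed.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return list of class `cx_synth_data`: `expr` (genes x samples, log2
#'   scale), `traits` (`sample_id`, `condition` 0/1, `pair`, `driver`),
#'   `truth` (labels, driver/candidate IDs, eigengenes, planted parameters,
#'   outlier positions).
#' @export
simulate_dataset <- function(spec, seed = 1L) {
  with_seed(seed, {
    ns <- spec$n_samples
    Q <- length(spec$module_sizes)
    pair_id <- if (spec$paired) rep(seq_len(ns / 2L), each = 2L) else rep(NA_integer_, ns)
    condition <- if (spec$paired) rep(c(1L, 0L), ns / 2L) else
      rep(c(1L, 0L), length.out = ns)

    ## latent structure: driver + eigengenes from the coupled Gaussian model
    c_q <- stats::setNames(rep(0, Q), seq_len(Q))
    c_q[as.character(spec$driver_plan$module)] <- spec$driver_plan$cor
    t_couple <- if (spec$eigengene_structure == "independent") 0 else min_coupling(c_q)
    lat <- draw_latents(ns, unname(c_q), t_couple)
    E <- lat$E
    driver_expr <- lat$z

    ## member genes: per-gene signal shares evenly spaced, hubs first
    gene_rows <- list(); gene_ids <- character(0); labels <- integer(0)
    rho_gene <- list()
    for (q in seq_len(Q)) {
      sz <- spec$module_sizes[q]
      ids <- sprintf("M%d_G%03d", q, seq_len(sz))
      rho_i <- seq(spec$rho[q] + spec$rho_spread, spec$rho[q] - spec$rho_spread,
                   length.out = sz)
      eps <- synth_residual(sz, ns, spec$paired, spec$pair_effect_sd, pair_id)
      X <- sqrt(rho_i) * matrix(E[, q], sz, ns, byrow = TRUE) +
        sqrt(1 - rho_i) * eps
      gene_rows[[length(gene_rows) + 1L]] <- X
      gene_ids <- c(gene_ids, ids)
      labels <- c(labels, rep(q, sz))
      rho_gene[[q]] <- stats::setNames(rho_i, ids)
    }
    ## candidate hub: correlates sqrt(candidate_rho) with its host eigengene
    ## and candidate_driver_cor with the driver; solve the loadings on
    ## (driver z, host eigengene) jointly
    cand_id <- "CAND1"
    c_host <- c_q[spec$candidate_module]
    b <- (sqrt(spec$candidate_rho) - spec$candidate_driver_cor * c_host) / (1 - c_host^2)
    a <- spec$candidate_driver_cor - b * c_host
    s2 <- 1 - (a^2 + b^2 + 2 * a * b * c_host)
    eps_c <- synth_residual(1L, ns, spec$paired, spec$pair_effect_sd, pair_id)
    cand <- a * driver_expr + b * E[, spec$candidate_module] +
      sqrt(pmax(s2, 0)) * as.numeric(eps_c)
    cand <- cand + spec$candidate_delta * condition
    gene_rows[[length(gene_rows) + 1L]] <- matrix(cand, 1L)
    gene_ids <- c(gene_ids, cand_id)
    labels <- c(labels, spec$candidate_module)
    ## driver gene row
    driver_id <- "DRIVER1"
    gene_rows[[length(gene_rows) + 1L]] <- matrix(driver_expr, 1L)
    gene_ids <- c(gene_ids, driver_id)
    labels <- c(labels, 0L)
    ## background noise
    if (spec$n_background > 0L) {
      bg <- synth_residual(spec$n_background, ns, spec$paired, spec$pair_effect_sd, pair_id)
      gene_rows[[length(gene_rows) + 1L]] <- bg
      gene_ids <- c(gene_ids, sprintf("BG_G%04d", seq_len(spec$n_background)))
      labels <- c(labels, rep(0L, spec$n_background))
    }
    expr <- do.call(rbind, gene_rows)
    rownames(expr) <- gene_ids
    colnames(expr) <- sprintf("S%02d", seq_len(ns))
    names(labels) <- gene_ids

    ## outlier contamination
    outliers <- NULL
    if (spec$outlier_fraction > 0) {
      n_cells <- length(expr)
      n_out <- round(spec$outlier_fraction * n_cells)
      if (n_out > 0L) {
        cells <- sample.int(n_cells, n_out)
        rs <- ((cells - 1L) %% nrow(expr)) + 1L
        row_mean <- rowMeans(expr)
        row_sd <- apply(expr, 1L, stats::sd)
        sign_out <- sample(c(-1, 1), n_out, replace = TRUE)
        expr[cells] <- row_mean[rs] + sign_out * spec$outlier_magnitude * row_sd[rs]
        outliers <- data.frame(gene = rownames(expr)[rs],
                               sample = colnames(expr)[((cells - 1L) %/% nrow(expr)) + 1L],
                               cell = cells)
      }
    }

    traits <- data.frame(sample_id = colnames(expr),
                         condition = condition,
                         pair = if (spec$paired) sprintf("P%02d", pair_id) else NA_character_,
                         driver = driver_expr,
                         stringsAsFactors = FALSE)
    truth <- list(labels = labels, driver = driver_id, candidate = cand_id,
                  eigengenes = E, driver_loadings = c_q, coupling = t_couple,
                  rho_gene = rho_gene,
                  candidate_driver_cor = spec$candidate_driver_cor,
                  outliers = outliers, spec = spec, seed = seed)
    structure(list(expr = expr, traits = traits, truth = truth),
              class = "cx_synth_data")
  })
}

#' Generate an independent validation cohort
#'
#' Fresh samples with the same planted module memberships and signal shares
#' as a base dataset (a second cohort sharing the module structure).
#' Optional distortions emulate platform differences: `distort_genes` draws
#' a per-gene location/scale change; `distort_samples` applies a strictly
#' increasing per-sample transform, which leaves rank-based signature scores
#' untouched.
#'
#' @param spec the [synthetic_spec()] used for the base dataset.
#' @param n_new_samples number of validation samples.
#' @param seed integer seed.
#' @param distort_genes per-gene location/scale distortion flag.
#' @param distort_samples per-sample monotone distortion flag.
#' @return a `cx_synth_data` (unpaired; traits carry the driver only).
#' @export
make_validation_cohort <- function(spec, n_new_samples, seed = 2L,
                                   distort_genes = FALSE, distort_samples = FALSE) {
  if (!is_count(n_new_samples)) cx_stop("E_SPEC", "n_new_samples must be a positive integer")
  vspec <- spec
  vspec$n_samples <- as.integer(n_new_samples)
  vspec$paired <- FALSE
  vspec$candidate_delta <- 0
  vspec$outlier_fraction <- 0
  ds <- simulate_dataset(vspec, seed = seed)
  if (distort_genes || distort_samples) {
    ds$expr <- with_seed(seed + 1L, {
      x <- ds$expr
      if (distort_genes) {
        loc <- stats::rnorm(nrow(x), 0, 2)
        scl <- stats::runif(nrow(x), 0.5, 2)
        x <- x * scl + loc
      }
      if (distort_samples) {
        for (s in seq_len(ncol(x))) {
          a <- stats::runif(1, 0.5, 2); b <- stats::rnorm(1, 0, 1)
          x[, s] <- a * exp(x[, s] / 4) + b   # strictly increasing per sample
        }
      }
      x
    })
  }
  ds
}

#' Inject outlier cells into an expression matrix
#'
#' Replaces a fraction of cells with `row mean +/- magnitude * row SD`,
#' exercising the robustness of the correlation step.
#'
#' @param expr expression matrix.
#' @param fraction fraction of cells to replace.
#' @param magnitude outlier size in per-gene SD units.
#' @param seed integer seed.
#' @return list: `expr` (contaminated), `cells` (data.frame of positions).
#' @export
inject_outliers <- function(expr, fraction = 0.01, magnitude = 6, seed = 1L) {
  with_seed(seed, {
    n_out <- round(fraction * length(expr))
    if (n_out < 1L) return(list(expr = expr, cells = NULL))
    cells <- sample.int(length(expr), n_out)
    rs <- ((cells - 1L) %% nrow(expr)) + 1L
    row_mean <- rowMeans(expr)
    row_sd <- apply(expr, 1L, stats::sd)
    sign_out <- sample(c(-1, 1), n_out, replace = TRUE)
    out <- expr
    out[cells] <- row_mean[rs] + sign_out * magnitude * row_sd[rs]
    list(expr = out,
         cells = data.frame(gene = rownames(expr)[rs],
                            sample = colnames(expr)[((cells - 1L) %/% nrow(expr)) + 1L],
                            cell = cells))
  })
}
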