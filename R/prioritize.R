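## Driver-anchored candidate prioritization, paired differential expression,
## and hypergeometric over-representation.

#' Rank candidate genes of a module against a driver gene
#'
#' For every gene of the chosen module, computes the Pearson correlation
#' `r_i` with the driver gene's expression (over a configurable sample
#' subset), its p-value and BH-adjusted q-value. A gene is eligible when
#' the sign of `r_i` matches `direction` and `p_i < alpha` (the raw-p screen
#' used for the driver-anticorrelation criterion; q is reported alongside).
#' Eligible genes receive a composite rank: the unweighted mean of their
#' fractional hub rank (by kIM) and fractional correlation-strength rank
#' (by |r| among eligible genes). The table is sorted by composite rank,
#' the top `N` eligible genes are flagged, and ineligible genes are listed
#' below with the reason. The driver itself is excluded from candidacy.
#'
#' @param expr expression matrix.
#' @param partition `cx_partition`.
#' @param stats data.frame from [gene_module_stats()].
#' @param module module label to rank.
#' @param driver driver gene ID (must be present in `expr`).
#' @param direction `"negative"` or `"positive"` driver correlation.
#' @param N number of top candidates to flag (default 47).
#' @param alpha raw-p threshold for eligibility.
#' @param sample_subset optional sample IDs over which correlations are
#'   computed (e.g. the case-condition samples); default all samples.
#' @return data.frame of class `cx_candidates`: `gene_id`, `module`, `kIM`,
#'   `hub_rank`, `r_driver`, `p`, `q`, `eligible`, `reason`, `composite`,
#'   `final_rank`, `top_n`.
#' @export
rank_candidates <- function(expr, partition, stats, module, driver,
                            direction = c("negative", "positive"),
                            N = 47L, alpha = 0.05, sample_subset = NULL) {
  direction <- match.arg(direction)
  if (!driver %in% rownames(expr)) cx_stop("E_NO_DRIVER", sprintf("driver '%s' not in data", driver))
  labels <- part_labels(partition)
  if (length(module) != 1L || is.na(module) || module == 0L) {
    cx_stop("E_GREY_MODULE", "candidates must come from a proper (non-grey) module")
  }
  module <- unname(module)
  genes <- sort(names(labels)[labels == module])
  if (!length(genes)) cx_stop("E_NO_MODULE", sprintf("module %s is empty", module))
  if (driver %in% genes) {
    cx_log("info", "I_DRIVER_IN_MODULE", "driver gene is a module member; excluded from candidates")
    genes <- setdiff(genes, driver)
  }
  cols <- if (is.null(sample_subset)) colnames(expr) else
    intersect(colnames(expr), sample_subset)
  if (length(cols) < 4L) cx_stop("E_FEW_SAMPLES", "need >= 4 samples for driver correlation")
  dvec <- expr[driver, cols]
  r <- as.numeric(stats::cor(t(expr[genes, cols, drop = FALSE]), dvec))
  p <- cor_pvalue(r, rep(length(cols), length(r)))
  q <- stats::p.adjust(p, method = "BH")
  sgn_ok <- if (direction == "negative") r < 0 else r > 0
  eligible <- sgn_ok & p < alpha & !is.na(r)
  reason <- ifelse(eligible, "",
                   ifelse(!sgn_ok, "wrong_sign", "not_significant"))

  st <- stats[match(genes, stats$gene_id), ]
  tab <- data.frame(gene_id = genes, module = module, kIM = st$kIM,
                    hub_rank = st$hub_rank, r_driver = r, p = p, q = q,
                    eligible = eligible, reason = reason,
                    composite = NA_real_, stringsAsFactors = FALSE)
  ne <- sum(eligible)
  if (ne == 0L) {
    cx_warn("W_NO_ELIGIBLE", "no gene passes the driver-correlation screen")
  } else {
    el <- tab[eligible, ]
    frac_hub <- rank(el$hub_rank, ties.method = "average") / ne
    frac_cor <- rank(-abs(el$r_driver), ties.method = "average") / ne
    tab$composite[eligible] <- (frac_hub + frac_cor) / 2
  }
  ## eligible genes first by composite (ties: hub rank, then ID), then the rest
  ord <- order(!tab$eligible, tab$composite, tab$hub_rank, tab$gene_id)
  tab <- tab[ord, ]
  tab$final_rank <- seq_len(nrow(tab))
  if (N > ne && ne > 0L) {
    cx_warn("W_FEW_CANDIDATES",
            sprintf("only %d eligible gene(s) for top-%d flag; flagging all", ne, N))
  }
  tab$top_n <- tab$eligible & tab$final_rank <= min(N, ne)
  rownames(tab) <- NULL
  class(tab) <- c("cx_candidates", class(tab))
  tab
}

#' Paired differential-expression t-test
#'
#' Classical paired Student t-test on per-pair differences of log2
#' expression (case minus control within each pair), per gene. Degenerate
#' cases: all differences zero gives t = 0 and p = 1; constant non-zero
#' differences give an infinite t (direction reported) with p = 0; both are
#' flagged.
#'
#' @param expr expression matrix.
#' @param traits trait table with `sample_id`, binary `condition` and `pair`.
#' @param genes gene IDs to test (default: all rows of `expr`).
#' @return data.frame: `gene_id`, `mean_diff`, `t`, `p`, `n_pairs`,
#'   `direction` (`"up"` = higher in condition 1), `degenerate`.
#' @export
paired_de_test <- function(expr, traits, genes = rownames(expr)) {
  genes <- intersect(genes, rownames(expr))
  if (!length(genes)) cx_stop("E_NO_GENES", "no requested gene present")
  if (!all(c("condition", "pair") %in% colnames(traits))) {
    cx_stop("E_UNPAIRED", "traits must contain 'condition' and 'pair' columns")
  }
  tr <- traits[traits$sample_id %in% colnames(expr) & !is.na(traits$pair), ]
  pairs <- split(tr, tr$pair)
  pairs <- pairs[vapply(pairs, function(d) nrow(d) == 2L && sum(d$condition) == 1L, logical(1))]
  if (length(pairs) < 3L) cx_stop("E_FEW_PAIRS", "need >= 3 complete pairs")
  case_s <- vapply(pairs, function(d) d$sample_id[d$condition == 1L], character(1))
  ctrl_s <- vapply(pairs, function(d) d$sample_id[d$condition == 0L], character(1))
  D <- expr[genes, case_s, drop = FALSE] - expr[genes, ctrl_s, drop = FALSE]
  n <- ncol(D)
  m <- rowMeans(D)
  s <- apply(D, 1L, stats::sd)
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)),
                   ifelse(m == 0, 0, sign(m) * Inf))
  p <- ifelse(s > 0, 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE),
              ifelse(m == 0, 1, 0))
  data.frame(gene_id = genes, mean_diff = m, t = t_stat, p = p, n_pairs = n,
             direction = ifelse(m > 0, "up", ifelse(m < 0, "down", "none")),
             degenerate = s == 0, stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test `P[X >= overlap]` of a gene selection
#' against each gene set, restricted to a stated universe, with BH
#' adjustment across sets. Selection genes outside the universe are dropped
#' with a warning.
#'
#' @param selection character vector of selected genes.
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param universe character vector: the analyzed gene universe.
#' @return data.frame: `set`, `overlap`, `set_size` (in universe),
#'   `selection_size`, `universe_size`, `p`, `q`.
#' @export
ora_hypergeometric <- function(selection, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) cx_stop("E_EMPTY_UNIVERSE", "empty universe")
  selection <- unique(selection)
  outside <- setdiff(selection, universe)
  if (length(outside)) {
    cx_warn("W_OUTSIDE_UNIVERSE",
            sprintf("%d selected gene(s) outside the universe dropped", length(outside)))
    selection <- intersect(selection, universe)
  }
  k <- length(selection)
  Nn <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    set_u <- intersect(unique(sets[[nm]]), universe)
    ov <- length(intersect(selection, set_u))
    m <- length(set_u)
    p <- if (ov == 0L) 1 else stats::phyper(ov - 1L, m, Nn - m, k, lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = m, selection_size = k,
               universe_size = Nn, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
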