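## Rank-based single-sample signature scoring. The score depends on
## expression only through within-sample gene ranks, so it is exactly
## invariant to any strictly increasing per-sample transform — the property
## that makes it comparable across samples and datasets.

#' Single-sample rank-based signature score
#'
#' Per sample: all `G` genes are ranked ascending by expression (average
#' ranks on ties), normalized to `(rank - 1) / (G - 1)`, and the raw score
#' is the mean normalized rank over the `S` signature genes present. The
#' raw score is min-max standardized by its attainable extremes
#' `(S - 1) / (2 (G - 1))` and `1 - (S - 1) / (2 (G - 1))`, so a signature
#' occupying the top `S` ranks scores exactly 1 and the bottom `S` ranks
#' exactly 0.
#'
#' @param expr expression matrix (genes x samples).
#' @param signature character vector of signature gene IDs.
#' @param name optional signature name.
#' @return list of class `cx_signature_score`: `score` (named per-sample
#'   vector in `[0, 1]`), `n_genes_used`, `n_genes_missing`, `name`.
#' @export
signature_score <- function(expr, signature, name = "signature") {
  signature <- unique(signature)
  present <- intersect(signature, rownames(expr))
  n_missing <- length(signature) - length(present)
  if (!length(present)) cx_stop("E_SIG_EMPTY", "no signature gene present in the data")
  if (n_missing > 0L) {
    cx_log("info", "I_SIG_MISSING",
           sprintf("signature '%s': %d gene(s) absent from the data", name, n_missing))
  }
  G <- nrow(expr)
  S <- length(present)
  if (S >= G) cx_stop("E_SIG_DEGENERATE", "signature covers all genes; score undefined")
  ranks <- apply(expr, 2L, rank)            # ascending, average ranks on ties
  nr <- (ranks - 1) / (G - 1)
  raw <- colMeans(nr[present, , drop = FALSE])
  lo <- (S - 1) / (2 * (G - 1))
  hi <- 1 - lo
  structure(list(score = (raw - lo) / (hi - lo),
                 n_genes_used = S, n_genes_missing = n_missing, name = name),
            class = "cx_signature_score")
}

#' Validate module hub signatures against a reference signature
#'
#' Scores a validation cohort with each module's hub-gene signature and with
#' a reference signature, and reports the Pearson correlation (with
#' asymptotic p) between each module's score vector and the reference score
#' vector, ranking the modules by correlation — the module whose hub program
#' best tracks the reference program ranks first.
#'
#' @param expr_validation validation-cohort expression matrix.
#' @param hub_signatures named list of hub gene sets (one per module).
#' @param reference_signature reference gene set.
#' @return data.frame sorted by descending R: `module`, `R`, `p`,
#'   `n_genes_used`; the reference scores are attached as
#'   `attr(, "reference_score")`.
#' @export
validate_signature <- function(expr_validation, hub_signatures, reference_signature) {
  if (ncol(expr_validation) < 4L) cx_stop("E_FEW_SAMPLES", "need >= 4 validation samples")
  ref <- signature_score(expr_validation, reference_signature, name = "reference")
  rows <- lapply(names(hub_signatures), function(nm) {
    sc <- signature_score(expr_validation, hub_signatures[[nm]], name = nm)
    if (stats::sd(sc$score) == 0 || stats::sd(ref$score) == 0) {
      cx_warn("W_CONSTANT_SCORE", sprintf("constant score vector for '%s'; R undefined", nm))
      return(data.frame(module = nm, R = NA_real_, p = NA_real_,
                        n_genes_used = sc$n_genes_used))
    }
    ct <- stats::cor.test(sc$score, ref$score)
    data.frame(module = nm, R = unname(ct$estimate), p = ct$p.value,
               n_genes_used = sc$n_genes_used)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$R), ]
  rownames(out) <- NULL
  attr(out, "reference_score") <- ref$score
  out
}
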