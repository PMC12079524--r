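## Expression matrices are plain numeric matrices, genes in rows and samples
## in columns, log2 scale, with unique row and column names. All functions in
## the package validate through validate_expression() rather than carrying a
## formal class, mirroring how the field's network-analysis packages treat
## expression data.

#' Validate an expression matrix
#'
#' Checks the structural invariants every downstream stage relies on: unique
#' gene and sample identifiers, at least 2 genes and 3 samples, numeric
#' values, and a per-gene minimum fraction of non-missing values.
#'
#' @param x numeric matrix, genes x samples, with rownames (gene IDs) and
#'   colnames (sample IDs).
#' @param min_present minimum fraction of non-missing values per gene row;
#'   rows below it are dropped with a warning.
#' @return the validated (possibly row-filtered) matrix.
#' @export
validate_expression <- function(x, min_present = 0.8) {
  if (!is.matrix(x) || !is.numeric(x)) {
    cx_stop("E_EXPR_TYPE", "expression data must be a numeric matrix")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    cx_stop("E_EXPR_IDS", "expression matrix must carry gene rownames and sample colnames")
  }
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g)) {
    cx_stop("E_DUP_GENE", paste("duplicate gene IDs:", paste(dup_g, collapse = ", ")))
  }
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s)) {
    cx_stop("E_DUP_SAMPLE", paste("duplicate sample IDs:", paste(dup_s, collapse = ", ")))
  }
  if (nrow(x) < 2L || ncol(x) < 3L) {
    cx_stop("E_EXPR_DIM", "need at least 2 genes and 3 samples")
  }
  present <- rowMeans(!is.na(x))
  if (any(present < min_present)) {
    drop <- rownames(x)[present < min_present]
    cx_warn("W_MISSING_ROWS",
            sprintf("dropping %d gene(s) with < %.0f%% non-missing values",
                    length(drop), 100 * min_present))
    x <- x[present >= min_present, , drop = FALSE]
    if (nrow(x) < 2L) cx_stop("E_EXPR_DIM", "fewer than 2 genes remain after missingness filter")
  }
  x
}

#' Read an expression matrix from tab-delimited text
#'
#' Two dialects are supported: plain `tsv` (header row of sample IDs, first
#' column `gene_id`) and the GEO series-matrix text dialect, in which metadata
#' lines start with `!` and the expression table is bracketed by the
#' series-matrix begin/end table markers.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` or `"geo_series_matrix"`.
#' @param min_present per-gene minimum non-missing fraction (see
#'   [validate_expression()]).
#' @return numeric matrix genes x samples. For the GEO dialect the metadata
#'   lines are attached as a two-column character matrix in
#'   `attr(x, "metadata")`.
#' @export
read_expression <- function(path, dialect = c("tsv", "geo_series_matrix"),
                            min_present = 0.8) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) cx_stop("E_NO_FILE", paste("file not found:", path))
  if (dialect == "tsv") {
    lines <- readLines(path)
    meta <- NULL
  } else {
    all_lines <- readLines(path)
    meta_lines <- grep("^!", all_lines, value = TRUE)
    meta_lines <- setdiff(meta_lines,
                          c("!series_matrix_table_begin", "!series_matrix_table_end"))
    kv <- sub("^!", "", meta_lines)
    key <- sub("\t.*$", "", kv)
    val <- ifelse(grepl("\t", kv), sub("^[^\t]*\t", "", kv), "")
    meta <- cbind(key = key, value = gsub("\"", "", val))
    beg <- match("!series_matrix_table_begin", all_lines)
    end <- match("!series_matrix_table_end", all_lines)
    if (is.na(beg) || is.na(end) || end <= beg + 1L) {
      cx_stop("E_GEO_TABLE", "series-matrix table markers missing or empty table")
    }
    lines <- all_lines[(beg + 1L):(end - 1L)]
  }
  if (!length(lines) || all(!nzchar(lines))) cx_stop("E_EMPTY", "empty expression table")
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.delim(con, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L) cx_stop("E_EMPTY", "empty expression table")
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    cx_stop("E_DUP_GENE", paste("duplicate gene IDs:", paste(dup, collapse = ", ")))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "" & toupper(vals) != "NA",
               arr.ind = TRUE)
  if (nrow(bad)) {
    cx_stop("E_NON_NUMERIC",
            sprintf("non-numeric value at row %d (gene %s), column %s",
                    bad[1, 1], ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  rownames(num) <- ids
  colnames(num) <- colnames(vals)
  num <- validate_expression(num, min_present = min_present)
  if (!is.null(meta)) attr(num, "metadata") <- meta
  num
}

#' Write an expression matrix as TSV
#'
#' @param expr expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  write_matrix_tsv(expr, path, id_name = "gene_id")
}

#' Read a sample trait table
#'
#' Tab-delimited, first column `sample_id`, remaining columns traits (binary
#' traits coded 0/1, categorical traits kept as character, continuous traits
#' numeric).
#'
#' @param path path to the trait TSV.
#' @param expr optional companion expression matrix; if supplied, trait
#'   samples must be a subset of its samples.
#' @return data.frame with `sample_id` plus trait columns.
#' @export
read_traits <- function(path, expr = NULL) {
  if (!file.exists(path)) cx_stop("E_NO_FILE", paste("file not found:", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) {
    cx_stop("E_TRAIT_HEADER", "trait table must have a 'sample_id' column")
  }
  if (anyDuplicated(df$sample_id)) cx_stop("E_DUP_SAMPLE", "duplicate sample IDs in trait table")
  if (!is.null(expr) && !all(df$sample_id %in% colnames(expr))) {
    miss <- setdiff(df$sample_id, colnames(expr))
    cx_stop("E_TRAIT_SAMPLES",
            paste("trait samples absent from expression:", paste(miss, collapse = ", ")))
  }
  df
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are removed with a warning.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors; each element carries its
#'   description in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) cx_stop("E_NO_FILE", paste("file not found:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) cx_stop("E_EMPTY", "empty GMT file")
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      cx_stop("E_GMT_FIELDS", sprintf("GMT line %d has fewer than 3 fields", i))
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      cx_warn("W_GMT_DUP", sprintf("set '%s': duplicate genes de-duplicated", f[1L]))
      genes <- unique(genes)
    }
    if (!length(genes)) cx_stop("E_GMT_EMPTY_SET", sprintf("set '%s' is empty", f[1L]))
    attr(genes, "description") <- f[2L]
    sets[[f[1L]]] <- genes
  }
  if (anyDuplicated(names(sets))) cx_stop("E_GMT_DUP_NAME", "duplicate set names in GMT")
  sets
}

#' Collapse probe-level rows to gene-level rows
#'
#' For genes measured by several probes, keeps the probe with the largest row
#' mean (`max_mean`, the default) or largest row variance (`max_variance`).
#' Probes absent from the mapping are dropped and counted.
#'
#' @param expr probe-level expression matrix (rownames = probe IDs).
#' @param probe2gene named character vector, `names()` = probe IDs, values =
#'   gene symbols.
#' @param rule `"max_mean"` or `"max_variance"`.
#' @return gene-level expression matrix; number of unmapped probes dropped is
#'   recorded in `attr(x, "n_unmapped")`.
#' @export
collapse_probes <- function(expr, probe2gene, rule = c("max_mean", "max_variance")) {
  rule <- match.arg(rule)
  if (!length(probe2gene) || is.null(names(probe2gene))) {
    cx_stop("E_EMPTY_MAP", "probe-to-gene mapping is empty or unnamed")
  }
  probes <- rownames(expr)
  mapped <- probes[probes %in% names(probe2gene)]
  n_unmapped <- length(probes) - length(mapped)
  if (n_unmapped > 0L) {
    cx_log("info", "I_UNMAPPED", sprintf("dropping %d unmapped probe(s)", n_unmapped))
  }
  if (!length(mapped)) cx_stop("E_NO_MAPPED", "no probes map to a gene")
  sub <- expr[mapped, , drop = FALSE]
  gene <- as.character(probe2gene[mapped])
  score <- if (rule == "max_mean") rowMeans(sub, na.rm = TRUE) else
    apply(sub, 1L, stats::var, na.rm = TRUE)
  ## deterministic: within a gene keep highest score, ties by probe ID
  ord <- order(gene, -score, mapped)
  keep <- !duplicated(gene[ord])
  sel <- ord[keep]
  out <- sub[sel, , drop = FALSE]
  rownames(out) <- gene[sel]
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Keep the most variable genes
#'
#' Retains `ceiling(fraction * n_genes)` rows with the largest variance (or
#' median absolute deviation), the usual pre-filter before network
#' construction. Ties are broken by gene ID in lexicographic order and the
#' original row order is preserved in the output.
#'
#' @param expr expression matrix.
#' @param fraction proportion of genes to keep, in (0, 1].
#' @param metric `"variance"` or `"mad"`.
#' @return row-subset of `expr`.
#' @export
filter_top_variable <- function(expr, fraction = 0.2, metric = c("variance", "mad")) {
  metric <- match.arg(metric)
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction > 1) {
    cx_stop("E_FRACTION", "fraction must be in (0, 1]")
  }
  n_keep <- ceiling(fraction * nrow(expr))
  if (n_keep >= nrow(expr)) return(expr)
  v <- if (metric == "variance") {
    apply(expr, 1L, stats::var, na.rm = TRUE)
  } else {
    apply(expr, 1L, stats::mad, na.rm = TRUE)
  }
  if (length(unique(v)) == 1L) {
    cx_warn("W_CONSTANT_VAR", "all genes have identical variability; ties broken by gene ID")
  }
  ord <- order(-v, rownames(expr))
  keep_ids <- rownames(expr)[ord[seq_len(n_keep)]]
  expr[rownames(expr) %in% keep_ids, , drop = FALSE]
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors (see [read_gmt()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- ""
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
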