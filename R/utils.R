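#' @keywords internal
"_PACKAGE"

## Logging goes to stderr via message() with stable event codes so that
## pipeline warnings are greppable in batch logs.
cx_log <- function(level = c("info", "warning", "debug"), code, msg) {
  level <- match.arg(level)
  message(sprintf("[coexmod:%s] %s %s", level, code, msg))
  invisible(NULL)
}

cx_warn <- function(code, msg) {
  warning(sprintf("[coexmod:%s] %s", code, msg), call. = FALSE)
  invisible(NULL)
}

cx_stop <- function(code, msg) {
  stop(sprintf("[coexmod:%s] %s", code, msg), call. = FALSE)
}

## Local RNG scope: every stochastic operation takes an explicit seed and
## restores the caller's random state on exit.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

## Derive a stream of child seeds from one master seed, kept within 32-bit
## integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

#' Write a numeric matrix as tab-delimited text
#'
#' Interchange format used between pipeline stages: first column holds row
#' identifiers under the supplied name, header row holds column identifiers.
#'
#' @param x numeric matrix with row and column names.
#' @param path output file path.
#' @param id_name name of the first (identifier) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, id_name = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_name, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path, id_name = "gene_id") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

## Accept a cx_partition, a list carrying $labels, or a bare named label
## vector wherever a partition is expected.
part_labels <- function(partition) {
  if (is.list(partition) && !is.null(partition$labels)) partition$labels else partition
}
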