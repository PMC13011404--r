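# Internal helpers shared across modules.

pg_log <- function(..., level = "INFO") {
  if (isTRUE(getOption("pangloss.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[pangloss %s] %s", level, sprintf(...)))
  invisible(NULL)
}

pg_warn <- function(...) {
  warning(sprintf(...), call. = FALSE)
}

pg_stop <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Nearest-rank percentile
#'
#' The smallest observed value whose cumulative fraction is at least `p`
#' (nearest-rank definition; no interpolation).
#'
#' @param x numeric vector.
#' @param p probability in (0, 1].
#' @return A single value of `x`.
#' @keywords internal
nearest_rank <- function(x, p) {
  stopifnot(length(x) >= 1, p > 0, p <= 1)
  xs <- sort(x)
  xs[ceiling(p * length(xs))]
}

#' Validate a binary presence/absence matrix
#'
#' Checks the presence/absence contract: a numeric genomes x gene-families
#' matrix of 0/1 entries with unique row (genome) and column (family)
#' names.  All-zero columns (families observed in no genome) are dropped
#' with a warning.
#'
#' @param m matrix to validate.
#' @param drop_empty drop all-zero columns (default) instead of erroring.
#' @return The validated (possibly column-reduced) integer matrix.
#' @export
validate_pa_matrix <- function(m, drop_empty = TRUE) {
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0)
    pg_stop("presence/absence matrix is empty or not a matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    pg_stop("presence/absence matrix needs genome row names and gene-family column names")
  if (anyDuplicated(rownames(m)))
    pg_stop("duplicate genome identifiers: %s",
            paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    pg_stop("duplicate gene-family identifiers: %s",
            paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!all(m %in% c(0, 1)))
    pg_stop("presence/absence matrix must contain only 0 and 1")
  storage.mode(m) <- "integer"
  empty <- colSums(m) == 0L
  if (any(empty)) {
    if (!drop_empty)
      pg_stop("%d gene families present in no genome", sum(empty))
    pg_warn("dropping %d gene families present in no genome: %s",
            sum(empty), paste(utils::head(colnames(m)[empty], 5), collapse = ", "))
    m <- m[, !empty, drop = FALSE]
  }
  m
}

# derive a child stream seed from a user seed; keeps within 32-bit range
pg_seed <- function(seed, offset = 0L) {
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    pg_log("no seed supplied; using generated seed %d", seed)
  }
  as.integer((as.numeric(seed) * 7919 + 104729 * offset) %% 2147483587)
}

#' Write a TSV report with a provenance header
#'
#' All report writers emit comment lines (prefixed `#`) recording the
#' package version, the seed and any parameters, followed by a plain TSV.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param params named list recorded in the header.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pangloss %s", as.character(packageVersion("pangloss"))), con)
  for (nm in names(params))
    writeLines(sprintf("# %s=%s", nm, paste(params[[nm]], collapse = ",")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
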