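# Taxon summaries and stratified Spearman co-occurrence networks with
# Benjamini-Hochberg FDR control and the dual significance threshold
# (p < 1e-5 AND FDR < 0.05).

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: sort p ascending, `q_i = min_{j >= i} m p_j / j`
#' clipped at 1, original order restored.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @return Adjusted values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    pg_stop("p-values must be in [0, 1] and non-missing")
  p.adjust(p_values, method = "BH")
}

#' Per-taxon abundance and prevalence summaries
#'
#' Mean and standard deviation of relative abundance (zeros included)
#' and prevalence (fraction of samples with abundance > 0), overall and
#' per stratum when a metadata key is given.
#'
#' @param table list with `abundance` (samples x taxa matrix, percent)
#'   and `metadata` (see [read_abundance()]), or a bare matrix.
#' @param group_by optional metadata column name (e.g. `"region"`).
#' @return Data frame (`stratum`, `taxon_id`, `mean_abundance`,
#'   `sd_abundance`, `prevalence`); stratum `"all"` rows come first.
#' @export
taxon_summaries <- function(table, group_by = NULL) {
  ab <- if (is.list(table)) table$abundance else table
  if (is.null(ab) || nrow(ab) == 0) pg_stop("empty abundance table")
  one <- function(m, stratum) {
    data.frame(stratum = stratum, taxon_id = colnames(m),
               mean_abundance = colMeans(m),
               sd_abundance = apply(m, 2, sd),
               prevalence = colMeans(m > 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- one(ab, "all")
  if (!is.null(group_by)) {
    md <- if (is.list(table)) table$metadata else NULL
    if (is.null(md) || !group_by %in% colnames(md))
      pg_stop("unknown metadata key '%s'", group_by)
    for (lev in unique(md[[group_by]]))
      out <- rbind(out, one(ab[md[[group_by]] == lev, , drop = FALSE], lev))
  }
  out
}

# Spearman rho and p for one pair; average ranks for ties, large-sample
# t approximation (exact null below n = 12 when tie-free).
.spearman_pair <- function(x, y) {
  n <- length(x)
  rho <- suppressWarnings(cor(x, y, method = "spearman"))
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n < 12 && !ties) {
    p <- suppressWarnings(cor.test(x, y, method = "spearman",
                                   exact = TRUE)$p.value)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  c(rho = rho, p = p)
}

#' Stratified Spearman co-occurrence network
#'
#' Correlates each focal taxon against every other taxon: Spearman rho
#' with average ranks for ties (zeros are genuine observations and enter
#' the ranking), p-values from the large-sample t approximation (exact
#' null below n = 12 when tie-free), Benjamini-Hochberg correction
#' within each (focal taxon, stratum) family, and the dual significance
#' threshold `p < 1e-5 AND FDR < 0.05`.  Partners below `min_prevalence`
#' in a stratum are excluded there.  When `strata` is given the analysis
#' runs pooled and per stratum, and each pooled-significant pair is
#' annotated with the strata in which it is independently significant.
#'
#' @param table list with `abundance` and `metadata`
#'   (see [read_abundance()]).
#' @param focal focal taxon id(s).
#' @param min_prevalence minimum partner prevalence per stratum
#'   (default 0.05).
#' @param strata optional metadata column to stratify by.
#' @param min_stratum_n strata with fewer samples are skipped with a
#'   warning (default 20).
#' @return Data frame (`focal_taxon`, `partner_taxon`, `stratum`, `n`,
#'   `rho`, `p_value`, `p_bh`, `significant`, `sign`,
#'   `significant_strata` on pooled rows).
#' @export
spearman_network <- function(table, focal, min_prevalence = 0.05,
                             strata = NULL, min_stratum_n = 20) {
  ab <- table$abundance
  md <- table$metadata
  miss <- setdiff(focal, colnames(ab))
  if (length(miss) > 0)
    pg_stop("focal taxa not in table: %s", paste(miss, collapse = ", "))
  run_stratum <- function(m, stratum) {
    prev <- colMeans(m > 0)
    rows <- list()
    for (f in focal) {
      partners <- setdiff(colnames(m)[prev >= min_prevalence], f)
      if (length(partners) == 0) next
      est <- vapply(partners, function(p2) .spearman_pair(m[, f], m[, p2]),
                    c(rho = 0, p = 0))
      keep <- !is.na(est["rho", ])
      if (!any(keep)) next
      df <- data.frame(
        focal_taxon = f, partner_taxon = partners[keep], stratum = stratum,
        n = nrow(m), rho = est["rho", keep], p_value = est["p", keep],
        stringsAsFactors = FALSE, row.names = NULL)
      df$p_bh <- bh_adjust(df$p_value)
      df$significant <- df$p_value < 1e-5 & df$p_bh < 0.05
      df$sign <- ifelse(df$rho >= 0, "positive", "negative")
      rows[[length(rows) + 1]] <- df
    }
    if (length(rows) == 0) NULL else do.call(rbind, rows)
  }
  out <- run_stratum(ab, "all")
  if (!is.null(strata)) {
    if (is.null(md) || !strata %in% colnames(md))
      pg_stop("unknown metadata key '%s'", strata)
    for (lev in unique(md[[strata]])) {
      sel <- md[[strata]] == lev
      if (sum(sel) < min_stratum_n) {
        pg_warn("stratum '%s' has %d samples (< %d); skipped",
                lev, sum(sel), min_stratum_n)
        next
      }
      out <- rbind(out, run_stratum(ab[sel, , drop = FALSE], lev))
    }
    # annotate pooled-significant pairs with independently significant strata
    pooled <- out$stratum == "all"
    out$significant_strata <- NA_character_
    sig_str <- out[!pooled & out$significant, , drop = FALSE]
    keys <- paste(sig_str$focal_taxon, sig_str$partner_taxon)
    ann <- vapply(which(pooled & out$significant), function(i) {
      k <- paste(out$focal_taxon[i], out$partner_taxon[i])
      paste(sig_str$stratum[keys == k], collapse = ",")
    }, "")
    out$significant_strata[pooled & out$significant] <- ann
  }
  rownames(out) <- NULL
  out
}
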