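#' Tabulate protein-level consequence classes and amino-acid changes
#'
#' Partitions the cohort's variants over the six canonical consequence
#' classes and tabulates the (reference, alternate) amino-acid pairs of
#' the missense variants. Percentages are computed against the total
#' variant count and reported to integer percent, matching how cohort
#' consequence spectra are usually quoted.
#'
#' @param variants Variant data.frame.
#' @return A list with \code{counts} (data.frame: class, count, percent),
#'   \code{aa_changes} (data.frame: ref_aa, alt_aa, count, kd_delta,
#'   direction; ordered by descending count then pair label), and
#'   \code{n_total}.
#' @export
tabulate_consequences <- function(variants) {
  cls <- factor(variants$consequence, levels = CONSEQUENCE_LEVELS)
  counts <- as.data.frame(table(class = cls), stringsAsFactors = FALSE)
  names(counts) <- c("class", "count")
  n_total <- nrow(variants)
  counts$percent <- if (n_total > 0) round(100 * counts$count / n_total) else 0
  mis <- variants[variants$consequence == "missense", , drop = FALSE]
  if (nrow(mis) > 0) {
    aa <- as.data.frame(table(ref_aa = mis$ref_aa, alt_aa = mis$alt_aa),
                        stringsAsFactors = FALSE)
    names(aa)[3] <- "count"
    aa <- aa[aa$count > 0, , drop = FALSE]
    aa$kd_delta <- kd_delta(aa$ref_aa, aa$alt_aa)
    aa$direction <- ifelse(is.na(aa$kd_delta), NA_character_,
                           ifelse(aa$kd_delta > 0, "more_hydrophobic",
                                  ifelse(aa$kd_delta < 0, "less_hydrophobic",
                                         "unchanged")))
    # deterministic ranking: descending count, then lexicographic pair label
    lab <- paste0(aa$ref_aa, ">", aa$alt_aa)
    aa <- aa[order(-aa$count, lab), , drop = FALSE]
    rownames(aa) <- NULL
  } else {
    aa <- data.frame(ref_aa = character(0), alt_aa = character(0),
                     count = integer(0), kd_delta = numeric(0),
                     direction = character(0), stringsAsFactors = FALSE)
  }
  list(counts = counts, aa_changes = aa, n_total = n_total)
}

#' Top amino-acid modifications by frequency
#'
#' @param consequence_table Output of \code{\link{tabulate_consequences}}.
#' @param n Number of top pairs to return (default 10).
#' @return Head of the ranked \code{aa_changes} table, with an added
#'   \code{rank} column.
#' @export
top_aa_changes <- function(consequence_table, n = 10) {
  aa <- utils::head(consequence_table$aa_changes, n)
  if (nrow(aa) > 0) aa$rank <- seq_len(nrow(aa))
  aa
}
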