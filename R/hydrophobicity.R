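.kd_cache <- new.env(parent = emptyenv())

#' The Kyte-Doolittle hydropathy scale
#'
#' Loads the 1982 Kyte-Doolittle per-residue hydropathy index from the
#' plain-text resource shipped with the package
#' (\code{extdata/kyte_doolittle.tsv}), so the scale is auditable and
#' replaceable. Hydrophobic residues have index > 0; isoleucine (+4.5) is
#' the most hydrophobic and arginine (-4.5) the least.
#'
#' @param path Optional path to an alternative two-column (aa, value) TSV.
#' @return Named numeric vector over the 20 standard one-letter codes.
#' @export
kd_scale <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.kd_cache$scale)) return(.kd_cache$scale)
    path <- system.file("extdata", "kyte_doolittle.tsv", package = "sarcosig")
  }
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  scale <- setNames(tab$value, tab$aa)
  if (length(scale) != 20 || anyDuplicated(names(scale)))
    stop("hydropathy scale must list the 20 standard amino acids once each")
  .kd_cache$scale <- scale
  scale
}

#' Hydrophobicity change of an amino-acid substitution
#'
#' \code{kd_delta(ref, alt) = KD(alt) - KD(ref)} on the Kyte-Doolittle
#' scale; positive values mean the variant residue is more hydrophobic
#' than the reference residue. Antisymmetric by construction. Pairs
#' involving a non-standard residue (stop, B, Z, X, U, ...) return NA.
#'
#' @param ref_aa,alt_aa One-letter amino-acid codes (vectorised).
#' @return Numeric vector of deltas (NA where a residue is non-standard).
#' @examples
#' kd_delta("D", "I")  # +8.0
#' @export
kd_delta <- function(ref_aa, alt_aa) {
  scale <- kd_scale()
  unname(scale[as.character(alt_aa)] - scale[as.character(ref_aa)])
}

#' Cohort-level hydrophobicity-shift statistics
#'
#' Summarises a vector of per-variant Kyte-Doolittle deltas: the mean
#' shift, a t-based 95% confidence interval, and the paired t test of the
#' alternate-residue indices against the reference-residue indices (which
#' is algebraically the one-sample t test of the deltas against zero).
#'
#' @param deltas Numeric vector of per-variant deltas (NAs dropped with a
#'   count).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A list: \code{n}, \code{n_excluded}, \code{n_increasing},
#'   \code{frac_increasing}, \code{mean_delta}, \code{ci95} (low, high),
#'   \code{t_statistic}, \code{p_paired}, \code{conf_level},
#'   \code{ci_defined}.
#' @export
cohort_shift <- function(deltas, conf_level = 0.95) {
  n_excluded <- sum(is.na(deltas))
  d <- deltas[!is.na(deltas)]
  if (length(d) == 0) stop("no usable deltas")
  n <- length(d)
  if (n == 1 || sd(d) == 0) {
    return(list(n = n, n_excluded = n_excluded,
                n_increasing = sum(d > 0),
                frac_increasing = mean(d > 0),
                mean_delta = mean(d), ci95 = c(NA_real_, NA_real_),
                t_statistic = NA_real_, p_paired = NA_real_,
                conf_level = conf_level, ci_defined = FALSE))
  }
  tt <- t.test(d, mu = 0, conf.level = conf_level)
  list(n = n, n_excluded = n_excluded,
       n_increasing = sum(d > 0),
       frac_increasing = mean(d > 0),
       mean_delta = unname(tt$estimate),
       ci95 = as.numeric(tt$conf.int),
       t_statistic = unname(tt$statistic),
       p_paired = tt$p.value,
       conf_level = conf_level, ci_defined = TRUE)
}

#' Hydrophobicity report for a variant cohort
#'
#' Computes the per-variant Kyte-Doolittle deltas of the cohort's
#' missense variants and the cohort shift statistics. Silent variants are
#' excluded by default (the shift is a statement about amino-acid
#' changes); set \code{include_silent = TRUE} to count them as delta 0.
#'
#' @param variants Variant data.frame.
#' @param include_silent Count silent variants as zero-delta observations.
#' @return A list with \code{per_variant} (data.frame: sample_id, ref_aa,
#'   alt_aa, delta) and \code{shift} (see \code{\link{cohort_shift}}).
#' @export
hydrophobicity_report <- function(variants, include_silent = FALSE) {
  mis <- variants[variants$consequence == "missense", , drop = FALSE]
  per <- data.frame(sample_id = mis$sample_id, ref_aa = mis$ref_aa,
                    alt_aa = mis$alt_aa,
                    delta = kd_delta(mis$ref_aa, mis$alt_aa),
                    stringsAsFactors = FALSE)
  if (include_silent) {
    sil <- variants[variants$consequence == "silent", , drop = FALSE]
    if (nrow(sil) > 0)
      per <- rbind(per, data.frame(sample_id = sil$sample_id,
                                   ref_aa = sil$ref_aa, alt_aa = sil$ref_aa,
                                   delta = 0, stringsAsFactors = FALSE))
  }
  list(per_variant = per, shift = cohort_shift(per$delta))
}
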