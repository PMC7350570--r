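#' Run the full cohort analysis pipeline
#'
#' Orchestrates burden, spectrum, consequence, hydrophobicity and
#' signature analysis over a variant table and writes every result as a
#' TSV plus a JSON manifest. Deterministic given its inputs: rerunning on
#' identical inputs reproduces identical output files, and the manifest
#' records input/output checksums, package version and every threshold
#' used so each number in a report is traceable to a file.
#'
#' @param variants Variant data.frame (e.g. from
#'   \code{\link{read_variant_table}} or \code{\link{simulate_cohort}}).
#' @param meta Sample metadata data.frame.
#' @param weights Signature reference matrix.
#' @param etiology_map Named signature -> etiology vector (default: the
#'   shipped map).
#' @param out_dir Output directory (created if needed).
#' @param min_exposure,min_snv Signature-fitting thresholds (see
#'   \code{\link{fit_exposures}}).
#' @param burden_test Method for the face/scalp vs rest burden
#'   comparison (\code{"welch_t"} or \code{"mann_whitney"}).
#' @return The manifest, invisibly, with elements \code{files},
#'   \code{checksums}, \code{params}, \code{counts} and the in-memory
#'   results (\code{burden}, \code{spectra}, \code{consequences},
#'   \code{hydrophobicity}, \code{fit}, \code{etiologies}).
#' @export
run_pipeline <- function(variants, meta, weights = synthetic_signature_matrix(),
                         etiology_map = read_etiology_map(),
                         out_dir = "results", min_exposure = 0.06,
                         min_snv = 50, burden_test = "welch_t") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)

  burden <- compute_burden(variants, meta)
  write.table(burden$per_sample, fp("burden_per_sample.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n")
  comparison <- NULL
  fs <- burden$per_sample$site_group == "face_scalp"
  if (any(fs) && any(!fs))
    comparison <- compare_groups(burden$per_sample$n_mutations[fs],
                                 burden$per_sample$n_mutations[!fs],
                                 method = burden_test)

  spectra <- build_spectra(variants, samples = meta$sample_id)
  write_spectra(spectra, fp("spectra.tsv"))

  cons <- tabulate_consequences(variants)
  write.table(cons$counts, fp("consequence_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n")
  write.table(cons$aa_changes, fp("aa_changes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n")

  hydro <- hydrophobicity_report(variants)
  hydro_df <- data.frame(
    n = hydro$shift$n, n_excluded = hydro$shift$n_excluded,
    n_increasing = hydro$shift$n_increasing,
    frac_increasing = hydro$shift$frac_increasing,
    mean_delta = hydro$shift$mean_delta,
    ci_low = hydro$shift$ci95[1], ci_high = hydro$shift$ci95[2],
    t_statistic = hydro$shift$t_statistic, p_paired = hydro$shift$p_paired)
  write.table(hydro_df, fp("hydrophobicity_shift.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n")

  fit <- fit_cohort_exposures(spectra, weights, min_exposure, min_snv)
  expo_df <- data.frame(sample_id = rownames(fit$exposures), fit$exposures,
                        check.names = FALSE)
  write.table(expo_df, fp("signature_exposures.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n")
  etio <- etiology_summary(fit$exposures, etiology_map)
  etio_df <- data.frame(sample_id = rownames(etio), etio, check.names = FALSE)
  write.table(etio_df, fp("etiology_probabilities.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n")

  files <- c("burden_per_sample.tsv", "spectra.tsv", "consequence_counts.tsv",
             "aa_changes.tsv", "hydrophobicity_shift.tsv",
             "signature_exposures.tsv", "etiology_probabilities.tsv")
  manifest <- list(
    package = "sarcosig",
    version = as.character(utils::packageVersion("sarcosig")),
    files = files,
    checksums = as.list(tools::md5sum(vapply(files, fp, character(1)))),
    params = list(min_exposure = min_exposure, min_snv = min_snv,
                  burden_test = burden_test),
    counts = list(n_variants = nrow(variants),
                  n_samples = nrow(meta),
                  n_patients = length(unique(meta$patient_id)),
                  n_rejected = if (is.null(attr(variants, "n_rejected"))) 0L
                               else attr(variants, "n_rejected"),
                  n_missense = cons$counts$count[cons$counts$class == "missense"],
                  n_no_context = sum(spectra$n_no_context)),
    comparison = comparison)
  jsonlite::write_json(manifest[setdiff(names(manifest), "comparison")],
                       fp("manifest.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$burden <- burden
  manifest$spectra <- spectra
  manifest$consequences <- cons
  manifest$hydrophobicity <- hydro
  manifest$fit <- fit
  manifest$etiologies <- etio
  invisible(manifest)
}
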