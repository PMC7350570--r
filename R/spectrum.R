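#' Build per-sample mutation spectra
#'
#' Classifies every single-nucleotide variant into one of the 12 raw
#' substitution classes and, where a valid trinucleotide context is
#' available, into one of the 96 pyrimidine-strand channels. Indels
#' (\code{ref} or \code{alt} of \code{"-"}) are excluded from spectra;
#' SNVs without a usable context contribute to the 12-class counts only
#' and are tallied as \code{n_no_context}.
#'
#' @param variants Variant data.frame (see \code{\link{read_variant_table}}).
#' @param samples Optional character vector of sample IDs to report;
#'   samples with no variants yield all-zero spectra. Defaults to the
#'   samples present in \code{variants}.
#' @return A data.frame with one row per sample: \code{sample_id},
#'   \code{n_snv}, \code{n_no_context}, 12 raw-class count columns and 96
#'   channel count columns (named as in \code{\link{sbs96_channels}}).
#' @export
build_spectra <- function(variants, samples = NULL) {
  if (is.null(samples)) samples <- unique(variants$sample_id)
  r12 <- raw12_classes()
  ch96 <- sbs96_channels()
  snv <- variants[variants$ref %in% NUCLEOTIDES &
                    variants$alt %in% NUCLEOTIDES, , drop = FALSE]
  out <- data.frame(sample_id = samples, n_snv = 0L, n_no_context = 0L,
                    stringsAsFactors = FALSE)
  m12 <- matrix(0L, nrow = length(samples), ncol = 12,
                dimnames = list(samples, r12))
  m96 <- matrix(0L, nrow = length(samples), ncol = 96,
                dimnames = list(samples, ch96))
  if (nrow(snv) > 0) {
    cls <- paste0(snv$ref, ">", snv$alt)
    t12 <- table(factor(snv$sample_id, levels = samples),
                 factor(cls, levels = r12))
    m12[] <- as.integer(t12)
    chan <- sbs96_channel_of(snv$ref, snv$alt, snv$context)
    ok <- !is.na(chan)
    t96 <- table(factor(snv$sample_id[ok], levels = samples),
                 factor(chan[ok], levels = ch96))
    m96[] <- as.integer(t96)
    out$n_snv <- as.integer(rowSums(m12))
    out$n_no_context <- out$n_snv - as.integer(rowSums(m96))
  }
  cbind(out, as.data.frame(m12, check.names = FALSE),
        as.data.frame(m96, check.names = FALSE))
}

#' Extract the 96-channel count matrix from a spectrum table
#'
#' @param spectra Output of \code{\link{build_spectra}}.
#' @return Integer matrix, samples x 96 channels.
#' @export
spectrum_matrix <- function(spectra) {
  m <- as.matrix(spectra[, sbs96_channels(), drop = FALSE])
  rownames(m) <- spectra$sample_id
  m
}

#' Write a spectrum table
#'
#' One row per sample; \code{n_snv}, 12 raw-class and 96 channel columns
#' in fixed order.
#'
#' @param spectra Output of \code{\link{build_spectra}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  write.table(spectra, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
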