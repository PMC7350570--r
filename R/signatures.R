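#' Validate a signature reference matrix
#'
#' @param weights Numeric 96 x K matrix; rows named by the 96 channels
#'   (\code{"A[C>A]A"} style), columns by signature labels. Each column
#'   must be a probability distribution over the channels.
#' @return The matrix with rows reordered to the canonical channel order.
#' @export
validate_signature_matrix <- function(weights) {
  ch <- sbs96_channels()
  if (is.null(rownames(weights)) || !setequal(rownames(weights), ch))
    stop("signature matrix rows must be the 96 channels")
  if (ncol(weights) < 1) stop("signature matrix needs at least one column")
  weights <- weights[ch, , drop = FALSE]
  if (any(weights < 0)) stop("signature matrix entries must be nonnegative")
  cs <- colSums(weights)
  if (any(abs(cs - 1) > 1e-8))
    stop("signature matrix columns must each sum to 1")
  weights
}

#' Read a signature matrix from TSV
#'
#' Expects the COSMIC-v2-style layout: first column the channel label
#' (\code{"A[C>A]A"}), remaining columns one signature each.
#'
#' @param path TSV path.
#' @return Validated 96 x K numeric matrix.
#' @export
read_signature_matrix <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  validate_signature_matrix(m)
}

#' Write a signature matrix to TSV
#'
#' @param weights Validated signature matrix.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_signature_matrix <- function(weights, path) {
  tab <- data.frame(channel = rownames(weights), weights, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  min(1, max(0, sum(a * b) / (na * nb)))
}

#' Fit per-sample signature exposures by nonnegative least squares
#'
#' Normalises a sample's 96-channel counts to frequencies and solves the
#' nonnegative least-squares decomposition against the reference
#' signature columns. Exposures are normalised to sum to 1, exposures
#' below \code{min_exposure} are zeroed (single-pass thresholding, as in
#' the deconstructSigs convention) and the remainder renormalised; the
#' result is the per-signature "probability" in [0, 1]. The cosine
#' similarity between the observed spectrum and its reconstruction is
#' reported as a fit diagnostic.
#'
#' @param counts96 Named numeric vector of 96 channel counts (names must
#'   be the canonical channels), or a single row of
#'   \code{\link{spectrum_matrix}}.
#' @param weights Validated 96 x K signature matrix.
#' @param min_exposure Exposures below this are zeroed after the first
#'   normalisation (default 0.06).
#' @param min_snv Below this many context-resolved SNVs the profile is
#'   flagged low-confidence rather than suppressed (default 50).
#' @return A list: \code{exposures} (named, sums to 1),
#'   \code{reconstruction_cosine}, \code{n_snv_used},
#'   \code{low_confidence}, \code{degenerate} (TRUE for an all-zero
#'   spectrum, in which case exposures are all NA).
#' @export
fit_exposures <- function(counts96, weights, min_exposure = 0.06,
                          min_snv = 50) {
  weights <- validate_signature_matrix(weights)
  ch <- sbs96_channels()
  if (is.null(names(counts96)) || !setequal(names(counts96), ch))
    stop("counts96 must be named by the 96 channels")
  v <- as.numeric(counts96[ch])
  n_used <- sum(v)
  K <- ncol(weights)
  if (n_used == 0) {
    return(list(exposures = setNames(rep(NA_real_, K), colnames(weights)),
                reconstruction_cosine = NA_real_, n_snv_used = 0,
                low_confidence = TRUE, degenerate = TRUE))
  }
  target <- v / n_used
  fit <- pracma::lsqnonneg(weights, target)
  x <- fit$x
  if (sum(x) == 0) {
    return(list(exposures = setNames(rep(NA_real_, K), colnames(weights)),
                reconstruction_cosine = NA_real_, n_snv_used = n_used,
                low_confidence = TRUE, degenerate = TRUE))
  }
  x <- x / sum(x)
  x[x < min_exposure] <- 0
  x <- x / sum(x)
  names(x) <- colnames(weights)
  recon <- as.numeric(weights %*% x)
  list(exposures = x,
       reconstruction_cosine = cosine_similarity(target, recon),
       n_snv_used = n_used,
       low_confidence = n_used < min_snv,
       degenerate = FALSE)
}

#' Fit exposures for every sample of a spectrum table
#'
#' @param spectra Output of \code{\link{build_spectra}}.
#' @param weights Validated signature matrix.
#' @param min_exposure,min_snv Passed to \code{\link{fit_exposures}}.
#' @return A list with \code{exposures} (samples x K matrix) and
#'   \code{diagnostics} (data.frame: sample_id, n_snv_used,
#'   reconstruction_cosine, low_confidence, degenerate).
#' @export
fit_cohort_exposures <- function(spectra, weights, min_exposure = 0.06,
                                 min_snv = 50) {
  m <- spectrum_matrix(spectra)
  weights <- validate_signature_matrix(weights)
  K <- ncol(weights)
  expo <- matrix(NA_real_, nrow = nrow(m), ncol = K,
                 dimnames = list(rownames(m), colnames(weights)))
  diag <- data.frame(sample_id = rownames(m), n_snv_used = 0,
                     reconstruction_cosine = NA_real_,
                     low_confidence = TRUE, degenerate = TRUE,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    f <- fit_exposures(m[i, ], weights, min_exposure, min_snv)
    expo[i, ] <- f$exposures
    diag$n_snv_used[i] <- f$n_snv_used
    diag$reconstruction_cosine[i] <- f$reconstruction_cosine
    diag$low_confidence[i] <- f$low_confidence
    diag$degenerate[i] <- f$degenerate
  }
  list(exposures = expo, diagnostics = diag)
}

#' Load an etiology map
#'
#' Reads a YAML file mapping each signature label to an etiology label
#' (aging, UV, MMR, APOBEC, POLE, POLH, other, ...). The package ships an
#' editable default for the 30-signature COSMIC v2 layout.
#'
#' @param path YAML path; defaults to the shipped map.
#' @return Named character vector, signature -> etiology.
#' @export
read_etiology_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "etiology_map.yaml", package = "sarcosig")
  m <- yaml::read_yaml(path)
  unlist(m)
}

#' Per-sample etiology probabilities
#'
#' Sums member-signature exposures per etiology, clipped to [0, 1]; the
#' resulting samples x etiology matrix has rows summing to 1 for
#' non-degenerate samples and matches the heatmap layout in which each
#' etiology's probability is read on a 0-1 scale.
#'
#' @param exposures Samples x K exposure matrix
#'   (\code{fit_cohort_exposures()$exposures}).
#' @param etiology_map Named character vector, signature -> etiology;
#'   every signature column must be mapped.
#' @return Numeric matrix, samples x etiologies (etiologies in first-seen
#'   map order).
#' @export
etiology_summary <- function(exposures, etiology_map) {
  unmapped <- setdiff(colnames(exposures), names(etiology_map))
  if (length(unmapped) > 0)
    stop("unmapped signature(s): ", paste(unmapped, collapse = ", "))
  et <- etiology_map[colnames(exposures)]
  levels <- unique(unname(etiology_map))
  out <- sapply(levels, function(e) {
    cols <- which(et == e)
    if (length(cols) == 0) rep(0, nrow(exposures))
    else rowSums(exposures[, cols, drop = FALSE])
  })
  out <- matrix(pmin(1, pmax(0, out)), nrow = nrow(exposures),
                dimnames = list(rownames(exposures), levels))
  out
}

#' Top etiology per sample
#'
#' @param etiologies Samples x etiologies matrix from
#'   \code{\link{etiology_summary}}.
#' @return Character vector naming each sample's highest-probability
#'   etiology (NA for degenerate samples); ties broken by column order.
#' @export
top_etiology <- function(etiologies) {
  apply(etiologies, 1, function(r) {
    if (all(is.na(r))) NA_character_ else colnames(etiologies)[which.max(r)]
  })
}
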