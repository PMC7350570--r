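#' @importFrom stats complete.cases p.adjust qt rlnorm runif sd setNames t.test
#'   wilcox.test chisq.test rbinom uniroot
#' @importFrom utils read.delim write.table head
NULL

NUCLEOTIDES <- c("A", "C", "G", "T")
PYRIMIDINE_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 12 raw substitution classes
#'
#' Ordered pair labels \code{"ref>alt"} over all 12 single-nucleotide
#' substitutions, without strand collapsing (G>A and C>T are distinct
#' classes, as in the cohort spectra this package reports).
#'
#' @return Character vector of length 12, alphabetical by ref then alt.
#' @export
raw12_classes <- function() {
  out <- c(t(outer(NUCLEOTIDES, NUCLEOTIDES, paste, sep = ">")))
  out[substr(out, 1, 1) != substr(out, 3, 3)]
}

#' The 96 trinucleotide substitution channels
#'
#' Standard SBS-96 channel labels in fixed order: substitution-major
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' base, then 3' base, each
#' alphabetical. Labels use the \code{"A[C>T]G"} convention so spectrum
#' files are comparable bit-for-bit with COSMIC-style matrices.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  grid <- expand.grid(p3 = NUCLEOTIDES, p5 = NUCLEOTIDES, sub = PYRIMIDINE_SUBS,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$sub, PYRIMIDINE_SUBS), grid$p5, grid$p3), ]
  paste0(grid$p5, "[", grid$sub, "]", grid$p3)
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of strings over A/C/G/T.
#' @return Reverse-complemented strings.
#' @export
reverse_complement <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
}

#' Classify a single-nucleotide substitution into one of 12 classes
#'
#' Returns the ordered-pair label \code{"ref>alt"}. No strand collapsing
#' is applied; transitions on opposite strands (e.g. G>A and C>T) remain
#' separate classes.
#'
#' @param ref,alt Single nucleotides in A/C/G/T (case-insensitive).
#' @return Character vector of class labels.
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (any(!ref %in% NUCLEOTIDES) || any(!alt %in% NUCLEOTIDES))
    stop("classify_substitution() requires single A/C/G/T alleles (no indels)")
  if (any(ref == alt))
    stop("ref and alt alleles must differ")
  paste0(ref, ">", alt)
}

#' Collapse a substitution and context to the pyrimidine strand
#'
#' Applies the standard SBS-96 convention: substitutions with a purine
#' reference are reverse-complemented so the reported reference base is a
#' pyrimidine (C or T), and the trinucleotide context is
#' reverse-complemented with it.
#'
#' @param ref,alt Single nucleotides, ref != alt.
#' @param context 3-mer over A/C/G/T with middle base equal to \code{ref}.
#' @return A list with \code{sub} (one of the 6 pyrimidine classes),
#'   \code{context} (collapsed 3-mer) and \code{channel} (the
#'   \code{"A[C>T]G"}-style label).
#' @export
collapse_to_pyrimidine <- function(ref, alt, context) {
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  stopifnot(length(ref) == 1, length(alt) == 1, length(context) == 1)
  if (nchar(context) != 3 || !all(strsplit(context, "")[[1]] %in% NUCLEOTIDES))
    stop("context must be a 3-mer over A/C/G/T")
  if (substr(context, 2, 2) != ref)
    stop("context middle base must equal ref")
  if (!ref %in% c("C", "T")) {
    ref <- chartr("ACGT", "TGCA", ref)
    alt <- chartr("ACGT", "TGCA", alt)
    context <- reverse_complement(context)
  }
  sub <- paste0(ref, ">", alt)
  list(sub = sub, context = context,
       channel = paste0(substr(context, 1, 1), "[", sub, "]",
                        substr(context, 3, 3)))
}

# Vectorised channel assignment; NA where context missing/invalid.
sbs96_channel_of <- function(ref, alt, context) {
  n <- length(ref)
  out <- rep(NA_character_, n)
  ok <- !is.na(context) & nchar(context) == 3 &
    grepl("^[ACGT]{3}$", context) &
    substr(context, 2, 2) == ref &
    ref %in% NUCLEOTIDES & alt %in% NUCLEOTIDES & ref != alt
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; ctx <- context[ok]
  purine <- r %in% c("A", "G")
  r[purine] <- chartr("ACGT", "TGCA", r[purine])
  a[purine] <- chartr("ACGT", "TGCA", a[purine])
  ctx[purine] <- reverse_complement(ctx[purine])
  out[ok] <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3))
  out
}
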