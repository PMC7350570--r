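CONSEQUENCE_LEVELS <- c("missense", "silent", "nonsense", "splice", "other",
                        "unknown")

# Canonical column order for the generic TSV dialect.
VARIANT_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "alt", "context",
                     "consequence", "consequence_raw", "protein_change",
                     "ref_aa", "alt_aa", "aa_pos")

# Built-in dialect column mappings (dialect name -> file column per field).
dialect_map <- function(dialect = c("generic_tsv", "maf_like")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    generic_tsv = c(sample = "sample_id", chrom = "chrom", pos = "pos",
                    ref = "ref", alt = "alt", context = "context",
                    consequence = "consequence",
                    protein_change = "protein_change"),
    maf_like = c(sample = "Tumor_Sample_Barcode", chrom = "Chromosome",
                 pos = "Start_Position", ref = "Reference_Allele",
                 alt = "Tumor_Seq_Allele2", context = "CONTEXT",
                 consequence = "Variant_Classification",
                 protein_change = "HGVSp_Short"))
}

# Map raw consequence annotation strings onto the six canonical classes.
# Unknown strings map to "other", never silently to "missense".
normalize_consequence <- function(x) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep("other", length(x0))
  out[x0 %in% c("missense", "missense_mutation", "missense_variant")] <- "missense"
  out[x0 %in% c("silent", "synonymous", "synonymous_variant")] <- "silent"
  out[x0 %in% c("nonsense", "nonsense_mutation", "stop_gained")] <- "nonsense"
  out[x0 %in% c("splice", "splice_site", "splice_region",
                "splice_acceptor_variant", "splice_donor_variant")] <- "splice"
  out[x0 %in% c("unknown", "", "na") | is.na(x)] <- "unknown"
  out
}

#' Parse HGVS protein-change notation
#'
#' Accepts short forms (\code{"p.A123V"}, \code{"A123V"}), 3-letter forms
#' (\code{"p.Ala123Val"}), synonymous forms (\code{"p.A123="},
#' \code{"p.A123A"}, \code{"p.Tyr55="}) and stop gains (\code{"p.Q61*"},
#' \code{"p.Gln61Ter"}; the stop codon is returned as \code{"*"}).
#' Frameshift, extension, and other complex notation is reported as not
#' parseable.
#'
#' @param text Character vector of protein-change strings.
#' @return A data.frame with columns \code{ref_aa}, \code{aa_pos},
#'   \code{alt_aa}; all-NA rows mark strings that could not be parsed.
#' @examples
#' parse_hgvs_p(c("p.G12D", "p.Tyr55=", "p.Q61*", "p.K45fs"))
#' @export
parse_hgvs_p <- function(text) {
  text <- trimws(as.character(text))
  n <- length(text)
  out <- data.frame(ref_aa = rep(NA_character_, n), aa_pos = rep(NA_integer_, n),
                    alt_aa = rep(NA_character_, n), stringsAsFactors = FALSE)
  if (n == 0) return(out)
  body <- sub("^p\\.", "", text)
  aa3 <- function(x) {
    # 3-letter -> 1-letter; "Ter" -> "*"; NA if unrecognised
    vapply(x, function(s) {
      if (is.na(s)) return(NA_character_)
      if (s %in% c("Ter", "ter")) return("*")
      a <- tryCatch(seqinr::a(paste0(toupper(substr(s, 1, 1)),
                                     tolower(substr(s, 2, 3)))),
                    error = function(e) NA_character_)
      if (is.null(a) || length(a) != 1 || is.na(a)) NA_character_ else a
    }, character(1), USE.NAMES = FALSE)
  }
  # short form: X123Y, X123*, X123=
  m1 <- regmatches(body, regexec("^([A-Z])([0-9]+)([A-Z*=])$", body))
  # 3-letter form: Abc123Xyz / Abc123Ter / Abc123=
  m3 <- regmatches(body, regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2}|=)$",
                                 body))
  for (i in seq_len(n)) {
    if (length(m1[[i]]) == 4) {
      ref <- m1[[i]][2]; pos <- as.integer(m1[[i]][3]); alt <- m1[[i]][4]
      if (alt == "=") alt <- ref
      out$ref_aa[i] <- ref; out$aa_pos[i] <- pos; out$alt_aa[i] <- alt
    } else if (length(m3[[i]]) == 4) {
      ref <- aa3(m3[[i]][2]); pos <- as.integer(m3[[i]][3])
      alt <- if (m3[[i]][4] == "=") ref else aa3(m3[[i]][4])
      if (!is.na(ref) && !is.na(alt)) {
        out$ref_aa[i] <- ref; out$aa_pos[i] <- pos; out$alt_aa[i] <- alt
      }
    }
  }
  out
}

validate_variants <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  is_indel <- df$ref == "-" | df$alt == "-"
  bad_allele <- !(df$ref %in% c(NUCLEOTIDES, "-")) |
    !(df$alt %in% c(NUCLEOTIDES, "-"))
  reason[bad_allele] <- "unparseable allele"
  same <- !is_indel & !bad_allele & df$ref == df$alt
  reason[same] <- "ref equals alt"
  both_dash <- df$ref == "-" & df$alt == "-"
  reason[both_dash & is.na(reason)] <- "ref and alt both missing"
  has_ctx <- !is.na(df$context) & nzchar(df$context)
  bad_ctx <- has_ctx & is.na(reason) &
    (!grepl("^[ACGT]{3}$", df$context) | substr(df$context, 2, 2) != df$ref)
  reason[bad_ctx] <- "context inconsistent with ref"
  bad_pos <- is.na(reason) & (is.na(df$pos) | df$pos < 1)
  reason[bad_pos] <- "invalid position"
  mis <- is.na(reason) & df$consequence == "missense"
  bad_mis <- mis & (is.na(df$ref_aa) | is.na(df$alt_aa) |
                      df$ref_aa == df$alt_aa)
  reason[bad_mis] <- "missense without distinct amino acids"
  sil <- is.na(reason) & df$consequence == "silent"
  bad_sil <- sil & !is.na(df$ref_aa) & !is.na(df$alt_aa) &
    df$ref_aa != df$alt_aa
  reason[bad_sil] <- "silent with amino-acid change"
  reason
}

#' Read a cohort variant table
#'
#' Reads a TSV of somatic variants in either the package's canonical
#' generic dialect or a MAF-like dialect, normalises alleles to upper
#' case, maps raw consequence annotations onto six canonical classes
#' (keeping the raw string in \code{consequence_raw} so the mapping is
#' auditable), parses protein changes, and enforces record invariants.
#' Rows violating an invariant are rejected with a per-row reason rather
#' than aborting the read; coordinates are 1-based fully closed.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect \code{"generic_tsv"} (canonical column names) or
#'   \code{"maf_like"} (MAF column names).
#' @param col_map Optional named character vector overriding the dialect's
#'   column mapping; names are the logical fields (\code{sample},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{context},
#'   \code{consequence}, \code{protein_change}), values the file columns.
#' @return A data.frame of accepted variant records in file order, with
#'   attributes \code{n_rejected} (count) and \code{rejections} (a
#'   data.frame of row number and reason).
#' @export
read_variant_table <- function(path, dialect = c("generic_tsv", "maf_like"),
                               col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("variant table not found: ", path)
  map <- dialect_map(dialect)
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  raw <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE, na.strings = c("NA", ""))
  mandatory <- c("sample", "chrom", "pos", "ref", "alt")
  for (f in mandatory) {
    if (!map[[f]] %in% names(raw))
      stop("missing mandatory column '", map[[f]], "' (field: ", f, ")")
  }
  get_col <- function(f) {
    if (map[[f]] %in% names(raw)) raw[[map[[f]]]] else rep(NA_character_, nrow(raw))
  }
  df <- data.frame(
    sample_id = get_col("sample"),
    chrom = get_col("chrom"),
    pos = suppressWarnings(as.integer(get_col("pos"))),
    ref = toupper(trimws(get_col("ref"))),
    alt = toupper(trimws(get_col("alt"))),
    context = toupper(get_col("context")),
    consequence_raw = get_col("consequence"),
    protein_change = get_col("protein_change"),
    stringsAsFactors = FALSE)
  df$consequence <- normalize_consequence(df$consequence_raw)
  aa <- parse_hgvs_p(df$protein_change)
  df$ref_aa <- aa$ref_aa
  df$alt_aa <- aa$alt_aa
  df$aa_pos <- aa$aa_pos
  # stop gain in the protein change forces the nonsense class
  stopg <- !is.na(df$alt_aa) & df$alt_aa == "*"
  df$consequence[stopg] <- "nonsense"
  # annotated missense/silent without parseable protein change is kept as-is
  # for silent, but missense requires the amino-acid pair (invariant below)
  if (nrow(df) == 0) {
    out <- df[, VARIANT_COLUMNS]
    attr(out, "n_rejected") <- 0L
    attr(out, "rejections") <- data.frame(row = integer(0),
                                          reason = character(0))
    return(out)
  }
  reason <- validate_variants(df)
  rej <- data.frame(row = which(!is.na(reason)),
                    reason = reason[!is.na(reason)],
                    stringsAsFactors = FALSE)
  if (nrow(rej) > 0)
    message("read_variant_table: rejected ", nrow(rej), " of ", nrow(df),
            " rows (", paste(unique(rej$reason), collapse = "; "), ")")
  out <- df[is.na(reason), VARIANT_COLUMNS]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- nrow(rej)
  attr(out, "rejections") <- rej
  out
}

#' Write a variant table in the canonical dialect
#'
#' Writes the canonical generic TSV (fixed column order, UTF-8, LF line
#' endings) that \code{\link{read_variant_table}} reads back losslessly.
#'
#' @param variants A variant data.frame as returned by
#'   \code{\link{read_variant_table}} or \code{\link{simulate_cohort}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  cols <- intersect(VARIANT_COLUMNS, names(variants))
  write.table(variants[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "", fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns \code{sample_id}, \code{patient_id},
#'   \code{site_group} (one of face_scalp/other/visceral) and
#'   \code{capture_size_bp}.
#' @return A data.frame, one row per sample.
#' @export
read_sample_meta <- function(path) {
  m <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  required <- c("sample_id", "patient_id", "site_group", "capture_size_bp")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0)
    stop("sample metadata missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in metadata")
  if (any(!is.finite(m$capture_size_bp)) || any(m$capture_size_bp <= 0))
    stop("capture_size_bp must be positive")
  m
}

#' Write a sample metadata table
#'
#' @param meta Sample metadata data.frame.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
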