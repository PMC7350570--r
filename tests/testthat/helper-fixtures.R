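# Small in-code fixtures shared across tests.

toy_variants <- function() {
  data.frame(
    sample_id = c("S1", "S1", "S1", "S2", "S2"),
    chrom = c("chr1", "chr1", "chr2", "chr3", "chrX"),
    pos = c(100L, 200L, 300L, 400L, 500L),
    ref = c("G", "C", "G", "A", "C"),
    alt = c("A", "T", "A", "T", "G"),
    context = c("TGC", "ACG", "AGA", "CAT", "TCA"),
    consequence = c("missense", "silent", "missense", "nonsense", "other"),
    consequence_raw = c("missense", "silent", "missense", "nonsense", "other"),
    protein_change = c("p.D10I", "p.A20=", "p.G30V", "p.Q40*", NA),
    ref_aa = c("D", "A", "G", "Q", NA),
    alt_aa = c("I", "A", "V", "*", NA),
    aa_pos = c(10L, 20L, 30L, 40L, NA),
    stringsAsFactors = FALSE)
}

toy_meta <- function() {
  data.frame(sample_id = c("S1", "S2"), patient_id = c("P1", "P2"),
             site_group = c("face_scalp", "other"),
             capture_size_bp = c(30e6, 30e6), stringsAsFactors = FALSE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

# Independent reverse complement used as an oracle (kept separate from
# the package's own helper on purpose).
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

small_spec <- function(seed = 11, n_face = 3, n_other = 4, median_face = 60,
                       median_other = 30) {
  cohort_spec(
    site_groups = list(
      face_scalp = list(n = n_face, burden = list(median = median_face,
                                                  dispersion = 0.5),
                        mixture = c(Signature.7 = 0.8, Signature.1 = 0.2)),
      other = list(n = n_other, burden = list(median = median_other,
                                              dispersion = 0.5),
                   mixture = c(Signature.1 = 1.0))),
    seed = seed)
}

withr_like_tempdir <- function() {
  d <- tempfile("out")
  dir.create(d)
  d
}
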