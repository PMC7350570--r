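test_that("classify_substitution labels ordered pairs and rejects degenerates", {
  expect_equal(classify_substitution("G", "A"), "G>A")
  expect_equal(classify_substitution("C", "T"), "C>T")
  expect_equal(classify_substitution(c("a", "t"), c("g", "c")),
               c("A>G", "T>C"))
  expect_error(classify_substitution("G", "G"))
  expect_error(classify_substitution("-", "A"))
})

test_that("pyrimidine collapse matches an independent reverse-complement oracle
           over all 192 substitution-context combinations", {
  expect_equal(collapse_to_pyrimidine("G", "A", "TGC"),
               list(sub = "C>T", context = "GCA", channel = "G[C>T]A"))
  expect_equal(collapse_to_pyrimidine("C", "T", "ACG")$channel, "A[C>T]G")
  nts <- c("A", "C", "G", "T")
  for (ref in nts) for (alt in setdiff(nts, ref))
    for (p5 in nts) for (p3 in nts) {
      ctx <- paste0(p5, ref, p3)
      got <- collapse_to_pyrimidine(ref, alt, ctx)
      # middle base always a pyrimidine
      expect_true(substr(got$sub, 1, 1) %in% c("C", "T"))
      # invariant under reverse-complementing the input variant
      rc <- collapse_to_pyrimidine(chartr("ACGT", "TGCA", ref),
                                   chartr("ACGT", "TGCA", alt),
                                   oracle_revcomp(ctx))
      expect_identical(got, rc)
    }
})

test_that("build_spectra counts every SNV once and keeps context accounting", {
  v <- data.frame(sample_id = "S1", chrom = "chr1", pos = 1:3,
                  ref = "G", alt = "A",
                  context = c("AGA", "CGT", NA),
                  consequence = "missense", stringsAsFactors = FALSE)
  sp <- build_spectra(v)
  expect_equal(sp$`G>A`, 3)
  expect_equal(sum(sp[, raw12_classes()]), 3)
  expect_equal(sp$n_snv, 3)
  expect_equal(sp$n_no_context, 1)
  expect_equal(sum(sp[, sbs96_channels()]), 2)
})

test_that("indels are excluded from spectra and zero-variant samples give
           all-zero rows", {
  v <- toy_variants()
  v$ref[1] <- "-"
  sp <- build_spectra(v, samples = c("S1", "S2", "S3"))
  expect_equal(sum(sp$n_snv), 4)
  expect_equal(sp$n_snv[sp$sample_id == "S3"], 0)
  expect_true(all(sp[sp$sample_id == "S3", c(raw12_classes(),
                                             sbs96_channels())] == 0))
})

test_that("spectra conserve SNV counts and are strand-symmetric", {
  sim <- simulate_cohort(small_spec(seed = 5))
  v <- sim$variants
  sp <- build_spectra(v)
  expect_equal(sum(sp$n_snv), nrow(v))
  # reverse-complement every variant: 96-channel spectra unchanged
  v_rc <- v
  v_rc$ref <- chartr("ACGT", "TGCA", v$ref)
  v_rc$alt <- chartr("ACGT", "TGCA", v$alt)
  v_rc$context <- oracle_revcomp(v$context)
  sp_rc <- build_spectra(v_rc)
  expect_equal(spectrum_matrix(sp_rc), spectrum_matrix(sp))
  # raw12 transition pair collapses onto the C>T channel total
  ct_cols <- grep("C>T", sbs96_channels(), fixed = TRUE, value = TRUE)
  expect_equal(sum(sp$`G>A`) + sum(sp$`C>T`),
               sum(sp[, ct_cols]))
})

test_that("empirical channel frequencies converge to the generator mixture", {
  spec <- cohort_spec(
    site_groups = list(one = list(
      n = 1, burden = list(median = 10000, dispersion = 0),
      mixture = c(Signature.7 = 0.6, Signature.1 = 0.4))),
    seed = 9)
  sim <- simulate_cohort(spec)
  expect_equal(nrow(sim$variants), 10000)
  sp <- build_spectra(sim$variants)
  emp <- as.numeric(spectrum_matrix(sp)[1, ])
  emp <- emp / sum(emp)
  W <- synthetic_signature_matrix()
  expected <- as.numeric(0.6 * W[, "Signature.7"] + 0.4 * W[, "Signature.1"])
  tv <- 0.5 * sum(abs(emp - expected))
  expect_lt(tv, 0.05)
})
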