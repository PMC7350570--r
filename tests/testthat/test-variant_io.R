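test_that("parse_hgvs_p handles short, 3-letter, synonymous and stop forms", {
  cases <- list(
    list("p.G12D", "G", 12L, "D"),
    list("G12D", "G", 12L, "D"),
    list("p.Ala123Val", "A", 123L, "V"),
    list("p.A123=", "A", 123L, "A"),
    list("p.A123A", "A", 123L, "A"),
    list("p.Tyr55=", "Y", 55L, "Y"),
    list("p.Q61*", "Q", 61L, "*"),
    list("p.Gln61Ter", "Q", 61L, "*"))
  for (cs in cases) {
    got <- parse_hgvs_p(cs[[1]])
    expect_equal(unlist(got, use.names = FALSE),
                 c(cs[[2]], as.character(cs[[3]]), cs[[4]]),
                 info = cs[[1]])
  }
  bad <- parse_hgvs_p(c("p.K45fs", "p.Met1ext-5", "p.A12_G14del", "", "nonsense"))
  expect_true(all(is.na(bad$ref_aa)))
})

test_that("invariant-violating rows are rejected with reasons, not aborts", {
  df <- data.frame(sample_id = c("S1", "S1", "S1"),
                   chrom = "chr1", pos = 1:3,
                   ref = c("G", "C", "T"), alt = c("A", "C", "T"),
                   context = c("AGA", "ACT", "ATT"),
                   consequence = c("missense", "silent", "silent"),
                   protein_change = c("p.G12D", "p.A5=", "p.L7="))
  path <- write_tsv(df)
  suppressMessages(v <- read_variant_table(path))
  expect_equal(nrow(v), 1)                      # rows 2 and 3 have ref == alt
  expect_equal(attr(v, "n_rejected"), 2)
  expect_equal(attr(v, "rejections")$reason, rep("ref equals alt", 2))
  expect_equal(nrow(v) + attr(v, "n_rejected"), nrow(df))
})

test_that("an empty file with a valid header reads to an empty cohort", {
  path <- write_tsv(toy_variants()[0, ])
  v <- read_variant_table(path)
  expect_equal(nrow(v), 0)
  expect_equal(attr(v, "n_rejected"), 0)
})

test_that("a missing mandatory column is a configuration error naming it", {
  df <- toy_variants()
  df$ref <- NULL
  path <- write_tsv(df)
  expect_error(read_variant_table(path), "ref")
})

test_that("alleles parse case-insensitively and are emitted upper-case", {
  df <- toy_variants()[1, ]
  df$ref <- "g"; df$alt <- "a"; df$context <- "tgc"
  path <- write_tsv(df)
  v <- read_variant_table(path)
  expect_equal(v$ref, "G")
  expect_equal(v$alt, "A")
  expect_equal(v$context, "TGC")
})

test_that("unknown consequence strings map to other, never to missense", {
  df <- toy_variants()[1, ]
  df$consequence <- "weird_annotation"
  df$protein_change <- NA
  path <- write_tsv(df)
  v <- read_variant_table(path)
  expect_equal(v$consequence, "other")
})

test_that("a simulated table round-trips through write and read identically", {
  sim <- simulate_cohort(small_spec(seed = 3))
  vars <- head(sim$variants, 200)
  path <- tempfile(fileext = ".tsv")
  write_variant_table(vars, path)
  back <- read_variant_table(path)
  expect_equal(attr(back, "n_rejected"), 0)
  for (col in names(vars))
    expect_equal(back[[col]], vars[[col]], info = col)
  # second round trip is byte-stable
  path2 <- tempfile(fileext = ".tsv")
  write_variant_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("the MAF-like dialect maps its columns onto the canonical fields", {
  df <- data.frame(Tumor_Sample_Barcode = "S1", Chromosome = "chr7",
                   Start_Position = 140453136,
                   Reference_Allele = "A", Tumor_Seq_Allele2 = "T",
                   CONTEXT = "CAC", Variant_Classification = "Missense_Mutation",
                   HGVSp_Short = "p.V600E")
  path <- write_tsv(df)
  v <- read_variant_table(path, dialect = "maf_like")
  expect_equal(v$sample_id, "S1")
  expect_equal(v$consequence, "missense")
  expect_equal(v$ref_aa, "V")
  expect_equal(v$alt_aa, "E")
  expect_equal(v$aa_pos, 600L)
})

test_that("sample metadata validation catches duplicates and bad capture sizes", {
  m <- toy_meta()
  path <- write_tsv(m)
  expect_equal(read_sample_meta(path)$sample_id, c("S1", "S2"))
  m2 <- rbind(m, m[1, ])
  expect_error(read_sample_meta(write_tsv(m2)), "duplicate")
  m3 <- m; m3$capture_size_bp[1] <- 0
  expect_error(read_sample_meta(write_tsv(m3)), "positive")
})
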