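test_that("signature matrix validation enforces shape and normalisation", {
  W <- synthetic_signature_matrix()
  expect_equal(dim(W), c(96, 30))
  expect_equal(unname(colSums(W)), rep(1, 30), tolerance = 1e-10)
  expect_true(all(W >= 0))
  bad <- W; bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(validate_signature_matrix(bad), "sum to 1")
  neg <- W; neg[1, 1] <- -neg[1, 1]
  expect_error(validate_signature_matrix(neg), "nonnegative")
  anon <- W; rownames(anon) <- NULL
  expect_error(validate_signature_matrix(anon), "96 channels")
})

test_that("a signature matrix round-trips through TSV", {
  W <- synthetic_signature_matrix(5)
  path <- tempfile(fileext = ".tsv")
  write_signature_matrix(W, path)
  back <- read_signature_matrix(path)
  expect_equal(back, W, tolerance = 1e-12)
})

test_that("a pure single-signature spectrum is recovered exactly", {
  W <- synthetic_signature_matrix()
  cnt <- W[, "Signature.7"] * 100
  names(cnt) <- rownames(W)
  f <- fit_exposures(cnt, W)
  expect_equal(unname(f$exposures["Signature.7"]), 1)
  expect_equal(f$reconstruction_cosine, 1, tolerance = 1e-8)
  expect_equal(f$n_snv_used, 100)
  expect_false(f$low_confidence)
})

test_that("a 0.7/0.3 mixture of well-separated signatures is recovered
           within 0.05 at 5000 mutations", {
  W <- synthetic_signature_matrix()
  s1 <- W[, "Signature.7"]; s2 <- W[, "Signature.26"]
  sep <- sum(s1 * s2) / sqrt(sum(s1^2) * sum(s2^2))
  expect_lt(sep, 0.3)
  set.seed(7)
  cnt <- as.vector(rmultinom(1, 5000, 0.7 * s1 + 0.3 * s2))
  names(cnt) <- sbs96_channels()
  f <- fit_exposures(cnt, W)
  expect_equal(unname(f$exposures["Signature.7"]), 0.7, tolerance = 0.05)
  expect_equal(unname(f$exposures["Signature.26"]), 0.3, tolerance = 0.05)
})

test_that("NNLS attains at least the best residual of a brute-force simplex
           grid on K <= 3 signatures", {
  W3 <- synthetic_signature_matrix(3)
  grid_pts <- seq(0, 1, by = 0.25)
  simplex <- expand.grid(a = grid_pts, b = grid_pts, c = grid_pts)
  simplex <- simplex[abs(rowSums(simplex) - 1) < 1e-9, ]
  set.seed(17)
  for (rep in 1:5) {
    mix <- as.vector(rmultinom(1, 3, rep(1, 3))) / 3
    cnt <- as.vector(rmultinom(1, 400, W3 %*% mix))
    target <- cnt / sum(cnt)
    grid_best <- min(apply(simplex, 1, function(g) {
      sum((as.vector(W3 %*% as.numeric(g)) - target)^2)
    }))
    fit <- pracma::lsqnonneg(W3, target)
    expect_lte(fit$resid.norm, grid_best + 1e-12)
  }
})

test_that("exposures are label-invariant, scale-invariant and sum to one", {
  W <- synthetic_signature_matrix(8)
  set.seed(23)
  cnt <- as.vector(rmultinom(1, 2000, W %*% c(0.5, 0, 0, 0.3, 0, 0.2, 0, 0)))
  names(cnt) <- sbs96_channels()
  f <- fit_exposures(cnt, W)
  expect_equal(sum(f$exposures), 1, tolerance = 1e-8)
  perm <- sample(ncol(W))
  f_perm <- fit_exposures(cnt, W[, perm])
  expect_equal(f_perm$exposures[colnames(W)], f$exposures, tolerance = 1e-8)
  f2 <- fit_exposures(cnt * 2, W)
  expect_equal(f2$exposures, f$exposures, tolerance = 1e-10)
})

test_that("degenerate and low-count spectra are flagged, not suppressed", {
  W <- synthetic_signature_matrix(5)
  zero <- setNames(rep(0, 96), sbs96_channels())
  f0 <- fit_exposures(zero, W)
  expect_true(f0$degenerate)
  expect_true(all(is.na(f0$exposures)))
  few <- setNames(rep(0, 96), sbs96_channels())
  few[c("A[C>T]G", "T[C>T]G")] <- c(5, 3)
  f1 <- fit_exposures(few, W, min_snv = 50)
  expect_true(f1$low_confidence)
  expect_false(f1$degenerate)
  expect_equal(sum(f1$exposures), 1, tolerance = 1e-8)
})

test_that("etiology probabilities sum member exposures and demand a full map", {
  expo <- matrix(c(0.6, 0.4), nrow = 1,
                 dimnames = list("S1", c("sigA", "sigB")))
  both_uv <- etiology_summary(expo, c(sigA = "UV", sigB = "UV"))
  expect_equal(unname(both_uv["S1", "UV"]), 1)
  split <- etiology_summary(expo, c(sigA = "aging", sigB = "UV"))
  expect_equal(unname(split["S1", ]), c(0.6, 0.4))
  expect_error(etiology_summary(expo, c(sigA = "UV")), "unmapped")
  aging_only <- etiology_summary(matrix(1, 1, 1, dimnames = list("S1", "sigA")),
                                 c(sigA = "aging", sigB = "UV"))
  expect_equal(unname(aging_only["S1", "aging"]), 1)
  expect_equal(unname(aging_only["S1", "UV"]), 0)
})

test_that("an MMR-dominated synthetic cohort ranks MMR first", {
  spec <- cohort_spec(
    site_groups = list(visceral = list(
      n = 4, burden = list(median = 300, dispersion = 0.3),
      mixture = c(Signature.6 = 0.5, Signature.20 = 0.3, Signature.1 = 0.2))),
    seed = 29)
  sim <- simulate_cohort(spec)
  fit <- fit_cohort_exposures(build_spectra(sim$variants),
                              synthetic_signature_matrix())
  tops <- top_etiology(etiology_summary(fit$exposures, read_etiology_map()))
  expect_true(all(tops == "MMR"))
})
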