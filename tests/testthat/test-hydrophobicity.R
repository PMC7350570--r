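test_that("the shipped hydropathy scale is the 20-residue Kyte-Doolittle set", {
  s <- kd_scale()
  expect_length(s, 20)
  expect_equal(names(which.max(s)), "I")
  expect_equal(names(which.min(s)), "R")
  expect_equal(unname(s["I"]), 4.5)
  expect_equal(unname(s["R"]), -4.5)
})

test_that("kd_delta is antisymmetric and NA for non-standard residues", {
  expect_equal(kd_delta("A", "A"), 0)
  expect_equal(kd_delta("D", "I"), 8)       # I = 4.5, D = -3.5
  expect_equal(kd_delta("I", "D"), -8)
  aas <- names(kd_scale())
  set.seed(1)
  a <- sample(aas, 50, replace = TRUE)
  b <- sample(aas, 50, replace = TRUE)
  expect_equal(kd_delta(a, b), -kd_delta(b, a))
  expect_true(all(is.na(kd_delta(c("X", "*", "B"), c("A", "A", "A")))))
})

test_that("cohort_shift matches the closed-form one-sample t at n = 5", {
  d <- c(1.2, -0.3, 2.1, 0.4, 0.9)
  got <- cohort_shift(d)
  m <- mean(d); s <- sd(d); n <- 5
  t_oracle <- m / (s / sqrt(n))
  p_oracle <- 2 * pt(-abs(t_oracle), df = n - 1)
  half <- qt(0.975, df = n - 1) * s / sqrt(n)
  expect_equal(got$t_statistic, t_oracle)
  expect_equal(got$p_paired, p_oracle)
  expect_equal(got$ci95, c(m - half, m + half))
  expect_equal(got$mean_delta, m)
  expect_equal(got$n_increasing, 4)
  expect_true(got$ci95[1] <= got$mean_delta && got$mean_delta <= got$ci95[2])
})

test_that("symmetric deltas give zero mean; a single delta flags the CI", {
  expect_equal(cohort_shift(c(1, -1))$mean_delta, 0)
  one <- cohort_shift(3.5)
  expect_false(one$ci_defined)
  expect_true(is.na(one$p_paired))
})

test_that("the shift statistic is invariant under variant order and equals the
           paired t test of alt vs ref indices", {
  sim <- simulate_cohort(small_spec(seed = 21))
  rep1 <- hydrophobicity_report(sim$variants)
  shuffled <- sim$variants[sample(nrow(sim$variants)), ]
  rep2 <- hydrophobicity_report(shuffled)
  expect_equal(rep2$shift[setdiff(names(rep2$shift), "per_variant")],
               rep1$shift[setdiff(names(rep1$shift), "per_variant")])
  # dual route: paired t on the residue indices themselves
  s <- kd_scale()
  mis <- sim$variants[sim$variants$consequence == "missense", ]
  tt <- t.test(s[mis$alt_aa], s[mis$ref_aa], paired = TRUE)
  expect_equal(rep1$shift$p_paired, tt$p.value)
  expect_equal(rep1$shift$mean_delta, unname(tt$estimate))
  expect_equal(rep1$shift$ci95, unname(tt$conf.int[1:2]))
})

test_that("silent variants contribute zero deltas only when requested", {
  v <- toy_variants()
  default <- hydrophobicity_report(v)
  expect_equal(default$shift$n, 2)          # two missense rows
  with_silent <- hydrophobicity_report(v, include_silent = TRUE)
  expect_equal(with_silent$shift$n, 3)
  expect_equal(sum(with_silent$per_variant$delta == 0), 1)
})

test_that("non-standard residues are excluded with a count", {
  v <- toy_variants()[1, ]
  v$alt_aa <- "X"
  v2 <- rbind(v, toy_variants()[3, ])
  rep <- hydrophobicity_report(v2)
  expect_equal(rep$shift$n, 1)
  expect_equal(rep$shift$n_excluded, 1)
})
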