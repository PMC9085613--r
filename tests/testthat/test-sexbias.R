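test_that("expressed filter uses the pooled interpolated percentile, strictly", {
  # one library holding values 1..100: the 5th percentile (type 7) is 5.95
  des <- data.frame(sample_id = c("s1", "s2"), species = "spX",
                    pair_id = "p1", sexual_system = "dioicous",
                    sex = "male", replicate = 1:2)
  tpm <- cbind(s1 = 1:100, s2 = 1:100)
  rownames(tpm) <- paste0("g", 1:100)
  e <- expression_matrix(tpm, des)
  es <- expressed_filter(e, "male")
  expect_equal(es$threshold, 5.95)
  expect_setequal(es$genes, paste0("g", 6:100))

  # degenerate all-equal matrix: empty expressed set
  tpm[] <- 7
  e2 <- expression_matrix(tpm, des)
  es2 <- expressed_filter(e2, "male")
  expect_equal(es2$threshold, 7)
  expect_length(es2$genes, 0L)

  # all-zero genes are never expressed under a strict threshold >= 0
  tpm[] <- 7; tpm[1L, ] <- 0
  expect_false("g1" %in% expressed_filter(expression_matrix(tpm, des),
                                          "male")$genes)
})

test_that("benjamini_hochberg matches hand step-up examples", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_true(all(benjamini_hochberg(runif(50)) >= sort(runif(50))[1L] * 0))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("sex-bias calls agree with a Welch oracle and the FC rule", {
  # strong male bias: ratio 20, p << 0.05.  A few low-expression filler
  # genes keep the female expressed threshold below the focal gene.
  set.seed(101)
  m <- matrix(rep(c(100, 110, 90), each = 1), 1)
  f <- matrix(c(5, 6, 4), 1)
  filler_m <- rbind(matrix(rep(c(50, 55, 45), 26), 26, byrow = TRUE),
                    matrix(0.3, 4, 3)) *
    2^matrix(rnorm(90, 0, .1), 30)
  filler_f <- filler_m * 2^matrix(rnorm(90, 0, .1), 30)
  e <- make_expr(rbind(m, filler_m), rbind(f, filler_f))
  sb <- call_sex_bias(e, engine = "welch")
  expect_identical(sb$class[1L], "MB")
  oracle <- t.test(log2(c(100, 110, 90) + 1), log2(c(5, 6, 4) + 1))
  expect_equal(sb$pvalue[1L], oracle$p.value, tolerance = 1e-12)
  expect_equal(2^sb$log2fc[1L], 100 / 5, tolerance = 1e-12)

  # identical values per gene: everything unbiased at p = 1
  e2 <- make_expr(filler_m, filler_m)
  for (eng in c("welch", "moderated")) {
    sb2 <- call_sex_bias(e2, engine = eng)
    expect_true(all(sb2$class %in% c("UNBIASED", "NOT_EXPRESSED")))
    expect_equal(sb2$pvalue[!is.na(sb2$pvalue)],
                 rep(1, sum(!is.na(sb2$pvalue))), tolerance = 1e-12)
  }

  # tiny p but ratio 1.8: fails the fold-change rule
  m3 <- matrix(rep(c(18, 18.2, 17.8), 40), 40, byrow = TRUE)
  f3 <- matrix(rep(c(10, 10.1, 9.9), 40), 40, byrow = TRUE)
  sb3 <- call_sex_bias(make_expr(m3, f3), engine = "welch")
  expect_true(all(sb3$class[!is.na(sb3$pvalue)] == "UNBIASED"))
})

test_that("sex-linked exclusion and sex-specific detection work and are final", {
  set.seed(42)
  base <- matrix(50 * 2^rnorm(120, 0, .1), 40)
  m <- base; f <- base * 2^matrix(rnorm(120, 0, .1), 40)
  m[1L, ] <- c(80, 90, 100); f[1L, ] <- 0      # male-specific
  m[2L, ] <- c(400, 420, 380); f[2L, ] <- c(5, 6, 4)   # male-biased
  e <- make_expr(m, f)
  sb <- call_sex_bias(e, exclude = "g2")
  expect_identical(sb$class[2L], "EXCLUDED_SEX_LINKED")
  expect_identical(sb$class[1L], "SEX_SPECIFIC_M")
  # excluded genes never reach a biased class downstream
  expect_false("g2" %in% sb$gene[sb$class %in% c("FB", "MB")])
})

test_that("FB/MB calls are antisymmetric under swapping sex labels", {
  set.seed(7)
  base <- matrix(30 * 2^rnorm(180, 0, 1), 60)
  eff <- matrix(0, 60, 3); eff[1:10, ] <- 2; eff[11:20, ] <- -2
  m <- base * 2^eff * 2^matrix(rnorm(180, 0, .15), 60)
  f <- base * 2^matrix(rnorm(180, 0, .15), 60)
  sb_fwd <- call_sex_bias(make_expr(m, f))
  sb_rev <- call_sex_bias(make_expr(f, m))
  fwd_mb <- sb_fwd$gene[sb_fwd$class == "MB"]
  rev_fb <- sb_rev$gene[sb_rev$class == "FB"]
  expect_setequal(fwd_mb, rev_fb)
  expect_setequal(sb_fwd$gene[sb_fwd$class == "FB"],
                  sb_rev$gene[sb_rev$class == "MB"])
})

test_that("bias fractions use the mean expressed denominator and strata", {
  set.seed(8)
  base <- matrix(40 * 2^rnorm(300, 0, .6), 100)
  m <- base; f <- base
  m[1:10, ] <- f[1:10, ] * 4       # FC 4 (stratum 2-15)
  m[11:12, ] <- f[11:12, ] * 40    # FC 40 (stratum >15)
  e <- make_expr(m * 2^matrix(rnorm(300, 0, .08), 100),
                 f * 2^matrix(rnorm(300, 0, .08), 100))
  sb <- call_sex_bias(e)
  fr <- bias_fractions(sb)
  ex <- attr(sb, "expressed")
  expect_equal(fr$denominator,
               (length(ex$female$genes) + length(ex$male$genes)) / 2)
  expect_equal(fr$pct_mb, 100 * fr$n_mb / fr$denominator)
  expect_gte(fr$strata$fc_over_15[fr$strata$class == "MB"], 1)
  # zero-bias case
  sb0 <- call_sex_bias(make_expr(base, base))
  fr0 <- bias_fractions(sb0)
  expect_equal(fr0$pct_fb + fr0$pct_mb, 0)
})

test_that("chi2_fb_mb matches the closed-form 2x2 chi-square", {
  # equal counts: statistic 0, p = 1
  expect_equal(chi2_fb_mb(50, 50, 1000)$p.value, 1)
  # (200 of 2000) vs (100 of 2000): chi2 = n(ad-bc)^2 / row/col products
  a <- 200; b <- 1800; c <- 100; d <- 1900; n <- a + b + c + d
  chi_hand <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  got <- chi2_fb_mb(200, 100, 2000, 2000)
  expect_equal(got$statistic, chi_hand, tolerance = 1e-10)
  expect_equal(got$p.value, pchisq(chi_hand, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # label-swap symmetry
  expect_equal(got$p.value, chi2_fb_mb(100, 200, 2000, 2000)$p.value)
  expect_error(chi2_fb_mb(1, 1, 0), "denominator")
})

test_that("dimorphism t-test returns the absolute mean difference with Welch p", {
  ph <- data.frame(species = "spX",
                   sex = rep(c("female", "male"), each = 3),
                   cell_length = c(30, 32, 34, 20, 22, 24))
  got <- dimorphism_ttest(ph, "spX")
  expect_equal(got$difference, 10)
  expect_equal(got$p.value,
               t.test(c(30, 32, 34), c(20, 22, 24))$p.value)
  # identical samples: difference 0, p = 1
  ph2 <- ph; ph2$cell_length <- rep(c(30, 32, 34), 2)
  got2 <- dimorphism_ttest(ph2, "spX")
  expect_equal(got2$difference, 0)
  expect_equal(got2$p.value, 1)
  expect_error(dimorphism_ttest(ph[ph$sex == "male", ], "spX"), "sex")
})

test_that("null data keeps the biased-call rate within the alpha envelope", {
  b <- generate_bundle(small_config(seed = 5L, sex_biased_fraction = 0,
                                    sex_specific_fraction = 0,
                                    sex_linked_fraction = 0,
                                    convergent_fraction = 0))
  sb <- call_sex_bias(b$exprs$dio1)
  tested <- sum(!is.na(sb$padj))
  fp <- sum(sb$class %in% c("FB", "MB", "SEX_SPECIFIC_F", "SEX_SPECIFIC_M"))
  se <- sqrt(0.05 * 0.95 / tested)
  expect_lte(fp / tested, 0.05 + 3 * se)
})
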