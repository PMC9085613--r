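test_that("similarity index behaves like Pearson r with its invariances", {
  p1 <- setNames(c(1, 2, 3, 4, 5), paste0("g", 1:5))
  expect_equal(similarity_index(p1, p1), 1)
  expect_equal(similarity_index(p1, mean(p1) - (p1 - mean(p1))), -1)
  # 5-gene hand example against the textbook formula
  p2 <- setNames(c(2.0, 1.1, 3.7, 2.5, 4.9), paste0("g", 1:5))
  r_hand <- sum((p1 - mean(p1)) * (p2 - mean(p2))) /
    sqrt(sum((p1 - mean(p1))^2) * sum((p2 - mean(p2))^2))
  expect_equal(similarity_index(p1, p2), r_hand)
  # gene-order and additive-constant invariance
  ord <- c(3, 1, 5, 2, 4)
  expect_equal(similarity_index(p1[ord], p2[ord], names(p1)[ord]),
               similarity_index(p1, p2))
  expect_equal(similarity_index(p1 + 7, p2), similarity_index(p1, p2))
  # zero variance is undefined
  expect_warning(r0 <- similarity_index(setNames(rep(1, 5), names(p1)), p2),
                 "zero variance")
  expect_true(is.na(r0))
  expect_error(similarity_index(p1[1:2], p2[1:2], names(p1)[1:2]), ">=3")
})

test_that("independent correlation comparison follows Fisher's z", {
  same <- compare_correlations_independent(0.4, 50, 0.4, 50)
  expect_equal(same$z, 0)
  expect_equal(same$p.value, 1)
  got <- compare_correlations_independent(0.9, 100, 0.1, 100)
  z_hand <- (atanh(0.9) - atanh(0.1)) / sqrt(2 / 97)
  expect_equal(got$z, z_hand)
  expect_equal(z_hand, 9.5541, tolerance = 1e-4)
  expect_lt(got$p.value, 1e-15)
  # antisymmetry
  swap <- compare_correlations_independent(0.1, 100, 0.9, 100)
  expect_equal(swap$z, -got$z)
  expect_equal(swap$p.value, got$p.value)
  expect_error(compare_correlations_independent(1, 10, 0.5, 10), "infinite")
})

test_that("dependent correlation comparison matches the published formula", {
  # hand evaluation of Dunn & Clark's z with the Silver/Hittner/May
  # backtransformed-mean modification, frozen from a desk computation
  got <- compare_correlations_dependent(0.5, 0.3, 0.2, 100)
  z1 <- atanh(0.5); z2 <- atanh(0.3)
  rm_ <- tanh((z1 + z2) / 2)
  cv <- (0.2 * (1 - 2 * rm_^2) - 0.5 * rm_^2 * (1 - 2 * rm_^2 - 0.04)) /
    (1 - rm_^2)^2
  z_hand <- (z1 - z2) * sqrt(97 / (2 - 2 * cv))
  expect_equal(got$z, z_hand, tolerance = 1e-12)
  expect_equal(got$z, 1.7783, tolerance = 1e-4)
  expect_equal(got$p.value, 2 * pnorm(-abs(z_hand)))

  # equal correlations: z = 0, p = 1
  eq <- compare_correlations_dependent(0.4, 0.4, 0.1, 60)
  expect_equal(eq$z, 0)
  expect_equal(eq$p.value, 1)
  # exchanging k and h flips the sign, same p
  sw <- compare_correlations_dependent(0.3, 0.5, 0.2, 100)
  expect_equal(sw$z, -got$z)
  expect_equal(sw$p.value, got$p.value)
  # inadmissible triple
  expect_error(compare_correlations_dependent(0.9, -0.9, 0.9, 50),
               "positive semidefinite")
})

test_that("dependent test approaches the independent one as r_kh -> 0 at large n", {
  dep <- compare_correlations_dependent(0.35, 0.30, 0, 1e4)
  ind <- compare_correlations_independent(0.35, 1e4, 0.30, 1e4)
  expect_lt(abs(dep$p.value - ind$p.value), 0.02)
})

test_that("convergence calling recovers planted shifts and obeys the sign rule", {
  b <- generate_bundle(small_config(seed = 17L))
  aso <- assemble_multi(b$og, names(b$exprs), gene_lengths = b$gene_lengths)
  ax <- ortholog_expression(aso, b$exprs)
  expect_warning(conv <- call_convergent(ax$tpm, ax$design), "skipped")
  truth <- b$truth[match(conv$og_id, b$truth$og_id), ]
  planted <- truth$conv != "none"
  # recovery of the planted convergent fraction within 5 points
  expect_lt(abs(mean(conv$convergent) - mean(planted)), 0.05)
  # planted direction agrees with the fitted per-pair shifts
  up <- conv$convergent & truth$conv == "up"
  shift_cols <- grep("^shift_", names(conv))
  expect_true(all(conv[up, shift_cols] > 0))

  # a sign-inconsistent ortholog is never convergent, however significant:
  # flip one pair's planted shift by editing the monoicous matrix
  g_up <- conv$og_id[up][1]
  gene4 <- aso$mono4[aso$og_id == g_up]
  e4 <- b$exprs$mono4
  e4$tpm[gene4, ] <- e4$tpm[gene4, ] / 2^(2 * truth$conv_shift[truth$og_id == g_up])
  b2 <- b; b2$exprs$mono4 <- e4
  ax2 <- ortholog_expression(aso, b2$exprs)
  conv2 <- suppressWarnings(call_convergent(ax2$tpm, ax2$design))
  expect_false(conv2$convergent[conv2$og_id == g_up])
})

test_that("null convergence data stays at the false-positive level", {
  b <- generate_bundle(small_config(seed = 23L, sex_biased_fraction = 0,
                                    sex_specific_fraction = 0,
                                    sex_linked_fraction = 0,
                                    convergent_fraction = 0))
  aso <- assemble_multi(b$og, names(b$exprs), gene_lengths = b$gene_lengths)
  ax <- ortholog_expression(aso, b$exprs)
  conv <- suppressWarnings(call_convergent(ax$tpm, ax$design))
  expect_lte(mean(conv$convergent), 0.05)
})

test_that("convergence permutation test bounds and observed-zero behaviour", {
  b <- generate_bundle(small_config(seed = 29L, convergent_fraction = 0,
                                    sex_biased_fraction = 0.05))
  aso <- assemble_multi(b$og, names(b$exprs), gene_lengths = b$gene_lengths)
  ax <- ortholog_expression(aso, b$exprs)
  pt <- suppressWarnings(
    convergence_permutation_test(ax$tpm, ax$design, n_perm = 150, seed = 2))
  expect_gte(pt$p.value, 1 / 151)
  expect_lte(pt$p.value, 1)
  if (pt$observed == 0) expect_equal(pt$p.value, 1)
  # planted convergence is detected as an excess over the null
  b2 <- generate_bundle(small_config(seed = 29L))
  ax2 <- ortholog_expression(assemble_multi(b2$og, names(b2$exprs),
                                            gene_lengths = b2$gene_lengths),
                             b2$exprs)
  pt2 <- suppressWarnings(
    convergence_permutation_test(ax2$tpm, ax2$design, n_perm = 150, seed = 2))
  expect_equal(pt2$p.value, 1 / 151)
})

test_that("sample ordination separates systems and reports proper variances", {
  b <- generate_bundle(small_config(seed = 37L))
  aso <- assemble_multi(b$og, names(b$exprs), gene_lengths = b$gene_lengths)
  ax <- ortholog_expression(aso, b$exprs)
  ord <- sample_ordination(ax$tpm, ax$design)
  ve <- ord$var_explained
  expect_true(all(diff(ve) <= 1e-12))
  expect_lte(sum(ve), 1 + 1e-8)
  # a strong planted system effect separates the system centroids
  sc <- ord$scores
  mono <- sc$sexual_system == "monoicous"
  d12 <- sqrt((mean(sc$PC1[mono]) - mean(sc$PC1[!mono]))^2 +
                (mean(sc$PC2[mono]) - mean(sc$PC2[!mono]))^2)
  within <- mean(c(sd(sc$PC1[mono]), sd(sc$PC1[!mono])))
  expect_gt(d12, within)

  # duplicated samples land on coincident points
  tpm2 <- cbind(ax$tpm, dup = ax$tpm[, 1L])
  des2 <- rbind(ax$design, ax$design[1L, ])
  des2$sample_id[nrow(des2)] <- "dup"
  ord2 <- sample_ordination(tpm2, des2)
  p <- ord2$scores
  expect_equal(unlist(p[p$sample_id == "dup", c("PC1", "PC2")]),
               unlist(p[1L, c("PC1", "PC2")]), tolerance = 1e-8,
               ignore_attr = TRUE)
})
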