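# Expressed-gene filtering and sex-biased gene calling within dioicous
# species (plus the phenotype-dimorphism t-test used alongside them).

#' Expressed-gene filter for one (species, sex) group
#'
#' A gene counts as expressed when at least one library of the group has a
#' TPM strictly above the pooled 5th percentile of the TPM distribution
#' across all genes and libraries of that group (linear-interpolation
#' quantile, R type 7).  With a degenerate all-equal matrix the threshold
#' equals the common value and the expressed set is empty (strict
#' inequality).
#'
#' @param expr [expression_matrix()] object.
#' @param sex one of "male", "female", "cosexual".
#' @param percentile percentile of the pooled distribution, default 5.
#' @return list of class `expressed_set`: `species`, `sex`, `threshold`,
#'   `genes` (character vector).
#' @export
expressed_filter <- function(expr, sex, percentile = 5) {
  keep <- expr$design$sex == sex
  if (!any(keep)) fatal("no samples with sex '%s' in species %s", sex,
                        expr$species)
  m <- expr$tpm[, keep, drop = FALSE]
  thr <- stats::quantile(as.vector(m), percentile / 100, type = 7,
                         names = FALSE)
  genes <- rownames(m)[apply(m > thr, 1L, any)]
  structure(list(species = expr$species, sex = sex, threshold = thr,
                 genes = genes), class = "expressed_set")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated front end over `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p values (same order).
#' @export
benjamini_hochberg <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) fatal("p values must lie in [0,1]")
  stats::p.adjust(pvalues, method = "BH")
}

# Pluggable DE engine: rows of matrix a (group 1) vs matrix b (group 2).
de_test <- function(a, b, engine) {
  if (engine == "welch") return(row_welch(a, b))
  grp <- factor(rep(c("g1", "g2"), c(ncol(a), ncol(b))), c("g2", "g1"))
  dm <- stats::model.matrix(~grp)
  fit <- limma::lmFit(cbind(a, b), dm)
  fit <- limma::eBayes(fit, trend = TRUE)
  tt <- fit$t[, 2L]; p <- fit$p.value[, 2L]
  # degenerate rows: moderated t would divide rounding noise by rounding
  # noise when a group difference and residual sd are both exactly zero
  zero <- abs(fit$coefficients[, 2L]) < 1e-9 & fit$sigma < 1e-9
  tt[zero] <- 0; p[zero] <- 1
  list(statistic = tt, p.value = p,
       mean1 = rowMeans(a), mean2 = rowMeans(b))
}

# Vectorized two-sided Welch t-test on the rows of two matrices.
# Zero-variance rows: p = 1 when the means agree (no evidence), p = 0 when
# two exactly constant groups differ (deterministic separation).
row_welch <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- row_var(a); v2 <- row_var(b)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- se2 == 0
  p[zero & m1 == m2] <- 1
  p[zero & m1 != m2] <- 0
  tt[zero] <- 0
  list(statistic = tt, p.value = p, mean1 = m1, mean2 = m2)
}

#' Call sex-biased genes in a dioicous species
#'
#' Genes restricted to the union of the male and female expressed sets are
#' tested male versus female on log2(TPM+1), BH corrected.  The default
#' engine is the moderated t of limma-trend (`limma::lmFit` +
#' `limma::eBayes(trend = TRUE)`), which pools variance information
#' across genes and keeps power at 2-3 replicates per sex;
#' `engine = "welch"` uses an unmoderated per-gene Welch t-test instead.
#' A gene is male-biased (MB) when `padj < alpha` and the
#' male/female ratio of raw mean TPM (each mean floored at `mean_floor`)
#' is at least `fc_min`; female-biased (FB) symmetrically.  Genes in the
#' sex-linked exclusion list are classed `EXCLUDED_SEX_LINKED` regardless
#' and are not tested.  Genes expressed in exactly one sex with
#' `padj < alpha` are `SEX_SPECIFIC_M`/`SEX_SPECIFIC_F`.  The reported
#' `log2fc` is log2 of the floored raw-mean ratio (male over female), so
#' `|log2fc| >= log2(fc_min)` holds for every FB/MB call.
#'
#' @param expr [expression_matrix()] of one dioicous species with >=2
#'   replicates per sex.
#' @param fc_min minimum fold change on raw mean TPM, default 2.
#' @param alpha adjusted-P cutoff, default 0.05.
#' @param exclude character vector of sex-linked gene ids to exclude.
#' @param percentile expressed-filter percentile, default 5.
#' @param mean_floor pseudo-mean floor (TPM) for fold changes, default 0.1.
#' @param engine differential-expression engine, `"moderated"`
#'   (limma-trend, default) or `"welch"`.
#' @return data.frame of class `sex_bias_table`: gene, class, log2fc,
#'   pvalue, padj, mean_female, mean_male, for every gene of the matrix.
#'   `attr(,"expressed")` carries the two expressed sets.
#' @export
call_sex_bias <- function(expr, fc_min = 2, alpha = 0.05,
                          exclude = character(), percentile = 5,
                          mean_floor = 0.1,
                          engine = c("moderated", "welch")) {
  engine <- match.arg(engine)
  des <- expr$design
  for (s in c("male", "female")) {
    if (sum(des$sex == s) < 2L)
      fatal("species %s has <2 %s replicates", expr$species, s)
  }
  ef <- expressed_filter(expr, "female", percentile)
  em <- expressed_filter(expr, "male", percentile)
  universe <- rownames(expr$tpm)
  expressed <- universe[universe %in% union(ef$genes, em$genes)]

  male <- expr$tpm[, des$sex == "male", drop = FALSE]
  female <- expr$tpm[, des$sex == "female", drop = FALSE]
  mean_m <- rowMeans(male); mean_f <- rowMeans(female)
  l2fc <- log2(pmax(mean_m, mean_floor) / pmax(mean_f, mean_floor))

  out <- data.frame(gene = universe, class = "NOT_EXPRESSED",
                    log2fc = l2fc, pvalue = NA_real_, padj = NA_real_,
                    mean_female = mean_f, mean_male = mean_m,
                    stringsAsFactors = FALSE, row.names = NULL)

  is_excl <- universe %in% exclude
  out$class[is_excl] <- "EXCLUDED_SEX_LINKED"

  test_idx <- which(universe %in% expressed & !is_excl)
  if (length(test_idx)) {
    w <- de_test(log2p1(male[test_idx, , drop = FALSE]),
                 log2p1(female[test_idx, , drop = FALSE]), engine)
    out$pvalue[test_idx] <- w$p.value
    out$padj[test_idx] <- benjamini_hochberg(w$p.value)
    g <- universe[test_idx]
    sig <- out$padj[test_idx] < alpha
    in_m <- g %in% em$genes; in_f <- g %in% ef$genes
    ratio_mb <- pmax(mean_m[test_idx], mean_floor) /
      pmax(mean_f[test_idx], mean_floor)
    cls <- rep("UNBIASED", length(g))
    cls[sig & ratio_mb >= fc_min] <- "MB"
    cls[sig & 1 / ratio_mb >= fc_min] <- "FB"
    cls[sig & in_m & !in_f] <- "SEX_SPECIFIC_M"
    cls[sig & in_f & !in_m] <- "SEX_SPECIFIC_F"
    out$class[test_idx] <- cls
  }
  structure(out, expressed = list(female = ef, male = em),
            species = expr$species, alpha = alpha, fc_min = fc_min,
            class = c("sex_bias_table", "data.frame"))
}

#' Summary fractions of sex-biased genes
#'
#' Percentages are computed against the mean of the two sexes' expressed
#' gene counts.  Fold-change strata split calls at ratios of `fc_breaks`
#' (defaults 2 and 15: 2-15 fold versus more than 15 fold).
#'
#' @param table [call_sex_bias()] result.
#' @param fc_breaks stratum boundaries on the fold-change ratio.
#' @return list: `pct_fb`, `pct_mb`, `denominator`, `strata` data.frame.
#' @export
bias_fractions <- function(table, fc_breaks = c(2, 15)) {
  ex <- attr(table, "expressed")
  denom <- mean(c(length(ex$female$genes), length(ex$male$genes)))
  n_fb <- sum(table$class == "FB"); n_mb <- sum(table$class == "MB")
  ratio <- 2^abs(table$log2fc)
  strata <- do.call(rbind, lapply(c("FB", "MB"), function(cl) {
    r <- ratio[table$class == cl]
    data.frame(class = cl,
               fc_2_to_15 = sum(r < fc_breaks[2L]),
               fc_over_15 = sum(r >= fc_breaks[2L]))
  }))
  list(species = attr(table, "species"),
       pct_fb = 100 * n_fb / denom, pct_mb = 100 * n_mb / denom,
       n_fb = n_fb, n_mb = n_mb,
       n_sex_specific = sum(table$class %in%
                              c("SEX_SPECIFIC_F", "SEX_SPECIFIC_M")),
       denominator = denom, strata = strata)
}

#' Two-proportion chi-square test of FB versus MB abundance
#'
#' @param fb,mb counts of female- and male-biased genes.
#' @param n_fb,n_mb their denominators (expressed-gene counts); `n_mb`
#'   defaults to `n_fb`.
#' @return list with `statistic` and `p.value` (two-sided, no continuity
#'   correction).
#' @export
chi2_fb_mb <- function(fb, mb, n_fb, n_mb = n_fb) {
  if (n_fb <= 0 || n_mb <= 0) fatal("zero denominator in chi2_fb_mb")
  ht <- stats::prop.test(c(fb, mb), c(n_fb, n_mb), correct = FALSE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Cell-length sexual-dimorphism t-test
#'
#' Two-sided Welch t-test of female versus male cell lengths of one
#' species; the absolute difference of means (in the units of the input,
#' micrometres) is the phenotypic-dimorphism proxy.  Note the proxy is an
#' absolute difference and therefore scales with the measurement unit.
#'
#' @param phenotypes data.frame from [read_phenotypes()].
#' @param species species label to test.
#' @return list: `difference`, `p.value`, `mean_female`, `mean_male`.
#' @export
dimorphism_ttest <- function(phenotypes, species) {
  d <- phenotypes[phenotypes$species == species, , drop = FALSE]
  f <- d$cell_length[d$sex == "female"]
  m <- d$cell_length[d$sex == "male"]
  if (length(f) < 2L || length(m) < 2L)
    fatal("species %s lacks a measured sex", species)
  if (isTRUE(all.equal(var(c(f, m)), 0)) && mean(f) == mean(m)) {
    return(list(difference = 0, p.value = 1,
                mean_female = mean(f), mean_male = mean(m)))
  }
  ht <- stats::t.test(f, m)
  list(difference = abs(mean(f) - mean(m)), p.value = ht$p.value,
       mean_female = mean(f), mean_male = mean(m))
}
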