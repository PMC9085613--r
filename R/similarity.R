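# Expression-profile similarity between monoicous species and the sexes
# of their dioicous counterparts, formal correlation-difference tests,
# convergence calling across pairs with a permutation null, and sample
# ordination.

#' Mean expression profile of a sample group
#'
#' Per-gene mean of log2(TPM+1) over the replicates of one sex (or all
#' samples).
#'
#' @param expr [expression_matrix()] object.
#' @param sex optional sex label to subset samples.
#' @return named numeric vector (genes).
#' @export
profile_means <- function(expr, sex = NULL) {
  m <- expr$tpm
  if (!is.null(sex)) m <- m[, expr$design$sex == sex, drop = FALSE]
  rowMeans(log2p1(m))
}

#' Pearson similarity index between two expression profiles
#'
#' @param profile_a,profile_b named numeric vectors of log2(TPM+1) means
#'   (e.g. from [profile_means()]), indexed by a shared gene/ortholog key.
#' @param genes subset of >= 3 keys over which to correlate.
#' @return Pearson r, or NA (with a warning) when either profile has zero
#'   variance over the subset.
#' @export
similarity_index <- function(profile_a, profile_b, genes = names(profile_a)) {
  if (length(genes) < 3L) fatal("need >=3 genes for a similarity index")
  a <- profile_a[genes]; b <- profile_b[genes]
  if (anyNA(a) || anyNA(b)) fatal("profiles lack some of the requested genes")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero variance in a profile; similarity undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Compare two independent Pearson correlations (Fisher's z)
#'
#' z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)), two-sided
#' normal p.
#'
#' @param r1,r2 the correlations (|r| < 1).
#' @param n1,n2 their sample sizes (> 3).
#' @return list: r1, r2, n1, n2, z, p.value, method = "fisher_z".
#' @export
compare_correlations_independent <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) fatal("|r| = 1 has an infinite transform")
  if (n1 <= 3 || n2 <= 3) fatal("need n > 3 in both groups")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(r1 = r1, r2 = r2, n1 = n1, n2 = n2, z = z,
       p.value = 2 * stats::pnorm(-abs(z)), method = "fisher_z")
}

#' Compare two dependent overlapping Pearson correlations
#'
#' Dunn & Clark's z for correlations r_jk and r_jh sharing the variable
#' j, with Silver, Hittner & May's modification: the correlation entering
#' the covariance term is the backtransformed mean of the two Fisher-z
#' transforms.  Two-sided normal p.
#'
#' @param r_jk,r_jh the two correlations being compared (share variable j).
#' @param r_kh the correlation between the non-shared variables.
#' @param n sample size (> 3).
#' @return list: z, p.value, method = "dunn_clark_z" plus the inputs.
#' @export
compare_correlations_dependent <- function(r_jk, r_jh, r_kh, n) {
  if (any(abs(c(r_jk, r_jh)) >= 1)) fatal("|r| = 1 has an infinite transform")
  if (n <= 3) fatal("need n > 3")
  R <- matrix(c(1, r_jk, r_jh,
                r_jk, 1, r_kh,
                r_jh, r_kh, 1), 3L, 3L)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    fatal("correlation triple (r_jk, r_jh, r_kh) is not positive semidefinite")
  z1 <- atanh(r_jk); z2 <- atanh(r_jh)
  rm_ <- tanh((z1 + z2) / 2)
  cov_ <- (r_kh * (1 - 2 * rm_^2) - 0.5 * rm_^2 * (1 - 2 * rm_^2 - r_kh^2)) /
    (1 - rm_^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_))
  list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n, z = z,
       p.value = 2 * stats::pnorm(-abs(z)), method = "dunn_clark_z")
}

#' Assemble an ASO ortholog-by-sample TPM matrix
#'
#' Joins the per-species expression matrices along the rows of an ASO
#' (or DSO) ortholog set.  Orthologs missing a species get NA in that
#' species' sample columns.
#'
#' @param oset `ortholog_set` with one gene column per species.
#' @param exprs named list of [expression_matrix()] objects, one per
#'   species of the set.
#' @return list: `tpm` (orthologs x samples matrix), `design` (combined
#'   design rows matching the columns).
#' @export
ortholog_expression <- function(oset, exprs) {
  species <- attr(oset, "species")
  miss <- setdiff(species, names(exprs))
  if (length(miss)) fatal("missing expression matrices for: %s",
                          paste(miss, collapse = ", "))
  blocks <- lapply(species, function(s) {
    e <- exprs[[s]]
    g <- oset[[s]]
    m <- matrix(NA_real_, nrow(oset), ncol(e$tpm),
                dimnames = list(oset$og_id, colnames(e$tpm)))
    ok <- !is.na(g)
    m[ok, ] <- e$tpm[g[ok], , drop = FALSE]
    m
  })
  design <- do.call(rbind, lapply(species, function(s) exprs[[s]]$design))
  list(tpm = do.call(cbind, blocks), design = design)
}

# Per-pair (monoicous - dioicous) log2 mean shifts and the per-ortholog
# t statistic of the sexual-system effect in expression ~ system + pair.
# Used identically for the observed data and for permuted system labels;
# dioicous (and permuted) group means are means of per-sex-group means,
# so cosexual samples relabelled dioicous form their own sex group.
convergence_stats <- function(Y, design) {
  pairs <- sort(unique(design$pair_id))
  sysf <- factor(design$sexual_system, levels = c("dioicous", "monoicous"))
  X <- stats::model.matrix(~ sysf + factor(design$pair_id))
  XtXi <- solve(crossprod(X))
  H <- X %*% XtXi
  B <- Y %*% H                     # coefficients, genes x p
  fit <- B %*% t(X)
  rss <- rowSums((Y - fit)^2)
  dfree <- ncol(Y) - ncol(X)
  sigma2 <- rss / dfree
  se <- sqrt(sigma2 * XtXi[2L, 2L])
  tt <- B[, 2L] / se
  p <- 2 * stats::pt(-abs(tt), dfree)
  p[se == 0 & B[, 2L] == 0] <- 1
  p[se == 0 & B[, 2L] != 0] <- 0
  shifts <- vapply(pairs, function(pr) {
    pd <- design$pair_id == pr
    grp_mono <- pd & design$sexual_system == "monoicous"
    grp_dio <- pd & !grp_mono
    sex_means <- function(sel) {
      sx <- unique(design$sex[sel])
      ms <- vapply(sx, function(s)
        rowMeans(Y[, sel & design$sex == s, drop = FALSE]), numeric(nrow(Y)))
      rowMeans(matrix(ms, nrow = nrow(Y)))
    }
    sex_means(grp_mono) - sex_means(grp_dio)
  }, numeric(nrow(Y)))
  colnames(shifts) <- pairs
  list(pvalue = p, shifts = shifts)
}

#' Call convergent expression changes across species pairs
#'
#' Per-ortholog fixed-effects linear model on log2(TPM+1),
#' `expression ~ sexual_system + pair`, BH-corrected two-sided t-test of
#' the sexual-system effect.  An ortholog is convergent when the adjusted
#' system p is below `alpha` and its per-pair (monoicous - dioicous)
#' log2 mean shifts share one strict sign across all pairs.  The
#' dioicous side of each shift is the mean of the per-sex replicate
#' means.  Orthologs missing data for any pair are skipped with a
#' warning.
#'
#' @param aso_tpm orthologs x samples TPM matrix
#'   (see [ortholog_expression()]); NA marks missing species.
#' @param design combined design rows matching the columns.
#' @param alpha BH-adjusted significance cutoff, default 0.05.
#' @return data.frame: og_id, one `shift_<pair>` column per pair,
#'   system_pvalue, system_padj, convergent.
#' @export
call_convergent <- function(aso_tpm, design, alpha = 0.05) {
  stopifnot(ncol(aso_tpm) == nrow(design))
  if (length(unique(design$pair_id)) < 2L) fatal("need >=2 species pairs")
  complete <- stats::complete.cases(aso_tpm)
  if (any(!complete))
    warning(sprintf("%d ortholog(s) skipped: missing pair data",
                    sum(!complete)))
  Y <- log2p1(aso_tpm[complete, , drop = FALSE])
  cs <- convergence_stats(Y, design)
  padj <- benjamini_hochberg(cs$pvalue)
  sgn <- sign(cs$shifts)
  consistent <- rowSums(sgn > 0) == ncol(sgn) | rowSums(sgn < 0) == ncol(sgn)
  out <- data.frame(og_id = rownames(Y), stringsAsFactors = FALSE,
                    row.names = NULL)
  for (pr in colnames(cs$shifts)) out[[paste0("shift_", pr)]] <- cs$shifts[, pr]
  out$system_pvalue <- cs$pvalue
  out$system_padj <- padj
  out$convergent <- padj < alpha & consistent
  out
}

count_convergent <- function(Y, design, alpha) {
  cs <- convergence_stats(Y, design)
  padj <- benjamini_hochberg(cs$pvalue)
  sgn <- sign(cs$shifts)
  consistent <- rowSums(sgn > 0) == ncol(sgn) | rowSums(sgn < 0) == ncol(sgn)
  sum(padj < alpha & consistent)
}

#' Permutation test of the number of convergent orthologs
#'
#' Permutes the sexual-system label assignment among samples
#' independently within each pair, recomputes the convergent-ortholog
#' count with the identical calling machinery, and reports
#' p = (1 + #\{count* >= count_obs\}) / (n_perm + 1).
#'
#' @inheritParams call_convergent
#' @param n_perm number of permutations, default 1e5.
#' @param seed integer seed.
#' @return list: `observed`, `p.value`, `n_perm`, `null_counts`.
#' @export
convergence_permutation_test <- function(aso_tpm, design, alpha = 0.05,
                                         n_perm = 1e5, seed = NULL) {
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p value")
  complete <- stats::complete.cases(aso_tpm)
  Y <- log2p1(aso_tpm[complete, , drop = FALSE])
  obs <- count_convergent(Y, design, alpha)
  if (!is.null(seed)) set.seed(seed)
  pairs <- unique(design$pair_id)
  counts <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    d2 <- design
    for (pr in pairs) {
      ix <- which(design$pair_id == pr)
      d2$sexual_system[ix] <- design$sexual_system[ix][sample.int(length(ix))]
    }
    counts[i] <- count_convergent(Y, d2, alpha)
  }
  list(observed = obs, p.value = (1 + sum(counts >= obs)) / (n_perm + 1),
       n_perm = n_perm, null_counts = counts)
}

#' Principal-component ordination of samples
#'
#' Centred, per-gene unit-scaled PCA of log2(TPM+1) over complete
#' orthologs; constant genes are dropped (count reported).
#'
#' @param aso_tpm orthologs x samples TPM matrix.
#' @param design matching design rows.
#' @return list: `scores` (samples x PCs data.frame with design columns),
#'   `var_explained` (fraction per axis), `n_dropped` constant/incomplete
#'   genes dropped.
#' @export
sample_ordination <- function(aso_tpm, design) {
  if (ncol(aso_tpm) < 3L) fatal("need >=3 samples")
  Y <- log2p1(aso_tpm[stats::complete.cases(aso_tpm), , drop = FALSE])
  keep <- row_var(Y) > 0
  n_dropped <- nrow(aso_tpm) - sum(keep)
  pc <- stats::prcomp(t(Y[keep, , drop = FALSE]), center = TRUE,
                      scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(design, pc$x[, seq_len(min(4L, ncol(pc$x))),
                                    drop = FALSE],
                       stringsAsFactors = FALSE, row.names = NULL)
  list(scores = scores, var_explained = ve, n_dropped = n_dropped)
}
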