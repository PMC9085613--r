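# The delta-X directional-selection statistic for expression shifts
# between a dioicous sex and its monoicous counterpart, and the Fisher
# enrichment machinery around it.
#
# delta-X = d / r with
#   d = (mean X_dio - mean X_mono) / mean X_dio
#   r = (max X_dio - min X_dio)   / mean X_dio
# computed on TPM.  Only the dioicous replicates enter r: the spread of
# the monoicous replicates is deliberately ignored by the statistic.
# Positive d (monoicous below dioicous) reads as "down in monoicous".

#' Compute delta-X for one ortholog
#'
#' @param dio_reps numeric vector of >=2 dioicous replicate TPMs (one sex).
#' @param mono_reps numeric vector of >=1 monoicous replicate TPMs.
#' @param og_id optional ortholog label.
#' @param context `"vs_female"` or `"vs_male"` — which dioicous sex the
#'   contrast uses.
#' @return one-row data.frame: og_id, context, d, r, delta_x, fc.
#'   `delta_x` is NA when the dioicous replicates have zero range (r = 0)
#'   or zero mean; `fc` is the max/min ratio of the two species' mean
#'   TPMs (Inf when one mean is 0).
#' @export
delta_x <- function(dio_reps, mono_reps, og_id = NA_character_,
                    context = c("vs_female", "vs_male")) {
  context <- match.arg(context)
  if (length(dio_reps) < 2L) fatal("need >=2 dioicous replicates")
  if (length(mono_reps) < 1L) fatal("need >=1 monoicous replicate")
  md <- mean(dio_reps); mm <- mean(mono_reps)
  if (md <= 0) {
    return(data.frame(og_id = og_id, context = context, d = NA_real_,
                      r = NA_real_, delta_x = NA_real_, fc = NA_real_,
                      stringsAsFactors = FALSE))
  }
  d <- (md - mm) / md
  r <- (max(dio_reps) - min(dio_reps)) / md
  dx <- if (r > 0) d / r else NA_real_
  fc <- if (min(md, mm) > 0) max(md, mm) / min(md, mm) else Inf
  data.frame(og_id = og_id, context = context, d = d, r = r,
             delta_x = dx, fc = fc, stringsAsFactors = FALSE)
}

#' Compute delta-X across a PSO set
#'
#' Vectorized form of [delta_x()] over the rows of a pairwise ortholog
#' set, contrasting one dioicous sex against the monoicous replicates.
#'
#' @param expr_dio,expr_mono [expression_matrix()] objects of the
#'   dioicous and monoicous species of one pair.
#' @param pso `ortholog_set` of kind PSO for those two species.
#' @param sex dioicous sex for the contrast ("female" or "male").
#' @return data.frame with one [delta_x()] row per ortholog.
#' @export
delta_x_table <- function(expr_dio, expr_mono, pso, sex = c("female", "male")) {
  sex <- match.arg(sex)
  context <- paste0("vs_", sex)
  gd <- pso[[expr_dio$species]]; gm <- pso[[expr_mono$species]]
  dio <- expr_dio$tpm[gd, expr_dio$design$sex == sex, drop = FALSE]
  mono <- expr_mono$tpm[gm, , drop = FALSE]
  md <- rowMeans(dio); mm <- rowMeans(mono)
  d <- (md - mm) / md
  r <- (apply(dio, 1L, max) - apply(dio, 1L, min)) / md
  dx <- ifelse(r > 0, d / r, NA_real_)
  lo <- pmin(md, mm); hi <- pmax(md, mm)
  fc <- ifelse(lo > 0, hi / lo, Inf)
  bad <- md <= 0
  d[bad] <- r[bad] <- dx[bad] <- fc[bad] <- NA_real_
  data.frame(og_id = pso$og_id, context = context, d = d, r = r,
             delta_x = dx, fc = fc, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Classify evolutionary expression shifts
#'
#' An ortholog has a significant shift when `|delta_x| > dx_min` and the
#' between-species mean-TPM fold change is at least `fc_min`.  Direction:
#' d > 0 means the gene is downregulated in the monoicous species.
#'
#' @param records data.frame of [delta_x()]/[delta_x_table()] rows.
#' @param dx_min strict threshold on |delta-X|, default 1.
#' @param fc_min minimum fold change (inclusive), default 1.5.
#' @return the records with added `shifted` (logical; FALSE when delta-X
#'   is undefined) and `direction` ("down"/"up" in the monoicous species,
#'   NA when unshifted).
#' @export
classify_shift <- function(records, dx_min = 1, fc_min = 1.5) {
  shifted <- !is.na(records$delta_x) & abs(records$delta_x) > dx_min &
    records$fc >= fc_min
  records$shifted <- shifted
  records$direction <- ifelse(shifted, ifelse(records$d > 0, "down", "up"),
                              NA_character_)
  records
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test (two-sided p = sum of tables, at the fixed
#' margins, whose point probability does not exceed the observed one),
#' via `stats::fisher.test`.  Rows are groups, columns outcome.
#'
#' @param a,b first group: count with / without the outcome.
#' @param c,d second group: count with / without the outcome.
#' @return list: `p.value`, `odds_ratio` (sample a*d/(b*c)),
#'   `odds_ratio_cmle` (conditional MLE).  A zero margin returns p = 1
#'   with a warning.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != round(x))) fatal("counts must be non-negative integers")
  m <- matrix(x, 2L, 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("zero margin in 2x2 table; p = 1")
    return(list(p.value = 1, odds_ratio = NA_real_,
                odds_ratio_cmle = NA_real_))
  }
  ht <- stats::fisher.test(m, alternative = "two.sided")
  list(p.value = ht$p.value, odds_ratio = (a * d) / (b * c),
       odds_ratio_cmle = unname(ht$estimate))
}

#' Per-class enrichment of delta-X shifts
#'
#' For FB and MB separately, tests with a 2x2 Fisher exact test whether
#' the class contains more shifted orthologs (per [classify_shift()])
#' than the unbiased class, and reports shifted fractions split by
#' direction.
#'
#' @param classes data.frame with columns `og_id` and `class`
#'   (FB/MB/UNBIASED; other classes are ignored).
#' @param records classified delta-X records (with `shifted`, `direction`).
#' @return data.frame, one row per class in (FB, MB): counts, fractions
#'   up/down, odds ratio and p versus unbiased.  Classes with no
#'   orthologs give an NA row.
#' @export
shift_enrichment <- function(classes, records) {
  m <- merge(records, classes, by = "og_id")
  m <- m[!is.na(m$delta_x) & !is.na(m$class), , drop = FALSE]
  unb <- m[m$class == "UNBIASED", , drop = FALSE]
  do.call(rbind, lapply(c("FB", "MB"), function(cl) {
    sub <- m[m$class == cl, , drop = FALSE]
    if (nrow(sub) == 0L || nrow(unb) == 0L) {
      return(data.frame(class = cl, n = nrow(sub), n_shifted = NA_integer_,
                        frac_shifted = NA_real_, frac_up = NA_real_,
                        frac_down = NA_real_, odds_ratio = NA_real_,
                        p.value = NA_real_))
    }
    ns <- sum(sub$shifted); nu <- sum(unb$shifted)
    ft <- fisher_exact_2x2(ns, nrow(sub) - ns, nu, nrow(unb) - nu)
    data.frame(class = cl, n = nrow(sub), n_shifted = ns,
               frac_shifted = ns / nrow(sub),
               frac_up = sum(sub$shifted & sub$direction == "up") / nrow(sub),
               frac_down = sum(sub$shifted & sub$direction == "down") / nrow(sub),
               odds_ratio = ft$odds_ratio, p.value = ft$p.value)
  }))
}
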