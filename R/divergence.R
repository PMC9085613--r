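# Pairwise coding-sequence divergence: Nei-Gojobori (1986) counting of
# synonymous and nonsynonymous sites and differences with equal-weight
# pathway averaging for multi-hit codons, Jukes-Cantor correction, the
# 0 < dS < 2 validity filter, and class-wise permutation t-tests.

# standard genetic code, written out rather than derived, so the test
# suite can cross-check it against an independent source
GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

SENSE_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]

NUCS <- c("A", "C", "G", "T")

.ng86 <- new.env(parent = emptyenv())

codon_neighbours <- function(codon) {
  out <- character(9L)
  k <- 0L
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      k <- k + 1L
      out[k] <- alt
    }
  }
  out
}

#' Nei-Gojobori synonymous/nonsynonymous site counts of a codon
#'
#' Each of the three positions contributes the fraction of its three
#' single-nucleotide changes that are synonymous; the two counts always
#' sum to exactly 3.  Changes into stop codons count as nonsynonymous.
#'
#' @param codon a sense codon over ACGT.
#' @return named numeric vector `c(S = ..., N = ...)`.
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  if (!codon %in% SENSE_CODONS)
    fatal("'%s' is not a sense codon over ACGT", codon)
  aa <- GENETIC_CODE_STD[[codon]]
  nb <- codon_neighbours(codon)
  syn <- sum(GENETIC_CODE_STD[nb] == aa)   # stops never match a sense aa
  c(S = syn / 3, N = 3 - syn / 3)
}

# Equal-weight pathway averaging of synonymous/nonsynonymous differences
# between two sense codons.  Pathways passing through a stop codon are
# excluded from the average; if every pathway is blocked, all pathways
# are used with the steps into/out of stops counted as nonsynonymous.
codon_path_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  ndiff <- length(pos)
  if (ndiff == 0L) return(c(sd = 0, nd = 0))
  orders <- if (ndiff == 1L) matrix(pos, 1L) else
    matrix(pos[perms(ndiff)], ncol = ndiff)
  step_class <- function(a, b) {
    if (GENETIC_CODE_STD[[b]] == "*" || GENETIC_CODE_STD[[a]] == "*")
      return(c(0, 1, TRUE))                 # through-stop step, nonsyn
    if (GENETIC_CODE_STD[[a]] == GENETIC_CODE_STD[[b]]) c(1, 0, FALSE)
    else c(0, 1, FALSE)
  }
  res <- matrix(0, nrow(orders), 3L)
  for (i in seq_len(nrow(orders))) {
    cur <- c1
    for (p in orders[i, ]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      st <- step_class(cur, nxt)
      res[i, 1:2] <- res[i, 1:2] + st[1:2]
      res[i, 3L] <- max(res[i, 3L], st[3L])
      cur <- nxt
    }
  }
  ok <- res[, 3L] == 0
  use <- if (any(ok)) res[ok, , drop = FALSE] else res
  c(sd = mean(use[, 1L]), nd = mean(use[, 2L]))
}

perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L))
  p <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, p + (p >= i))
  }))
}

# cached 64x64 pathway-difference matrices and per-codon site counts
ng86_tables <- function() {
  if (!is.null(.ng86$sd)) return(invisible(NULL))
  nc <- length(SENSE_CODONS)
  sdm <- ndm <- matrix(NA_real_, nc, nc,
                       dimnames = list(SENSE_CODONS, SENSE_CODONS))
  for (i in seq_len(nc)) {
    for (j in i:nc) {
      d <- codon_path_diffs(SENSE_CODONS[i], SENSE_CODONS[j])
      sdm[i, j] <- sdm[j, i] <- d[["sd"]]
      ndm[i, j] <- ndm[j, i] <- d[["nd"]]
    }
  }
  .ng86$sd <- sdm
  .ng86$nd <- ndm
  .ng86$S <- vapply(SENSE_CODONS, function(cd) ng86_sites(cd)[["S"]],
                    numeric(1L))
  invisible(NULL)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
}

jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Pairwise NG86 divergence of an aligned codon sequence pair
#'
#' Codon columns containing a gap, an ambiguous character, or a stop
#' codon in either sequence are dropped.  Site counts are averaged over
#' the two sequences, differences are pathway-averaged, and proportions
#' are Jukes-Cantor corrected.  A record is valid when both corrections
#' are defined and 0 < dS < 2.
#'
#' @param seq_a,seq_b equal-length aligned coding sequences (length a
#'   multiple of 3).
#' @param og_id optional ortholog label.
#' @return one-row data.frame: og_id, n_codons, S, N, sd, nd, ps, pn,
#'   ds, dn, omega, valid.
#' @export
ng86_pair <- function(seq_a, seq_b, og_id = NA_character_) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) fatal("sequences must be aligned")
  if (nchar(seq_a) %% 3L != 0L) fatal("length not divisible by 3")
  ng86_tables()
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  keep <- ca %in% SENSE_CODONS & cb %in% SENSE_CODONS
  ca <- ca[keep]; cb <- cb[keep]
  rec <- data.frame(og_id = og_id, n_codons = length(ca), S = NA_real_,
                    N = NA_real_, sd = NA_real_, nd = NA_real_,
                    ps = NA_real_, pn = NA_real_, ds = NA_real_,
                    dn = NA_real_, omega = NA_real_, valid = FALSE,
                    stringsAsFactors = FALSE)
  if (length(ca) == 0L) return(rec)
  S <- (sum(.ng86$S[ca]) + sum(.ng86$S[cb])) / 2
  N <- 3 * length(ca) - S
  idx <- cbind(match(ca, SENSE_CODONS), match(cb, SENSE_CODONS))
  sd_tot <- sum(.ng86$sd[idx]); nd_tot <- sum(.ng86$nd[idx])
  rec$S <- S; rec$N <- N; rec$sd <- sd_tot; rec$nd <- nd_tot
  if (S <= 0) return(rec)
  rec$ps <- sd_tot / S; rec$pn <- nd_tot / N
  rec$ds <- jc_correct(rec$ps); rec$dn <- jc_correct(rec$pn)
  if (!is.na(rec$ds) && rec$ds > 0 && !is.na(rec$dn))
    rec$omega <- rec$dn / rec$ds
  rec$valid <- !is.na(rec$ds) && !is.na(rec$dn) && rec$ds > 0 && rec$ds < 2
  rec
}

#' Filter divergence records by dS validity
#'
#' @param records data.frame of [ng86_pair()] rows.
#' @param lo,hi strict bounds on dS, defaults 0 and 2.
#' @return the subset with `lo < dS < hi` (undefined dS excluded).
#' @export
ds_filter <- function(records, lo = 0, hi = 2) {
  keep <- !is.na(records$ds) & records$ds > lo & records$ds < hi &
    !is.na(records$dn)
  records[keep, , drop = FALSE]
}

welch_stat <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  den <- sqrt(vx + vy)
  if (den == 0) return(if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y)))
  (mean(x) - mean(y)) / den
}

#' Permutation t-test (Welch statistic, label permutation)
#'
#' Two-sided test of equal means: group labels are permuted and the
#' absolute Welch t statistic compared with the observed one.  When the
#' number of distinct label splits `choose(n, nA)` does not exceed
#' `n_perm` all splits are enumerated and the p value is exact; otherwise
#' `n_perm` random permutations give p = (1 + #{|t*| >= |t|}) / (n_perm + 1).
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param n_perm permutation budget, default 1e5.
#' @param seed optional integer seed for the random mode.
#' @return list: `p.value`, `statistic`, `n_perm`, `exact`.
#' @export
permutation_t_test <- function(x, y, n_perm = 1e5, seed = NULL) {
  if (length(x) < 2L || length(y) < 2L) fatal("each group needs >=2 values")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p value")
  pooled <- c(x, y)
  if (var(pooled) == 0) return(list(p.value = 1, statistic = 0,
                                    n_perm = 0L, exact = TRUE))
  nx <- length(x); n <- length(pooled)
  t_obs <- abs(welch_stat(x, y))
  tol <- 1e-12 * max(1, t_obs)
  n_splits <- choose(n, nx)
  if (n_splits <= n_perm) {
    splits <- utils::combn(n, nx)
    tp <- apply(splits, 2L, function(ix)
      abs(welch_stat(pooled[ix], pooled[-ix])))
    p <- sum(tp >= t_obs - tol) / n_splits
    return(list(p.value = p, statistic = t_obs, n_perm = n_splits,
                exact = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    ix <- sample.int(n, nx)
    if (abs(welch_stat(pooled[ix], pooled[-ix])) >= t_obs - tol)
      hits <- hits + 1L
  }
  list(p.value = (1 + hits) / (n_perm + 1), statistic = t_obs,
       n_perm = n_perm, exact = FALSE)
}

#' Class-wise divergence summary with permutation tests
#'
#' Joins valid divergence records to FB/MB/UNBIASED gene classes (after
#' removing orthologs whose sex bias is inconsistent across species, when
#' such an exclusion list is supplied) and reports per-class mean and
#' median omega plus pairwise permutation-t p values.
#'
#' @param records [ng86_pair()] rows with an `og_id` column.
#' @param classes data.frame with `og_id` and `class`.
#' @param exclude og_ids to drop (cross-species inconsistent bias).
#' @param n_perm permutations per pairwise test.
#' @param seed integer seed.
#' @return list: `summary` data.frame (class, n, mean/median omega) and
#'   `tests` data.frame (pairwise permutation p values; NA when a class
#'   is empty).
#' @export
class_divergence_report <- function(records, classes, exclude = character(),
                                    n_perm = 1e4, seed = NULL) {
  recs <- ds_filter(records)
  recs <- recs[!(recs$og_id %in% exclude), , drop = FALSE]
  m <- merge(recs, classes, by = "og_id")
  m <- m[m$class %in% c("FB", "MB", "UNBIASED") & !is.na(m$omega), ,
         drop = FALSE]
  cls <- c("FB", "MB", "UNBIASED")
  summ <- do.call(rbind, lapply(cls, function(cl) {
    w <- m$omega[m$class == cl]
    data.frame(class = cl, n = length(w),
               mean_omega = if (length(w)) mean(w) else NA_real_,
               median_omega = if (length(w)) stats::median(w) else NA_real_)
  }))
  pairs <- utils::combn(cls, 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- m$omega[m$class == pairs[1L, i]]
    b <- m$omega[m$class == pairs[2L, i]]
    p <- if (length(a) >= 2L && length(b) >= 2L)
      permutation_t_test(a, b, n_perm = n_perm, seed = seed)$p.value
    else NA_real_
    data.frame(class_a = pairs[1L, i], class_b = pairs[2L, i], p.value = p)
  }))
  list(summary = summ, tests = tests)
}
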