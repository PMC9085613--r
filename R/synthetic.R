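# Seeded synthetic-data generator: emits a complete input bundle
# (expression matrices, design, orthogroups, species tree, codon
# alignments, phenotypes, sex-linked exclusion lists) with planted
# ground truth, emulating the statistical structure of a four-pair
# dioicous/monoicous comparative RNA-seq design.
#
# Expression model, all on log2 scale: each orthogroup has a lognormal
# baseline shared across species plus a per-(orthogroup, pair) offset;
# the female mean is the baseline, the male mean adds the planted
# sex-bias effect, and the monoicous mean is the female mean shifted by
# the planted convergent effect (monoicy-from-ancestral-females).
# Replicate values are mean * 2^N(0, noise_log2_sd).

#' Configuration of the synthetic-data generator
#'
#' Defaults encode the emulated study conditions: four
#' dioicous-monoicous pairs, 3 replicates per sample group (one pair has
#' 2), replicate noise giving log-scale replicate concordance r^2 of
#' about 0.94 (within the 0.89-0.99 band), per-species sex-biased
#' fractions spanning 13-33% with >= 2-fold heavy-tailed effects, a 61%
#' convergent fraction of orthologs with shifts of at least 1.5 log2
#' units, and class-dependent omega (MB > unbiased >= FB) with target dS
#' inside (0, 2).
#'
#' @param n_pairs number of species pairs (2-4 supported by the tree).
#' @param genes_per_species number of core orthologous genes.
#' @param replicates per-pair replicate count, recycled.
#' @param baseline_log2_mean,baseline_log2_sd lognormal baseline of mean
#'   TPM (log2 scale).
#' @param pair_offset_sd per-(orthogroup, pair) expression offset sd.
#' @param noise_log2_sd replicate noise sd (log2).
#' @param sex_biased_fraction per-dioicous-species fraction of genes
#'   planted FB or MB, recycled.
#' @param mb_fb_ratio ratio of MB to FB planted genes.
#' @param effect_min,effect_exp_mean sex-bias |log2FC| = effect_min +
#'   Exp(mean = effect_exp_mean).
#' @param sex_specific_fraction fraction of genes expressed in one sex
#'   only (not sex-linked).
#' @param sex_linked_fraction fraction of single-sex genes that are
#'   DNA-backed sex-linked (planted AND listed in the exclusion list).
#' @param convergent_fraction fraction of orthogroups with a shared-sign
#'   monoicous shift across every pair.
#' @param conv_shift_min,conv_shift_exp_mean convergent |log2 shift| =
#'   conv_shift_min + Exp(mean = conv_shift_exp_mean).
#' @param loss_fraction fraction of orthogroups missing in one species.
#' @param dup_fraction fraction with a duplicate in one species.
#' @param messy_fraction fraction with patterns excluded by the
#'   single-copy rules (two species missing, or three copies).
#' @param dup_cov_range range of the duplicate aligned-coverage fraction.
#' @param omega_fb,omega_unb,omega_mb planted dN/dS per bias class.
#' @param ds_range range of the target synonymous divergence.
#' @param n_divergence codon alignments simulated per pair.
#' @param n_codons codons per simulated alignment.
#' @param phenotype_cells measured cells per (species, sex).
#' @param seed integer seed fixing every byte of the bundle.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pairs = 4L,
                             genes_per_species = 3000L,
                             replicates = c(3L, 2L, 3L, 3L),
                             baseline_log2_mean = 4,
                             baseline_log2_sd = 2,
                             pair_offset_sd = 0.5,
                             noise_log2_sd = 0.2,
                             sex_biased_fraction = c(0.13, 0.20, 0.26, 0.33),
                             mb_fb_ratio = 1,
                             effect_min = 1.25,
                             effect_exp_mean = 0.8,
                             sex_specific_fraction = 0.02,
                             sex_linked_fraction = 0.01,
                             convergent_fraction = 0.61,
                             conv_shift_min = 1.5,
                             conv_shift_exp_mean = 0.5,
                             loss_fraction = 0.20,
                             dup_fraction = 0.08,
                             messy_fraction = 0.04,
                             dup_cov_range = c(0.3, 1),
                             omega_fb = 0.2,
                             omega_unb = 0.3,
                             omega_mb = 0.8,
                             ds_range = c(0.1, 1.2),
                             n_divergence = 300L,
                             n_codons = 150L,
                             phenotype_cells = 30L,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (n_pairs < 2L || n_pairs > 4L) fatal("n_pairs must be 2..4")
  fr <- c(sex_biased_fraction, sex_specific_fraction, sex_linked_fraction,
          convergent_fraction, loss_fraction, dup_fraction, messy_fraction)
  if (any(fr < 0 | fr > 1)) fatal("fractions must lie in [0,1]")
  if (loss_fraction + dup_fraction + messy_fraction >= 1)
    fatal("orthogroup pattern fractions must sum to < 1")
  if (any(sex_biased_fraction + sex_specific_fraction + sex_linked_fraction > 1))
    fatal("per-species class fractions exceed 1")
  if (baseline_log2_sd <= 0 || noise_log2_sd <= 0) fatal("sd must be > 0")
  if (any(ds_range <= 0) || any(ds_range >= 2)) fatal("ds_range must be inside (0,2)")
  cfg$replicates <- rep_len(as.integer(replicates), n_pairs)
  cfg$sex_biased_fraction <- rep_len(sex_biased_fraction, n_pairs)
  structure(cfg, class = "synthetic_config")
}

#' Species tree of the emulated clades
#'
#' Rooted ultrametric binary tree with one cherry per
#' dioicous-monoicous pair: root age 200 (millions of years), pair-split
#' ages spanning 20-88, internal joins between 120 and 200.
#'
#' @param config [synthetic_config()] (only `n_pairs` is used).
#' @return `phylo` tree with tips `dio1..dioK`, `mono1..monoK`.
#' @export
generate_tree <- function(config) {
  k <- config$n_pairs
  split_age <- seq(20, 88, length.out = k)
  join_age <- rev(seq(200, 120, length.out = k - 1L))
  nwk <- sprintf("(dio1:%g,mono1:%g)", split_age[1L], split_age[1L])
  depth <- split_age[1L]
  for (i in seq_len(k - 1L)) {
    cherry <- sprintf("(dio%d:%g,mono%d:%g)", i + 1L, split_age[i + 1L],
                      i + 1L, split_age[i + 1L])
    nwk <- sprintf("(%s:%g,%s:%g)", nwk, join_age[i] - depth, cherry,
                   join_age[i] - split_age[i + 1L])
    depth <- join_age[i]
  }
  validate_tree(ape::read.tree(text = paste0(nwk, ";")))
}

#' Generate a synthetic input bundle with planted ground truth
#'
#' See [synthetic_config()] for the planted structure.  The same seed
#' always produces a byte-identical bundle.
#'
#' @param config [synthetic_config()].
#' @param out_dir optional directory: when given, every file the package
#'   readers consume is written there (TSV matrices and design,
#'   orthogroup table, Newick tree, per-pair codon FASTA alignments,
#'   phenotype table, per-species exclusion lists, gene lengths, truth
#'   tables).
#' @return list of class `synthetic_bundle`: `config`, `design`
#'   (combined), `exprs` (named list of [expression_matrix()]), `og`
#'   (orthogroup_table), `tree`, `alignments` (per pair: named list of
#'   2-sequence character vectors), `phenotypes`, `exclude` (named list
#'   of sex-linked gene ids per dioicous species), `gene_lengths`,
#'   `truth` (orthogroup-level planted classes) and `truth_alignments`.
#' @export
generate_bundle <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  k <- config$n_pairs
  ng <- config$genes_per_species
  dio <- paste0("dio", seq_len(k)); mono <- paste0("mono", seq_len(k))
  pair_ids <- paste0("pair", seq_len(k))
  species <- c(rbind(dio, mono))
  og_ids <- sprintf("OG%05d", seq_len(ng))

  # --- orthogroup patterns ------------------------------------------------
  pat <- sample(c("complete", "loss", "dup", "messy"), ng, replace = TRUE,
                prob = c(1 - config$loss_fraction - config$dup_fraction -
                           config$messy_fraction,
                         config$loss_fraction, config$dup_fraction,
                         config$messy_fraction))
  pat_sp <- sample(species, ng, replace = TRUE)      # species hit by loss/dup
  dup_cov <- runif(ng, config$dup_cov_range[1L], config$dup_cov_range[2L])
  messy_kind <- sample(c("two_missing", "triple"), ng, replace = TRUE)

  # --- planted expression truth ------------------------------------------
  base <- rnorm(ng, config$baseline_log2_mean, config$baseline_log2_sd)
  pair_off <- matrix(rnorm(ng * k, 0, config$pair_offset_sd), ng, k,
                     dimnames = list(og_ids, pair_ids))

  # convergent status is drawn first: single-sex (sex-specific and
  # sex-linked) genes are planted only on non-convergent orthogroups,
  # because a multiplicative monoicous shift of a female-silent gene is
  # not realizable in the emitted matrices
  conv <- sample(c("none", "up", "down"), ng, replace = TRUE,
                 prob = c(1 - config$convergent_fraction,
                          config$convergent_fraction / 2,
                          config$convergent_fraction / 2))
  conv_mag <- config$conv_shift_min + rexp(ng, 1 / config$conv_shift_exp_mean)
  conv_shift <- ifelse(conv == "none", 0,
                       ifelse(conv == "up", conv_mag, -conv_mag))

  class_mat <- matrix("UNBIASED", ng, k,
                      dimnames = list(og_ids, dio))   # class in each dio sp.
  effect <- matrix(0, ng, k)
  for (j in seq_len(k)) {
    frac_b <- config$sex_biased_fraction[j]
    n_b <- round(frac_b * ng)
    n_ss <- round(config$sex_specific_fraction * ng)
    n_sl <- round(config$sex_linked_fraction * ng)
    bias <- sample.int(ng, n_b)
    eligible <- setdiff(which(conv == "none"), bias)
    if (length(eligible) < n_ss + n_sl)
      fatal("config infeasible: not enough non-convergent orthogroups for single-sex genes")
    single <- sample(eligible, n_ss + n_sl)
    ss <- single[seq_len(n_ss)]
    sl <- single[n_ss + seq_len(n_sl)]
    n_mb <- round(n_b * config$mb_fb_ratio / (1 + config$mb_fb_ratio))
    class_mat[bias[seq_len(n_mb)], j] <- "MB"
    class_mat[bias[-seq_len(n_mb)], j] <- "FB"
    class_mat[ss, j] <- sample(c("SEX_SPECIFIC_F", "SEX_SPECIFIC_M"),
                               length(ss), replace = TRUE)
    class_mat[sl, j] <- sample(c("SEX_LINKED_F", "SEX_LINKED_M"),
                               length(sl), replace = TRUE)
    effect[, j] <- (config$effect_min +
                      rexp(ng, 1 / config$effect_exp_mean))
  }

  # --- per-species mean TPMs ---------------------------------------------
  # female mean (log2): baseline + pair offset; male adds the effect;
  # monoicous = female + convergent shift.  Single-sex classes zero the
  # silent sex.
  mean_f <- mean_m <- matrix(NA_real_, ng, k)
  for (j in seq_len(k)) {
    f <- 2^(base + pair_off[, j])
    m <- f
    cl <- class_mat[, j]
    m[cl == "MB"] <- f[cl == "MB"] * 2^effect[cl == "MB", j]
    m[cl == "FB"] <- f[cl == "FB"] * 2^-effect[cl == "FB", j]
    m[cl %in% c("SEX_SPECIFIC_F", "SEX_LINKED_F")] <- 0
    f[cl %in% c("SEX_SPECIFIC_M", "SEX_LINKED_M")] <- 0
    mean_f[, j] <- f; mean_m[, j] <- m
  }
  mean_mono <- mean_f * matrix(2^conv_shift, ng, k)

  # --- sample design ------------------------------------------------------
  design <- do.call(rbind, lapply(seq_len(k), function(j) {
    reps <- config$replicates[j]
    rbind(
      data.frame(sample_id = sprintf("%s_%s_r%d", dio[j],
                                     rep(c("M", "F"), each = reps),
                                     rep(seq_len(reps), 2L)),
                 species = dio[j], pair_id = pair_ids[j],
                 sexual_system = "dioicous",
                 sex = rep(c("male", "female"), each = reps),
                 replicate = rep(seq_len(reps), 2L),
                 stringsAsFactors = FALSE),
      data.frame(sample_id = sprintf("%s_C_r%d", mono[j], seq_len(reps)),
                 species = mono[j], pair_id = pair_ids[j],
                 sexual_system = "monoicous", sex = "cosexual",
                 replicate = seq_len(reps), stringsAsFactors = FALSE))
  }))
  validate_design(design)

  # --- expression matrices ------------------------------------------------
  noisy <- function(mu, n) {
    m <- matrix(rep(mu, n), length(mu), n)
    m * 2^matrix(rnorm(length(mu) * n, 0, config$noise_log2_sd),
                 length(mu), n)
  }
  gene_id <- function(sp) paste0(sp, "_g", sprintf("%05d", seq_len(ng)))
  gene_names <- setNames(lapply(species, gene_id), species)

  # genes present per species: core minus losses (duplicates appended)
  lost <- lapply(setNames(species, species), function(sp) {
    l <- which(pat == "loss" & pat_sp == sp)
    if (any(pat == "messy")) {
      mm <- which(pat == "messy" & messy_kind == "two_missing")
      # two species missing: the designated one and its clockwise neighbour
      nxt <- species[(match(pat_sp[mm], species) %% length(species)) + 1L]
      l <- union(l, c(mm[pat_sp[mm] == sp], mm[nxt == sp]))
    }
    sort(l)
  })
  dup_rows <- lapply(setNames(species, species), function(sp) {
    d <- which(pat == "dup" & pat_sp == sp)
    t3 <- which(pat == "messy" & messy_kind == "triple" & pat_sp == sp)
    list(dup = d, triple = t3)
  })

  exprs <- list(); exclude <- list()
  for (j in seq_len(k)) {
    reps <- config$replicates[j]
    for (side in c("dio", "mono")) {
      sp <- if (side == "dio") dio[j] else mono[j]
      keep <- setdiff(seq_len(ng), lost[[sp]])
      ids <- gene_names[[sp]][keep]
      if (side == "dio") {
        m_m <- noisy(mean_m[keep, j], reps)
        m_f <- noisy(mean_f[keep, j], reps)
        tpm <- cbind(m_m, m_f)
      } else {
        tpm <- noisy(mean_mono[keep, j], reps)
      }
      rownames(tpm) <- ids
      # duplicate / triple copies share the parent's per-sex means
      extra <- c(dup_rows[[sp]]$dup, rep(dup_rows[[sp]]$triple, 2L))
      if (length(extra)) {
        copy_id <- paste0(gene_names[[sp]][extra], "_d",
                          ave(extra, extra, FUN = seq_along))
        if (side == "dio") {
          etpm <- cbind(noisy(mean_m[extra, j], reps),
                        noisy(mean_f[extra, j], reps))
        } else {
          etpm <- noisy(mean_mono[extra, j], reps)
        }
        rownames(etpm) <- copy_id
        tpm <- rbind(tpm, etpm)
      }
      colnames(tpm) <- design$sample_id[design$species == sp]
      exprs[[sp]] <- expression_matrix(tpm, design)
    }
    cl <- class_mat[, j]
    exclude[[dio[j]]] <-
      gene_names[[dio[j]]][cl %in% c("SEX_LINKED_F", "SEX_LINKED_M")]
  }

  # --- orthogroup table ---------------------------------------------------
  og_cells <- sapply(species, function(sp) {
    cell <- gene_names[[sp]]
    cell[lost[[sp]]] <- ""
    dd <- dup_rows[[sp]]
    if (length(dd$dup))
      cell[dd$dup] <- paste(gene_names[[sp]][dd$dup],
                            paste0(gene_names[[sp]][dd$dup], "_d1"), sep = ",")
    if (length(dd$triple))
      cell[dd$triple] <- paste(gene_names[[sp]][dd$triple],
                               paste0(gene_names[[sp]][dd$triple], "_d1"),
                               paste0(gene_names[[sp]][dd$triple], "_d2"),
                               sep = ",")
    cell
  })
  og <- data.frame(og_id = og_ids, og_cells,
                   dup_coverage = ifelse(pat == "dup", dup_cov, NA_real_),
                   stringsAsFactors = FALSE, check.names = FALSE)
  og <- structure(og, species = species,
                  class = c("orthogroup_table", "data.frame"))

  gene_lengths <- setNames(
    sample(300:3000, length(unlist(gene_names)), replace = TRUE) * 3L,
    unlist(gene_names))
  dups_all <- unlist(lapply(species, function(sp)
    setdiff(unlist(strsplit(og_cells[, sp], ",")), gene_names[[sp]])))
  dups_all <- dups_all[nzchar(dups_all)]
  gene_lengths <- c(gene_lengths,
                    setNames(sample(300:3000, length(dups_all),
                                    replace = TRUE) * 3L, dups_all))

  # --- codon alignments ---------------------------------------------------
  ng86_tables()
  omega_of <- c(FB = config$omega_fb, MB = config$omega_mb,
                UNBIASED = config$omega_unb)
  aln_truth <- list(); alignments <- list()
  for (j in seq_len(if (config$n_divergence > 0L) k else 0L)) {
    ok_rows <- which(pat == "complete")
    take <- ok_rows[seq_len(min(config$n_divergence, length(ok_rows)))]
    pj <- pair_ids[j]
    alignments[[pj]] <- list()
    cls <- class_mat[take, j]
    cls[!cls %in% c("FB", "MB")] <- "UNBIASED"
    tds <- runif(length(take), config$ds_range[1L], config$ds_range[2L])
    for (i in seq_along(take)) {
      a <- sim_codon_pair(config$n_codons, omega_of[[cls[i]]], tds[i])
      names(a) <- c(gene_names[[dio[j]]][take[i]],
                    gene_names[[mono[j]]][take[i]])
      alignments[[pj]][[og_ids[take[i]]]] <- a
    }
    aln_truth[[pj]] <- data.frame(og_id = og_ids[take], pair = pj,
                                  omega_class = cls, target_ds = tds,
                                  stringsAsFactors = FALSE)
  }

  # --- phenotypes ---------------------------------------------------------
  phen <- do.call(rbind, lapply(seq_len(k), function(j) {
    mu_f <- 28 + 4 * j
    dim_d <- runif(1, 0, 12)          # dimorphism unrelated to sex bias
    do.call(rbind, lapply(c("female", "male"), function(sx) {
      mu <- if (sx == "female") mu_f else mu_f - dim_d
      data.frame(species = dio[j], sex = sx,
                 cell_length = pmax(1, rnorm(config$phenotype_cells, mu, 3)),
                 stringsAsFactors = FALSE)
    }))
  }))

  truth <- data.frame(og_id = og_ids, pattern = pat, pattern_species = pat_sp,
                      class_mat, conv = conv, conv_shift = conv_shift,
                      stringsAsFactors = FALSE, check.names = FALSE)

  bundle <- structure(list(config = config, design = design, exprs = exprs,
                           og = og, tree = generate_tree(config),
                           alignments = alignments, phenotypes = phen,
                           exclude = exclude, gene_lengths = gene_lengths,
                           truth = truth,
                           truth_alignments = do.call(rbind, aln_truth)),
                      class = "synthetic_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# Simulate an aligned codon sequence pair: random sense-codon start, then
# random single-nucleotide proposals with nonsynonymous changes accepted
# with probability omega (Jukes-Cantor mutation, no ts/tv bias), until the
# accumulated synonymous substitutions reach the target dS (converted to
# an expected proportion of synonymous sites).
sim_codon_pair <- function(n_codons, omega, target_ds) {
  ng86_tables()
  a <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  b <- a
  S0 <- sum(.ng86$S[a])
  ps_target <- 0.75 * (1 - exp(-4 * target_ds / 3))
  goal <- ps_target * S0
  ks <- 0
  max_iter <- 200L * ceiling(goal + 10)
  it <- 0L
  while (ks < goal && it < max_iter) {
    it <- it + 1L
    ci <- sample.int(n_codons, 1L)
    pos <- sample.int(3L, 1L)
    cod <- b[ci]
    nt <- sample(setdiff(NUCS, substr(cod, pos, pos)), 1L)
    alt <- cod
    substr(alt, pos, pos) <- nt
    if (!alt %in% SENSE_CODONS) next
    if (GENETIC_CODE_STD[[alt]] == GENETIC_CODE_STD[[cod]]) {
      b[ci] <- alt
      ks <- ks + 1
    } else if (runif(1) < omega) {
      b[ci] <- alt
    }
  }
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}

#' Write a synthetic bundle to disk
#'
#' @param bundle [generate_bundle()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_tsv(bundle$design, fp("design.tsv"))
  for (sp in names(bundle$exprs))
    write_expression(bundle$exprs[[sp]], fp(sprintf("tpm_%s.tsv", sp)))
  write_orthogroups(bundle$og, fp("orthogroups.tsv"))
  ape::write.tree(bundle$tree, fp("tree.nwk"))
  write_tsv(bundle$phenotypes, fp("phenotypes.tsv"))
  write_tsv(data.frame(gene = names(bundle$gene_lengths),
                       length = unname(bundle$gene_lengths)),
            fp("gene_lengths.tsv"))
  for (sp in names(bundle$exclude))
    writeLines(bundle$exclude[[sp]], fp(sprintf("sex_linked_%s.txt", sp)))
  dir.create(fp("alignments"), showWarnings = FALSE)
  for (pj in names(bundle$alignments)) {
    dir.create(fp("alignments", pj), showWarnings = FALSE)
    for (og in names(bundle$alignments[[pj]]))
      write_codon_fasta(bundle$alignments[[pj]][[og]],
                        fp("alignments", pj, paste0(og, ".fa")))
  }
  write_tsv(bundle$truth, fp("truth.tsv"))
  write_tsv(bundle$truth_alignments, fp("truth_alignments.tsv"))
  invisible(out_dir)
}
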