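# End-to-end orchestration: simulate (or load) a bundle, call sex bias
# per dioicous species, assemble ortholog sets, compute delta-X
# enrichment, ancestral reconstruction, similarity and convergence, and
# sequence divergence, emitting a machine-readable report.

#' Cross-file consistency diagnostics for an input bundle
#'
#' Checks species names across design/matrices/tree, orthogroup gene
#' membership against the per-species gene universes, and tree tips.
#' Problems are reported as messages, never raised.
#'
#' @param bundle a `synthetic_bundle` or an equivalently shaped list
#'   (`design`, `exprs`, `og`, `tree`).
#' @return character vector of diagnostics (empty when consistent).
#' @export
validate_inputs <- function(bundle) {
  out <- character()
  sp_design <- unique(bundle$design$species)
  sp_expr <- names(bundle$exprs)
  for (s in setdiff(sp_design, sp_expr))
    out <- c(out, sprintf("species %s has design rows but no expression matrix", s))
  og_sp <- attr(bundle$og, "species")
  for (s in intersect(og_sp, sp_expr)) {
    universe <- rownames(bundle$exprs[[s]]$tpm)
    genes <- setdiff(unlist(strsplit(bundle$og[[s]], ",", fixed = TRUE)), "")
    bad <- setdiff(genes, universe)
    if (length(bad)) {
      i <- which(vapply(strsplit(bundle$og[[s]], ",", fixed = TRUE),
                        function(g) bad[1L] %in% g, logical(1L)))[1L]
      out <- c(out, sprintf("orthogroup %s references unknown gene %s (%s)",
                            bundle$og$og_id[i], bad[1L], s))
    }
  }
  miss <- setdiff(sp_design, bundle$tree$tip.label)
  for (s in miss) out <- c(out, sprintf("tree is missing species %s", s))
  out
}

#' Run the full comparative pipeline
#'
#' Stages, in dependency order: synthetic-bundle generation (or a
#' caller-supplied bundle), per-dioicous-species sex-bias calling with
#' FB/MB fractions, PSO/DSO/ASO assembly, per-pair delta-X shift
#' enrichment, Mk ancestral reconstruction with branch events and the
#' multi-set intersection test, PIC class comparison and PGLS of
#' phenotypic dimorphism against sex-bias fraction, similarity indexes
#' with correlation-difference tests, convergence calling with a
#' permutation null and sample ordination, and NG86 divergence with
#' class-wise permutation tests.  Every random stage derives its seed
#' from the global seed via [stage_seed()], so identical config + seed
#' gives an identical report.
#'
#' @param bundle input bundle (see [generate_bundle()]).
#' @param fc_min,alpha sex-bias thresholds (defaults 2, 0.05).
#' @param dx_min,dx_fc_min delta-X shift thresholds (defaults 1, 1.5).
#' @param percentile expressed-filter percentile (default 5).
#' @param n_perm permutations for the convergence and divergence tests.
#' @param seed global seed.
#' @param out_dir optional directory for TSV/JSON outputs.
#' @return nested list report (also written as JSON when `out_dir` is
#'   given).
#' @export
run_pipeline <- function(bundle, fc_min = 2, alpha = 0.05, dx_min = 1,
                         dx_fc_min = 1.5, percentile = 5, n_perm = 1e4,
                         seed = 1L, out_dir = NULL) {
  diag <- validate_inputs(bundle)
  if (length(diag)) fatal("inconsistent inputs:\n%s",
                          paste("-", diag, collapse = "\n"))
  design <- bundle$design
  dio_sp <- unique(design$species[design$sexual_system == "dioicous"])
  mono_sp <- unique(design$species[design$sexual_system == "monoicous"])
  pair_of <- vapply(dio_sp, function(s)
    design$pair_id[design$species == s][1L], character(1L))
  mono_of <- vapply(pair_of, function(p)
    unique(design$species[design$pair_id == p &
                            design$sexual_system == "monoicous"]),
    character(1L))

  report <- list(seed = seed,
                 n_species = length(dio_sp) + length(mono_sp))

  # --- sex bias -----------------------------------------------------------
  sb <- lapply(setNames(dio_sp, dio_sp), function(s)
    call_sex_bias(bundle$exprs[[s]], fc_min = fc_min, alpha = alpha,
                  exclude = bundle$exclude[[s]] %||% character(),
                  percentile = percentile))
  report$sexbias <- lapply(sb, function(tb) {
    fr <- bias_fractions(tb)
    chi <- chi2_fb_mb(fr$n_fb, fr$n_mb, fr$denominator)
    c(fr[c("species", "pct_fb", "pct_mb", "n_fb", "n_mb",
           "n_sex_specific", "denominator")],
      list(chi2_p = chi$p.value))
  })

  # --- ortholog sets ------------------------------------------------------
  pso <- lapply(setNames(dio_sp, dio_sp), function(s)
    assemble_pso(bundle$og, s, mono_of[[s]]))
  dso <- assemble_multi(bundle$og, dio_sp, gene_lengths = bundle$gene_lengths)
  aso <- assemble_multi(bundle$og, c(dio_sp, mono_sp),
                        gene_lengths = bundle$gene_lengths)
  report$orthosets <- list(pso = vapply(pso, nrow, integer(1L)),
                           dso = nrow(dso), aso = nrow(aso))

  # per-species class of each DSO row (sex-specific mapped to the
  # corresponding bias; excluded / unexpressed treated as missing data)
  class_of <- function(tb, genes) {
    cl <- tb$class[match(genes, tb$gene)]
    cl[cl == "SEX_SPECIFIC_F"] <- "FB"
    cl[cl == "SEX_SPECIFIC_M"] <- "MB"
    cl[cl %in% c("EXCLUDED_SEX_LINKED", "NOT_EXPRESSED")] <- NA
    cl
  }

  # --- delta-X ------------------------------------------------------------
  report$deltax <- lapply(setNames(dio_sp, dio_sp), function(s) {
    classes <- data.frame(og_id = pso[[s]]$og_id,
                          class = class_of(sb[[s]], pso[[s]][[s]]),
                          stringsAsFactors = FALSE)
    out <- lapply(c("female", "male"), function(sx) {
      dx <- classify_shift(delta_x_table(bundle$exprs[[s]],
                                         bundle$exprs[[mono_of[[s]]]],
                                         pso[[s]], sx),
                           dx_min = dx_min, fc_min = dx_fc_min)
      enr <- shift_enrichment(classes, dx)
      unb <- merge(dx, classes, by = "og_id")
      unb <- unb[unb$class == "UNBIASED" & !is.na(unb$delta_x), ]
      list(enrichment = enr,
           frac_unbiased_shifted = mean(unb$shifted))
    })
    names(out) <- c("vs_female", "vs_male")
    out
  })

  # --- ancestral reconstruction ------------------------------------------
  dio_tree <- ape::drop.tip(bundle$tree,
                            setdiff(bundle$tree$tip.label, dio_sp))
  states <- vapply(dio_sp, function(s) class_of(sb[[s]], dso[[s]]),
                   character(nrow(dso)))
  rownames(states) <- dso$og_id
  anc <- mk_ancestral_set(dio_tree, states)
  biased_any <- apply(states, 1L, function(r)
    any(r %in% c("FB", "MB")))
  # ancestrally biased: the root MAP state is FB or MB AND carries a
  # marginal probability above 1/2 (saturated genes have near-uniform
  # root marginals whose MAP label is meaningless)
  root_map <- anc$map[, length(dio_tree$tip.label) + 1L]
  root_maxp <- anc$root_prob[cbind(seq_len(nrow(anc$root_prob)),
                                   match(root_map, colnames(anc$root_prob)))]
  root_biased <- root_map %in% c("FB", "MB") & root_maxp > 0.5
  report$ancestry <- list(
    n_dso = nrow(dso),
    n_biased_any = sum(biased_any),
    pct_ancestrally_biased = 100 * sum(root_biased & biased_any) /
      max(1L, sum(biased_any)),
    events = branch_events(anc$map, dio_tree))
  biased_sets <- lapply(setNames(dio_sp, dio_sp), function(s)
    dso$og_id[states[, s] %in% c("FB", "MB")])
  report$ancestry$intersection <-
    multiset_intersection_test(biased_sets, universe_size = nrow(dso))

  # --- PIC and PGLS -------------------------------------------------------
  expr_dso <- vapply(dio_sp, function(s) {
    pm <- profile_means(bundle$exprs[[s]])
    unname(pm[dso[[s]]])
  }, numeric(nrow(dso)))
  rownames(expr_dso) <- dso$og_id
  ok <- !apply(expr_dso, 1L, anyNA)
  pics <- pic_mean_abs(dio_tree, expr_dso[ok, , drop = FALSE])
  b_some <- biased_any[ok] &
    apply(states[ok, , drop = FALSE], 1L, function(r)
      any(r == "UNBIASED", na.rm = TRUE))
  pt <- pic_class_test(pics, names(pics)[b_some], names(pics)[!biased_any[ok]])
  report$pic <- list(p.value = pt$p.value,
                     mean_pic_biased = mean(pics[b_some]),
                     mean_pic_unbiased = mean(pics[!biased_any[ok]]))
  dim_proxy <- vapply(setNames(dio_sp, dio_sp), function(s)
    dimorphism_ttest(bundle$phenotypes, s)$difference, numeric(1L))
  sb_frac <- vapply(setNames(dio_sp, dio_sp), function(s)
    report$sexbias[[s]]$pct_fb + report$sexbias[[s]]$pct_mb, numeric(1L))
  pg <- pgls(dim_proxy, sb_frac, dio_tree)
  report$pgls <- pg[c("slope", "intercept", "p.value", "adj_r_squared")]

  # --- similarity ---------------------------------------------------------
  report$similarity <- lapply(setNames(dio_sp, dio_sp), function(s) {
    ps <- pso[[s]]
    pf <- profile_means(bundle$exprs[[s]], "female")[ps[[s]]]
    pm <- profile_means(bundle$exprs[[s]], "male")[ps[[s]]]
    pmo <- profile_means(bundle$exprs[[mono_of[[s]]]])[ps[[mono_of[[s]]]]]
    names(pf) <- names(pm) <- names(pmo) <- ps$og_id
    cl <- class_of(sb[[s]], ps[[s]])
    sets <- list(sbg = ps$og_id[cl %in% c("FB", "MB")],
                 unbiased = ps$og_id[cl %in% "UNBIASED"])
    r_f_unb <- similarity_index(pmo, pf, sets$unbiased)
    r_m_unb <- similarity_index(pmo, pm, sets$unbiased)
    r_fm_unb <- stats::cor(pf[sets$unbiased], pm[sets$unbiased])
    cmp_unb <- compare_correlations_dependent(r_f_unb, r_m_unb, r_fm_unb,
                                              length(sets$unbiased))
    out <- list(r_female_unbiased = r_f_unb, r_male_unbiased = r_m_unb,
                unbiased_f_vs_m_p = cmp_unb$p.value)
    if (length(sets$sbg) >= 4L) {
      r_f_sbg <- similarity_index(pmo, pf, sets$sbg)
      r_m_sbg <- similarity_index(pmo, pm, sets$sbg)
      cmp_sbg <- compare_correlations_dependent(
        r_f_sbg, r_m_sbg, stats::cor(pf[sets$sbg], pm[sets$sbg]),
        length(sets$sbg))
      out$r_female_sbg <- r_f_sbg
      out$r_male_sbg <- r_m_sbg
      out$sbg_f_vs_m_p <- cmp_sbg$p.value
      out$sbg_vs_unbiased_female_p <- compare_correlations_independent(
        r_f_sbg, length(sets$sbg), r_f_unb, length(sets$unbiased))$p.value
    }
    out
  })

  # --- convergence --------------------------------------------------------
  ax <- ortholog_expression(aso, bundle$exprs)
  conv <- call_convergent(ax$tpm, ax$design, alpha = alpha)
  perm <- convergence_permutation_test(ax$tpm, ax$design, alpha = alpha,
                                       n_perm = n_perm,
                                       seed = stage_seed(seed, "convergence"))
  ord <- sample_ordination(ax$tpm, ax$design)
  report$convergence <- list(
    n_aso_modelled = nrow(conv),
    n_convergent = sum(conv$convergent),
    pct_convergent = 100 * mean(conv$convergent),
    permutation_p = perm$p.value,
    n_perm = perm$n_perm,
    pc_var_explained = ord$var_explained[1:2])

  # --- divergence ---------------------------------------------------------
  if (length(bundle$alignments)) {
    recs <- list(); cls <- list()
    for (s in dio_sp) {
      pj <- pair_of[[s]]
      alns <- bundle$alignments[[pj]]
      if (is.null(alns)) next
      rr <- do.call(rbind, lapply(names(alns), function(ogid)
        ng86_pair(alns[[ogid]][1L], alns[[ogid]][2L], og_id = ogid)))
      rr$pair <- pj
      recs[[pj]] <- rr
      dso_gene <- bundle$og[[s]][match(rr$og_id, bundle$og$og_id)]
      dso_gene <- vapply(strsplit(dso_gene, ",", fixed = TRUE),
                         function(g) g[1L], character(1L))
      cls[[pj]] <- data.frame(og_id = rr$og_id,
                              class = class_of(sb[[s]], dso_gene),
                              stringsAsFactors = FALSE)
    }
    recs <- do.call(rbind, recs)
    classes <- do.call(rbind, cls)
    # pool across pairs: key on (og, pair) so the same OG may recur
    key <- paste(recs$og_id, recs$pair)
    recs$og_id <- key
    classes$og_id <- paste(classes$og_id, recs$pair)
    rep_div <- class_divergence_report(recs, classes, n_perm = n_perm,
                                       seed = stage_seed(seed, "divergence"))
    report$divergence <- list(summary = rep_div$summary,
                              tests = rep_div$tests,
                              n_valid = sum(recs$valid))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write_tsv(conv, file.path(out_dir, "convergence.tsv"))
    for (s in dio_sp)
      write_tsv(as.data.frame(sb[[s]]),
                file.path(out_dir, sprintf("sexbias_%s.tsv", s)))
  }
  report
}
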