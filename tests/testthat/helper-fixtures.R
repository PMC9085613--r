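# Shared fixtures, built in code at test time.

# minimal one-species design
make_design <- function(species = "spX", sexes = c("male", "female"),
                        reps = 3L, pair = "p1",
                        system = "dioicous") {
  do.call(rbind, lapply(sexes, function(sx) {
    data.frame(sample_id = sprintf("%s_%s_r%d", species, sx, seq_len(reps)),
               species = species, pair_id = pair, sexual_system = system,
               sex = sx, replicate = seq_len(reps),
               stringsAsFactors = FALSE)
  }))
}

# expression matrix with explicit per-gene per-sex replicate values
make_expr <- function(values_male, values_female, genes = NULL) {
  genes <- genes %||% paste0("g", seq_len(nrow(values_male)))
  des <- make_design(reps = ncol(values_male))
  tpm <- cbind(values_male, values_female)
  rownames(tpm) <- genes
  colnames(tpm) <- des$sample_id
  expression_matrix(tpm, des)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small synthetic bundle for fast end-to-end tests
small_config <- function(seed = 1L, ...) {
  args <- list(genes_per_species = 300L, n_divergence = 25L,
               n_codons = 60L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

split_codons_test <- function(s)
  substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))

# orthogroup table from a named list of per-species gene vectors
make_og <- function(cells, dup_coverage = NULL) {
  df <- data.frame(og_id = sprintf("OG%03d", seq_along(cells[[1L]])),
                   stringsAsFactors = FALSE)
  for (s in names(cells)) df[[s]] <- cells[[s]]
  df$dup_coverage <- dup_coverage %||% rep(NA_real_, nrow(df))
  structure(df, species = names(cells),
            class = c("orthogroup_table", "data.frame"))
}
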