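# Assembly of single-copy ortholog sets (PSO / DSO / ASO) from an
# orthogroup table, with the duplicate-tolerance and one-missing rules.

new_ortholog_set <- function(df, kind, species) {
  structure(df, kind = kind, species = species,
            class = c("ortholog_set", "data.frame"))
}

#' Assemble pairwise single-copy orthologs (PSOs)
#'
#' Keeps orthogroups where each of the two species has exactly one member
#' (other species in the table are ignored).
#'
#' @param og orthogroup_table from [read_orthogroups()].
#' @param species_a,species_b the two species column names.
#' @return `ortholog_set` data.frame: og_id plus one gene column per
#'   species; `attr(,"kind") == "PSO"`.
#' @export
assemble_pso <- function(og, species_a, species_b) {
  sp <- attr(og, "species")
  if (!all(c(species_a, species_b) %in% sp))
    fatal("species absent from orthogroup table: %s",
          paste(setdiff(c(species_a, species_b), sp), collapse = ", "))
  cnt <- og_counts(og)
  keep <- cnt[, species_a] == 1L & cnt[, species_b] == 1L
  df <- data.frame(og_id = og$og_id[keep],
                   a = og[[species_a]][keep], b = og[[species_b]][keep],
                   stringsAsFactors = FALSE)
  names(df)[2:3] <- c(species_a, species_b)
  new_ortholog_set(df, "PSO", c(species_a, species_b))
}

#' Assemble multi-species single-copy ortholog sets (DSO / ASO)
#'
#' A row is included when it is (a) strictly one gene in every species,
#' (b) one gene in all but at most `allow_missing` species (the absent
#' species is recorded as NA), or (c) exactly one species carries exactly
#' two genes whose mutual aligned-length coverage is strictly greater
#' than `dup_coverage_min` while every other species has exactly one gene
#' — in which case the longer duplicate is retained (ties, or missing
#' lengths, resolved lexicographically by gene id).  Duplicate rows with a
#' simultaneously missing species are excluded, as are rows whose
#' duplicate lacks a coverage value (with a warning).
#'
#' @param og orthogroup_table.
#' @param species character vector (>= 3) of species columns to use.
#' @param allow_missing maximum number of absent species per row, default 1.
#' @param dup_coverage_min strict lower bound on duplicate coverage,
#'   default 0.6.
#' @param gene_lengths optional named numeric vector of gene lengths used
#'   to pick the longer duplicate.
#' @param kind set label; defaults to DSO for 4 species, ASO for 8.
#' @return `ortholog_set` data.frame (og_id + one gene column per species,
#'   NA marking an absent species).
#' @export
assemble_multi <- function(og, species, allow_missing = 1L,
                           dup_coverage_min = 0.6, gene_lengths = NULL,
                           kind = NULL) {
  sp <- attr(og, "species")
  if (length(species) < 3L) fatal("need at least 3 species")
  if (!all(species %in% sp))
    fatal("species absent from orthogroup table: %s",
          paste(setdiff(species, sp), collapse = ", "))
  if (is.null(kind))
    kind <- if (length(species) == 4L) "DSO"
            else if (length(species) == 8L) "ASO" else "MULTI"
  cnt <- og_counts(og)[, species, drop = FALSE]
  n0 <- rowSums(cnt == 0L); n1 <- rowSums(cnt == 1L); n2 <- rowSums(cnt == 2L)
  k <- length(species)
  complete <- n1 == k
  missing_ok <- n0 >= 1L & n0 <= allow_missing & (n0 + n1) == k
  dup_cand <- n2 == 1L & n1 == k - 1L

  rows <- vector("list", nrow(og))
  n_nocov <- 0L
  pick <- function(i) {
    genes <- setNames(rep(NA_character_, k), species)
    for (s in species) {
      v <- og[[s]][i]
      if (v == "") next
      members <- strsplit(v, ",", fixed = TRUE)[[1L]]
      if (length(members) == 1L) {
        genes[s] <- members
      } else {                                   # the qualifying duplicate
        members <- sort(members)                 # lexicographic tie-break
        if (!is.null(gene_lengths) && all(members %in% names(gene_lengths))) {
          len <- gene_lengths[members]
          members <- members[order(-len, members)]
        }
        genes[s] <- members[1L]
      }
    }
    genes
  }
  for (i in seq_len(nrow(og))) {
    take <- FALSE
    if (complete[i] || missing_ok[i]) {
      take <- TRUE
    } else if (dup_cand[i]) {
      cov <- og$dup_coverage[i]
      if (is.na(cov)) { n_nocov <- n_nocov + 1L }
      else if (cov > dup_coverage_min) take <- TRUE
    }
    if (take) rows[[i]] <- c(og_id = og$og_id[i], pick(i))
  }
  if (n_nocov > 0L)
    warning(sprintf("%d duplicate row(s) excluded for missing dup_coverage",
                    n_nocov))
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    df <- setNames(as.data.frame(matrix(character(), 0L, k + 1L),
                                 stringsAsFactors = FALSE),
                   c("og_id", species))
  new_ortholog_set(df, kind, species)
}

#' Cross-set membership matrix of orthogroups
#'
#' @param sets named list of `ortholog_set` objects.
#' @return logical matrix (union of og_ids x sets) suitable for
#'   upset-style intersection counting.
#' @export
intersect_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  ids <- sort(unique(unlist(lapply(sets, function(s) s$og_id))))
  out <- vapply(sets, function(s) ids %in% s$og_id,
                logical(length(ids)))
  out <- matrix(out, nrow = length(ids),
                dimnames = list(ids, names(sets)))
  out
}
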