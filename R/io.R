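# Readers and writers for the package's external formats.  All tabular
# files are tab-separated UTF-8 with '#' comments allowed; the first
# column is always the key.  Gene identifiers are opaque strings and all
# joins are exact-match.

SEXES <- c("male", "female", "cosexual")
SYSTEMS <- c("dioicous", "monoicous")
BIAS_CLASSES <- c("FB", "MB", "UNBIASED", "SEX_SPECIFIC_F", "SEX_SPECIFIC_M",
                  "EXCLUDED_SEX_LINKED", "NOT_EXPRESSED")

#' Read a sample-design table
#'
#' The design table has one row per RNA-seq library with columns
#' `sample_id`, `species`, `pair_id`, `sexual_system` (dioicous/monoicous),
#' `sex` (male/female/cosexual) and `replicate`.  Cosexual samples must
#' belong to monoicous species and vice versa; every (species, sex) group
#' needs at least two replicates; each pair must contain exactly one
#' dioicous and one monoicous species.
#'
#' @param path TSV file path.
#' @return data.frame of validated design rows, in file order.
#' @export
read_design <- function(path) {
  d <- read_tsv(path)
  validate_design(d)
}

#' @rdname read_design
#' @param design data.frame with the design columns.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "species", "pair_id", "sexual_system", "sex",
            "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) fatal("design is missing columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    fatal("duplicate sample_id in design")
  if (!all(design$sexual_system %in% SYSTEMS))
    fatal("sexual_system must be one of: %s", paste(SYSTEMS, collapse = ", "))
  if (!all(design$sex %in% SEXES))
    fatal("sex must be one of: %s", paste(SEXES, collapse = ", "))
  bad <- xor(design$sex == "cosexual", design$sexual_system == "monoicous")
  if (any(bad))
    fatal("cosexual sex and monoicous system must coincide (sample %s)",
          design$sample_id[which(bad)[1L]])
  if (any(design$replicate < 1))
    fatal("replicate must be a positive integer")
  n_rep <- table(paste(design$species, design$sex))
  if (any(n_rep < 2L))
    fatal("every (species, sex) group needs >=2 replicates; offending group: %s",
          names(n_rep)[which(n_rep < 2L)[1L]])
  # a design may describe a subset of a study (e.g. one species), but a
  # pair can never hold two species of the same sexual system
  for (p in unique(design$pair_id)) {
    sub <- unique(design[design$pair_id == p, c("species", "sexual_system")])
    if (sum(sub$sexual_system == "dioicous") > 1L ||
        sum(sub$sexual_system == "monoicous") > 1L)
      fatal("pair %s must contain exactly one dioicous and one monoicous species", p)
  }
  design
}

#' Construct an expression matrix object
#'
#' Bundles a non-negative TPM matrix (genes x samples) of one species with
#' its sample design rows.  Gene and sample order are preserved as given.
#'
#' @param tpm numeric matrix, rownames = gene labels, colnames = sample ids.
#' @param design design data.frame covering at least the matrix samples.
#' @return object of class `uvshift_expr` with elements `tpm`, `design`,
#'   `species`.
#' @export
expression_matrix <- function(tpm, design) {
  if (is.null(rownames(tpm)) || is.null(colnames(tpm)))
    fatal("tpm matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(tpm)))
    fatal("duplicate gene label: %s",
          rownames(tpm)[duplicated(rownames(tpm))][1L])
  if (any(tpm < 0)) fatal("negative TPM values are not allowed")
  unknown <- setdiff(colnames(tpm), design$sample_id)
  if (length(unknown))
    fatal("sample '%s' in matrix header is absent from the design", unknown[1L])
  des <- design[match(colnames(tpm), design$sample_id), , drop = FALSE]
  rownames(des) <- NULL
  if (length(unique(des$species)) != 1L)
    fatal("an expression matrix must contain samples of a single species")
  structure(list(tpm = tpm, design = des, species = des$species[1L]),
            class = "uvshift_expr")
}

#' Read a TPM expression matrix with its design
#'
#' @param tpm_path TSV: header row of sample ids, first column gene labels.
#' @param design_path TSV with the sample-design columns (see
#'   [read_design()]); may describe more samples than the matrix.
#' @return [expression_matrix()] object.
#' @export
read_expression <- function(tpm_path, design_path) {
  design <- read_design(design_path)
  tab <- read_tsv(tpm_path)
  genes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  expression_matrix(m, design)
}

#' @rdname read_expression
#' @param expr an `uvshift_expr` object.
#' @param design_path optional path to also write the design rows.
#' @export
write_expression <- function(expr, tpm_path, design_path = NULL) {
  df <- data.frame(gene = rownames(expr$tpm), expr$tpm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, tpm_path)
  if (!is.null(design_path)) write_tsv(expr$design, design_path)
  invisible(tpm_path)
}

#' Read an orthogroup membership table
#'
#' One row per orthogroup: column `og_id`, one column per species holding a
#' comma-separated gene list (empty when the species has no member), and an
#' optional `dup_coverage` column holding the mutual aligned-length
#' fraction of a within-species duplicate pair.
#'
#' @param path TSV file path.
#' @return data.frame of class `orthogroup_table`; `attr(, "species")`
#'   names the species columns.
#' @export
read_orthogroups <- function(path) {
  d <- read_tsv(path, colClasses = "character")
  if (names(d)[1L] != "og_id") fatal("first column must be og_id")
  has_cov <- "dup_coverage" %in% names(d)
  sp <- setdiff(names(d), c("og_id", "dup_coverage"))
  if (has_cov) {
    d$dup_coverage <- suppressWarnings(as.numeric(d$dup_coverage))
    bad <- !is.na(d$dup_coverage) &
      (d$dup_coverage < 0 | d$dup_coverage > 1)
    if (any(bad))
      fatal("dup_coverage outside [0,1] for og %s", d$og_id[which(bad)[1L]])
  } else {
    d$dup_coverage <- NA_real_
  }
  for (s in sp) d[[s]][is.na(d[[s]])] <- ""
  structure(d[, c("og_id", sp, "dup_coverage")], species = sp,
            class = c("orthogroup_table", "data.frame"))
}

#' @rdname read_orthogroups
#' @param og orthogroup_table to write.
#' @export
write_orthogroups <- function(og, path) {
  write_tsv(as.data.frame(og), path)
  invisible(path)
}

#' Per-species membership counts of an orthogroup table
#'
#' @param og orthogroup_table.
#' @return integer matrix (orthogroups x species).
#' @export
og_counts <- function(og) {
  sp <- attr(og, "species")
  out <- sapply(sp, function(s) {
    v <- og[[s]]
    ifelse(v == "", 0L, lengths(strsplit(v, ",", fixed = TRUE)))
  })
  out <- matrix(as.integer(out), nrow = nrow(og),
                dimnames = list(og$og_id, sp))
  out
}

#' Read a rooted binary species tree
#'
#' @param path Newick file.
#' @param tips optional species labels that must all be present.
#' @return `ape::phylo` tree, validated rooted and binary with
#'   non-negative branch lengths.
#' @export
read_tree <- function(path, tips = NULL) {
  tr <- ape::read.tree(path)
  validate_tree(tr, tips)
}

#' @rdname read_tree
#' @param tree a `phylo` object.
#' @export
validate_tree <- function(tree, tips = NULL) {
  if (!inherits(tree, "phylo")) fatal("not a phylo tree")
  if (!ape::is.rooted(tree)) fatal("tree must be rooted")
  if (!ape::is.binary(tree)) fatal("tree must be binary")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    fatal("tree needs non-negative branch lengths")
  if (!is.null(tips)) {
    miss <- setdiff(tips, tree$tip.label)
    if (length(miss)) fatal("tree is missing tip(s): %s",
                            paste(miss, collapse = ", "))
  }
  tree
}

# codons of the standard genetic code that terminate translation
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read an aligned codon FASTA
#'
#' Sequences must all have equal length divisible by three.  Sequences
#' containing an internal in-frame stop codon are dropped with a warning.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase aligned sequences.
#' @export
read_codon_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  validate_codon_alignment(seqs)
}

#' @rdname read_codon_fasta
#' @param seqs named character vector of aligned sequences.
#' @export
validate_codon_alignment <- function(seqs) {
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) fatal("alignment sequences have unequal lengths")
  if (w[1L] %% 3L != 0L) fatal("alignment length %d not divisible by 3", w[1L])
  seqs <- toupper(seqs)
  has_stop <- vapply(seqs, function(s) {
    cods <- substring(s, seq(1L, nchar(s) - 2L, 3L), seq(3L, nchar(s), 3L))
    cods <- cods[-length(cods)]            # terminal stop is legitimate
    any(cods %in% STOP_CODONS)
  }, logical(1L))
  if (any(has_stop)) {
    warning(sprintf("dropping %d sequence(s) with internal stop codons: %s",
                    sum(has_stop),
                    paste(names(seqs)[has_stop], collapse = ", ")))
    seqs <- seqs[!has_stop]
  }
  seqs
}

#' @rdname read_codon_fasta
#' @export
write_codon_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a cell-length phenotype table
#'
#' @param path TSV with columns `species`, `sex`, `cell_length` (one row
#'   per measured cell, lengths in micrometres).
#' @return validated data.frame.
#' @export
read_phenotypes <- function(path) {
  d <- read_tsv(path)
  need <- c("species", "sex", "cell_length")
  if (!all(need %in% names(d)))
    fatal("phenotype table needs columns: %s", paste(need, collapse = ", "))
  d$cell_length <- as.numeric(d$cell_length)
  if (any(!is.finite(d$cell_length)) || any(d$cell_length <= 0))
    fatal("cell_length must be positive")
  n <- table(paste(d$species, d$sex))
  if (any(n < 2L))
    fatal("need >=2 cells per (species, sex); offending group: %s",
          names(n)[which(n < 2L)[1L]])
  d
}
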