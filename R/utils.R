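#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor lm optimize p.adjust pnorm prcomp pt
#'   quantile rbinom rexp rnorm runif setNames t.test var wilcox.test
#'   dhyper phyper fisher.test prop.test rpois model.matrix anova
#'   complete.cases ave median lm.fit
#' @importFrom utils read.delim write.table combn head
NULL

# --- small shared helpers -------------------------------------------------

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "", ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fatal <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive a per-stage random seed from a global seed
#'
#' Stage seeds are the global seed combined with a deterministic integer
#' fingerprint of the stage name, so that re-running a single stage in
#' isolation reproduces the full-run stream for that stage regardless of
#' execution order.  All values stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  as.integer((abs(seed) %% 20000L) * 99991L + h) %% 2147483629L
}

# log2(TPM + 1), the package-wide expression transform
log2p1 <- function(x) log2(x + 1)

# row-wise variance of a numeric matrix
row_var <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}
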