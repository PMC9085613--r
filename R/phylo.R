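# Ancestral-state reconstruction of sex-bias classes under a symmetric
# (equal-rates) Mk model via Felsenstein pruning with marginal
# reconstruction, branch gain/loss mapping, the exact multi-set
# intersection test, phylogenetically independent contrasts and PGLS.

MK_STATES <- c("FB", "MB", "UNBIASED")

# ER Mk transition-probability matrix for k states: closed form from the
# single eigenvalue -k*q of the rate matrix
mk_pmat <- function(q, t, k) {
  e <- exp(-k * q * t)
  p_same <- 1 / k + (k - 1) / k * e
  p_diff <- 1 / k * (1 - e)
  m <- matrix(p_diff, k, k)
  diag(m) <- p_same
  m
}

# Post-order partial likelihoods; tip_idx is an integer state per tip (NA
# = missing data, partial likelihood 1 for every state).
mk_partials <- function(tree, tip_idx, q, k) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  L <- matrix(1, nt + nn, k)
  obs <- which(!is.na(tip_idx))
  L[obs, ] <- 0
  L[cbind(obs, tip_idx[obs])] <- 1
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1L]; chi <- ord$edge[i, 2L]
    P <- mk_pmat(q, ord$edge.length[i], k)
    L[par, ] <- L[par, ] * as.vector(P %*% L[chi, ])
  }
  L
}

mk_loglik <- function(tree, tip_idx, q, k) {
  L <- mk_partials(tree, tip_idx, q, k)
  root <- length(tree$tip.label) + 1L
  log(sum(L[root, ]) / k)
}

#' Maximum-likelihood Mk ancestral-state reconstruction
#'
#' Fits a single-rate (equal-rates) Mk model over the given states by
#' maximizing the pruning likelihood over the rate q (Brent search on
#' log q, tolerance 1e-8), then computes marginal state probabilities at
#' every node with a uniform root prior and reports MAP states.  Tips
#' with NA state (e.g. the absent species of a 1:1:1:0 ortholog row) are
#' treated as missing data.  When at most one distinct state is observed
#' the rate is 0 and all nodes take that state with probability 1.
#'
#' @param tree rooted binary `phylo` tree with positive branch lengths.
#' @param tip_states named character vector (names = tip labels); NA =
#'   missing.
#' @param states the state space, default FB/MB/UNBIASED.
#' @param q optional fixed rate (skips the ML step).
#' @return list of class `mk_reconstruction`: `q`, `loglik`,
#'   `node_prob` (nodes x states marginal probabilities, tips included),
#'   `map` (MAP state per node), `states`.
#' @export
mk_ancestral <- function(tree, tip_states, states = MK_STATES, q = NULL) {
  validate_tree(tree)
  k <- length(states)
  nt <- length(tree$tip.label); nn <- tree$Nnode
  tip_states <- tip_states[tree$tip.label]
  tip_idx <- match(tip_states, states)
  if (any(!is.na(tip_states) & is.na(tip_idx)))
    fatal("tip state outside the state space")
  obs <- unique(tip_idx[!is.na(tip_idx)])

  if (length(obs) <= 1L && is.null(q)) {
    prob <- matrix(1 / k, nt + nn, k, dimnames = list(NULL, states))
    if (length(obs) == 1L) {
      prob[] <- 0
      prob[, obs] <- 1
    }
    map <- states[max.col(prob, ties.method = "first")]
    map[seq_len(nt)][!is.na(tip_idx)] <- states[tip_idx[!is.na(tip_idx)]]
    ll <- if (length(obs) == 1L) log(1 / k) else 0
    return(structure(list(q = 0, loglik = ll, node_prob = prob, map = map,
                          states = states), class = "mk_reconstruction"))
  }
  if (is.null(q)) {
    opt <- stats::optimize(function(lq) mk_loglik(tree, tip_idx, exp(lq), k),
                           interval = log(c(1e-8, 1e3)), maximum = TRUE,
                           tol = 1e-8)
    q <- exp(opt$maximum)
    ll <- opt$objective
  } else {
    ll <- mk_loglik(tree, tip_idx, q, k)
  }

  L <- mk_partials(tree, tip_idx, q, k)
  root <- nt + 1L
  # preorder pass: G[v, ] = likelihood of everything outside the subtree
  # of v, as a function of the state at v's parent end
  G <- matrix(NA_real_, nt + nn, k)
  G[root, ] <- rep(1 / k, k)
  ord <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(ord$edge)))
  marg <- matrix(NA_real_, nt + nn, k)
  mroot <- G[root, ] * L[root, ]
  marg[root, ] <- mroot / sum(mroot)
  for (i in pre) {
    par <- ord$edge[i, 1L]; chi <- ord$edge[i, 2L]
    P <- mk_pmat(q, ord$edge.length[i], k)
    sibs <- ord$edge[ord$edge[, 1L] == par, 2L]
    sibs <- sibs[sibs != chi]
    above <- G[par, ]
    for (s in sibs) {
      es <- which(ord$edge[, 2L] == s)
      Ps <- mk_pmat(q, ord$edge.length[es], k)
      above <- above * as.vector(Ps %*% L[s, ])
    }
    G[chi, ] <- as.vector(above %*% P)   # sum_i above_i P[i, j]
    mv <- G[chi, ] * L[chi, ]
    marg[chi, ] <- mv / sum(mv)
  }
  colnames(marg) <- states
  map <- states[max.col(marg, ties.method = "first")]
  structure(list(q = q, loglik = ll, node_prob = marg, map = map,
                 states = states), class = "mk_reconstruction")
}

#' Ancestral reconstruction for a matrix of genes
#'
#' Applies [mk_ancestral()] to every row of a genes x tips state matrix,
#' memoizing on the tip-state pattern (the per-gene maximum-likelihood
#' rate depends only on the pattern for a fixed tree).
#'
#' @param tree rooted binary `phylo` tree.
#' @param state_matrix character matrix, rows = genes, columns = tip
#'   labels, entries in the state space or NA.
#' @param states state space.
#' @return list: `map` (genes x nodes MAP-state matrix), `root_prob`
#'   (genes x states marginal root probabilities), `q` per gene.
#' @export
mk_ancestral_set <- function(tree, state_matrix, states = MK_STATES) {
  state_matrix <- state_matrix[, tree$tip.label, drop = FALSE]
  key <- apply(state_matrix, 1L, function(r) paste(ifelse(is.na(r), ".", r),
                                                   collapse = "|"))
  uniq <- !duplicated(key)
  cache <- lapply(which(uniq), function(i) {
    mk_ancestral(tree, setNames(state_matrix[i, ], colnames(state_matrix)),
                 states)
  })
  names(cache) <- key[uniq]
  nt <- length(tree$tip.label)
  n_nodes <- nt + tree$Nnode
  map <- t(vapply(key, function(k2) cache[[k2]]$map, character(n_nodes)))
  rootp <- t(vapply(key, function(k2) cache[[k2]]$node_prob[nt + 1L, ],
                    numeric(length(states))))
  rownames(map) <- rownames(rootp) <- rownames(state_matrix)
  colnames(rootp) <- states
  list(map = map, root_prob = rootp,
       q = vapply(key, function(k2) cache[[k2]]$q, numeric(1L)))
}

#' Branch gains and losses of sex bias
#'
#' Compares MAP states of the two ends of every branch: UNBIASED->MB is
#' an MB gain, MB->UNBIASED an MB loss, and an FB<->MB change counts as
#' one loss plus one gain.
#'
#' @param map genes x nodes MAP-state matrix from [mk_ancestral_set()]
#'   (or a single reconstruction's `map` as a one-row matrix).
#' @param tree the tree used for the reconstruction.
#' @return data.frame, one row per edge: parent, child (node indices),
#'   child_label (tip label where applicable), fb_gain, fb_loss,
#'   mb_gain, mb_loss summed over genes.
#' @export
branch_events <- function(map, tree) {
  if (is.null(dim(map))) map <- matrix(map, 1L)
  nt <- length(tree$tip.label)
  do.call(rbind, lapply(seq_len(nrow(tree$edge)), function(i) {
    par <- tree$edge[i, 1L]; chi <- tree$edge[i, 2L]
    from <- map[, par]; to <- map[, chi]
    data.frame(parent = par, child = chi,
               child_label = if (chi <= nt) tree$tip.label[chi] else NA_character_,
               fb_gain = sum(from != "FB" & to == "FB"),
               fb_loss = sum(from == "FB" & to != "FB"),
               mb_gain = sum(from != "MB" & to == "MB"),
               mb_loss = sum(from == "MB" & to != "MB"))
  }))
}

#' Exact multi-set intersection test
#'
#' Probability, under independent uniform draws of subsets of the
#' observed sizes from a common universe, that the all-way intersection
#' is at least as large as observed.  The distribution of the running
#' intersection size is an exact hypergeometric chain (the next set
#' intersects the current intersection hypergeometrically), so the test
#' is exact for any number of sets; a seeded Monte-Carlo mode is kept as
#' a cross-check.
#'
#' @param sets list of character vectors (gene sets).
#' @param universe_size size of the common universe (>= every set).
#' @param method "exact" (default) or "mc".
#' @param n_draws Monte-Carlo draws when `method = "mc"`.
#' @param seed seed for the Monte-Carlo mode.
#' @return list: `observed`, `expected`, `p.value`, `method`.
#' @export
multiset_intersection_test <- function(sets, universe_size,
                                       method = c("exact", "mc"),
                                       n_draws = 1e5, seed = NULL) {
  method <- match.arg(method)
  sizes <- lengths(sets)
  if (any(sizes > universe_size)) fatal("a set is larger than the universe")
  obs <- length(Reduce(intersect, sets))
  expected <- universe_size * prod(sizes / universe_size)
  if (obs == 0L)
    return(list(observed = 0L, expected = expected, p.value = 1,
                method = method))
  if (method == "exact") {
    # dist[j + 1] = P(running intersection == j)
    dist <- numeric(sizes[1L] + 1L)
    dist[sizes[1L] + 1L] <- 1
    for (m in seq_along(sizes)[-1L]) {
      nm <- sizes[m]
      newd <- numeric(length(dist))
      for (j in which(dist > 0) - 1L) {
        t_max <- min(j, nm)
        tt <- 0:t_max
        newd[tt + 1L] <- newd[tt + 1L] +
          dist[j + 1L] * stats::dhyper(tt, j, universe_size - j, nm)
      }
      dist <- newd
    }
    p <- sum(dist[(obs + 1L):length(dist)])
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_draws)) {
      inter <- sample.int(universe_size, sizes[1L])
      for (m in seq_along(sizes)[-1L])
        inter <- intersect(inter, sample.int(universe_size, sizes[m]))
      if (length(inter) >= obs) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_draws + 1)
  }
  list(observed = obs, expected = expected, p.value = p, method = method)
}

#' Phylogenetically independent contrasts
#'
#' Standardized contrasts (Felsenstein 1985) via `ape::pic`.
#'
#' @param tree rooted binary `phylo` with positive branch lengths.
#' @param tip_values named numeric vector (names = tip labels).
#' @return numeric vector of n_tips - 1 standardized contrasts.
#' @export
pic_contrasts <- function(tree, tip_values) {
  validate_tree(tree)
  ape::pic(tip_values[tree$tip.label], tree)
}

#' Mean absolute standardized contrast per gene
#'
#' @param tree `phylo` tree.
#' @param value_matrix genes x tips numeric matrix.
#' @return named numeric vector (one mean |PIC| per gene).
#' @export
pic_mean_abs <- function(tree, value_matrix) {
  value_matrix <- value_matrix[, tree$tip.label, drop = FALSE]
  apply(value_matrix, 1L, function(v) mean(abs(ape::pic(v, tree))))
}

#' Mann-Whitney comparison of contrast magnitudes between gene classes
#'
#' @param pic_by_gene named vector of per-gene mean |PIC| values.
#' @param genes_a,genes_b the two gene groups (each >= 2 genes with
#'   contrast values).
#' @return list: `p.value`, `statistic` (two-sided Mann-Whitney U).
#' @export
pic_class_test <- function(pic_by_gene, genes_a, genes_b) {
  a <- pic_by_gene[names(pic_by_gene) %in% genes_a]
  b <- pic_by_gene[names(pic_by_gene) %in% genes_b]
  if (length(a) < 2L || length(b) < 2L) fatal("each group needs >=2 genes")
  ht <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  list(p.value = ht$p.value, statistic = unname(ht$statistic),
       n_a = length(a), n_b = length(b))
}

#' Phylogenetic generalized least squares regression
#'
#' Fits `y ~ x` across species by explicit generalized least squares
#' under a Brownian-motion covariance (shared path lengths, `ape::vcv`):
#' the data are whitened with the inverse Cholesky factor of the
#' covariance and fitted by ordinary least squares.  The slope p value
#' is the usual t-test with n - 2 degrees of freedom; r-squared compares
#' the whitened residuals with the whitened intercept-only model.
#' (Equivalent to `nlme::gls` with `ape::corBrownian`, but also defined
#' for noise-free inputs.)
#'
#' @param x,y named numeric vectors (names = species, present as tree
#'   tips), >= 3 species.
#' @param tree `phylo` tree covering the species.
#' @return list: `slope`, `intercept`, `p.value` (slope), `r_squared`,
#'   `adj_r_squared`, `sigma2`.
#' @export
pgls <- function(x, y, tree) {
  sp <- names(x)
  if (is.null(sp) || !setequal(sp, names(y)))
    fatal("x and y must be named by the same species")
  if (length(sp) < 3L) fatal("need >=3 species")
  validate_tree(tree, sp)
  tr <- if (length(setdiff(tree$tip.label, sp)))
    ape::drop.tip(tree, setdiff(tree$tip.label, sp)) else tree
  V <- ape::vcv(tr)[sp, sp]
  W <- tryCatch(solve(t(chol(V))), error = function(e)
    fatal("singular phylogenetic covariance"))
  n <- length(sp)
  yw <- as.vector(W %*% y[sp])
  Xw <- W %*% cbind(intercept = 1, x = as.numeric(x))
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - 2L)
  XtXi <- chol2inv(chol(crossprod(Xw)))
  se <- sqrt(sigma2 * diag(XtXi))
  tval <- fit$coefficients / se
  p <- 2 * stats::pt(-abs(tval), n - 2L)
  p[se == 0] <- ifelse(fit$coefficients[se == 0] == 0, 1, 0)
  rss0 <- sum(stats::lm.fit(W %*% matrix(1, n), yw)$residuals^2)
  r2 <- 1 - rss / rss0
  list(slope = unname(fit$coefficients["x"]),
       intercept = unname(fit$coefficients["intercept"]),
       p.value = unname(p["x"]), r_squared = r2,
       adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2), sigma2 = sigma2)
}
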