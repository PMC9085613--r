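# enumeration oracle for the Mk likelihood: sum over all internal-state
# assignments with eigen-decomposed matrix exponentials
mk_enum_loglik <- function(tree, tip_states, q, states) {
  k <- length(states)
  Q <- matrix(q, k, k); diag(Q) <- -(k - 1) * q
  expm <- function(t) {
    e <- eigen(Q * t)
    Re(e$vectors %*% diag(exp(e$values), k) %*% solve(e$vectors))
  }
  nt <- length(tree$tip.label); nn <- tree$Nnode
  tipidx <- match(tip_states[tree$tip.label], states)
  internal <- nt + seq_len(nn)
  grids <- do.call(expand.grid, rep(list(seq_len(k)), nn))
  tot <- 0
  for (g in seq_len(nrow(grids))) {
    assign_state <- c(tipidx, as.integer(grids[g, ]))
    pr <- 1 / k                         # uniform root prior
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; chi <- tree$edge[e, 2L]
      P <- expm(tree$edge.length[e])
      sc <- assign_state[chi]
      if (is.na(sc)) next               # missing tip: marginalize
      pr <- pr * P[assign_state[par], sc]
    }
    # missing tips marginalize to 1 (rows of P sum to 1), handled above
    if (ok) tot <- tot + pr
  }
  log(tot)
}

test_that("pruning likelihood equals brute-force enumeration on 4-tip trees", {
  tr <- ape::read.tree(text = "((A:0.3,B:0.8):0.5,(C:1.2,D:0.4):0.9);")
  states <- c("FB", "MB", "UNBIASED")
  set.seed(4)
  for (i in 1:12) {
    tips <- setNames(sample(states, 4, replace = TRUE),
                     c("A", "B", "C", "D"))
    if (i > 9) tips[sample(4, 1)] <- NA  # exercise missing data
    q <- runif(1, 0.05, 2)
    got <- mk_ancestral(tr, tips, q = q)
    expect_equal(got$loglik, mk_enum_loglik(tr, tips, q, states),
                 tolerance = 1e-10)
  }
})

test_that("marginal reconstructions are proper and match enumeration", {
  tr <- ape::read.tree(text = "((A:0.3,B:0.8):0.5,(C:1.2,D:0.4):0.9);")
  states <- c("FB", "MB", "UNBIASED")
  tips <- c(A = "FB", B = "FB", C = "UNBIASED", D = "MB")
  q <- 0.4
  got <- mk_ancestral(tr, tips, q = q)
  expect_equal(unname(rowSums(got$node_prob)), rep(1, 7), tolerance = 1e-12)

  # enumeration marginal at the root
  k <- 3
  Q <- matrix(q, k, k); diag(Q) <- -2 * q
  expm <- function(t) {
    e <- eigen(Q * t)
    Re(e$vectors %*% diag(exp(e$values), k) %*% solve(e$vectors))
  }
  tipidx <- match(tips[tr$tip.label], states)
  root_joint <- numeric(k)
  for (r in 1:k) for (l in 1:k) for (rr in 1:k) {
    # internal nodes: 5 = root, 6 = (A,B) ancestor, 7 = (C,D) ancestor
    pr <- (1 / k) *
      expm(0.5)[r, l] * expm(0.9)[r, rr] *
      expm(0.3)[l, tipidx[1]] * expm(0.8)[l, tipidx[2]] *
      expm(1.2)[rr, tipidx[3]] * expm(0.4)[rr, tipidx[4]]
    root_joint[r] <- root_joint[r] + pr
  }
  expect_equal(unname(got$node_prob[5L, ]),
               root_joint / sum(root_joint), tolerance = 1e-10)
})

test_that("likelihood is invariant to tip order within cherries and ML matches ace", {
  states <- c("FB", "MB", "UNBIASED")
  tr1 <- ape::read.tree(text = "((A:0.3,B:0.8):0.5,(C:1.2,D:0.4):0.9);")
  tr2 <- ape::read.tree(text = "((B:0.8,A:0.3):0.5,(D:0.4,C:1.2):0.9);")
  tips <- c(A = "FB", B = "MB", C = "UNBIASED", D = "MB")
  g1 <- mk_ancestral(tr1, tips, q = 0.7)
  g2 <- mk_ancestral(tr2, tips, q = 0.7)
  expect_equal(g1$loglik, g2$loglik, tolerance = 1e-12)

  # cross-check against ape::ace (ER, marginal): the achieved maximum
  # log-likelihood must agree, and root marginals must agree at ace's
  # own rate estimate (the rate itself is weakly identified on 4 tips,
  # so it is compared through the likelihood, not point-wise)
  fit <- suppressWarnings(          # ace warns about its own rate SEs
    ape::ace(factor(tips[tr1$tip.label], levels = states), tr1,
             type = "discrete", model = "ER", marginal = TRUE))
  ml <- mk_ancestral(tr1, tips)
  # ace reports the likelihood without the uniform 1/k root prior
  expect_equal(ml$loglik + log(3), fit$loglik, tolerance = 1e-5)
  at_ace_rate <- mk_ancestral(tr1, tips, q = unname(fit$rates))
  expect_equal(unname(at_ace_rate$node_prob[5L, ]),
               unname(fit$lik.anc[1L, ]), tolerance = 1e-4)
})

test_that("single-state tips give rate 0 and certain reconstruction", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tips <- setNames(rep("UNBIASED", 4), c("A", "B", "C", "D"))
  got <- mk_ancestral(tr, tips)
  expect_equal(got$q, 0)
  expect_true(all(got$map == "UNBIASED"))
  expect_true(all(got$node_prob[, "UNBIASED"] >= 0.999))
})

test_that("branch events follow the gain/loss rules", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # uniform states: no events
  map0 <- matrix("UNBIASED", 1, 7)
  ev0 <- branch_events(map0, tr)
  expect_true(all(ev0[, c("fb_gain", "fb_loss", "mb_gain", "mb_loss")] == 0))
  # parent UNBIASED, child MB on tip A: one MB gain on that branch
  map1 <- map0; map1[1, 1] <- "MB"
  ev1 <- branch_events(map1, tr)
  expect_identical(sum(ev1$mb_gain), 1L)
  expect_identical(ev1$mb_gain[ev1$child_label %in% "A"], 1L)
  # FB -> MB counts one FB loss plus one MB gain
  map2 <- map0; map2[1, 5:7] <- "FB"; map2[1, 1:4] <- "FB"; map2[1, 2] <- "MB"
  ev2 <- branch_events(map2, tr)
  expect_identical(sum(ev2$fb_loss), 1L)
  expect_identical(sum(ev2$mb_gain), 1L)
})

test_that("planted single-gain histories map to the right branch", {
  tr <- ape::read.tree(text = "((A:20,B:20):60,(C:30,D:30):50);")
  # genes gain MB on the terminal branch to A: A is MB, everyone else
  # UNBIASED; the reconstruction should put the gain on A's branch
  n_ok <- 0L
  for (i in 1:20) {
    tips <- setNames(c("MB", "UNBIASED", "UNBIASED", "UNBIASED"),
                     c("A", "B", "C", "D"))
    got <- mk_ancestral(tr, tips)
    ev <- branch_events(matrix(got$map, 1), tr)
    if (sum(ev$mb_gain) == 1L && ev$mb_gain[ev$child_label %in% "A"] == 1L)
      n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / 20, 0.9)
})

test_that("multiset intersection test is exact against enumeration", {
  # two sets of size 2 in a universe of 4 with full overlap: p = 1/6
  got <- multiset_intersection_test(list(c("a", "b"), c("a", "b")), 4)
  expect_equal(got$p.value, 1 / 6)
  # zero observed overlap: p = 1
  expect_equal(multiset_intersection_test(list("a", "b"), 4)$p.value, 1)

  # brute-force oracle over all placements, universes <= 8, three sets
  enum_p <- function(sizes, N, obs) {
    sets <- lapply(sizes, function(s) combn(N, s, simplify = FALSE))
    tot <- 0; hit <- 0
    for (s1 in sets[[1]]) for (s2 in sets[[2]]) for (s3 in sets[[3]]) {
      tot <- tot + 1
      if (length(Reduce(intersect, list(s1, s2, s3))) >= obs) hit <- hit + 1
    }
    hit / tot
  }
  u <- letters[1:6]
  cases <- list(list(c("a","b","c"), c("a","b"), c("a","b","c","d")),
                list(c("a","b"), c("c","d"), c("a","c")),
                list(c("a","b","c","d"), c("a","b","c"), c("a","b","c")))
  for (cs in cases) {
    obs <- length(Reduce(intersect, cs))
    got <- multiset_intersection_test(cs, 6)$p.value
    if (obs == 0) { expect_equal(got, 1); next }
    expect_equal(got, enum_p(lengths(cs), 6, obs), tolerance = 1e-12)
  }

  # Monte-Carlo mode converges to the exact value
  cs <- cases[[3]]
  ex <- multiset_intersection_test(cs, 6)$p.value
  mc <- multiset_intersection_test(cs, 6, method = "mc", n_draws = 20000,
                                   seed = 5)$p.value
  se <- sqrt(ex * (1 - ex) / 20000)
  expect_lt(abs(mc - ex), 3 * se + 1e-4)
  expect_error(multiset_intersection_test(list(letters[1:5]), 4), "universe")
})

test_that("contrasts match the closed form and Brownian calibration", {
  # two tips: (x1 - x2) / sqrt(b1 + b2)
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(pic_contrasts(tr2, c(A = 4, B = 2))), 2 / sqrt(2))
  # equal tip values: all contrasts zero
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(all(pic_contrasts(tr4, c(A = 3, B = 3, C = 3, D = 3)) == 0))
  # Brownian simulation: standardized contrasts have variance ~ sigma^2
  set.seed(6)
  sims <- replicate(1000, {
    x <- ape::rTraitCont(tr4, sigma = 1.5)
    pic_contrasts(tr4, x)
  })
  expect_equal(var(as.vector(sims)), 1.5^2, tolerance = 0.15)
  # determinism
  expect_identical(pic_contrasts(tr4, c(A = 1, B = 5, C = 2, D = 8)),
                   pic_contrasts(tr4, c(A = 1, B = 5, C = 2, D = 8)))
})

test_that("PIC class test equals brute-force U counting and responds to shifts", {
  vals <- setNames(c(0.1, 0.4, 0.2, 0.9, 1.4, 1.1, 0.8, 0.35),
                   paste0("g", 1:8))
  a <- paste0("g", 1:4); b <- paste0("g", 5:8)
  got <- pic_class_test(vals, a, b)
  # brute-force U: count pairs where a-value > b-value (+ 0.5 ties)
  u <- sum(outer(vals[a], vals[b], ">")) + 0.5 * sum(outer(vals[a], vals[b], "=="))
  expect_equal(got$statistic, u)
  # identical distributions: p = 1
  same <- setNames(rep(c(1, 2, 3), 4), paste0("h", 1:12))
  expect_equal(pic_class_test(same, paste0("h", 1:6),
                              paste0("h", 7:12))$p.value, 1)
  # shifting one class far away makes p collapse
  far <- vals; far[a] <- far[a] + 10
  expect_lt(pic_class_test(far, a, b)$p.value, got$p.value)
  expect_error(pic_class_test(vals, "g1", b), ">=2")
})

test_that("PGLS equals OLS on a star phylogeny and matrix GLS in general", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  star <- ape::multi2di(star)
  star$edge.length[star$edge.length == 0] <- 1e-12
  x <- c(A = 1, B = 2, C = 3, D = 4)
  y <- c(A = 2.2, B = 3.9, C = 6.1, D = 8.0)
  got <- pgls(x, y, star)
  ols <- lm(y ~ x)
  expect_equal(got$slope, unname(coef(ols)[2]), tolerance = 1e-6)
  expect_equal(got$intercept, unname(coef(ols)[1]), tolerance = 1e-6)

  # exact linear relation: slope 2, r^2 = 1 on any tree
  tr <- ape::read.tree(text = "((A:1,B:2):3,(C:2,D:1):2);")
  got2 <- pgls(x, 2 * x, tr)
  expect_equal(got2$slope, 2, tolerance = 1e-10)
  expect_equal(got2$r_squared, 1, tolerance = 1e-10)

  # hand matrix-algebra GLS oracle
  V <- ape::vcv(tr)[names(x), names(x)]
  X <- cbind(1, x)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
  got3 <- pgls(x, y, tr)
  expect_equal(got3$intercept, beta[1], tolerance = 1e-6)
  expect_equal(got3$slope, beta[2], tolerance = 1e-6)
})
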