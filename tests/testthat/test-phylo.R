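sp <- load_scfg_params()
unif4 <- make_subst_model(stats::setNames(rep(0.25, 4), c("A", "C", "G", "U")),
                          matrix(1, 4, 4))

test_that("parameter asset loads with valid grammar and models", {
  expect_s3_class(sp, "scfg_params")
  g <- sp$grammar
  expect_equal(unname(g[["S->LS"]] + g[["S->L"]]), 1, tolerance = 1e-9)
  expect_equal(unname(g[["L->s"]] + g[["L->dFd"]]), 1, tolerance = 1e-9)
  expect_equal(unname(g[["F->dFd"]] + g[["F->LS"]]), 1, tolerance = 1e-9)
  expect_true(all(g > 0))
  expect_equal(sum(sp$single$pi), 1, tolerance = 1e-12)
  expect_equal(sum(sp$pair$pi), 1, tolerance = 1e-12)
  canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
  expect_gt(sum(sp$pair$pi[canon]), 0.9)
  ## rate matrices: rows sum to zero, detailed balance (reversibility)
  for (m in list(sp$single, sp$pair)) {
    expect_lt(max(abs(rowSums(m$Q))), 1e-12)
    flux <- m$pi * m$Q
    expect_lt(max(abs(flux - t(flux))), 1e-12)
  }
})

test_that("transition matrices match series expansion; stochastic rows", {
  for (m in list(sp$single, sp$pair, unif4)) {
    for (t in c(0, 0.07, 0.5, 3)) {
      P <- transition_matrix(m, t)
      expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
      expect_lt(max(abs(P - hierfold:::.expm_series(m$Q * t))), 1e-9)
    }
    expect_lt(max(abs(transition_matrix(m, 0) - diag(m$nstate))), 1e-12)
  }
})

test_that("tree estimation: identical rows, saturation, NJ on near-additive data", {
  two <- make_aln(c("ACGUACGU", "ACGUACGU"))
  tr <- estimate_tree(two)
  expect_equal(sort(tr$tip.label), c("t1", "t2"))
  expect_equal(tr$edge.length, c(0, 0))

  sat <- make_aln(c("ACGU", "CAUG"))
  expect_error(estimate_tree(sat), "saturated")
  expect_error(estimate_tree(make_aln("ACGU")), "at least 2")

  ## 4 taxa: oracle = exhaustive topology search minimizing least squares
  ## over the hand-computed JC distance matrix
  set.seed(31)
  tree0 <- ape::read.tree(text = "((t1:0.10,t2:0.14):0.08,(t3:0.12,t4:0.16):0.08);")
  g <- generate_pair(synth_spec(tree = tree0, len1 = 400, len2 = 10,
                                helices1 = list(), helices2 = list(),
                                inter_pos1 = integer(0), inter_pos2 = integer(0),
                                seed = 31))
  aln <- g$aln1
  est <- estimate_tree(aln)
  ## hand JC distances
  mat <- hierfold:::aln_matrix(aln)
  D <- matrix(0, 4, 4)
  for (a in 1:3) for (b in (a + 1):4) {
    p <- mean(mat[a, ] != mat[b, ])
    D[a, b] <- D[b, a] <- -3 / 4 * log(1 - 4 * p / 3)
  }
  ## least-squares branch lengths for each of the 3 unrooted topologies
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  fit_ls <- function(pair1) {
    pair2 <- setdiff(1:4, pair1)
    ## design matrix for distances over edges e1..e4 (pendant) + e5 (internal)
    combs <- t(combn(4, 2))
    X <- matrix(0, 6, 5)
    y <- numeric(6)
    for (r in 1:6) {
      i <- combs[r, 1]; j <- combs[r, 2]
      X[r, i] <- 1; X[r, j] <- 1
      same <- (all(c(i, j) %in% pair1)) || (all(c(i, j) %in% pair2))
      if (!same) X[r, 5] <- 1
      y[r] <- D[i, j]
    }
    b <- qr.solve(X, y)
    list(rss = sum((X %*% b - y)^2), split = pair1)
  }
  fits <- lapply(splits, fit_ls)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "rss"))]]
  ## the estimated tree's internal split must equal the LS-best split
  est_split <- ape::prop.part(ape::unroot(est))
  tips <- est$tip.label
  found <- any(vapply(est_split, function(pp) {
    idx <- match(tips[pp], paste0("t", 1:4))
    setequal(idx, best$split) || setequal(idx, setdiff(1:4, best$split))
  }, TRUE))
  expect_true(found)
  expect_true(all(est$edge.length >= 0))
})

test_that("single-column pruning matches closed forms and matrix sums", {
  t1 <- fixed_tree(1)
  expect_equal(column_loglik(t1, unif4, "A"), log(0.25))
  ## two leaves, zero branch lengths: identity transitions
  t0 <- ape::read.tree(text = "(t1:0,t2:0);")
  expect_equal(column_loglik(t0, unif4, c("A", "A")), log(0.25))
  expect_equal(column_loglik(t0, unif4, c("A", "C")), -Inf)
  ## two leaves at t = 0.1: direct sum over root states with series oracle
  tt <- ape::read.tree(text = "(t1:0.1,t2:0.1);")
  P <- hierfold:::.expm_series(unif4$Q * 0.1)
  direct <- sum(0.25 * P[, 1] * P[, 2])   # residues A, C
  expect_equal(column_loglik(tt, unif4, c("A", "C")), log(direct),
               tolerance = 1e-9)
  ## gaps and N are missing data
  expect_equal(column_loglik(tt, unif4, c("-", "-")), 0)
  expect_equal(column_loglik(tt, unif4, c("A", "N")),
               column_loglik(tt, unif4, c("A", "-")))
  expect_error(column_loglik(tt, unif4, c("A", "X")), "alphabet")
})

test_that("pruning likelihoods normalize and are leaf-order invariant", {
  tt <- fixed_tree(2)
  tot <- sum(vapply(c("A", "C", "G", "U"), function(a)
    sum(vapply(c("A", "C", "G", "U"), function(b)
      exp(column_loglik(tt, sp$single, c(a, b))), 0)), 0))
  expect_equal(tot, 1, tolerance = 1e-9)
  ## named columns are matched to tips, so order does not matter
  expect_equal(column_loglik(tt, sp$single, c(t1 = "G", t2 = "U")),
               column_loglik(tt, sp$single, c(t2 = "U", t1 = "G")))
})

test_that("pair-column pruning: closed forms, enumeration oracle, saturation", {
  t1 <- fixed_tree(1)
  expect_equal(paircol_loglik(t1, sp$pair, "G", "C"),
               log(unname(sp$pair$pi["GC"])))
  tt <- fixed_tree(2)
  expect_equal(paircol_loglik(tt, sp$pair, c("-", "-"), c("-", "-")), 0)
  ## gap in one of the two columns: leaf missing in both
  expect_equal(paircol_loglik(tt, sp$pair, c("G", "-"), c("C", "A")),
               paircol_loglik(tt, sp$pair, c("G", "-"), c("C", "-")))

  ## 3-taxon tree equals brute-force sum over internal 16-state assignments
  tr3 <- ape::read.tree(text = "((t1:0.08,t2:0.13):0.06,t3:0.17);")
  ci <- c("G", "G", "A"); cj <- c("C", "U", "U")
  st <- function(a, b) (match(a, c("A", "C", "G", "U")) - 1) * 4 +
    match(b, c("A", "C", "G", "U"))
  leaves <- mapply(st, ci, cj)
  P1 <- hierfold:::.expm_series(sp$pair$Q * 0.08)
  P2 <- hierfold:::.expm_series(sp$pair$Q * 0.13)
  P3 <- hierfold:::.expm_series(sp$pair$Q * 0.06)
  P4 <- hierfold:::.expm_series(sp$pair$Q * 0.17)
  tot <- 0
  for (x in 1:16) for (y in 1:16) {   # root x, internal y
    tot <- tot + sp$pair$pi[x] * P4[x, leaves[3]] * P3[x, y] *
      P1[y, leaves[1]] * P2[y, leaves[2]]
  }
  expect_equal(paircol_loglik(tr3, sp$pair, ci, cj), log(unname(tot)),
               tolerance = 1e-9)

  ## long branches decouple the leaves into stationary draws
  tfar <- ape::read.tree(text = "(t1:50,t2:50);")
  v <- paircol_loglik(tfar, sp$pair, c("G", "A"), c("C", "U"))
  expect_equal(exp(v), unname(sp$pair$pi["GC"] * sp$pair$pi["AU"]),
               tolerance = 1e-6)
})

test_that("user-supplied Newick trees are validated against the taxa", {
  p <- tempfile(fileext = ".nwk")
  ape::write.tree(fixed_tree(3), p)
  tr <- read_tree_file(p, taxa = c("t1", "t2", "t3"))
  expect_s3_class(tr, "phylo")
  expect_error(read_tree_file(p, taxa = c("a", "b", "c")), "do not match")
  p2 <- tempfile(); writeLines("(t1:0.1,t2:-0.4);", p2)
  expect_error(read_tree_file(p2), "negative")
})
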