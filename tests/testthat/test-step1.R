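sp <- load_scfg_params()
em <- energy_model()

mk_rel <- function(pair, ss, beta = 1) {
  structure(list(pair = pair, ss = ss, L = nrow(pair), beta = beta,
                 alpha = 0.2, provenance = "step1"),
            class = "reliability_matrix")
}

test_that("gate applies the min/mean OR rule", {
  ps <- hierfold:::new_partial_structure(rbind(c(2, 8)), 1L, 0.6,
                                         ev_prob = 0.05,
                                         th_probs = c(0.5, 0.04))
  expect_false(gate(ps, 0.1, "min"))          # min(th) = 0.04 < 0.1, ev < 0.1
  expect_true(gate(ps, 0.1, "mean"))          # mean(th) = 0.27 >= 0.1
  ps2 <- hierfold:::new_partial_structure(rbind(c(2, 8)), 1L, 0.6,
                                          ev_prob = 0.05,
                                          th_probs = c(0.5, 0.2))
  expect_true(gate(ps2, 0.1, "min"))
  ## empty partial has probability 1 everywhere
  ps3 <- hierfold:::new_partial_structure(matrix(integer(0), 0, 2), 1L, 0.9,
                                          ev_prob = 1, th_probs = c(1, 1))
  expect_true(gate(ps3, 1, "min"))
})

test_that("selection: empty case, conflict-freeness, cutoff adaptation", {
  ## (2,9) is a clean G-C pair with a legal loop; (4,6) is G-C but its
  ## 1-nt hairpin is impossible thermodynamically and its span is below the
  ## grammar minimum, so any selection containing it has probability 0 in
  ## both models
  aln <- make_aln(c("AGAGACAACUA", "AGAGACAACUA"))
  tree <- estimate_tree(aln)
  L <- aln$L
  params <- hf_params()
  ## all reliabilities at or below the start cutoff: empty partial, 1 pass
  low <- mk_rel(matrix(0.4, L, L) * upper.tri(matrix(0, L, L)), rep(0.1, L))
  low$pair <- low$pair + t(low$pair)
  ps <- select_partial(low, aln, tree, params, sp, em)
  expect_equal(nrow(ps$pairs), 0L)
  expect_equal(ps$ev_prob, 1)
  expect_equal(ps$th_probs, c(1, 1))
  expect_equal(attr(ps, "iterations"), 1L)

  ## selections above a cutoff > 0.5 of a normalized posterior are
  ## automatically conflict-free
  set.seed(61)
  for (rep in 1:20) {
    P <- random_nested_posterior(9)
    sel <- which(upper.tri(P) & P > 0.55, arr.ind = TRUE)
    expect_silent(hierfold:::check_noncrossing(sel))
  }

  ## scripted adaptation fixture: a low cutoff sweeps in a pair that is
  ## impossible in both models; gamma is placed between the measured
  ## ensemble probabilities so the adaptation must raise the cutoff
  pairm <- matrix(0, L, L)
  pairm[2, 9] <- 1.24   # normalized 0.62: survives cutoff 0.60
  pairm[4, 6] <- 1.12   # normalized 0.56: impossible (span below minimum)
  pairm <- pairm + t(pairm)
  rel <- mk_rel(pairm, rep(0.05, L))
  good <- rbind(c(2, 9))
  p_good_ev <- evo_ensemble_prob(aln, tree, sp, good)
  p_good_th <- min(vapply(1:2, function(s)
    as.numeric(thermo_ensemble_prob(aln$rows[s], em,
                                    map_consensus_to_seq(good, aln, s))), 0))
  gamma <- max(p_good_ev, p_good_th) / 2
  expect_gt(gamma, 0)   # the good selection is attainable
  params2 <- hf_params(gamma = gamma, delta_start = 0.5, delta_step = 0.05)
  ps2 <- select_partial(rel, aln, tree, params2, sp, em)
  expect_equal(unname(ps2$pairs), rbind(c(2L, 9L)))
  expect_equal(ps2$delta_used, 0.6)
  expect_lte(attr(ps2, "iterations"),
             ceiling((1 - 0.5) / params2$delta_step) + 1)
  expect_gte(ps2$delta_used, 0.5)
})

test_that("stem extension adds inner/outer pairs under both conditions", {
  ## complementary stem with a roomy loop; all rows identical for clarity
  aln <- make_aln(rep("AGGGGAAAAACCCCAA", 3))
  tree <- estimate_tree(aln)
  L <- aln$L
  ## seed partial: middle of the helix (3,13),(4,12); reliabilities reward
  ## the inner (5,11) and outer (2,14) extensions
  pairm <- matrix(0, L, L)
  for (p in list(c(3, 13), c(4, 12), c(5, 11), c(2, 14))) {
    pairm[p[1], p[2]] <- pairm[p[2], p[1]] <- 1.9
  }
  rel <- mk_rel(pairm, rep(0.05, L))
  params <- hf_params(gamma = 1e-6)
  ps <- hierfold:::new_partial_structure(
    rbind(c(3, 13), c(4, 12)), 1L, 0.9,
    ev_prob = evo_ensemble_prob(aln, tree, sp, rbind(c(3, 13), c(4, 12))),
    th_probs = vapply(1:3, function(s)
      as.numeric(thermo_ensemble_prob(aln$rows[s], em,
                                      rbind(c(3, 13), c(4, 12)))), 0))
  ext <- extend_stems(ps, rel, params, aln, tree, sp, em)
  expect_true(all(c("5 11", "2 14") %in% paste(ext$pairs[, 1], ext$pairs[, 2])))
  ## never removes pairs; stays conflict-free; still passes the gate
  expect_true(all(paste(ps$pairs[, 1], ps$pairs[, 2]) %in%
                  paste(ext$pairs[, 1], ext$pairs[, 2])))
  expect_silent(hierfold:::check_noncrossing(ext$pairs))
  expect_true(gate(ext, params$gamma, params$gamma_agg))

  ## a candidate that would collide with an existing pair is not added:
  ## occupy position 1 so the outer extension (1,15) is blocked
  pairm2 <- pairm
  pairm2[1, 15] <- pairm2[15, 1] <- 1.9
  rel2 <- mk_rel(pairm2, rep(0.05, L))
  blocked <- rbind(c(1, 16))   # position 1 already used, (1,15) would collide
  psb <- hierfold:::new_partial_structure(
    rbind(ps$pairs, blocked), 1L, 0.9, ev_prob = ps$ev_prob,
    th_probs = rep(1, 3))
  extb <- extend_stems(psb, rel2, params, aln, tree, sp, em)
  expect_false("1 15" %in% paste(extb$pairs[, 1], extb$pairs[, 2]))

  ## empty partial is unchanged
  pse <- hierfold:::new_partial_structure(matrix(integer(0), 0, 2), 1L, 0.9,
                                          1, rep(1, 3))
  expect_equal(nrow(extend_stems(pse, rel, params, aln, tree, sp, em)$pairs),
               0L)
})
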