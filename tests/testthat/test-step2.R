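sp <- load_scfg_params()
em <- energy_model()

empty_partial <- function(part, n) {
  hierfold:::new_partial_structure(matrix(integer(0), 0, 2), part, 0.9,
                                   ev_prob = 1, th_probs = rep(1, n))
}

test_that("empty partials reduce Step 2 to unconstrained scoring", {
  pr <- fixture_pair(3)
  partials <- list(empty_partial(1, 3), empty_partial(2, 3))
  th2 <- thermo_step2(pr, partials, em, hf_params())
  expect_equal(th2$scale1, rep(1, 3))
  expect_equal(th2$scale2, rep(1, 3))
  for (s in 1:3) {
    cf <- cofold_partition(hierfold:::ungapped_seq(pr$aln1, s),
                           hierfold:::ungapped_seq(pr$aln2, s), em)
    expect_equal(th2$P[[s]], hierfold:::.seq_prob_to_cols_cat(cf$pair_prob, pr, s),
                 tolerance = 1e-12)
    expect_equal(th2$ss[[s]],
                 hierfold:::.seq_ss_to_cols_cat(cf$unpaired_prob, pr, s),
                 tolerance = 1e-12)
  }
  ev2 <- evo_step2(pr, partials, scfg = sp, params = hf_params())
  ca <- concatenate(pr, "evo")
  po <- inside_outside(ca, ev2$tree, sp)
  keep <- global_to_phys(ca, seq_len(ca$L))
  expect_equal(ev2$P, po$pair_rel[keep, keep], tolerance = 1e-12)
  expect_equal(ev2$ss, po$ss_rel[keep], tolerance = 1e-12)
})

test_that("Eq.-(16)-style rescaling: fixed rule and product rule", {
  pr <- fixture_pair(2)
  n <- 2
  L1 <- pr$aln1$L
  ## constrain the strong stem of part 1; part 2 stays free
  sig1 <- rbind(c(3, 16), c(4, 15))
  partials <- list(
    hierfold:::new_partial_structure(
      sig1, 1L, 0.6,
      ev_prob = evo_ensemble_prob(pr$aln1, estimate_tree(pr$aln1), sp, sig1),
      th_probs = vapply(1:n, function(s)
        as.numeric(thermo_ensemble_prob(hierfold:::ungapped_seq(pr$aln1, s), em,
                                        map_consensus_to_seq(sig1, pr$aln1, s))), 0)),
    empty_partial(2, n))
  params <- hf_params()
  th2 <- thermo_step2(pr, partials, em, params)
  for (s in 1:n) {
    s1 <- hierfold:::ungapped_seq(pr$aln1, s)
    s2 <- hierfold:::ungapped_seq(pr$aln2, s)
    sc1 <- partials[[1]]$th_probs[s]; sc2 <- 1
    expect_equal(th2$scale1[s], sc1)
    ## raw cofold with the sigma^p positions single-stranded
    fu <- as.vector(map_consensus_to_seq(sig1, pr$aln1, s))
    ## positions project 1:1 here (gapless rows)
    cf <- cofold_partition(s1, s2, em,
                           constraint = list(forced_unpaired = sort(unique(c(
                             sig1[, 1], sig1[, 2])))))
    raw <- hierfold:::.seq_prob_to_cols_cat(cf$pair_prob, pr, s)
    ## constrained pairs carry the fixed per-sequence ensemble probability
    for (r in seq_len(nrow(sig1))) {
      expect_equal(th2$P[[s]][sig1[r, 1], sig1[r, 2]], sc1)
    }
    ## all other pairs: raw times the product of the two scale factors
    other <- th2$P[[s]]
    other[sig1] <- raw[sig1]; other[sig1[, c(2, 1)]] <- raw[sig1[, c(2, 1)]]
    expect_equal(other, raw * sc1 * sc2, tolerance = 1e-12)
    ## single-stranded: sigma^p positions 0, others rescaled raw
    sig_pos <- sort(unique(as.vector(sig1)))
    expect_equal(th2$ss[[s]][sig_pos], rep(0, length(sig_pos)))
    rawss <- hierfold:::.seq_ss_to_cols_cat(cf$unpaired_prob, pr, s)
    expect_equal(th2$ss[[s]][-sig_pos], (rawss * sc1 * sc2)[-sig_pos],
                 tolerance = 1e-12)
    ## scale factors never exceed 1; rescaled never exceeds raw
    expect_lte(sc1, 1)
    expect_true(all(other <= raw + 1e-12))
  }
  ## eq15 variant scores constrained pairs with weight 1
  th15 <- thermo_step2(pr, partials, em, hf_params(eq15 = TRUE))
  for (r in seq_len(nrow(sig1))) {
    expect_equal(th15$P[[1]][sig1[r, 1], sig1[r, 2]], 1)
  }
})

test_that("evolutionary Step 2 rescales by the part ensemble probabilities", {
  pr <- fixture_pair(3)
  sig1 <- rbind(c(3, 16), c(4, 15))
  e1 <- evo_ensemble_prob(pr$aln1, estimate_tree(pr$aln1), sp, sig1)
  partials <- list(
    hierfold:::new_partial_structure(sig1, 1L, 0.6, ev_prob = e1,
                                     th_probs = rep(1, 3)),
    empty_partial(2, 3))
  ev2 <- evo_step2(pr, partials, scfg = sp, params = hf_params())
  expect_equal(ev2$scale1, e1)
  expect_equal(ev2$scale2, 1)
  ## raw constrained posterior recomputed directly, then Eq.-(18) algebra
  ca <- concatenate(pr, "evo")
  cc <- structure_constraint(ca$phys_L,
                             forced_unpaired = global_to_phys(ca, unique(as.vector(sig1))),
                             prior_free = ca$prior_free)
  po <- inside_outside(ca, ev2$tree, sp, cc)
  keep <- global_to_phys(ca, seq_len(ca$L))
  raw <- po$pair_rel[keep, keep]
  manual <- raw * e1 * 1
  for (r in seq_len(nrow(sig1))) {
    manual[sig1[r, 1], sig1[r, 2]] <- e1
    manual[sig1[r, 2], sig1[r, 1]] <- e1
  }
  expect_equal(ev2$P, manual, tolerance = 1e-12)
  ## sigma^p positions single-stranded probability 0
  expect_equal(ev2$ss[unique(as.vector(sig1))],
               rep(0, length(unique(as.vector(sig1)))))
  ## no pair involving a sigma^p position except the sigma^p pairs
  off <- ev2$P[unique(as.vector(sig1)), ]
  off[cbind(match(sig1[, 1], unique(as.vector(sig1))), sig1[, 2])] <- 0
  off[cbind(match(sig1[, 2], unique(as.vector(sig1))), sig1[, 1])] <- 0
  expect_equal(sum(off), 0)
})

test_that("combination mirrors the Step-1 formula", {
  pr <- fixture_pair(2)
  partials <- list(empty_partial(1, 2), empty_partial(2, 2))
  params <- hf_params(alpha = 0.3, beta = 0.8)
  th2 <- thermo_step2(pr, partials, em, params)
  ev2 <- evo_step2(pr, partials, scfg = sp, params = params)
  rel2 <- combine_step2(ev2, th2, params)
  hand <- ev2$P + (params$beta / 2) * (th2$P[[1]] + th2$P[[2]])
  expect_equal(rel2$pair, hand, tolerance = 1e-12)
  expect_equal(rel2$ss,
               params$alpha * (ev2$ss + (params$beta / 2) * (th2$ss[[1]] + th2$ss[[2]])),
               tolerance = 1e-12)
  expect_lt(max(abs(rel2$pair - t(rel2$pair))), 1e-12)
  ## beta = 0: evolutionary component only
  rel0 <- combine_step2(ev2, th2, hf_params(beta = 0))
  expect_equal(rel0$pair, ev2$P, tolerance = 1e-15)
})

test_that("independence of the parts when no inter-molecular pairs exist", {
  ## no residue of s2 can pair with any residue of s1 or s2
  s1 <- "GGGAAACCC"; s2 <- "AAAA"
  single <- partition(s1, em)
  cf <- cofold_partition(s1, s2, em)
  expect_equal(cf$pair_prob[1:9, 1:9], single$pair_prob, tolerance = 1e-9)
  expect_equal(sum(cf$pair_prob[, 10:13]), 0)
})
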