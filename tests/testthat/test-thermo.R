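em <- energy_model()

test_that("degenerate ensembles: open chain only", {
  p <- partition("AAAA", em)
  expect_equal(p$logZ, 0)           # open chain has energy 0
  expect_equal(p$dG, 0)
  expect_equal(sum(p$pair_prob), 0)
  expect_equal(p$unpaired_prob, rep(1, 4))
  ## constraint forcing all positions unpaired
  p2 <- partition("GGGAAACCC", em,
                  constraint = list(forced_unpaired = 1:9))
  expect_equal(p2$logZ, 0)
  expect_equal(sum(p2$pair_prob), 0)
})

test_that("partition matches Boltzmann enumeration (incl. constraints)", {
  set.seed(5)
  o <- oracle_thermo("GGGAAACCC", em)
  p <- partition("GGGAAACCC", em)
  expect_lt(max(abs(p$pair_prob - o$P)), 1e-9)
  expect_equal(exp(p$logZ) / o$Z, 1, tolerance = 1e-12)
  for (rep in 1:6) {
    L <- sample(6:11, 1)
    s <- random_rna(L)
    fu <- sample(seq_len(L), sample(0:2, 1))
    cons <- if (length(fu)) list(forced_unpaired = fu) else NULL
    o <- oracle_thermo(s, em, constraint = cons)
    p <- partition(s, em, constraint = cons)
    expect_lt(max(abs(p$pair_prob - o$P)), 1e-9)
    expect_equal(exp(p$logZ) / max(o$Z, 1e-300), 1, tolerance = 1e-9)
    expect_true(all(abs(p$pair_prob - t(p$pair_prob)) < 1e-12))
    expect_true(all(rowSums(p$pair_prob) <= 1 + 1e-9))
  }
})

test_that("cofolding: linker semantics and enumeration equivalence", {
  cf <- cofold_partition("GGG", "CCC", em)
  expect_gt(sum(cf$pair_prob[1:3, 4:6]), 0)   # only inter pairs possible
  expect_equal(sum(cf$pair_prob[1:3, 1:3]), 0)
  ## all of s1 forced unpaired kills every pair
  cf0 <- cofold_partition("GGG", "CCC", em,
                          constraint = list(forced_unpaired = 1:3))
  expect_equal(sum(cf0$pair_prob), 0)
  ## linker exemption from the hairpin minimum: G & C pair at distance 1
  g1 <- cofold_partition("G", "C", em)
  expect_equal(g1$pair_prob[1, 2], 0.5)       # pair and open chain, energy 0
  set.seed(12)
  for (rep in 1:5) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    s1 <- random_rna(n1); s2 <- random_rna(n2)
    o <- oracle_thermo(paste0(s1, s2), em, cut = n1)
    p <- cofold_partition(s1, s2, em)
    expect_lt(max(abs(p$pair_prob - o$P)), 1e-9)
    expect_equal(exp(p$logZ) / o$Z, 1, tolerance = 1e-9)
  }
})

test_that("isolated-pair filtering matches its enumeration semantics", {
  emn <- energy_model(no_isolated = TRUE)
  set.seed(19)
  for (rep in 1:4) {
    n1 <- sample(4:7, 1); n2 <- sample(4:7, 1)
    s1 <- random_rna(n1); s2 <- random_rna(n2)
    o <- oracle_thermo(paste0(s1, s2), emn, cut = n1)
    p <- cofold_partition(s1, s2, emn)
    expect_lt(max(abs(p$pair_prob - o$P)), 1e-9)
    expect_equal(exp(p$logZ) / o$Z, 1, tolerance = 1e-9)
  }
  ## a lone canonical pair is removed by the filter
  p1 <- partition("GAAAC", emn)
  expect_equal(sum(p1$pair_prob), 0)
  p2 <- partition("GAAAC", em)
  expect_gt(p2$pair_prob[1, 5], 0)
})

test_that("thermodynamic ensemble probability of partial structures", {
  expect_equal(thermo_ensemble_prob("GGGAAACCC", em, NULL), 1)
  ## single-helix sequence: constrained mass equals the oracle ratio
  s <- "GGGAAAACCC"
  o <- oracle_thermo(s, em)
  oc <- oracle_thermo(s, em, constraint = list(forced_pairs = rbind(c(1, 10))))
  expect_equal(as.numeric(thermo_ensemble_prob(s, em, rbind(c(1, 10)))),
               oc$Z / o$Z, tolerance = 1e-9)
  ## monotone under supersets of constraints
  pr1 <- thermo_ensemble_prob(s, em, rbind(c(1, 10)))
  pr2 <- thermo_ensemble_prob(s, em, rbind(c(1, 10), c(2, 9)))
  expect_lte(as.numeric(pr2), as.numeric(pr1) + 1e-12)
  expect_true(all(c(pr1, pr2) >= 0 & c(pr1, pr2) <= 1))
  ## non-canonical pair: probability 0 and the pair is flagged
  bad <- thermo_ensemble_prob("GGGAAACCC", em, rbind(c(1, 4)))  # G-A
  expect_equal(as.numeric(bad), 0)
  expect_equal(nrow(attr(bad, "illegal_pairs")), 1L)
  expect_error(thermo_ensemble_prob(s, em, rbind(c(1, 10), c(5, 12))))
})

test_that("consensus-to-sequence projection drops gap and non-canonical ends", {
  aln <- make_aln(c("GGCAAAGC-U", "GGCAAAGCCU", "GACAAAGCUU"))
  ## consensus pair (2, 9): row 1 gapped at col 9 -> dropped
  m1 <- map_consensus_to_seq(rbind(c(2, 9)), aln, 1)
  expect_equal(nrow(m1), 0L)
  expect_equal(nrow(attr(m1, "dropped_gap")), 1L)
  ## row 2 keeps it at mapped coordinates (no gaps upstream)
  m2 <- map_consensus_to_seq(rbind(c(2, 9)), aln, 2)
  expect_equal(unname(m2[1, ]), c(2L, 9L))
  ## row 3: projected G-U is canonical; A at 2 with U at 9 is canonical too
  ## exhaustive hand-mapped check over all rows for two consensus pairs
  cons <- rbind(c(1, 10), c(3, 8))
  for (s in 1:3) {
    got <- map_consensus_to_seq(cons, aln, s)
    chars <- strsplit(aln$rows[s], "")[[1]]
    pos <- cumsum(chars != "-")
    expected <- list()
    for (r in 1:2) {
      i <- cons[r, 1]; j <- cons[r, 2]
      if (chars[i] == "-" || chars[j] == "-") next
      a <- chars[i]; b <- chars[j]
      if (paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")) {
        expected[[length(expected) + 1L]] <- c(pos[i], pos[j])
      }
    }
    expected <- if (length(expected)) do.call(rbind, expected) else
      matrix(integer(0), 0, 2)
    expect_equal(unname(got[, , drop = FALSE]), unname(expected))
  }
})

test_that("pair-probability dump is plain text with correct values", {
  p <- partition("GGGAAACCC", em)
  f <- tempfile()
  dump_pair_probs(p, f)
  tab <- utils::read.table(f, header = TRUE)
  expect_true(all(tab$i < tab$j))
  expect_equal(tab$prob, p$pair_prob[cbind(tab$i, tab$j)], tolerance = 1e-12)
})
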