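## Seeded synthetic alignment-pair generator: evolves a sequence pair down a
## tree with planted conserved intra-molecular stems and a covarying
## inter-molecular binding site (compensatory co-substitution at planted
## pair columns), emitting the alignments plus the planted ground truth.

#' Specification of a synthetic alignment pair
#'
#' Defaults describe the package's standard validation condition: 5 taxa on
#' a fixed tree (branch lengths 0.06-0.18 substitutions/site), two 60 nt
#' parts, two 4-bp planted stems per part, and one 6-bp inter-molecular
#' site placed in the loops of the first stem of each part (a kissing-hairpin
#' geometry).
#'
#' @param tree Newick string or ape `phylo` with branch lengths.
#' @param len1,len2 part lengths (columns; the alignments are gapless unless
#'   `gap_rate > 0`).
#' @param helices1,helices2 planted stems per part: list of `c(i, j, len)`,
#'   the outermost pair and the helix length.
#' @param inter_pos1,inter_pos2 planted inter-molecular site: equal-length
#'   vectors of part-local positions; `inter_pos1[k]` pairs with
#'   `inter_pos2[k]`.
#' @param compensatory evolve planted pair columns under the 16-state pair
#'   model conditioned on canonical pairs (compensatory co-substitution);
#'   otherwise the two columns evolve independently.
#' @param gap_rate per-cell probability of replacing a background (unpaired)
#'   residue by a gap.
#' @param scfg parameter set providing the substitution models.
#' @param seed integer seed (`NULL`: use the current RNG state).
#' @return a `synth_spec`.
#' @export
synth_spec <- function(tree = "((t1:0.12,t2:0.12):0.06,(t3:0.12,t4:0.12):0.06,t5:0.18);",
                       len1 = 60L, len2 = 60L,
                       helices1 = list(c(8L, 28L, 4L), c(36L, 52L, 4L)),
                       helices2 = list(c(7L, 27L, 4L), c(34L, 50L, 4L)),
                       inter_pos1 = 14:19, inter_pos2 = 21:16,
                       compensatory = TRUE, gap_rate = 0,
                       scfg = load_scfg_params(), seed = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  helix_pairs <- function(hx) {
    if (length(hx) == 0L) return(matrix(integer(0), 0, 2))
    do.call(rbind, lapply(hx, function(h) {
      stopifnot(length(h) == 3L, h[3] >= 1L)
      cbind(h[1] + seq_len(h[3]) - 1L, h[2] - seq_len(h[3]) + 1L)
    }))
  }
  s1 <- helix_pairs(helices1)
  s2 <- helix_pairs(helices2)
  stopifnot(length(inter_pos1) == length(inter_pos2))
  if (any(s1 < 1L | s1 > len1) || any(s2 < 1L | s2 > len2) ||
      any(inter_pos1 < 1L | inter_pos1 > len1) ||
      any(inter_pos2 < 1L | inter_pos2 > len2)) {
    stop("infeasible spec: planted element outside part range", call. = FALSE)
  }
  check_noncrossing(s1, "planted part-1 stems")
  check_noncrossing(s2, "planted part-2 stems")
  if (anyDuplicated(c(as.vector(s1), inter_pos1)) ||
      anyDuplicated(c(as.vector(s2), inter_pos2))) {
    stop("infeasible spec: planted elements overlap", call. = FALSE)
  }
  structure(list(tree = tree, len1 = len1, len2 = len2,
                 sigma1 = s1, sigma2 = s2,
                 inter_pos1 = as.integer(inter_pos1),
                 inter_pos2 = as.integer(inter_pos2),
                 compensatory = isTRUE(compensatory), gap_rate = gap_rate,
                 scfg = scfg, seed = seed),
            class = "synth_spec")
}

## sample index from (possibly unnormalized) non-negative weights
.sample_state <- function(w) {
  sample.int(length(w), 1L, prob = w)
}

CANON_IDX <- c(4L, 13L, 10L, 7L, 12L, 15L)  # AU UA GC CG GU UG in 16-state order

## evolve one column (or column pair) down the tree; returns leaf states
.evolve_states <- function(tree, model, root_weights, restrict = NULL) {
  tree <- stats::reorder(tree, "postorder")
  edges <- tree$edge
  ntip <- length(tree$tip.label)
  root <- edges[nrow(edges), 1]
  nnode <- ntip + tree$Nnode
  state <- integer(nnode)
  w <- root_weights
  if (!is.null(restrict)) {
    w2 <- rep(0, length(w)); w2[restrict] <- w[restrict]; w <- w2
  }
  state[root] <- .sample_state(w)
  for (e in rev(seq_len(nrow(edges)))) {      # preorder
    par <- edges[e, 1]; chd <- edges[e, 2]
    P <- transition_matrix(model, tree$edge.length[e])
    w <- P[state[par], ]
    if (!is.null(restrict)) {
      w2 <- rep(0, length(w)); w2[restrict] <- w[restrict]; w <- w2
    }
    state[chd] <- .sample_state(w)
  }
  state[seq_len(ntip)]
}

#' Generate a synthetic alignment pair with planted ground truth
#'
#' Draws a root sequence pair, evolves it down the tree (independent
#' single-nucleotide substitutions at background positions; compensatory
#' 16-state co-substitution restricted to canonical pairs at planted pair
#' columns), and returns the paired alignments together with the planted
#' joint structure.
#'
#' @param spec a [synth_spec()].
#' @return list with `pair` (an `alignment_pair`), `truth` (a
#'   `joint_structure` carrying the planted pairs) and the per-part
#'   alignments `aln1`, `aln2`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  tree <- spec$tree
  ntip <- length(tree$tip.label)
  single <- spec$scfg$single
  pairm <- spec$scfg$pair
  m1 <- matrix("", ntip, spec$len1)
  m2 <- matrix("", ntip, spec$len2)
  ## planted pair columns: (col-in-part1-or-2 coding via part flag)
  blk <- function(i, pi_, j, pj_) {
    if (length(i) == 0L) matrix(integer(0), 0, 4) else
      cbind(i, rep(pi_, length(i)), j, rep(pj_, length(j)))
  }
  plant <- rbind(blk(spec$sigma1[, 1], 1L, spec$sigma1[, 2], 1L),
                 blk(spec$sigma2[, 1], 2L, spec$sigma2[, 2], 2L),
                 blk(spec$inter_pos1, 1L, spec$inter_pos2, 2L))
  restrict <- if (spec$compensatory) CANON_IDX else NULL
  for (r in seq_len(nrow(plant))) {
    if (spec$compensatory) {
      st <- .evolve_states(tree, pairm, pairm$pi, restrict)
      a <- (st - 1L) %/% 4L + 1L
      b <- (st - 1L) %% 4L + 1L
    } else {
      a <- .evolve_states(tree, single, single$pi)
      b <- .evolve_states(tree, single, single$pi)
    }
    if (plant[r, 2] == 1L) m1[, plant[r, 1]] <- NT[a] else
      m2[, plant[r, 1]] <- NT[a]
    if (plant[r, 4] == 1L) m1[, plant[r, 3]] <- NT[b] else
      m2[, plant[r, 3]] <- NT[b]
  }
  bg1 <- which(m1[1, ] == "")
  bg2 <- which(m2[1, ] == "")
  for (i in bg1) m1[, i] <- NT[.evolve_states(tree, single, single$pi)]
  for (i in bg2) m2[, i] <- NT[.evolve_states(tree, single, single$pi)]
  if (spec$gap_rate > 0) {
    g1 <- matrix(stats::runif(ntip * spec$len1) < spec$gap_rate,
                 ntip, spec$len1)
    g1[, setdiff(seq_len(spec$len1), bg1)] <- FALSE
    m1[g1] <- "-"
    g2 <- matrix(stats::runif(ntip * spec$len2) < spec$gap_rate,
                 ntip, spec$len2)
    g2[, setdiff(seq_len(spec$len2), bg2)] <- FALSE
    m2[g2] <- "-"
  }
  taxa <- tree$tip.label
  aln1 <- new_rna_alignment(taxa, apply(m1, 1L, paste, collapse = ""))
  aln2 <- new_rna_alignment(taxa, apply(m2, 1L, paste, collapse = ""))
  pair <- pair_taxa(aln1, aln2, policy = "exact_id")
  n_int <- length(spec$inter_pos1)
  truth <- new_joint_structure(
    sigma1 = spec$sigma1, sigma2 = spec$sigma2,
    sigma_int = cbind(spec$inter_pos1, spec$len1 + spec$inter_pos2),
    layers = c(rep("constrained", nrow(spec$sigma1) + nrow(spec$sigma2)),
               rep("step2-inter", n_int)),
    rels = rep(NA_real_, nrow(spec$sigma1) + nrow(spec$sigma2) + n_int),
    L1 = spec$len1, L2 = spec$len2)
  list(pair = pair, truth = truth, aln1 = aln1, aln2 = aln2)
}
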