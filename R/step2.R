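## Step 2: constrained expected-accuracy scoring of the concatenated
## alignment.  The partial structures from Step 1 are constrained
## single-stranded during cofolding (so that inter-molecular pairs with the
## induced loop regions -- pseudoknots relative to the constrained pairs --
## stay accessible to a nested DP), and the raw constrained probabilities
## are rescaled by the Step-1 ensemble probabilities; the constrained pairs
## themselves keep their fixed ensemble probability.

## positions (global coordinates 1..L1+L2) covered by the two partials
.sigma_positions <- function(partials, L1) {
  p1 <- as.vector(partials[[1]]$pairs)
  p2 <- as.vector(partials[[2]]$pairs) + L1
  sort(unique(c(p1, p2)))
}

.sigma_pairs_global <- function(partials, L1) {
  rbind(partials[[1]]$pairs,
        partials[[2]]$pairs + L1)
}

#' Step-2 thermodynamic scoring (constrained cofolding)
#'
#' For every row `s1 & s2` of the paired alignment: the Step-1 partial
#' structure positions are projected onto the row and constrained
#' single-stranded, the row is cofolded, and the raw pair probabilities are
#' rescaled by the product of the two per-sequence Step-1 ensemble
#' probabilities.  Pairs belonging to a partial structure get that partial's
#' fixed per-sequence ensemble probability instead (weight 1 under the
#' `eq15` variant).  Single-stranded probabilities follow the same
#' rescaling; partial-structure positions get 0 (they are paired in the
#' final structure).
#'
#' @param pair an `alignment_pair`.
#' @param partials list of the two `partial_structure`s (parts 1 and 2).
#' @param emodel an [energy_model()].
#' @param params an [hf_params()].
#' @return list with per-sequence `P` matrices and `ss` vectors on global
#'   coordinates (1..L1+L2), the per-sequence scale factors, and flags for
#'   rows with an illegal partial-structure projection.
#' @export
thermo_step2 <- function(pair, partials, emodel = energy_model(),
                         params = hf_params()) {
  L1 <- pair$aln1$L; L2 <- pair$aln2$L
  n <- pair$aln1$n
  L <- L1 + L2
  sig_pos <- .sigma_positions(partials, L1)
  sig_pairs <- .sigma_pairs_global(partials, L1)
  Ps <- vector("list", n)
  sss <- vector("list", n)
  scale1 <- scale2 <- numeric(n)
  flagged <- logical(n)
  for (s in seq_len(n)) {
    s1 <- ungapped_seq(pair$aln1, s)
    s2 <- ungapped_seq(pair$aln2, s)
    n1 <- nchar(s1)
    ## per-sequence Step-1 ensemble probabilities (Step 1 stores them in
    ## alignment row order)
    scale1[s] <- partials[[1]]$th_probs[s]
    scale2[s] <- partials[[2]]$th_probs[s]
    if (scale1[s] == 0 || scale2[s] == 0) flagged[s] <- TRUE
    ## project sigma^p positions onto this row (concatenated coordinates)
    fu1 <- col_to_seqpos(pair$aln1, s, sig_pos[sig_pos <= L1])
    fu2 <- col_to_seqpos(pair$aln2, s, sig_pos[sig_pos > L1] - L1)
    fu <- c(fu1[!is.na(fu1)], fu2[!is.na(fu2)] + n1)
    tr <- cofold_partition(s1, s2, emodel,
                           constraint = list(forced_unpaired = fu))
    Praw <- .seq_prob_to_cols_cat(tr$pair_prob, pair, s)
    ssraw <- .seq_ss_to_cols_cat(tr$unpaired_prob, pair, s)
    sc <- scale1[s] * scale2[s]
    P <- Praw * sc
    ss <- ssraw * sc
    ## fixed-probability rule for the constrained pairs themselves
    if (nrow(sig_pairs) > 0L) {
      for (r in seq_len(nrow(sig_pairs))) {
        i <- sig_pairs[r, 1]; j <- sig_pairs[r, 2]
        fixed <- if (params$eq15) 1 else if (i <= L1 && j <= L1) scale1[s]
        else scale2[s]
        P[i, j] <- fixed
        P[j, i] <- fixed
      }
      ss[sig_pos] <- 0
    }
    Ps[[s]] <- P
    sss[[s]] <- ss
  }
  list(P = Ps, ss = sss, scale1 = scale1, scale2 = scale2, flagged = flagged,
       L = L, L1 = L1)
}

## map cofold matrices (row coordinates of s1s2) to global columns
.seq_prob_to_cols_cat <- function(P, pair, s) {
  c1 <- strsplit(pair$aln1$rows[s], "", fixed = TRUE)[[1]]
  c2 <- strsplit(pair$aln2$rows[s], "", fixed = TRUE)[[1]]
  nongap <- c(which(c1 != "-"), pair$aln1$L + which(c2 != "-"))
  out <- matrix(0, pair$aln1$L + pair$aln2$L, pair$aln1$L + pair$aln2$L)
  out[nongap, nongap] <- P
  out
}

.seq_ss_to_cols_cat <- function(up, pair, s) {
  c1 <- strsplit(pair$aln1$rows[s], "", fixed = TRUE)[[1]]
  c2 <- strsplit(pair$aln2$rows[s], "", fixed = TRUE)[[1]]
  nongap <- c(which(c1 != "-"), pair$aln1$L + which(c2 != "-"))
  out <- rep(1, pair$aln1$L + pair$aln2$L)
  out[nongap] <- up
  out
}

#' Step-2 evolutionary scoring (constrained joint-alignment folding)
#'
#' Runs the constrained phylo-SCFG on the concatenated alignment (three
#' prior-free linker columns; single tree deduced from the concatenation)
#' with the Step-1 positions forced unpaired, then rescales the raw
#' posteriors by `Pr_ev[E(sigma1)] * Pr_ev[E(sigma2)]`; the constrained
#' pairs themselves get their part's fixed evolutionary ensemble
#' probability.  Matrices are returned on global coordinates (linker columns
#' removed).
#'
#' @inheritParams thermo_step2
#' @param tree_joint tree over the concatenated alignment (estimated from it
#'   when `NULL`).
#' @param scfg an `scfg_params` set.
#' @export
evo_step2 <- function(pair, partials, tree_joint = NULL,
                      scfg = load_scfg_params(), params = hf_params()) {
  ca <- concatenate(pair, mode = "evo")
  if (is.null(tree_joint)) tree_joint <- estimate_tree(ca)
  L1 <- pair$aln1$L; L <- ca$L
  sig_pos <- .sigma_positions(partials, L1)
  sig_pairs <- .sigma_pairs_global(partials, L1)
  constraint <- structure_constraint(
    ca$phys_L, forced_unpaired = global_to_phys(ca, sig_pos),
    prior_free = ca$prior_free)
  post <- inside_outside(ca, tree_joint, scfg, constraint)
  keep <- global_to_phys(ca, seq_len(L))
  Praw <- post$pair_rel[keep, keep]
  ssraw <- post$ss_rel[keep]
  e1 <- partials[[1]]$ev_prob
  e2 <- partials[[2]]$ev_prob
  sc <- e1 * e2
  P <- Praw * sc
  ss <- ssraw * sc
  if (nrow(sig_pairs) > 0L) {
    for (r in seq_len(nrow(sig_pairs))) {
      i <- sig_pairs[r, 1]; j <- sig_pairs[r, 2]
      fixed <- if (params$eq15) 1 else if (i <= L1 && j <= L1) e1 else e2
      P[i, j] <- fixed
      P[j, i] <- fixed
    }
    ss[sig_pos] <- 0
  }
  list(P = P, ss = ss, scale1 = e1, scale2 = e2, tree = tree_joint,
       logZ = post$logZ, L = L, L1 = L1)
}

#' Combine the Step-2 components into final reliabilities
#'
#' Mirrors the Step-1 combination:
#' `R2_bp(i,j) = evo + (beta/n) sum_s thermo_s` and
#' `R2_ss(i) = alpha * [evo_ss + (beta/n) sum_s thermo_ss_s]`.
#'
#' @param evo_out result of [evo_step2()] (or `NULL` with the evolutionary
#'   model disabled).
#' @param thermo_out result of [thermo_step2()].
#' @param params an [hf_params()].
#' @return a `reliability_matrix` with provenance `"step2"` and the scale
#'   factors kept for audit.
#' @export
combine_step2 <- function(evo_out, thermo_out, params = hf_params()) {
  n <- length(thermo_out$P)
  L <- thermo_out$L
  th_pair <- Reduce(`+`, thermo_out$P)
  th_ss <- Reduce(`+`, thermo_out$ss)
  ev_pair <- if (is.null(evo_out)) matrix(0, L, L) else evo_out$P
  ev_ss <- if (is.null(evo_out)) rep(0, L) else evo_out$ss
  if (!all(dim(ev_pair) == c(L, L))) stop("dimension mismatch", call. = FALSE)
  structure(list(pair = ev_pair + (params$beta / n) * th_pair,
                 ss = params$alpha * (ev_ss + (params$beta / n) * th_ss),
                 alpha = params$alpha, beta = params$beta, n = n, L = L,
                 L1 = thermo_out$L1, provenance = "step2",
                 scales = list(
                   thermo = cbind(s1 = thermo_out$scale1,
                                  s2 = thermo_out$scale2),
                   evo = if (is.null(evo_out)) NULL else
                     c(s1 = evo_out$scale1, s2 = evo_out$scale2))),
            class = "reliability_matrix")
}
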