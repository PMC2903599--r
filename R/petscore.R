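## Expected-accuracy scoring: combined evolutionary + thermodynamic
## reliabilities, the expected-accuracy functional, and the Nussinov-style
## maximum expected accuracy decoder.

#' Pipeline parameters
#'
#' @param delta reliability cutoff for selecting partial-structure pairs,
#'   in `[0.5, 1]` on the normalized reliability scale (normalization by
#'   `1 + beta` keeps the non-crossing guarantee of cutoffs >= 0.5).  The
#'   demonstration configuration of the method; selection itself starts the
#'   cutoff adaptation at `delta_start`.
#' @param gamma ensemble-probability gate in `[0, 1]`: the partial structure
#'   must reach this probability in the evolutionary or the thermodynamic
#'   model.
#' @param alpha weight of single-stranded reliabilities (>= 0).  Only the
#'   ratio of pair to single-stranded weights matters to the decoder.
#' @param beta weight of the thermodynamic relative to the evolutionary
#'   contribution (>= 0).
#' @param delta_start start of the cutoff adaptation (clamped up to 0.5):
#'   the cutoff is raised from here in steps of `delta_step` until the
#'   selected ensemble is probable enough, so the smallest sufficient cutoff
#'   is found.  Set `delta_start = delta` to start at the strict demo cutoff.
#' @param delta_step increment of the cutoff adaptation.
#' @param extend_stems extend constrained stems by inner/outer pairs after
#'   selection.
#' @param no_isolated disallow isolated pairs in the thermodynamic model.
#' @param eq15 score constrained pairs with weight 1 instead of their fixed
#'   ensemble probability (the stricter independence-assumption variant).
#' @param evo use the evolutionary model (disable for single sequences).
#' @param gamma_agg aggregate per-sequence thermodynamic ensemble
#'   probabilities by `"min"` (each sequence must be probable) or `"mean"`.
#' @return an object of class `hf_params`.
#' @export
hf_params <- function(delta = 0.9, gamma = 0.1, alpha = 0.2, beta = 1.0,
                      delta_start = 0.5, delta_step = 0.05,
                      extend_stems = TRUE, no_isolated = FALSE, eq15 = FALSE,
                      evo = TRUE, gamma_agg = c("min", "mean")) {
  gamma_agg <- match.arg(gamma_agg)
  if (delta < 0.5 || delta > 1) {
    stop("delta must be in [0.5, 1] (cutoffs below 0.5 lose the ",
         "non-crossing guarantee)", call. = FALSE)
  }
  stopifnot(gamma >= 0, gamma <= 1, alpha >= 0, beta >= 0, delta_step > 0,
            is.finite(alpha), is.finite(beta))
  structure(list(delta = delta, gamma = gamma, alpha = alpha, beta = beta,
                 delta_start = max(delta_start, 0.5),
                 delta_step = delta_step,
                 extend_stems = isTRUE(extend_stems),
                 no_isolated = isTRUE(no_isolated), eq15 = isTRUE(eq15),
                 evo = isTRUE(evo), gamma_agg = gamma_agg),
            class = "hf_params")
}

## map a per-sequence pair-probability matrix to alignment columns; gap ends
## contribute nothing.
.seq_prob_to_cols <- function(P, aln, s) {
  chars <- strsplit(aln$rows[s], "", fixed = TRUE)[[1]]
  nongap <- which(chars != "-")
  out <- matrix(0, aln$L, aln$L)
  out[nongap, nongap] <- P
  out
}

.seq_ss_to_cols <- function(up, aln, s) {
  chars <- strsplit(aln$rows[s], "", fixed = TRUE)[[1]]
  nongap <- which(chars != "-")
  out <- rep(1, aln$L)        # gap columns contribute 1 to single-strandedness
  out[nongap] <- up
  out
}

#' Combine evolutionary and thermodynamic probabilities into reliabilities
#'
#' `R_bp(i,j) = P_ev(i,j) + (beta/n) * sum_s P_th(i,j,s)` and
#' `R_ss(i) = alpha * [P_ev(i) + (beta/n) * sum_s P_th_ss(i,s)]`, with
#' per-sequence matrices mapped to alignment columns (gap ends contribute 0
#' to pairs, gap columns contribute 1 to single-strandedness).
#'
#' @param evo an `evo_posterior`, or `NULL` when the evolutionary model is
#'   disabled (its contribution is then 0).
#' @param thermo_list list of `thermo_result`, one per alignment row.
#' @param aln the alignment the rows come from.
#' @param beta,alpha weights as in [hf_params()].
#' @return a `reliability_matrix`: `pair`, `ss`, plus bookkeeping fields.
#' @export
combine_reliabilities <- function(evo, thermo_list, aln, beta = 1.0,
                                  alpha = 0.2) {
  n <- aln$n
  L <- aln$L
  if (length(thermo_list) != n) stop("need one thermo result per sequence",
                                     call. = FALSE)
  pair <- if (is.null(evo)) matrix(0, L, L) else evo$pair_rel
  ss_ev <- if (is.null(evo)) rep(0, L) else evo$ss_rel
  if (!is.null(evo) && evo$L != L) stop("dimension mismatch", call. = FALSE)
  th_pair <- matrix(0, L, L)
  th_ss <- rep(0, L)
  for (s in seq_len(n)) {
    tr <- thermo_list[[s]]
    th_pair <- th_pair + .seq_prob_to_cols(tr$pair_prob, aln, s)
    th_ss <- th_ss + .seq_ss_to_cols(tr$unpaired_prob, aln, s)
  }
  structure(list(pair = pair + (beta / n) * th_pair,
                 ss = alpha * (ss_ev + (beta / n) * th_ss),
                 alpha = alpha, beta = beta, n = n, L = L,
                 provenance = "step1"),
            class = "reliability_matrix")
}

#' Expected accuracy of a nested structure
#'
#' `sum_{(i,j) in sigma} 2 R_bp(i,j) + sum_{i in ss(sigma)} R_ss(i)`: each
#' base pair credits its two columns, each unpaired position credits once
#' (the single-stranded weight `alpha` is already inside `R_ss`).
#'
#' @param pairs 2-column matrix of pairs (nested; crossing input is an
#'   error).
#' @param rel a `reliability_matrix`.
#' @export
expected_accuracy <- function(pairs, rel) {
  L <- rel$L
  if (is.null(pairs) || NROW(pairs) == 0L) return(sum(rel$ss))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  stopifnot(all(pairs >= 1L & pairs <= L))
  check_noncrossing(pairs)
  paired <- as.vector(pairs)
  sum(2 * rel$pair[pairs]) + sum(rel$ss[setdiff(seq_len(L), paired)])
}

#' Maximum expected accuracy decoding
#'
#' Nussinov-style DP maximizing [expected_accuracy()] over nested structures
#' honoring the constraint.  `pair_weight_overrides` replaces the pair gain
#' `2 R_bp(i,j)` of specific pairs (the final assembly passes 0 for the
#' constrained partial-structure pairs).  Ties are broken deterministically:
#' prefer unpaired, then the smallest left index.
#'
#' @param rel a `reliability_matrix`.
#' @param constraint optional [structure_constraint()] (prior-free positions
#'   are treated as forced unpaired here).
#' @param pair_weight_overrides optional 3-column matrix `(i, j, weight)`.
#' @return 2-column matrix of pairs, with attribute `score`.
#' @export
mea_decode <- function(rel, constraint = NULL, pair_weight_overrides = NULL) {
  L <- rel$L
  wp <- 2 * rel$pair
  wp[!upper.tri(wp)] <- -Inf
  wss <- as.numeric(rel$ss)
  if (!is.null(constraint)) {
    fu <- c(constraint$forced_unpaired, constraint$prior_free)
    if (length(fu) > 0L) {
      wp[fu, ] <- -Inf
      wp[, fu] <- -Inf
    }
    fp <- constraint$forced_pairs
    if (nrow(fp) > 0L) {
      for (r in seq_len(nrow(fp))) {
        k <- fp[r, 1]; l <- fp[r, 2]
        keep <- wp[k, l]
        wp[c(k, l), ] <- -Inf; wp[, c(k, l)] <- -Inf
        wp[k, l] <- keep
        wss[c(k, l)] <- -Inf
      }
    }
  }
  if (!is.null(pair_weight_overrides) && NROW(pair_weight_overrides) > 0L) {
    ov <- matrix(as.numeric(pair_weight_overrides), ncol = 3L)
    for (r in seq_len(nrow(ov))) {
      i <- min(ov[r, 1:2]); j <- max(ov[r, 1:2])
      if (is.finite(wp[i, j])) wp[i, j] <- ov[r, 3]
    }
  }
  res <- .mea_dp_cpp(wp, wss)
  pairs <- cbind(i = res$pairs_i, j = res$pairs_j)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(pairs, score = res$score)
}
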