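## Step 1: selection of reliable, conflict-free intra-molecular partial
## structures with cutoff adaptation under the ensemble-probability gate,
## and extension of constrained stems.

new_partial_structure <- function(pairs, part, delta_used, ev_prob, th_probs) {
  pairs <- if (NROW(pairs) == 0L) matrix(integer(0), 0, 2) else {
    m <- matrix(as.integer(pairs), ncol = 2L)
    m <- t(apply(m, 1L, sort))
    m[order(m[, 1]), , drop = FALSE]
  }
  check_noncrossing(pairs, "partial-structure pairs")
  stopifnot(delta_used >= 0.5)
  structure(list(pairs = pairs, part = part, delta_used = delta_used,
                 ev_prob = ev_prob, th_probs = th_probs),
            class = "partial_structure")
}

#' @export
print.partial_structure <- function(x, ...) {
  cat(sprintf("Partial structure (part %s): %d pairs, delta = %.2f\n",
              x$part, nrow(x$pairs), x$delta_used))
  if (nrow(x$pairs) > 0L) {
    cat("  pairs:", paste(sprintf("(%d,%d)", x$pairs[, 1], x$pairs[, 2]),
                          collapse = " "), "\n")
  }
  cat(sprintf("  Pr_ev[E(sigma^p)] = %s; Pr_th per sequence: %s\n",
              format(x$ev_prob, digits = 4),
              paste(format(x$th_probs, digits = 4), collapse = ", ")))
  invisible(x)
}

## ensemble probabilities of a consensus pair set in both models
.partial_probs <- function(pairs, aln, tree, scfg, emodel, use_evo) {
  ev <- if (use_evo) evo_ensemble_prob(aln, tree, scfg, pairs) else NA_real_
  th <- vapply(seq_len(aln$n), function(s) {
    proj <- map_consensus_to_seq(pairs, aln, s)
    as.numeric(thermo_ensemble_prob(ungapped_seq(aln, s), emodel, proj))
  }, 0)
  list(ev = ev, th = th)
}

#' Ensemble-probability gate
#'
#' A partial structure passes at threshold `gamma` if it is probable enough
#' in the evolutionary model or in the thermodynamic model (per-sequence
#' probabilities aggregated by `agg`; `"min"` demands that every sequence is
#' probable).
#' @param partial a `partial_structure`.
#' @param gamma threshold in `[0, 1]`.
#' @param agg `"min"` or `"mean"`.
#' @export
gate <- function(partial, gamma, agg = c("min", "mean")) {
  agg <- match.arg(agg)
  thv <- partial$th_probs
  tha <- if (length(thv) == 0L) 1 else if (agg == "min") min(thv) else mean(thv)
  ev_pass <- !is.na(partial$ev_prob) && partial$ev_prob >= gamma
  ev_pass || tha >= gamma
}

#' Select a reliable partial structure
#'
#' Selects consensus pairs whose normalized Step-1 reliability
#' `R(i,j)/(1+beta)` strictly exceeds the cutoff; cutoffs >= 0.5 guarantee a
#' conflict-free (non-crossing, position-disjoint) selection.  The cutoff is
#' adapted upward in steps of `delta_step` until the ensemble of structures
#' extending the selection is probable enough ([gate()]) or the selection is
#' empty (which passes trivially with all probabilities 1).
#'
#' @param rel Step-1 `reliability_matrix` of this alignment.
#' @param aln the alignment.
#' @param tree its tree (`NULL` allowed when `params$evo` is off).
#' @param params an [hf_params()].
#' @param scfg an `scfg_params` set.
#' @param emodel an [energy_model()].
#' @param part part label (1 or 2) carried into the result.
#' @return a `partial_structure` with fields `pairs`, `delta_used`,
#'   `ev_prob`, `th_probs`, plus attribute `iterations`.
#' @export
select_partial <- function(rel, aln, tree, params, scfg = load_scfg_params(),
                           emodel = energy_model(), part = 1L) {
  norm <- rel$pair / (1 + rel$beta)
  delta <- max(params$delta_start, 0.5)
  iter <- 0L
  use_evo <- params$evo && aln$n >= 2L
  repeat {
    iter <- iter + 1L
    idx <- which(upper.tri(norm) & norm > delta, arr.ind = TRUE)
    pairs <- idx[order(idx[, 1]), , drop = FALSE]
    if (nrow(pairs) == 0L) {
      out <- new_partial_structure(pairs, part, delta, if (use_evo) 1 else NA,
                                   rep(1, aln$n))
      break
    }
    pr <- .partial_probs(pairs, aln, tree, scfg, emodel, use_evo)
    cand <- new_partial_structure(pairs, part, delta, pr$ev, pr$th)
    if (gate(cand, params$gamma, params$gamma_agg)) {
      out <- cand
      break
    }
    delta <- delta + params$delta_step
  }
  attr(out, "iterations") <- iter
  out
}

## maximal helices of a non-crossing pair set: list of index vectors into
## pairs, each a run (i,j),(i+1,j-1),...
.find_helices <- function(pairs) {
  if (nrow(pairs) == 0L) return(list())
  ord <- order(pairs[, 1])
  pairs <- pairs[ord, , drop = FALSE]
  helices <- list()
  cur <- 1L
  for (r in seq_len(nrow(pairs))[-1]) {
    prev <- pairs[r - 1L, ]; this <- pairs[r, ]
    if (this[1] == prev[1] + 1L && this[2] == prev[2] - 1L) {
      cur <- c(cur, r)
    } else {
      helices[[length(helices) + 1L]] <- ord[cur]
      cur <- r
    }
  }
  helices[[length(helices) + 1L]] <- ord[cur]
  helices
}

.compatible_with <- function(cand, pairs) {
  if (any(cand %in% as.vector(pairs))) return(FALSE)
  for (r in seq_len(nrow(pairs))) {
    if (pairs_cross(cand, pairs[r, ])) return(FALSE)
  }
  TRUE
}

#' Extend constrained stems
#'
#' Constraining reliable pairs single-stranded in Step 2 destabilizes the
#' helices they came from, so each maximal helix is extended: the
#' immediately inner pair, then the immediately outer pair, is added as long
#' as (a) the extended stem's average normalized reliability exceeds the
#' selection cutoff, (b) the ensemble-probability gate still passes for the
#' extended partial structure, and (c) no position conflict or crossing
#' arises.  Helices are processed 5' to 3'; the gate is re-evaluated after
#' every single added pair.
#'
#' @inheritParams select_partial
#' @param partial the `partial_structure` from [select_partial()].
#' @return the (possibly) extended `partial_structure`.
#' @export
extend_stems <- function(partial, rel, params, aln, tree,
                         scfg = load_scfg_params(), emodel = energy_model()) {
  if (nrow(partial$pairs) == 0L) return(partial)
  norm <- rel$pair / (1 + rel$beta)
  use_evo <- params$evo && aln$n >= 2L
  delta <- partial$delta_used
  pairs <- partial$pairs
  probs <- list(ev = partial$ev_prob, th = partial$th_probs)
  helix_sets <- .find_helices(pairs)
  helix_pairs <- lapply(helix_sets, function(ix) pairs[ix, , drop = FALSE])
  ord <- order(vapply(helix_pairs, function(h) min(h[, 1]), 0L))
  for (h in ord) {
    stem <- helix_pairs[[h]]
    for (dir in c("inner", "outer")) {
      repeat {
        cand <- if (dir == "inner") {
          c(max(stem[, 1]) + 1L, min(stem[, 2]) - 1L)
        } else {
          c(min(stem[, 1]) - 1L, max(stem[, 2]) + 1L)
        }
        if (cand[1] < 1L || cand[2] > rel$L || cand[2] - cand[1] < 1L) break
        if (!.compatible_with(cand, pairs)) break
        ext_stem <- rbind(stem, cand)
        if (mean(norm[ext_stem]) <= delta) break
        ext_pairs <- rbind(pairs, cand)
        pr <- .partial_probs(ext_pairs, aln, tree, scfg, emodel, use_evo)
        cand_ps <- new_partial_structure(ext_pairs, partial$part, delta,
                                         pr$ev, pr$th)
        if (!gate(cand_ps, params$gamma, params$gamma_agg)) break
        stem <- ext_stem
        pairs <- cand_ps$pairs
        probs <- list(ev = pr$ev, th = pr$th)
      }
    }
  }
  new_partial_structure(pairs, partial$part, delta, probs$ev, probs$th)
}
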