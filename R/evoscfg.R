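## Phylo-SCFG posteriors: inside-outside over the lightweight structural
## grammar with phylogenetic column emissions, constrained variants, and the
## ensemble probability of a partial structure in the evolutionary model.

#' Structural constraints for the SCFG
#'
#' @param L number of columns.
#' @param forced_pairs 2-column matrix of pairs that must be present
#'   (mutually non-crossing, position-disjoint).
#' @param forced_unpaired positions that may not pair.
#' @param prior_free positions (linker columns) emitting probability 1,
#'   constrained unpaired and exempt from the grammar's unpaired production
#'   probability.
#' @return a `structure_constraint`.
#' @export
structure_constraint <- function(L, forced_pairs = NULL,
                                 forced_unpaired = integer(0),
                                 prior_free = integer(0)) {
  fu <- sort(unique(as.integer(forced_unpaired)))
  pf <- sort(unique(as.integer(prior_free)))
  stopifnot(all(fu >= 1L & fu <= L), all(pf >= 1L & pf <= L))
  fp <- if (is.null(forced_pairs) || NROW(forced_pairs) == 0L) {
    matrix(integer(0), 0, 2)
  } else {
    m <- matrix(as.integer(forced_pairs), ncol = 2L)
    m <- t(apply(m, 1L, sort))
    stopifnot(all(m >= 1L & m <= L), all(m[, 1] < m[, 2]))
    check_noncrossing(m, "forced pairs")
    m
  }
  if (any(as.vector(fp) %in% c(fu, pf))) {
    stop("forced pair positions overlap forced-unpaired/prior-free positions",
         call. = FALSE)
  }
  structure(list(L = L, forced_pairs = fp, forced_unpaired = fu,
                 prior_free = pf), class = "structure_constraint")
}

.scfg_weights <- function(aln, tree, params, constraint) {
  L <- if (inherits(aln, "concat_alignment")) aln$phys_L else aln$L
  em <- emission_logliks(aln, tree, params)
  gr <- log(params$grammar)
  ws <- gr[["L->s"]] + em$log_es
  lep <- em$log_ep
  diag(lep) <- -Inf
  if (!is.null(constraint)) {
    stopifnot(constraint$L == L)
    pf <- constraint$prior_free
    if (length(pf) > 0L) {
      ws[pf] <- 0
      lep[pf, ] <- -Inf
      lep[, pf] <- -Inf
    }
    fu <- constraint$forced_unpaired
    if (length(fu) > 0L) {
      lep[fu, ] <- -Inf
      lep[, fu] <- -Inf
    }
    fp <- constraint$forced_pairs
    if (nrow(fp) > 0L) {
      for (r in seq_len(nrow(fp))) {
        k <- fp[r, 1]; l <- fp[r, 2]
        keep <- lep[k, l]
        lep[k, ] <- -Inf; lep[, k] <- -Inf
        lep[l, ] <- -Inf; lep[, l] <- -Inf
        lep[k, l] <- keep; lep[l, k] <- keep
        ws[c(k, l)] <- -Inf
      }
    }
  }
  list(ws = ws, lep = lep, lq = gr)
}

#' Phylo-SCFG inside-outside posteriors
#'
#' Computes, for every alignment column, the posterior probability of being
#' single-stranded and, for every column pair, the posterior base-pair
#' reliability under the grammar prior and the phylogenetic emission model,
#' optionally under structural constraints.  For a `concat_alignment` in
#' `evo` mode the linker columns are prior-free automatically; posteriors
#' are reported on physical columns.
#'
#' @param aln an `rna_alignment` or `concat_alignment`.
#' @param tree ape `phylo` over the alignment taxa.
#' @param params an `scfg_params` parameter set.
#' @param constraint optional [structure_constraint()].
#' @return an `evo_posterior`: `pair_rel` (symmetric matrix), `ss_rel`
#'   (vector), `logZ` (constrained log-likelihood normalizer), `feasible`.
#' @export
inside_outside <- function(aln, tree, params, constraint = NULL) {
  L <- if (inherits(aln, "concat_alignment")) aln$phys_L else aln$L
  if (inherits(aln, "concat_alignment") && length(aln$prior_free) > 0L) {
    if (is.null(constraint)) {
      constraint <- structure_constraint(L, prior_free = aln$prior_free)
    } else if (!all(aln$prior_free %in% constraint$prior_free)) {
      constraint <- structure_constraint(
        L, forced_pairs = constraint$forced_pairs,
        forced_unpaired = constraint$forced_unpaired,
        prior_free = union(constraint$prior_free, aln$prior_free))
    }
  }
  w <- .scfg_weights(aln, tree, params, constraint)
  res <- .scfg_io_cpp(w$ws, w$lep, w$lq, TRUE)
  if (!is.finite(res$logZ)) {
    return(structure(list(pair_rel = matrix(0, L, L), ss_rel = rep(0, L),
                          logZ = -Inf, feasible = FALSE, L = L),
                     class = "evo_posterior"))
  }
  pair <- res$P
  ss <- res$Pss
  tot <- ss + rowSums(pair)
  free <- if (!is.null(constraint)) constraint$prior_free else integer(0)
  chk <- setdiff(seq_len(L), free)
  dev <- max(abs(tot[chk] - 1))
  if (dev > 1e-6) {
    stop("inside-outside normalization failure (max deviation ", dev, ")")
  }
  ## enforce the per-column partition identity exactly
  ss[chk] <- pmax(0, 1 - rowSums(pair)[chk])
  if (length(free) > 0L) ss[free] <- 1
  structure(list(pair_rel = pair, ss_rel = ss, logZ = res$logZ,
                 feasible = TRUE, L = L),
            class = "evo_posterior")
}

#' Evolutionary ensemble probability of a partial structure
#'
#' `Pr[E(sigma^p) | A, T, M]`: the posterior mass (over parse trees) of all
#' consensus structures extending the partial structure, computed as the
#' ratio of the constrained to the unconstrained inside normalizer.
#'
#' @inheritParams inside_outside
#' @param pairs 2-column matrix of consensus pairs (may be empty).
#' @export
evo_ensemble_prob <- function(aln, tree, params, pairs = NULL) {
  L <- if (inherits(aln, "concat_alignment")) aln$phys_L else aln$L
  if (is.null(pairs) || NROW(pairs) == 0L) return(1)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  check_noncrossing(pairs)
  pf <- if (inherits(aln, "concat_alignment")) aln$prior_free else integer(0)
  c0 <- if (length(pf) > 0L) structure_constraint(L, prior_free = pf) else NULL
  w0 <- .scfg_weights(aln, tree, params, c0)
  z0 <- .scfg_io_cpp(w0$ws, w0$lep, w0$lq, FALSE)$logZ
  cc <- structure_constraint(L, forced_pairs = pairs, prior_free = pf)
  wc <- .scfg_weights(aln, tree, params, cc)
  zc <- .scfg_io_cpp(wc$ws, wc$lep, wc$lq, FALSE)$logZ
  if (!is.finite(zc)) return(0)
  min(1, exp(zc - z0))
}
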