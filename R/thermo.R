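## Per-sequence thermodynamic ensembles: constrained McCaskill-style
## partition functions, base-pair probabilities and cofolding across a
## linker.  The DP kernel lives in src/thermo.cpp.

PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")

.default_stack <- function() {
  ## simplified nearest-neighbor stacking: pair strengths GC/CG = 3,
  ## AU/UA = 2, GU/UG = 1 kcal/mol; a stack of pairs p on q contributes
  ## -(s_p + s_q)/2 - 0.5 kcal/mol.
  s <- c(AU = 2, UA = 2, GC = 3, CG = 3, GU = 1, UG = 1)
  m <- -(outer(s, s, "+") / 2 + 0.5)
  dimnames(m) <- list(PAIR_TYPES, PAIR_TYPES)
  m
}

#' Simplified nearest-neighbor energy model
#'
#' A pluggable scorer for nested structures: stacking energies for the six
#' canonical pair steps plus affine hairpin, interior/bulge and multiloop
#' penalties (kcal/mol).  The open chain has energy 0.  This is deliberately
#' not the full Turner parameter set: the package's contract is a
#' thermodynamic ensemble with constraints, validated against exhaustive
#' enumeration, not kcal-level agreement with any particular parameterization.
#' No dangling-end terms are defined.
#'
#' @param stack 6x6 stacking matrix indexed by `AU,UA,GC,CG,GU,UG`.
#' @param hairpin_a,hairpin_b hairpin penalty `a + b * loopsize`.
#' @param interior_a,interior_b interior/bulge penalty `a + b * unpaired`.
#' @param ml_a,ml_b,ml_c multiloop penalty `a + b * unpaired + c * branches`.
#' @param RT gas constant times temperature, default 0.61633 kcal/mol
#'   (310.15 K).
#' @param min_hairpin minimum unpaired positions in an intra-molecular
#'   hairpin loop (inter-molecular pairs across the linker are exempt).
#' @param no_isolated if `TRUE`, pairs without a stacked neighbor get zero
#'   weight (every helix must be at least 2 pairs long).
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(stack = .default_stack(), hairpin_a = 1.8,
                         hairpin_b = 0.3, interior_a = 1.0, interior_b = 0.3,
                         ml_a = 3.4, ml_b = 0.3, ml_c = 0.4, RT = 0.61633,
                         min_hairpin = 3L, no_isolated = FALSE) {
  stopifnot(is.matrix(stack), all(dim(stack) == 6L), RT > 0, min_hairpin >= 0)
  structure(list(stack = stack, hairpin_a = hairpin_a, hairpin_b = hairpin_b,
                 interior_a = interior_a, interior_b = interior_b,
                 ml_a = ml_a, ml_b = ml_b, ml_c = ml_c, RT = RT,
                 min_hairpin = as.integer(min_hairpin),
                 no_isolated = isTRUE(no_isolated)),
            class = "energy_model")
}

encode_rna <- function(seq) {
  chars <- if (length(seq) == 1L && nchar(seq[1]) > 1L) {
    strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  } else toupper(seq)
  chars <- gsub("T", "U", chars, fixed = TRUE)
  idx <- match(chars, NT)
  idx[is.na(idx)] <- 0L   # N and friends never pair
  as.integer(idx)
}

## constraint: list(forced_unpaired = integer positions,
##                  forced_pairs = 2-column matrix)
.thermo_masks <- function(L, constraint) {
  pair_ok <- matrix(TRUE, L, L)
  can_ss <- rep(TRUE, L)
  if (is.null(constraint)) {
    return(list(pair_ok = pair_ok, can_ss = can_ss))
  }
  fu <- as.integer(constraint$forced_unpaired %||% integer(0))
  fp <- constraint$forced_pairs
  if (length(fu) > 0L) {
    stopifnot(all(fu >= 1L & fu <= L))
    pair_ok[fu, ] <- FALSE
    pair_ok[, fu] <- FALSE
  }
  if (!is.null(fp) && NROW(fp) > 0L) {
    fp <- matrix(as.integer(fp), ncol = 2L)
    fp <- t(apply(fp, 1L, sort))
    stopifnot(all(fp >= 1L & fp <= L), all(fp[, 1] < fp[, 2]))
    ends <- as.vector(fp)
    if (anyDuplicated(ends)) stop("forced pairs share a position")
    if (any(ends %in% fu)) stop("forced pair position also forced unpaired")
    for (r in seq_len(nrow(fp))) {
      k <- fp[r, 1]; l <- fp[r, 2]
      pair_ok[k, ] <- FALSE; pair_ok[, k] <- FALSE
      pair_ok[l, ] <- FALSE; pair_ok[, l] <- FALSE
    }
    for (r in seq_len(nrow(fp))) {
      k <- fp[r, 1]; l <- fp[r, 2]
      pair_ok[k, l] <- TRUE; pair_ok[l, k] <- TRUE
      can_ss[c(k, l)] <- FALSE
    }
  }
  list(pair_ok = pair_ok, can_ss = can_ss)
}

#' Constrained partition function of a single RNA sequence
#'
#' Inside/outside dynamic programming over nested structures under the
#' package's energy model.  Constraints may force positions unpaired or
#' force specific base pairs to be present.
#'
#' @param seq ungapped RNA string (or character vector of residues).
#' @param model an [energy_model()].
#' @param constraint optional list with `forced_unpaired` (integer positions)
#'   and/or `forced_pairs` (2-column matrix).
#' @param want_prob compute the base-pair probability matrix (outside pass).
#' @return a `thermo_result`: `logZ`, ensemble free energy `dG = -RT logZ`,
#'   symmetric `pair_prob` matrix, `unpaired_prob` vector, `L`.
#' @export
partition <- function(seq, model = energy_model(), constraint = NULL,
                      want_prob = TRUE) {
  enc <- encode_rna(seq)
  L <- length(enc)
  stopifnot(L >= 1L)
  mk <- .thermo_masks(L, constraint)
  res <- .thermo_dp_cpp(enc, 0L, mk$pair_ok, mk$can_ss, unclass(model),
                        model$no_isolated, want_prob)
  .thermo_result(res, L, model)
}

#' Cofold two sequences across a linker
#'
#' Partition function over the concatenation `s1 & s2` where the linker can
#' never pair.  Any loop containing the linker is scored as an exterior-like
#' region (no loop penalty, no hairpin minimum), so a single inter-molecular
#' pair between adjacent chain ends is legal.  Positions in `constraint` are
#' given in concatenated coordinates 1..n1+n2.
#'
#' @param s1,s2 ungapped RNA strings.
#' @inheritParams partition
#' @return a `thermo_result` over the concatenation, with attribute `cut`
#'   (= nchar(s1)); pairs `(i,j)` with `i <= cut < j` are inter-molecular.
#' @export
cofold_partition <- function(s1, s2, model = energy_model(),
                             constraint = NULL, want_prob = TRUE) {
  e1 <- encode_rna(s1); e2 <- encode_rna(s2)
  enc <- c(e1, e2)
  L <- length(enc)
  cut <- length(e1)
  stopifnot(cut >= 1L, L - cut >= 1L)
  mk <- .thermo_masks(L, constraint)
  res <- .thermo_dp_cpp(enc, cut, mk$pair_ok, mk$can_ss, unclass(model),
                        model$no_isolated, want_prob)
  out <- .thermo_result(res, L, model)
  out$cut <- cut
  out
}

.thermo_result <- function(res, L, model) {
  P <- res$P
  up <- 1 - rowSums(P)
  up[up < 0 & up > -1e-9] <- 0
  structure(list(logZ = res$logZ, dG = -model$RT * res$logZ,
                 pair_prob = P, unpaired_prob = up, L = L,
                 feasible = isTRUE(res$Z_positive)),
            class = "thermo_result")
}

#' Thermodynamic ensemble probability of a partial structure
#'
#' `Pr[E(sigma^p) | s] = Z_constrained / Z = exp(-(dG_c - dG)/RT)`: the
#' Boltzmann mass of all nested structures containing the given pairs.
#' Pairs that are illegal on this sequence (non-canonical after projection)
#' give probability 0, flagged in the `"illegal_pairs"` attribute.
#'
#' @inheritParams partition
#' @param pairs 2-column matrix of pairs to constrain as present (may be
#'   empty).
#' @export
thermo_ensemble_prob <- function(seq, model = energy_model(), pairs = NULL) {
  enc <- encode_rna(seq)
  if (is.null(pairs) || NROW(pairs) == 0L) return(1)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  check_noncrossing(pairs)
  can <- .canonical_ok(enc, pairs)
  if (!all(can)) {
    out <- 0
    attr(out, "illegal_pairs") <- pairs[!can, , drop = FALSE]
    return(out)
  }
  z0 <- partition(seq, model, want_prob = FALSE)
  zc <- partition(seq, model, constraint = list(forced_pairs = pairs),
                  want_prob = FALSE)
  if (!is.finite(zc$logZ)) return(0)
  min(1, exp(zc$logZ - z0$logZ))
}

.canonical_ok <- function(enc, pairs) {
  canon <- list(c(1L, 4L), c(4L, 1L), c(3L, 2L), c(2L, 3L), c(3L, 4L),
                c(4L, 3L))
  apply(pairs, 1L, function(p) {
    a <- enc[min(p)]; b <- enc[max(p)]
    any(vapply(canon, function(cc) cc[1] == a && cc[2] == b, TRUE))
  })
}

#' Project consensus pairs onto one alignment row
#'
#' Maps consensus (column) pairs onto ungapped sequence coordinates of row
#' `seq_index`; pairs with a gap end are dropped, as are pairs that are
#' non-canonical in this row (both recorded in attributes).
#'
#' @param pairs 2-column matrix of consensus column pairs.
#' @param aln an `rna_alignment`.
#' @param seq_index row index.
#' @return 2-column matrix of sequence-coordinate pairs, with attributes
#'   `dropped_gap` and `dropped_noncanonical`.
#' @export
map_consensus_to_seq <- function(pairs, aln, seq_index) {
  if (is.null(pairs) || NROW(pairs) == 0L) {
    return(structure(matrix(integer(0), 0, 2),
                     dropped_gap = matrix(integer(0), 0, 2),
                     dropped_noncanonical = matrix(integer(0), 0, 2)))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  i <- col_to_seqpos(aln, seq_index, pairs[, 1])
  j <- col_to_seqpos(aln, seq_index, pairs[, 2])
  gap <- is.na(i) | is.na(j)
  mapped <- cbind(i[!gap], j[!gap])
  enc <- encode_rna(ungapped_seq(aln, seq_index))
  can <- if (nrow(mapped) > 0L) .canonical_ok(enc, mapped) else logical(0)
  out <- mapped[can, , drop = FALSE]
  structure(out,
            dropped_gap = pairs[gap, , drop = FALSE],
            dropped_noncanonical = mapped[!can, , drop = FALSE])
}

## shared helpers on pair sets -------------------------------------------

check_noncrossing <- function(pairs, what = "pairs") {
  if (NROW(pairs) < 2L) return(invisible(TRUE))
  pairs <- t(apply(matrix(as.integer(pairs), ncol = 2L), 1L, sort))
  if (anyDuplicated(as.vector(pairs))) {
    stop(what, " share a position", call. = FALSE)
  }
  n <- nrow(pairs)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      i <- pairs[a, 1]; j <- pairs[a, 2]; k <- pairs[b, 1]; l <- pairs[b, 2]
      if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) {
        stop(what, " cross: (", i, ",", j, ") and (", k, ",", l, ")",
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

pairs_cross <- function(p, q) {
  (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) ||
    (q[1] < p[1] && p[1] < q[2] && q[2] < p[2])
}

#' Write a pair-probability matrix as plain text
#' @param tr a `thermo_result`.
#' @param path output file; three columns i, j, probability (i < j).
#' @param min_prob entries below this are omitted.
#' @export
dump_pair_probs <- function(tr, path, min_prob = 1e-6) {
  idx <- which(upper.tri(tr$pair_prob) & tr$pair_prob > min_prob,
               arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], prob = tr$pair_prob[idx])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
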