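## Independent brute-force oracles used across the test suite.
## These enumerate structures / parse trees explicitly and score them from
## the model definitions directly; they share no DP code with the package.

## ---- nested structure enumeration -------------------------------------

## all nested pair sets over 1..L where pairable(i, j) is TRUE; returns a
## list of 2-column matrices (possibly the empty matrix)
enum_nested <- function(L, pairable) {
  rec <- function(i, j) {
    if (i > j) return(list(matrix(integer(0), 0, 2)))
    out <- list()
    for (s in rec(i + 1L, j)) out[[length(out) + 1L]] <- s
    for (k in seq_len(j)) {
      if (k <= i) next
      if (!pairable(i, k)) next
      inner <- rec(i + 1L, k - 1L)
      outer <- rec(k + 1L, j)
      for (si in inner) for (so in outer) {
        out[[length(out) + 1L]] <- rbind(c(i, k), si, so)
      }
    }
    out
  }
  rec(1L, L)
}

.o_pt <- function(a, b) {
  key <- paste0(c("A", "C", "G", "U")[a], c("A", "C", "G", "U")[b])
  match(key, c("AU", "UA", "GC", "CG", "GU", "UG"))
}

o_canonical <- function(enc, i, j) {
  a <- enc[i]; b <- enc[j]
  if (a == 0 || b == 0) return(FALSE)
  !is.na(.o_pt(a, b))
}

## energy of one nested structure under the package's model semantics,
## computed from the structure tree; Inf = illegal structure.
## cut = 0 for a single sequence; cut > 0: linker between cut and cut+1.
oracle_energy <- function(pairs, enc, model, cut = 0L) {
  if (NROW(pairs) == 0L) return(0)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  spans <- function(i, j) cut > 0L && i <= cut && j > cut
  np <- nrow(pairs)
  ## children of each pair (and of the root "exterior")
  parent_of <- function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    best <- 0L; bw <- Inf
    for (q in seq_len(np)) {
      if (q == r) next
      a <- pairs[q, 1]; b <- pairs[q, 2]
      if (a < i && j < b && (b - a) < bw) { best <- q; bw <- b - a }
    }
    best
  }
  parents <- vapply(seq_len(np), parent_of, 0L)
  E <- 0
  for (r in seq_len(np)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!o_canonical(enc, i, j)) return(Inf)
    kids <- which(parents == r)
    kids <- kids[order(pairs[kids, 1])]
    kp <- pairs[kids, , drop = FALSE]
    covered <- unlist(lapply(seq_len(nrow(kp)), function(q)
      seq(kp[q, 1], kp[q, 2])))
    u <- (j - i - 1L) - length(covered)
    cut_in_loop <- spans(i, j) &&
      !any(vapply(seq_len(nrow(kp)), function(q)
        spans(kp[q, 1], kp[q, 2]), TRUE))
    if (cut_in_loop) next               # exterior-like region: no penalty
    m <- nrow(kp)
    if (m == 0L) {
      if (u < model$min_hairpin) return(Inf)
      E <- E + model$hairpin_a + model$hairpin_b * u
    } else if (m == 1L) {
      if (kp[1, 1] == i + 1L && kp[1, 2] == j - 1L) {
        pto <- .o_pt(enc[i], enc[j]); pti <- .o_pt(enc[kp[1, 1]], enc[kp[1, 2]])
        E <- E + model$stack[pto, pti]
      } else {
        E <- E + model$interior_a + model$interior_b * u
      }
    } else {
      E <- E + model$ml_a + model$ml_b * u + model$ml_c * m
    }
  }
  E
}

## isolated-pair test mirroring the model semantics: two adjacent pairs form
## a stack only if they agree on spanning the cut
oracle_has_isolated <- function(pairs, cut = 0L) {
  if (NROW(pairs) == 0L) return(FALSE)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  spans <- function(i, j) cut > 0L && i <= cut && j > cut
  key <- paste(pairs[, 1], pairs[, 2])
  stacked_with <- function(i, j, a, b) {
    paste(a, b) %in% key && (spans(i, j) == spans(a, b))
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!stacked_with(i, j, i + 1L, j - 1L) &&
        !stacked_with(i, j, i - 1L, j + 1L)) return(TRUE)
  }
  FALSE
}

## full Boltzmann enumeration: Z, logZ, pair probability matrix.
## constraint: list(forced_unpaired, forced_pairs) as in the package.
oracle_thermo <- function(seq, model, cut = 0L, constraint = NULL) {
  enc <- hierfold:::encode_rna(seq)
  L <- length(enc)
  fu <- as.integer(constraint$forced_unpaired %||% integer(0))
  fp <- constraint$forced_pairs
  pairable <- function(i, j) {
    if (!o_canonical(enc, i, j)) return(FALSE)
    if (i %in% fu || j %in% fu) return(FALSE)
    TRUE
  }
  structs <- enum_nested(L, pairable)
  if (!is.null(fp) && NROW(fp) > 0L) {
    fp <- matrix(as.integer(fp), ncol = 2L)
    keyf <- paste(pmin(fp[, 1], fp[, 2]), pmax(fp[, 1], fp[, 2]))
    structs <- Filter(function(s) {
      if (NROW(s) == 0L) return(length(keyf) == 0L)
      all(keyf %in% paste(s[, 1], s[, 2]))
    }, structs)
  }
  if (isTRUE(model$no_isolated)) {
    structs <- Filter(function(s) !oracle_has_isolated(s, cut), structs)
  }
  w <- vapply(structs, function(s) {
    E <- oracle_energy(s, enc, model, cut)
    if (is.finite(E)) exp(-E / model$RT) else 0
  }, 0)
  keep <- w > 0
  structs <- structs[keep]; w <- w[keep]
  Z <- sum(w)
  P <- matrix(0, L, L)
  for (q in seq_along(structs)) {
    s <- structs[[q]]
    if (NROW(s) > 0L) {
      P[s] <- P[s] + w[q]
      P[s[, c(2, 1), drop = FALSE]] <- P[s[, c(2, 1), drop = FALSE]] + w[q]
    }
  }
  list(Z = Z, logZ = if (Z > 0) log(Z) else -Inf,
       P = if (Z > 0) P / Z else P, structures = structs, weights = w)
}

## ---- SCFG parse-tree enumeration --------------------------------------

## explicit enumeration of all parse trees of S -> LS | L, L -> s | dFd,
## F -> dFd | LS over weights ws (log, incl. the L->s production factor),
## lep (log pair emissions) and log production probabilities lq.
## Returns list of records: w (linear weight), pairs, ss (unpaired columns).
oracle_parses <- function(ws, lep, lq) {
  q <- exp(lq)
  L <- length(ws)
  emptyrec <- function() list()
  pL <- function(i, j) {
    out <- list()
    if (i == j && is.finite(ws[i])) {
      out[[1]] <- list(w = exp(ws[i]), pairs = matrix(integer(0), 0, 2),
                       ss = i)
    }
    if (j >= i + 3L && is.finite(lep[i, j])) {
      for (f in pF(i + 1L, j - 1L)) {
        out[[length(out) + 1L]] <-
          list(w = exp(lep[i, j]) * q[["L->dFd"]] * f$w,
               pairs = rbind(c(i, j), f$pairs), ss = f$ss)
      }
    }
    out
  }
  pF <- function(i, j) {
    out <- list()
    if (j >= i + 3L && is.finite(lep[i, j])) {
      for (f in pF(i + 1L, j - 1L)) {
        out[[length(out) + 1L]] <-
          list(w = exp(lep[i, j]) * q[["F->dFd"]] * f$w,
               pairs = rbind(c(i, j), f$pairs), ss = f$ss)
      }
    }
    if (j > i) {
      for (k in i:(j - 1L)) {
        for (l in pL(i, k)) for (s in pS(k + 1L, j)) {
          out[[length(out) + 1L]] <-
            list(w = q[["F->LS"]] * l$w * s$w,
                 pairs = rbind(l$pairs, s$pairs), ss = c(l$ss, s$ss))
        }
      }
    }
    out
  }
  pS <- function(i, j) {
    out <- list()
    for (l in pL(i, j)) {
      out[[length(out) + 1L]] <-
        list(w = q[["S->L"]] * l$w, pairs = l$pairs, ss = l$ss)
    }
    if (j > i) {
      for (k in i:(j - 1L)) {
        for (l in pL(i, k)) for (s in pS(k + 1L, j)) {
          out[[length(out) + 1L]] <-
            list(w = q[["S->LS"]] * l$w * s$w,
                 pairs = rbind(l$pairs, s$pairs), ss = c(l$ss, s$ss))
        }
      }
    }
    out
  }
  pS(1L, L)
}

## posterior quantities from the parse enumeration
oracle_scfg <- function(ws, lep, lq) {
  recs <- oracle_parses(ws, lep, lq)
  L <- length(ws)
  Z <- sum(vapply(recs, `[[`, 0, "w"))
  P <- matrix(0, L, L)
  Pss <- rep(0, L)
  for (r in recs) {
    if (NROW(r$pairs) > 0L) {
      P[r$pairs] <- P[r$pairs] + r$w
      P[r$pairs[, c(2, 1), drop = FALSE]] <-
        P[r$pairs[, c(2, 1), drop = FALSE]] + r$w
    }
    Pss[r$ss] <- Pss[r$ss] + r$w
  }
  list(Z = Z, P = P / Z, Pss = Pss / Z, parses = recs)
}

## mass of parses whose pair set contains all of `pairs`
oracle_scfg_ensemble <- function(ws, lep, lq, pairs) {
  recs <- oracle_parses(ws, lep, lq)
  Z <- sum(vapply(recs, `[[`, 0, "w"))
  if (NROW(pairs) == 0L) return(1)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  m <- sum(vapply(recs, function(r) {
    if (NROW(r$pairs) == 0L) return(0)
    if (all(key %in% paste(r$pairs[, 1], r$pairs[, 2]))) r$w else 0
  }, 0))
  m / Z
}

## ---- exhaustive MEA search --------------------------------------------

## brute-force maximum of the expected-accuracy functional over all nested
## structures (any i < j pairable unless masked); returns the best score
oracle_mea_best <- function(pairmat, ssvec, forced_unpaired = integer(0)) {
  L <- length(ssvec)
  pairable <- function(i, j) !(i %in% forced_unpaired) &&
    !(j %in% forced_unpaired)
  structs <- enum_nested(L, pairable)
  best <- -Inf
  for (s in structs) {
    sc <- if (NROW(s) == 0L) sum(ssvec) else {
      sum(2 * pairmat[s]) + sum(ssvec[-as.vector(s)])
    }
    if (sc > best) best <- sc
  }
  best
}

## ---- misc helpers ------------------------------------------------------

random_rna <- function(L, letters = c("A", "C", "G", "U")) {
  paste(sample(letters, L, replace = TRUE), collapse = "")
}

## small random alignment: a root sequence mutated independently per row
random_alignment <- function(n, L, mut = 0.2, gap = 0) {
  root <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
  rows <- vapply(seq_len(n), function(k) {
    r <- root
    flip <- runif(L) < mut
    r[flip] <- sample(c("A", "C", "G", "U"), sum(flip), replace = TRUE)
    if (gap > 0) r[runif(L) < gap] <- "-"
    paste(r, collapse = "")
  }, "")
  hierfold:::new_rna_alignment(paste0("t", seq_len(n)), rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
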