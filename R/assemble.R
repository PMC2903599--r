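## Final assembly: MEA decoding on the Step-2 reliabilities with the
## constrained pairs at weight 0, re-insertion of the partial structures,
## pseudoknot layering, and text rendering.
##
## Bracket classes: [ ] constrained partial-structure pairs (sigma^p),
## ( ) new intra-molecular pairs, < > inter-molecular pairs.  Crossings can
## occur only between the constrained layer and the Step-2 layers; within
## each layer the pairs are nested.

new_joint_structure <- function(sigma1, sigma2, sigma_int, layers, rels,
                                L1, L2) {
  js <- structure(list(sigma1 = sigma1, sigma2 = sigma2,
                       sigma_int = sigma_int, layers = layers,
                       reliabilities = rels, L1 = L1, L2 = L2),
                  class = "joint_structure")
  validate_joint_structure(js)
  js
}

## all pairs in global coordinates with their layer tags
joint_pairs_global <- function(js) {
  p1 <- if (NROW(js$sigma1)) cbind(js$sigma1[, 1], js$sigma1[, 2]) else
    matrix(integer(0), 0, 2)
  p2 <- if (NROW(js$sigma2)) cbind(js$sigma2[, 1] + js$L1,
                                   js$sigma2[, 2] + js$L1) else
    matrix(integer(0), 0, 2)
  pint <- if (NROW(js$sigma_int)) js$sigma_int else matrix(integer(0), 0, 2)
  rbind(p1, p2, pint)
}

#' Validate the joint-structure partition invariants
#'
#' Each position sits in at most one pair; intra-molecular pairs stay within
#' their part and inter-molecular pairs bridge the parts; within each
#' bracket layer the pairs are non-crossing, so crossings (pseudoknots)
#' occur only between the constrained layer and the Step-2 layers.
#' @param js a `joint_structure`.
#' @export
validate_joint_structure <- function(js) {
  allp <- joint_pairs_global(js)
  if (nrow(allp) == 0L) return(invisible(TRUE))
  if (length(js$layers) != nrow(allp)) {
    stop("assembly error: layer tags do not match pairs", call. = FALSE)
  }
  ends <- as.vector(allp)
  if (anyDuplicated(ends)) {
    stop("assembly error: position in two pairs", call. = FALSE)
  }
  if (NROW(js$sigma1) && any(js$sigma1 > js$L1)) {
    stop("assembly error: sigma1 outside part 1", call. = FALSE)
  }
  if (NROW(js$sigma2) && any(js$sigma2 < 1L | js$sigma2 > js$L2)) {
    stop("assembly error: sigma2 outside part 2", call. = FALSE)
  }
  if (NROW(js$sigma_int) &&
      !all(js$sigma_int[, 1] <= js$L1 & js$sigma_int[, 2] > js$L1)) {
    stop("assembly error: inter-molecular pair within one part",
         call. = FALSE)
  }
  for (layer in unique(js$layers)) {
    check_noncrossing(allp[js$layers == layer, , drop = FALSE],
                      paste("layer", layer, "pairs"))
  }
  invisible(TRUE)
}

#' Final decoding of the joint structure
#'
#' Decodes the maximum expected accuracy structure from the Step-2
#' reliabilities with the constrained (sigma^p) positions forced unpaired
#' and their pairs at weight 0 -- which is what permits pseudoknots between
#' the constrained and the newly decoded pairs -- then re-adds the sigma^p
#' pairs unconditionally and classifies every pair into the constrained,
#' intra-molecular or inter-molecular layer.
#'
#' @param rel2 the Step-2 `reliability_matrix` (from [combine_step2()]).
#' @param partials list of the two `partial_structure`s.
#' @param params an [hf_params()].
#' @return a `joint_structure`.
#' @export
final_decode <- function(rel2, partials, params = hf_params()) {
  L <- rel2$L
  L1 <- rel2$L1
  L2 <- L - L1
  sig_pairs <- .sigma_pairs_global(partials, L1)
  sig_pos <- .sigma_positions(partials, L1)
  constraint <- structure_constraint(L, forced_unpaired = sig_pos)
  overrides <- if (nrow(sig_pairs) > 0L) cbind(sig_pairs, 0) else NULL
  dec <- mea_decode(rel2, constraint, overrides)
  dec <- matrix(as.integer(dec), ncol = 2L)
  if (nrow(dec) > 0L && any(as.vector(dec) %in% sig_pos)) {
    stop("assembly error: decoded pair touches a constrained position",
         call. = FALSE)
  }
  is_int <- dec[, 1] <= L1 & dec[, 2] > L1
  is_p1 <- dec[, 2] <= L1
  is_p2 <- dec[, 1] > L1
  sigma1 <- dec[is_p1, , drop = FALSE]
  sigma2 <- dec[is_p2, , drop = FALSE] - L1
  sigma_int <- dec[is_int, , drop = FALSE]
  ## re-add the constrained pairs (part-local coordinates)
  c1 <- partials[[1]]$pairs
  c2 <- partials[[2]]$pairs
  sigma1 <- rbind(c1, sigma1)
  sigma2 <- rbind(c2, sigma2)
  layers <- c(rep("constrained", nrow(c1)),
              rep("step2-intra", sum(is_p1)),
              rep("constrained", nrow(c2)),
              rep("step2-intra", sum(is_p2)),
              rep("step2-inter", sum(is_int)))
  ## reliabilities on the combined Step-2 scale; constrained pairs report
  ## their fixed ensemble-probability-based scores, already in rel2
  js_tmp <- list(sigma1 = sigma1, sigma2 = sigma2, sigma_int = sigma_int,
                 L1 = L1, L2 = L2)
  gp <- joint_pairs_global(structure(js_tmp, class = "joint_structure"))
  rels <- if (nrow(gp)) rel2$pair[gp] else numeric(0)
  new_joint_structure(sigma1, sigma2, sigma_int, layers, rels, L1, L2)
}

## dot-bracket strings per layer over global coordinates
.layer_strings <- function(js) {
  L <- js$L1 + js$L2
  gp <- joint_pairs_global(js)
  out <- c(constrained = strrep(".", L), `step2-intra` = strrep(".", L),
           `step2-inter` = strrep(".", L))
  br <- list(constrained = c("[", "]"), `step2-intra` = c("(", ")"),
             `step2-inter` = c("<", ">"))
  for (layer in names(out)) {
    sel <- which(js$layers == layer)
    if (length(sel) == 0L) next
    chars <- rep(".", L)
    chars[gp[sel, 1]] <- br[[layer]][1]
    chars[gp[sel, 2]] <- br[[layer]][2]
    out[layer] <- paste(chars, collapse = "")
  }
  out
}

#' Joint structure string in layered bracket notation
#'
#' One string over the global coordinates (no linker), combining the three
#' layers; by construction each position belongs to at most one pair so the
#' layers never collide on a character.
#' @param js a `joint_structure`.
#' @export
structure_string <- function(js) {
  ls <- .layer_strings(js)
  chars <- strsplit(ls[["constrained"]], "", fixed = TRUE)[[1]]
  for (layer in c("step2-intra", "step2-inter")) {
    lc <- strsplit(ls[[layer]], "", fixed = TRUE)[[1]]
    chars[lc != "."] <- lc[lc != "."]
  }
  paste(chars, collapse = "")
}

#' Render a joint prediction as a Stockholm-style text report
#'
#' Shows both alignments joined by the display linker `&`, the joint
#' structure string (`[ ]` constrained, `( )` intra-molecular, `< >`
#' inter-molecular), and a per-pair reliability table.  The gap filter hides
#' columns with at least `gap_filter` gap fraction from the *display only*;
#' it never affects computation.
#'
#' @param js a `joint_structure`.
#' @param pair the `alignment_pair` it was computed from.
#' @param gap_filter display threshold in (0, 1], or `NULL` to show all
#'   columns.
#' @return character vector of report lines (invisibly printed by
#'   `print.hierfold`).
#' @export
render <- function(js, pair, gap_filter = NULL) {
  ca <- concatenate(pair, mode = "display")
  struct <- structure_string(js)
  ## physical display strings: insert the '&' column into the structure
  schars <- strsplit(struct, "", fixed = TRUE)[[1]]
  phys_struct <- c(schars[seq_len(js$L1)], "&",
                   schars[js$L1 + seq_len(js$L2)])
  keep <- seq_len(ca$phys_L)
  if (!is.null(gap_filter)) {
    mat <- aln_matrix(ca)
    gapfrac <- colMeans(mat == "-")
    keep <- which(gapfrac < gap_filter | seq_len(ca$phys_L) %in% ca$linker_phys)
  }
  w <- max(nchar(c(ca$taxa, "#=GC joint_SS"))) + 2L
  lines <- character(0)
  mat <- aln_matrix(ca)
  for (k in seq_len(ca$n)) {
    lines <- c(lines, sprintf("%-*s%s", w, ca$taxa[k],
                              paste(mat[k, keep], collapse = "")))
  }
  lines <- c(lines, sprintf("%-*s%s", w, "#=GC joint_SS",
                            paste(phys_struct[keep], collapse = "")))
  gp <- joint_pairs_global(js)
  if (nrow(gp) > 0L) {
    lines <- c(lines, "", "# pairs (global coordinates; part 2 starts at L1+1):",
               sprintf("# %4s %4s  %-12s %s", "i", "j", "layer", "reliability"))
    ord <- order(gp[, 1])
    for (r in ord) {
      lines <- c(lines, sprintf("# %4d %4d  %-12s %.4f", gp[r, 1], gp[r, 2],
                                js$layers[r], js$reliabilities[r]))
    }
  } else {
    lines <- c(lines, "", "# no base pairs predicted")
  }
  lines
}

#' Parse a layered bracket string back into pair sets
#'
#' Inverse of [structure_string()] (used for round-trip validation): each
#' bracket class is matched independently with a stack.
#' @param s structure string over global coordinates.
#' @param L1 length of part 1.
#' @return list with `pairs` (2-column global matrix) and `layers`.
#' @export
parse_structure_string <- function(s, L1) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  br <- list(constrained = c("[", "]"), `step2-intra` = c("(", ")"),
             `step2-inter` = c("<", ">"))
  pairs <- matrix(integer(0), 0, 2)
  layers <- character(0)
  for (layer in names(br)) {
    open <- br[[layer]][1]; close <- br[[layer]][2]
    stack <- integer(0)
    for (pos in seq_along(chars)) {
      if (chars[pos] == open) {
        stack <- c(stack, pos)
      } else if (chars[pos] == close) {
        if (length(stack) == 0L) stop("unbalanced '", close, "' at ", pos)
        pairs <- rbind(pairs, c(stack[length(stack)], pos))
        layers <- c(layers, layer)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0L) stop("unbalanced '", open, "'")
  }
  list(pairs = pairs, layers = layers)
}

#' Summed inter-molecular reliability
#'
#' Convenience ranking metric: the sum of the combined Step-2 reliabilities
#' of the predicted inter-molecular pairs.  This scalar is an artifact of
#' this package (the method itself defines no overall interaction score).
#' @param js a `joint_structure`.
#' @export
interaction_score <- function(js) {
  sum(js$reliabilities[js$layers == "step2-inter"])
}

#' @export
print.joint_structure <- function(x, ...) {
  cat(sprintf("Joint structure: %d + %d intra pairs, %d inter pairs (L1=%d, L2=%d)\n",
              NROW(x$sigma1), NROW(x$sigma2), NROW(x$sigma_int), x$L1, x$L2))
  cat(" ", structure_string(x), "\n")
  invisible(x)
}
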