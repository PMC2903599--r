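## Phylogenetic machinery: substitution models, Felsenstein pruning over
## single and paired alignment columns, and neighbor-joining tree estimation.
## Trees are ape "phylo" objects throughout; branch lengths are expected
## substitutions per site.

NT <- c("A", "C", "G", "U")
## 16 dinucleotide states ordered first-nucleotide-major (AA AC AG AU CA ...),
## so pair (a, b) has index (a-1)*4 + b.
PAIR_STATES <- paste0(rep(NT, each = 4L), NT)

#' Load a phylo-SCFG parameter set
#'
#' Parses the plain key/value parameter format bundled with the package
#' (see `inst/extdata/scfg_params_synthetic.txt`, a synthetic stand-in asset)
#' and builds the grammar probabilities plus reversible single-nucleotide
#' (4-state) and base-pair (16-state) substitution models.  Rate matrices are
#' GTR-style: `Q[x,y] = exch(x,y) * pi[y]`, scaled to one expected
#' substitution per unit branch length.
#'
#' @param path parameter file; defaults to the bundled asset.
#' @return an object of class `scfg_params`: list with `grammar` (named
#'   production probabilities), `single` and `pair` (`subst_model` objects).
#' @export
load_scfg_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scfg_params_synthetic.txt",
                        package = "hierfold", mustWork = TRUE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  key <- vapply(toks, `[`, "", 1L)
  get1 <- function(k) {
    v <- toks[key == k]
    if (length(v) != 1L) stop("parameter file: expected one '", k, "' entry")
    as.numeric(v[[1]][2])
  }
  getmap <- function(k) {
    v <- toks[key == k]
    stats::setNames(vapply(v, function(t) as.numeric(t[3]), 0),
                    vapply(v, `[`, "", 2L))
  }
  gr <- getmap("grammar")
  need <- c("S->LS", "S->L", "L->s", "L->dFd", "F->dFd", "F->LS")
  if (!all(need %in% names(gr))) {
    stop("parameter file: missing grammar production(s): ",
         paste(setdiff(need, names(gr)), collapse = ", "))
  }
  gr <- gr[need]
  if (any(gr <= 0)) stop("grammar probabilities must be > 0")
  for (nt in c("S", "L", "F")) {
    s <- sum(gr[startsWith(names(gr), paste0(nt, "->"))])
    if (abs(s - 1) > 1e-6) stop("grammar: productions of ", nt, " sum to ", s)
    gr[startsWith(names(gr), paste0(nt, "->"))] <-
      gr[startsWith(names(gr), paste0(nt, "->"))] / s
  }
  pf <- getmap("single_freq")[NT]
  if (any(is.na(pf))) stop("parameter file: need single_freq for A,C,G,U")
  pf <- pf / sum(pf)
  ex1 <- get1("single_exch")
  single <- make_subst_model(pf, matrix(ex1, 4, 4), NT)

  pp <- getmap("pair_freq")[PAIR_STATES]
  if (any(is.na(pp))) stop("parameter file: need all 16 pair_freq entries")
  pp <- pp / sum(pp)
  es <- get1("pair_exch_single"); ed <- get1("pair_exch_double")
  prate <- if (any(key == "pair_rate")) get1("pair_rate") else 2
  d1 <- substr(PAIR_STATES, 1, 1); d2 <- substr(PAIR_STATES, 2, 2)
  ndiff <- outer(d1, d1, "!=") + outer(d2, d2, "!=")
  exch <- ifelse(ndiff == 1, es, ifelse(ndiff == 2, ed, 0))
  pair <- make_subst_model(pp, exch, PAIR_STATES, rate = prate)
  canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
  if (sum(pp[canon]) < 0.5) {
    stop("pair model: stationary mass is not concentrated on canonical pairs")
  }
  structure(list(grammar = gr, single = single, pair = pair, path = path),
            class = "scfg_params")
}

#' Build a reversible substitution model
#'
#' @param pi stationary distribution (named by state).
#' @param exch symmetric exchangeability matrix (diagonal ignored).
#' @param states state labels.
#' @param rate expected substitutions per unit branch length (branch lengths
#'   are per *site*: a dinucleotide pair state covers two sites and so runs
#'   at rate 2 by convention).
#' @return a `subst_model`: stationary distribution, scaled rate matrix and
#'   its symmetrized eigendecomposition for fast matrix exponentials.
#' @export
make_subst_model <- function(pi, exch, states = names(pi), rate = 1) {
  k <- length(pi)
  stopifnot(k == nrow(exch), k == ncol(exch), all(pi > 0))
  pi <- pi / sum(pi)
  Q <- exch * rep(pi, each = k)       # Q[x,y] = exch[x,y] * pi[y]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))            # expected substitutions per unit time
  if (mu <= 0) stop("degenerate rate matrix")
  Q <- Q * (rate / mu)
  ## reversibility makes D^{1/2} Q D^{-1/2} symmetric: stable eigen
  sq <- sqrt(pi)
  B <- (sq %o% (1 / sq)) * Q
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- (1 / sq) * e$vectors           # rows scaled
  Uinv <- t(e$vectors * sq)
  structure(list(states = states, pi = stats::setNames(pi, states), Q = Q,
                 eigval = e$values, U = U, Uinv = Uinv, nstate = k),
            class = "subst_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by eigendecomposition of the (reversible) rate matrix with a
#' scaling-and-squaring series fallback; reconstruction tolerance 1e-12.
#' @param model a `subst_model`.
#' @param t branch length (>= 0).
#' @export
transition_matrix <- function(model, t) {
  stopifnot(t >= 0, is.finite(t))
  if (t == 0) return(diag(model$nstate))   # exact identity, exact zeros
  P <- model$U %*% (exp(model$eigval * t) * model$Uinv)
  if (any(!is.finite(P)) ||
      max(abs(rowSums(P) - 1)) > 1e-8) {
    P <- .expm_series(model$Q * t)
  }
  P[P < 0] <- 0
  P
}

## scaling-and-squaring Taylor series; used as fallback and as test oracle
.expm_series <- function(A, terms = 30L) {
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  A <- A / 2^s
  P <- diag(nrow(A)); term <- diag(nrow(A))
  for (k in seq_len(terms)) {
    term <- term %*% A / k
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

#' Estimate a phylogenetic tree from an alignment
#'
#' Neighbor-joining on Jukes-Cantor pairwise distances (gaps excluded
#' pairwise); negative NJ branch lengths are clamped to 0.  Deterministic
#' given the input row order.  Linker columns of a concatenated alignment are
#' gap characters and therefore excluded automatically.
#'
#' @param aln an `rna_alignment` or `concat_alignment`.
#' @return an ape `phylo` tree whose tips are the alignment taxa.
#' @export
estimate_tree <- function(aln) {
  if (aln$n < 2L) stop("tree estimation needs at least 2 sequences",
                       call. = FALSE)
  rows <- gsub("&", "-", aln$rows, fixed = TRUE)
  mat <- do.call(rbind, strsplit(chartr("U", "T", rows), "", fixed = TRUE))
  rownames(mat) <- aln$taxa
  d <- ape::dist.dna(ape::as.DNAbin(tolower(mat)), model = "JC69",
                     pairwise.deletion = TRUE)
  dm <- as.matrix(d)
  bad <- which(!is.finite(dm), arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (nrow(bad) > 0L) {
    stop("saturated or undefined JC distance between '",
         aln$taxa[bad[1, 1]], "' and '", aln$taxa[bad[1, 2]], "'",
         call. = FALSE)
  }
  if (aln$n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10f,%s:%.10f);",
                                        aln$taxa[1], dm[1, 2] / 2,
                                        aln$taxa[2], dm[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Read a user-supplied Newick tree and match it to alignment taxa
#' @param path Newick file.
#' @param taxa taxon ids the leaf set must equal.
#' @export
read_tree_file <- function(path, taxa = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("failed to parse Newick file: ", path, call. = FALSE)
  if (!is.null(taxa) && !setequal(tr$tip.label, taxa)) {
    stop("tree leaves do not match alignment taxa.\n  tree: ",
         paste(sort(tr$tip.label), collapse = ", "), "\n  alignment: ",
         paste(sort(taxa), collapse = ", "), call. = FALSE)
  }
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tr$edge.length < 0)) stop("negative branch length in tree",
                                    call. = FALSE)
  tr
}

## Vectorized Felsenstein pruning.
## leaf_lik: list (by tree tip order) of nstate x K likelihood matrices.
## Returns the log-likelihood vector of length K (log of column probability).
prune_loglik <- function(tree, model, leaf_lik) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  K <- ncol(leaf_lik[[1]])
  part <- vector("list", nnode)
  logscale <- matrix(0, nnode, K)
  for (k in seq_len(ntip)) part[[k]] <- leaf_lik[[k]]
  edges <- tree$edge
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; chd <- edges[e, 2]
    P <- transition_matrix(model, tree$edge.length[e])
    contrib <- P %*% part[[chd]]
    if (is.null(part[[par]])) {
      part[[par]] <- contrib
      logscale[par, ] <- logscale[chd, ]
    } else {
      part[[par]] <- part[[par]] * contrib
      logscale[par, ] <- logscale[par, ] + logscale[chd, ]
    }
    ## rescale to avoid underflow
    mx <- apply(part[[par]], 2, max)
    pos <- mx > 0
    if (any(pos)) {
      part[[par]][, pos] <- part[[par]][, pos, drop = FALSE] /
        rep(mx[pos], each = model$nstate)
      logscale[par, pos] <- logscale[par, pos] + log(mx[pos])
    }
  }
  root <- edges[nrow(edges), 1]
  lik <- as.vector(model$pi %*% part[[root]])
  out <- ifelse(lik > 0, log(lik) + logscale[root, ], -Inf)
  out
}

.residue_index <- function(chars) {
  idx <- match(chars, NT)   # NA for gap / N
  idx
}

.leaf_lik_single <- function(res_idx, K) {
  ## res_idx: integer vector length K (NA = missing)
  m <- matrix(0, 4, K)
  known <- !is.na(res_idx)
  m[cbind(res_idx[known], which(known))] <- 1
  m[, !known] <- 1
  m
}

#' Log-likelihood of one unpaired alignment column
#'
#' Felsenstein pruning under the single-nucleotide model; gaps and ambiguity
#' codes are missing data (all-ones partial likelihood).
#' @param tree ape `phylo`; tips in `column` order when `column` is unnamed,
#'   otherwise matched by name.
#' @param model a `subst_model` with 4 states.
#' @param column character vector of residues/gaps, one per leaf.
#' @return log probability (possibly `-Inf`).
#' @export
column_loglik <- function(tree, model, column) {
  column <- .match_leaves(tree, column)
  bad <- !(column %in% c(NT, "N", "-"))
  if (any(bad)) stop("residue outside alphabet: ", column[which(bad)[1]],
                     call. = FALSE)
  if (length(tree$tip.label) == 1L || is.null(tree$edge) ||
      nrow(tree$edge) == 0L) {
    idx <- .residue_index(column[1])
    return(if (is.na(idx)) 0 else log(model$pi[[idx]]))
  }
  ll <- lapply(.residue_index(column), .leaf_lik_single, K = 1L)
  prune_loglik(tree, model, ll)[1]
}

#' Log-likelihood of a paired column pair
#'
#' Pruning over 16 dinucleotide states.  A leaf with a gap (or N) in either
#' column is treated as missing in both (symmetric missing-data rule).
#' @inheritParams column_loglik
#' @param model a `subst_model` with 16 states.
#' @param col_i,col_j character vectors of residues, one per leaf.
#' @export
paircol_loglik <- function(tree, model, col_i, col_j) {
  col_i <- .match_leaves(tree, col_i); col_j <- .match_leaves(tree, col_j)
  bad <- !(c(col_i, col_j) %in% c(NT, "N", "-"))
  if (any(bad)) stop("residue outside alphabet", call. = FALSE)
  a <- .residue_index(col_i); b <- .residue_index(col_j)
  st <- ifelse(is.na(a) | is.na(b), NA_integer_, (a - 1L) * 4L + b)
  if (length(tree$tip.label) == 1L || is.null(tree$edge) ||
      nrow(tree$edge) == 0L) {
    return(if (is.na(st[1])) 0 else log(model$pi[[st[1]]]))
  }
  ll <- lapply(st, function(s) {
    m <- matrix(if (is.na(s)) 1 else 0, 16, 1)
    if (!is.na(s)) m[s, 1] <- 1
    m
  })
  prune_loglik(tree, model, ll)[1]
}

.match_leaves <- function(tree, column) {
  if (!is.null(names(column))) {
    idx <- match(tree$tip.label, names(column))
    if (any(is.na(idx))) stop("column names do not cover tree leaves",
                              call. = FALSE)
    column <- column[idx]
  }
  if (length(column) != length(tree$tip.label)) {
    stop("column length != number of leaves", call. = FALSE)
  }
  toupper(column)
}

## All single-column and paired-column log emissions of an alignment, for the
## SCFG.  Returns list(log_es = L vector, log_ep = L x L matrix (upper
## triangle filled, symmetric)).  aln rows are matched to tree tips by taxon
## id.  Linker '&' characters are treated as gaps here (callers mask
## prior-free columns separately).
emission_logliks <- function(aln, tree, params) {
  mat <- aln_matrix(aln)
  mat[mat == "&"] <- "-"
  ord <- match(tree$tip.label, aln$taxa)
  if (any(is.na(ord))) stop("tree leaves do not match alignment taxa",
                            call. = FALSE)
  mat <- mat[ord, , drop = FALSE]
  L <- ncol(mat); n <- nrow(mat)
  res <- matrix(.residue_index(mat), n, L)
  if (n == 1L) {
    les <- ifelse(is.na(res[1, ]), 0, log(params$single$pi[res[1, ]]))
    ut <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    st <- ifelse(is.na(res[1, ut[, 1]]) | is.na(res[1, ut[, 2]]), NA_integer_,
                 (res[1, ut[, 1]] - 1L) * 4L + res[1, ut[, 2]])
    lep <- matrix(-Inf, L, L)
    lep[ut] <- ifelse(is.na(st), 0, log(params$pair$pi[st]))
    lep[lower.tri(lep)] <- t(lep)[lower.tri(lep)]
    return(list(log_es = les, log_ep = lep))
  }
  ll_s <- lapply(seq_len(n), function(k) .leaf_lik_single(res[k, ], L))
  log_es <- prune_loglik(tree, params$single, ll_s)

  ut <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  ii <- ut[, 1]; jj <- ut[, 2]
  K <- length(ii)
  ll_p <- lapply(seq_len(n), function(k) {
    a <- res[k, ii]; b <- res[k, jj]
    st <- ifelse(is.na(a) | is.na(b), NA_integer_, (a - 1L) * 4L + b)
    m <- matrix(0, 16, K)
    known <- !is.na(st)
    m[cbind(st[known], which(known))] <- 1
    m[, !known] <- 1
    m
  })
  lp <- prune_loglik(tree, params$pair, ll_p)
  log_ep <- matrix(-Inf, L, L)
  log_ep[ut] <- lp
  log_ep[lower.tri(log_ep)] <- t(log_ep)[lower.tri(log_ep)]
  list(log_es = log_es, log_ep = log_ep)
}
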