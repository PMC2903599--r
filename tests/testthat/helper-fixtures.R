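## Shared fixtures: small fixed trees and in-memory alignments.

fixed_tree <- function(n) {
  switch(n,
         ape::read.tree(text = "(t1:0.1);"),
         ape::read.tree(text = "(t1:0.1,t2:0.15);"),
         ape::read.tree(text = "((t1:0.1,t2:0.12):0.05,t3:0.2);"),
         ape::read.tree(text = "((t1:0.1,t2:0.12):0.05,(t3:0.08,t4:0.2):0.04);"))
}

make_aln <- function(rows, taxa = paste0("t", seq_along(rows))) {
  hierfold:::new_rna_alignment(taxa, rows)
}

write_fasta <- function(rows, taxa = paste0("t", seq_along(rows)),
                        path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", taxa, "\n", rows), path)
  path
}

## a two-part fixture with one clean stem per part and complementary loops
fixture_pair <- function(n = 3) {
  r1 <- "GGCGAAGGAGGAAACGCCAA"   # stem (1,18)..(4,15)-ish region; loop middle
  r2 <- "AAGGCGAUCCUCCAAACGCC"
  make_pair <- function(r, taxa) make_aln(rep(r, n), taxa = taxa)
  taxa <- paste0("t", seq_len(n))
  pair_taxa(make_pair(r1, taxa), make_pair(r2, taxa))
}

## random posterior over nested structures: mixture of k random nested
## structures on L columns (a valid base-pair reliability source)
random_nested_posterior <- function(L, k = sample(2:5, 1)) {
  pairable <- function(i, j) j - i >= 2
  structs <- enum_nested(L, pairable)
  pick <- sample(length(structs), min(k, length(structs)))
  w <- stats::rgamma(length(pick), 1)
  w <- w / sum(w)
  P <- matrix(0, L, L)
  for (q in seq_along(pick)) {
    s <- structs[[pick[q]]]
    if (NROW(s) > 0L) {
      P[s] <- P[s] + w[q]
      P[s[, c(2, 1), drop = FALSE]] <- P[s[, c(2, 1), drop = FALSE]] + w[q]
    }
  }
  P
}
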