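## Alignment containers and I/O.
##
## An `rna_alignment` is a plain list: `taxa` (unique ids), `rows` (equal-length
## gapped uppercase RNA strings over A,C,G,U,N,-), `n` sequences and `L`
## columns.  All interfaces are 1-based with closed intervals; column i of the
## alignment is the i-th character of every row.

ALN_ALPHABET <- c("A", "C", "G", "U", "N", "-")
## IUPAC ambiguity codes are accepted on read and collapsed to N (fully
## ambiguous: marginalized in likelihoods, never paired thermodynamically).
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

new_rna_alignment <- function(taxa, rows) {
  taxa <- as.character(taxa)
  rows <- toupper(as.character(rows))
  if (length(rows) == 0L) stop("empty alignment: no sequences", call. = FALSE)
  if (anyDuplicated(taxa)) {
    stop("duplicated taxon ids: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  }
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: row lengths ", paste(lens, collapse = ", "),
         call. = FALSE)
  }
  if (lens[1] < 1L) stop("empty alignment: zero columns", call. = FALSE)
  rows <- gsub(".", "-", gsub("T", "U", rows, fixed = TRUE), fixed = TRUE)
  for (a in IUPAC_AMBIG) rows <- gsub(a, "N", rows, fixed = TRUE)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  bad <- which(matrix(!(mat %in% ALN_ALPHABET), nrow(mat)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("unknown residue '%s' in row '%s' (sequence %d), column %d",
                 mat[bad[1, 1], bad[1, 2]], taxa[bad[1, 1]],
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  structure(list(taxa = taxa, rows = rows, n = length(rows), L = lens[1]),
            class = "rna_alignment")
}

#' Read a multiple RNA alignment
#'
#' Reads FASTA, Clustal or Stockholm alignments (format auto-detected from the
#' file content by default).  Sequences are normalized to uppercase RNA
#' (`T` becomes `U`, `.` becomes `-`, IUPAC ambiguity codes become `N`).  A
#' Stockholm `#=GC SS_cons` annotation, if present, is ignored with a notice:
#' this package computes its own consensus structures.
#'
#' @param path path to the alignment file.
#' @param format one of `"auto"`, `"fasta"`, `"clustal"`, `"stockholm"`.
#' @return an object of class `rna_alignment` with fields `taxa`, `rows`,
#'   `n` and `L`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  head_lines <- head_lines[nzchar(trimws(head_lines))]
  if (length(head_lines) == 0L) stop("empty-input: ", path, call. = FALSE)
  if (format == "auto") {
    first <- head_lines[1]
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm"
    else if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal"
    else if (grepl("^>", first)) "fasta"
    else stop("cannot auto-detect alignment format of ", path, call. = FALSE)
  }
  if (format == "stockholm" &&
      any(grepl("^#=GC\\s+SS_cons", readLines(path, warn = FALSE)))) {
    message("note: #=GC SS_cons line in ", basename(path),
            " is ignored; structures are recomputed")
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty-input: ", path, call. = FALSE)
    taxa <- sub("\\s.*$", "", names(set))
    rows <- as.character(set)
  } else {
    msa <- .read_msa_biostrings(path, format)
    rows <- as.character(msa)
    taxa <- rownames(msa) %||% names(rows)
    if (is.null(taxa) || !any(nzchar(taxa))) taxa <- names(rows)
  }
  new_rna_alignment(taxa, rows)
}

## Biostrings has fixed alphabets (RNA lacks T, DNA lacks U), so try both.
.read_msa_biostrings <- function(path, format) {
  res <- tryCatch(Biostrings::readRNAMultipleAlignment(path, format = format),
                  error = function(e) e)
  if (inherits(res, "error")) {
    res <- tryCatch(Biostrings::readDNAMultipleAlignment(path, format = format),
                    error = function(e) e)
  }
  if (inherits(res, "error")) {
    stop("failed to parse ", path, " as ", format, ": ",
         conditionMessage(res), call. = FALSE)
  }
  res
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat(sprintf("RNA alignment: %d sequences x %d columns\n", x$n, x$L))
  w <- min(x$L, 60L)
  for (k in seq_len(min(x$n, 8L))) {
    cat(sprintf("  %-15s %s%s\n", substr(x$taxa[k], 1, 15),
                substr(x$rows[k], 1, w), if (x$L > w) "..." else ""))
  }
  if (x$n > 8L) cat(sprintf("  ... (%d more)\n", x$n - 8L))
  invisible(x)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

#' Pair the taxa of two alignments
#'
#' Restricts two alignments (one ncRNA family, one target-region family) to a
#' common taxon set in a common order.  Columns that become all-gap after the
#' restriction are dropped; the original column indices of the kept columns
#' are recorded in `col_keep1`/`col_keep2`.
#'
#' @param aln1,aln2 `rna_alignment` objects.
#' @param policy `"exact_id"` matches identical ids, `"prefix"` matches on the
#'   id portion before `prefix_sep`, `"order"` pairs rows by position.
#' @param prefix_sep separator used by the prefix policy.
#' @param min_taxa minimum number of paired taxa (set to 1 only when the
#'   evolutionary model is disabled downstream).
#' @return an `alignment_pair` with fields `aln1`, `aln2`, `taxa`,
#'   `col_keep1`, `col_keep2`.
#' @export
pair_taxa <- function(aln1, aln2, policy = c("exact_id", "prefix", "order"),
                      prefix_sep = "_", min_taxa = 2L) {
  policy <- match.arg(policy)
  stopifnot(inherits(aln1, "rna_alignment"), inherits(aln2, "rna_alignment"))
  if (policy == "order") {
    m <- min(aln1$n, aln2$n)
    idx1 <- seq_len(m); idx2 <- seq_len(m)
    labels <- aln1$taxa[idx1]
  } else {
    key1 <- if (policy == "exact_id") aln1$taxa else
      sub(paste0(prefix_sep, ".*$"), "", aln1$taxa)
    key2 <- if (policy == "exact_id") aln2$taxa else
      sub(paste0(prefix_sep, ".*$"), "", aln2$taxa)
    shared <- key1[key1 %in% key2]
    shared <- shared[!duplicated(shared)]
    if (length(shared) == 0L) {
      stop("no shared taxa under policy '", policy, "'.\n  alignment 1: ",
           paste(aln1$taxa, collapse = ", "), "\n  alignment 2: ",
           paste(aln2$taxa, collapse = ", "), call. = FALSE)
    }
    idx1 <- match(shared, key1)
    idx2 <- match(shared, key2)
    labels <- shared
  }
  if (length(idx1) < min_taxa) {
    stop("only ", length(idx1), " paired taxa; need at least ", min_taxa,
         call. = FALSE)
  }
  r1 <- .restrict_rows(aln1, idx1, labels)
  r2 <- .restrict_rows(aln2, idx2, labels)
  structure(list(aln1 = r1$aln, aln2 = r2$aln, taxa = labels,
                 col_keep1 = r1$keep, col_keep2 = r2$keep),
            class = "alignment_pair")
}

.restrict_rows <- function(aln, idx, labels) {
  mat <- aln_matrix(aln)[idx, , drop = FALSE]
  keep <- which(colSums(mat != "-") > 0L)
  if (length(keep) < ncol(mat)) {
    message("dropping ", ncol(mat) - length(keep),
            " all-gap column(s) after taxon restriction")
  }
  if (length(keep) == 0L) stop("alignment is all gaps after restriction",
                               call. = FALSE)
  rows <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  list(aln = new_rna_alignment(labels, rows), keep = keep)
}

#' Concatenate a paired alignment with a linker
#'
#' Joins the two alignments row-wise.  In `display` mode a single `&` column
#' is inserted (the RNAcofold convention); in `evo` mode three prior-free
#' linker columns are inserted, which the evolutionary model treats as
#' unpaired columns with unit emission and no grammar contribution.  In both
#' modes the *global* numbering of part 2 starts at L1+1: linker columns are
#' excluded from the numbering.
#'
#' @param pair an `alignment_pair`.
#' @param mode `"display"` or `"evo"`.
#' @return a `concat_alignment`.
#' @export
concatenate <- function(pair, mode = c("display", "evo")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pair, "alignment_pair"))
  lw <- if (mode == "display") 1L else 3L
  linker <- strrep(if (mode == "display") "&" else "-", lw)
  rows <- paste0(pair$aln1$rows, linker, pair$aln2$rows)
  L1 <- pair$aln1$L; L2 <- pair$aln2$L
  structure(list(pair = pair, mode = mode, taxa = pair$taxa, rows = rows,
                 n = pair$aln1$n, L1 = L1, L2 = L2, linker_width = lw,
                 linker_phys = L1 + seq_len(lw),
                 prior_free = if (mode == "evo") L1 + seq_len(lw) else integer(0),
                 L = L1 + L2, phys_L = L1 + lw + L2),
            class = "concat_alignment")
}

#' Map between global and physical columns of a concatenation
#'
#' Global positions run 1..L1 for part 1 and L1+1..L1+L2 for part 2; physical
#' columns additionally contain the linker.
#' @param ca a `concat_alignment`.
#' @param i global position(s).
#' @export
global_to_phys <- function(ca, i) {
  stopifnot(all(i >= 1L & i <= ca$L))
  ifelse(i <= ca$L1, i, i + ca$linker_width)
}

#' @rdname global_to_phys
#' @param phys physical column(s).
#' @export
phys_to_global <- function(ca, phys) {
  stopifnot(all(phys >= 1L & phys <= ca$phys_L))
  out <- ifelse(phys <= ca$L1, phys,
                ifelse(phys > ca$L1 + ca$linker_width,
                       phys - ca$linker_width, NA_integer_))
  as.integer(out)
}

#' @rdname global_to_phys
#' @export
part_of <- function(ca, phys) {
  stopifnot(inherits(ca, "concat_alignment"),
            all(phys >= 1L & phys <= ca$phys_L))
  ifelse(phys <= ca$L1, "1",
         ifelse(phys <= ca$L1 + ca$linker_width, "linker", "2"))
}

#' @rdname global_to_phys
#' @param j position within part 2 (1-based).
#' @export
col_of_part2 <- function(ca, j) {
  stopifnot(all(j >= 1L & j <= ca$L2))
  ca$L1 + as.integer(j)
}

#' Column / sequence-position maps
#'
#' `col_to_seqpos` maps an alignment column to the 1-based ungapped position
#' in one row (`NA` for a gap); `seqpos_to_col` is its inverse over non-gap
#' columns.
#' @param aln an `rna_alignment`.
#' @param seq_index row index.
#' @param col column index (1..L).
#' @export
col_to_seqpos <- function(aln, seq_index, col) {
  stopifnot(seq_index >= 1L, seq_index <= aln$n)
  if (any(col < 1L | col > aln$L)) stop("column out of range", call. = FALSE)
  chars <- strsplit(aln$rows[seq_index], "", fixed = TRUE)[[1]]
  pos <- cumsum(chars != "-")
  ifelse(chars[col] == "-", NA_integer_, as.integer(pos[col]))
}

#' @rdname col_to_seqpos
#' @param pos ungapped sequence position.
#' @export
seqpos_to_col <- function(aln, seq_index, pos) {
  chars <- strsplit(aln$rows[seq_index], "", fixed = TRUE)[[1]]
  nongap <- which(chars != "-")
  if (any(pos < 1L | pos > length(nongap))) {
    stop("sequence position out of range", call. = FALSE)
  }
  nongap[pos]
}

ungapped_seq <- function(aln, seq_index) {
  gsub("-", "", aln$rows[seq_index], fixed = TRUE)
}

#' Write an alignment in Stockholm format
#'
#' Optionally adds `#=GC` annotation lines (e.g. a joint structure string).
#' @param aln an `rna_alignment` or `concat_alignment`.
#' @param path output path.
#' @param gc named character vector of `#=GC` annotation lines.
#' @export
write_stockholm <- function(aln, path, gc = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  w <- max(nchar(c(aln$taxa, paste("#=GC", names(gc))))) + 2L
  for (k in seq_along(aln$taxa)) {
    writeLines(sprintf("%-*s%s", w, aln$taxa[k], aln$rows[k]), con)
  }
  if (!is.null(gc)) {
    for (nm in names(gc)) {
      writeLines(sprintf("%-*s%s", w, paste("#=GC", nm), gc[[nm]]), con)
    }
  }
  writeLines("//", con)
  invisible(path)
}
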