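#' Gapped multiple sequence alignments
#'
#' An `alignment` is a lightweight container for a gapped FASTA alignment:
#' an ordered set of equal-length gapped sequences with unique ids and an
#' alphabet tag (`"aa"` or `"nt"`).  The only gap character is `"-"`
#' (`"."` is normalized to `"-"` on construction).  In amino-acid
#' alignments `x`/`X` denote an unknown residue (used for translated STOP
#' codons) and count as residues, never as gaps.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character vector of gapped sequences, all the same length.
#' @param alphabet `"aa"` or `"nt"`.
#' @return An object of class `alignment`: a list with elements `ids`,
#'   `seqs`, `alphabet` and `n_cols`.
#' @examples
#' aln <- alignment(c("s1", "s2"), c("MK-R", "MKAR"), "aa")
#' aln$n_cols
#' @export
alignment <- function(ids, seqs, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  ids <- as.character(ids)
  seqs <- chartr(".", "-", as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- nchar(seqs)
  if (length(seqs) > 0 && length(unique(widths)) != 1L)
    stop("alignment shape error: sequences have unequal lengths (",
         paste(unique(widths), collapse = ", "), ")")
  legal <- if (alphabet == "aa") {
    "^[ACDEFGHIKLMNPQRSTVWYXacdefghiklmnpqrstvwyx-]*$"
  } else {
    "^[ACGTNUacgtnu-]*$"
  }
  bad <- !grepl(legal, seqs)
  if (any(bad))
    stop("alphabet error: illegal characters in sequence(s) ",
         paste(ids[bad], collapse = ", "))
  structure(
    list(ids = ids, seqs = seqs, alphabet = alphabet,
         n_cols = if (length(seqs)) widths[1] else 0L),
    class = "alignment"
  )
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d %s sequence(s) x %d columns\n",
              length(x$ids), x$alphabet, x$n_cols))
  n <- min(length(x$ids), 6L)
  for (i in seq_len(n)) {
    s <- x$seqs[i]
    if (nchar(s) > 50) s <- paste0(substr(s, 1, 47), "...")
    cat(sprintf("  %-15s %s\n", x$ids[i], s))
  }
  if (length(x$ids) > n) cat("  ...\n")
  invisible(x)
}

#' @export
length.alignment <- function(x) length(x$ids)

#' Read a gapped FASTA alignment
#'
#' Wrapped or unwrapped FASTA is accepted; `.` gaps are normalized to `-`.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"aa"` or `"nt"`.
#' @return An [alignment()].
#' @export
read_fasta <- function(path, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))   # id = first whitespace-delimited token
  alignment(ids, as.character(x), alphabet)
}

#' Write an alignment as 60-column wrapped FASTA
#'
#' @param aln an [alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  x <- Biostrings::BStringSet(setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# character matrix view (n_seqs x n_cols), one residue/gap per cell
aln_matrix <- function(aln) {
  if (length(aln$ids) == 0)
    return(matrix(character(0), nrow = 0, ncol = aln$n_cols))
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Residue-to-column coordinate maps
#'
#' For each sequence, the alignment column (1-based) of each ungapped
#' residue (1-based), i.e. the bijection between residue indices and the
#' non-gap columns of that row.
#'
#' @param aln an [alignment()].
#' @return Named list of integer vectors; element `i` has one entry per
#'   residue of sequence `i`, giving its alignment column.
#' @export
coord_map <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  out <- lapply(strsplit(aln$seqs, "", fixed = TRUE),
                function(ch) which(ch != "-"))
  names(out) <- aln$ids
  out
}

#' Remove gaps from alignment sequences
#'
#' @param aln an [alignment()].
#' @return Named character vector of ungapped sequences.
#' @export
degap <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  setNames(gsub("-", "", aln$seqs, fixed = TRUE), aln$ids)
}

#' Transfer protein alignment gaps onto coding sequences
#'
#' Expands every amino-acid gap to a `---` codon gap so that the coding
#' nucleotide sequences inherit the protein alignment: the output is a
#' codon-phased nucleotide alignment with `3 * n_cols` columns.
#'
#' @param protein_aln an amino-acid [alignment()].
#' @param cds_seqs named character vector of ungapped coding sequences;
#'   names must match `protein_aln$ids` and each must be exactly three
#'   times the ungapped protein length.
#' @return A nucleotide [alignment()].
#' @export
transfer_gaps <- function(protein_aln, cds_seqs) {
  stopifnot(inherits(protein_aln, "alignment"),
            protein_aln$alphabet == "aa")
  if (is.null(names(cds_seqs)) || !all(protein_aln$ids %in% names(cds_seqs)))
    stop("cds_seqs must be named and cover every alignment id")
  out <- character(length(protein_aln$ids))
  for (i in seq_along(protein_aln$ids)) {
    aa <- strsplit(protein_aln$seqs[i], "", fixed = TRUE)[[1]]
    nt <- cds_seqs[[protein_aln$ids[i]]]
    n_res <- sum(aa != "-")
    if (nchar(nt) != 3L * n_res)
      stop("codon-phase error for ", protein_aln$ids[i], ": CDS length ",
           nchar(nt), " != 3 x ", n_res, " residues")
    codons <- substring(nt, seq(1, nchar(nt), by = 3),
                        seq(3, max(nchar(nt), 3), by = 3))
    cells <- rep("---", length(aa))
    cells[aa != "-"] <- codons
    out[i] <- paste(cells, collapse = "")
  }
  alignment(protein_aln$ids, out, "nt")
}

# standard genetic code with STOP mapped to 'x' (unknown residue);
# codons containing N (or any non-ACGT base) also give 'x'
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  gc[gc == "*"] <- "x"
  gc
})

#' Translate a codon-phased nucleotide sequence
#'
#' Standard genetic code; STOP codons are translated to `x` (unknown
#' residue), never truncating the sequence.  Gaps must come in whole-codon
#' `---` triplets, each becoming a single `-`.
#'
#' @param nt_seq a single nucleotide sequence, possibly gapped.
#' @return The amino-acid translation (length `nchar(nt_seq) / 3`).
#' @export
translate_cds <- function(nt_seq) {
  stopifnot(length(nt_seq) == 1L)
  n <- nchar(nt_seq)
  if (n == 0L) return("")
  if (n %% 3L != 0L)
    stop("codon-phase error: sequence length ", n, " not divisible by 3")
  codons <- toupper(substring(nt_seq, seq(1, n, by = 3), seq(3, n, by = 3)))
  has_gap <- grepl("-", codons, fixed = TRUE)
  if (any(has_gap & codons != "---"))
    stop("codon-phase error: gap not aligned to a codon boundary")
  aa <- character(length(codons))
  aa[has_gap] <- "-"
  if (any(!has_gap)) {
    tr <- unname(.codon_table[codons[!has_gap]])
    tr[is.na(tr)] <- "x"
    aa[!has_gap] <- tr
  }
  paste(aa, collapse = "")
}

#' Translate a codon-phased nucleotide alignment
#'
#' @param nt_aln a nucleotide [alignment()] with whole-codon gaps.
#' @return An amino-acid [alignment()] with `n_cols / 3` columns.
#' @export
translate_alignment <- function(nt_aln) {
  stopifnot(inherits(nt_aln, "alignment"), nt_aln$alphabet == "nt")
  alignment(nt_aln$ids, vapply(nt_aln$seqs, translate_cds, character(1)), "aa")
}
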