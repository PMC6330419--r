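#' Evaluate an expression under a local RNG seed
#'
#' Seeds the RNG, evaluates `expr`, and restores the previous global RNG
#' state, so seeded simulator calls never disturb the caller's random
#' stream.  A `NULL` seed evaluates `expr` unseeded.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

.sense_codons <- names(.codon_table)[.codon_table != "x"]

#' Specification of one simulated primary sequence error
#'
#' @param error_type `"frameshift"` (a single-nucleotide indel followed by
#'   the compensatory opposite indel after `length_codons` out-of-frame
#'   codons), `"scramble"` (uniform shuffle of the nucleotides of a
#'   `length_codons`-codon window), or `"insertion"` (insertion of a
#'   shuffled copy of a random same-length window of the same sequence).
#' @param seq_id sequence to affect.
#' @param length_codons error length in codons (= amino acids); at least 1.
#' @param anchor 1-based codon index at which the error starts, or
#'   `"random"` to draw it uniformly among positions that keep the window
#'   clear of the first and last codon.
#' @param seed integer seed driving all randomness for this error.
#' @return An object of class `error_spec`.
#' @export
error_spec <- function(error_type = c("frameshift", "scramble", "insertion"),
                       seq_id, length_codons, anchor = "random", seed = NULL) {
  error_type <- match.arg(error_type)
  length_codons <- as.integer(length_codons)
  if (is.na(length_codons) || length_codons < 1L)
    stop("length_codons must be a positive integer")
  structure(list(error_type = error_type, seq_id = seq_id,
                 length_codons = length_codons, anchor = anchor, seed = seed),
            class = "error_spec")
}

#' Introduce one primary sequence error into a codon alignment
#'
#' The error is applied to the ungapped CDS of the target sequence, so
#' the returned sequences are unaligned (gap-free).  Frameshifts conserve
#' total length (one nucleotide deleted and one inserted, or vice versa,
#' with the direction drawn at random); scrambles permute the window's
#' nucleotides; insertions lengthen the CDS by `3 * length_codons`.
#'
#' @param nt_aln a codon-phased nucleotide [alignment()], or a named
#'   character vector of ungapped coding sequences.
#' @param spec an [error_spec()].
#' @return List with `cds` (named character vector of ungapped, possibly
#'   modified coding sequences) and `truth` (one-row data frame:
#'   `seq_id`, `error_type`, `length_aa`, `anchor`, `start_res`,
#'   `end_res` — the affected residue span in the post-error protein).
#' @export
introduce_error <- function(nt_aln, spec) {
  stopifnot(inherits(spec, "error_spec"))
  cds <- if (inherits(nt_aln, "alignment")) {
    stopifnot(nt_aln$alphabet == "nt")
    degap(nt_aln)
  } else {
    stopifnot(is.character(nt_aln), !is.null(names(nt_aln)))
    nt_aln
  }
  i <- match(spec$seq_id, names(cds))
  if (is.na(i)) stop("unknown seq_id: ", spec$seq_id)
  s <- cds[[i]]
  n_codons <- nchar(s) %/% 3L
  L <- spec$length_codons
  with_seed(spec$seed, {
    a <- spec$anchor
    if (identical(a, "random")) {
      hi <- if (spec$error_type == "insertion") n_codons else n_codons - L
      if (hi < 2L) stop("placement error: sequence too short for the window")
      a <- if (hi == 2L) 2L else sample(2:hi, 1L)
    }
    a <- as.integer(a)
    if (spec$error_type != "insertion" &&
        (a < 1L || a + L - 1L > n_codons))
      stop("placement error: window outside the coding sequence")
    nt <- strsplit(s, "", fixed = TRUE)[[1]]
    p <- 3L * (a - 1L) + 1L            # first nt of the anchor codon
    q <- 3L * (a + L - 1L)             # last nt of the window
    if (spec$error_type == "frameshift") {
      x <- sample(c("A", "C", "G", "T"), 1L)
      del_first <- sample(c(TRUE, FALSE), 1L)
      nt <- if (del_first) {
        # delete at the window start, re-insert after L out-of-frame codons
        c(nt[seq_len(p - 1L)], nt[(p + 1L):q], x,
          if (q < length(nt)) nt[(q + 1L):length(nt)])
      } else {
        # insert at the window start, delete the window's last nucleotide
        c(nt[seq_len(p - 1L)], x, nt[p:(q - 1L)],
          if (q < length(nt)) nt[(q + 1L):length(nt)])
      }
    } else if (spec$error_type == "scramble") {
      nt[p:q] <- sample(nt[p:q])
    } else {
      src_a <- sample(seq_len(n_codons - L + 1L), 1L)
      src <- nt[(3L * (src_a - 1L) + 1L):(3L * (src_a + L - 1L))]
      nt <- c(nt[seq_len(p - 1L)], sample(src),
              if (p <= length(nt)) nt[p:length(nt)])
    }
    cds[[i]] <- paste(nt, collapse = "")
    list(cds = cds,
         truth = data.frame(seq_id = spec$seq_id,
                            error_type = spec$error_type,
                            length_aa = L, anchor = a,
                            start_res = a, end_res = a + L - 1L))
  })
}

#' Build an error-injected, translated, realigned protein MSA
#'
#' Applies at most one [error_spec()] per sequence to the ungapped coding
#' sequences, translates everything (STOP codons to `x`), realigns the
#' proteins, and lifts the true error spans into alignment-column
#' coordinates (realignment moves gaps, never residues, so residue
#' indices survive unchanged).
#'
#' @param nt_aln a codon-phased nucleotide [alignment()].
#' @param specs list of [error_spec()] (at most one per sequence).
#' @param aligner `"internal"` — reuse the source alignment's gap pattern,
#'   opening new all-gap columns for inserted segments (exact for
#'   length-conserving errors, deterministic, no external binary) — or
#'   `"mafft"` to realign with MAFFT L-INS-i.
#' @return List with `alignment` (amino-acid [alignment()]) and `truth`
#'   (data frame: one row per error with `start_res`/`end_res` and their
#'   alignment columns `start_col`/`end_col`).
#' @export
build_erroneous_msa <- function(nt_aln, specs = list(),
                                aligner = c("internal", "mafft")) {
  aligner <- match.arg(aligner)
  stopifnot(inherits(nt_aln, "alignment"), nt_aln$alphabet == "nt")
  ids <- vapply(specs, `[[`, character(1), "seq_id")
  if (anyDuplicated(ids)) stop("at most one error per sequence")
  cds <- degap(nt_aln)
  truth <- NULL
  for (sp in specs) {
    res <- introduce_error(cds, sp)
    cds <- res$cds
    truth <- rbind(truth, res$truth)
  }
  aa <- vapply(cds, translate_cds, character(1))
  aa_aln <- if (aligner == "mafft") {
    mafft_align(aa)
  } else {
    .internal_realign(nt_aln, aa, truth)
  }
  if (!is.null(truth)) {
    cmap <- coord_map(aa_aln)
    truth$start_col <- mapply(function(id, k) cmap[[id]][k],
                              truth$seq_id, truth$start_res)
    truth$end_col <- mapply(function(id, k) cmap[[id]][k],
                            truth$seq_id, truth$end_res)
  } else {
    truth <- data.frame(seq_id = character(0), error_type = character(0),
                        length_aa = integer(0), anchor = integer(0),
                        start_res = integer(0), end_res = integer(0),
                        start_col = integer(0), end_col = integer(0))
  }
  list(alignment = aa_aln, truth = truth)
}

# Deterministic fallback "aligner": reuse the source alignment's protein
# gap pattern (valid because frameshift and scramble errors conserve
# residue counts); for insertion errors, open a block of new columns at
# the insertion point, gapped in every other sequence.
.internal_realign <- function(nt_aln, aa_ungapped, truth) {
  prot <- translate_alignment(nt_aln)   # original gap pattern
  rows <- lapply(seq_along(prot$ids), function(i) {
    ch <- strsplit(prot$seqs[i], "", fixed = TRUE)[[1]]
    ch   # cells; residues will be re-filled from the erroneous proteins
  })
  names(rows) <- prot$ids
  # insertions (if any) add columns; process left-to-right per sequence
  if (!is.null(truth)) {
    ins <- truth[truth$error_type == "insertion", , drop = FALSE]
    cmap <- coord_map(prot)
    if (nrow(ins) > 0) {
      # column after which each block goes: column of original residue a-1;
      # process right-to-left so earlier columns stay valid
      ins$at <- vapply(seq_len(nrow(ins)), function(j) {
        a <- ins$anchor[j]
        if (a <= 1L) 0L else cmap[[ins$seq_id[j]]][a - 1L]
      }, integer(1))
      ins <- ins[order(-ins$at), , drop = FALSE]
      for (j in seq_len(nrow(ins))) {
        id <- ins$seq_id[j]
        L <- ins$length_aa[j]
        at <- ins$at[j]
        for (k in seq_along(rows)) {
          fill <- rep("-", L)
          rows[[k]] <- append(rows[[k]], fill, after = at)
        }
        # mark the inserted cells of the affected row as residue slots
        rows[[id]][(at + 1L):(at + L)] <- "?"
      }
    }
  }
  seqs <- vapply(seq_along(rows), function(i) {
    ch <- rows[[i]]
    res <- strsplit(aa_ungapped[[i]], "", fixed = TRUE)[[1]]
    slot <- ch != "-"
    if (sum(slot) != length(res))
      stop("internal aligner: residue count mismatch for ", names(rows)[i])
    ch[slot] <- res
    paste(ch, collapse = "")
  }, character(1))
  alignment(prot$ids, seqs, "aa")
}

#' Align protein sequences with MAFFT (L-INS-i)
#'
#' @param aa named character vector of ungapped protein sequences.
#' @param maxiterate iterative refinement cycles.
#' @return An amino-acid [alignment()].
#' @export
mafft_align <- function(aa, maxiterate = 5000) {
  if (Sys.which("mafft") == "")
    stop("dependency error: 'mafft' not found on PATH; use aligner = \"internal\"")
  inp <- tempfile(fileext = ".fasta"); out <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(inp, out)), add = TRUE)
  Biostrings::writeXStringSet(Biostrings::BStringSet(aa), inp, width = 60L)
  st <- system2("mafft", c("--localpair", "--maxiterate", maxiterate,
                           "--anysymbol", "--quiet", inp),
                stdout = out, stderr = FALSE)
  if (st != 0L) stop("engine error: mafft exited with status ", st)
  res <- read_fasta(out, "aa")
  ord <- match(names(aa), res$ids)   # restore input order
  if (anyNA(ord)) stop("engine error: mafft dropped sequences")
  alignment(res$ids[ord], res$seqs[ord], "aa")
}

#' Generate a synthetic codon alignment on a star tree
#'
#' A random root CDS of `n_codons` sense codons evolves independently
#' along `n_seqs` branches: every nucleotide is substituted with
#' probability `divergence` (uniformly to one of the three other bases),
#' and each codon is independently deleted or duplicated-by-insertion
#' with probability `indel_rate / 2` each.  Insertions open sequence-
#' specific columns, so the returned codon alignment is exact by
#' construction.  Substitutions may create in-frame STOP codons; these
#' are kept (they translate to `x`).
#'
#' @param n_seqs number of sequences (at least 2).
#' @param n_codons root CDS length in codons.
#' @param divergence per-branch per-nucleotide substitution probability.
#' @param indel_rate per-branch per-codon indel probability (half
#'   deletions, half single-codon insertions).
#' @param seed integer seed; identical seeds give identical alignments.
#' @return A codon-phased nucleotide [alignment()] with ids
#'   `"seq01"`, `"seq02"`, ...
#' @export
generate_fixture_msa <- function(n_seqs = 25, n_codons = 200,
                                 divergence = 0.05, indel_rate = 0.01,
                                 seed = NULL) {
  stopifnot(n_seqs >= 2, n_codons >= 2,
            divergence >= 0, divergence <= 1, indel_rate >= 0, indel_rate <= 1)
  with_seed(seed, {
    root <- sample(.sense_codons, n_codons, replace = TRUE)
    root_nt <- strsplit(paste(root, collapse = ""), "", fixed = TRUE)[[1]]
    bases <- c("A", "C", "G", "T")
    body <- matrix("", nrow = n_seqs, ncol = n_codons)  # codon cells
    inserts <- vector("list", n_seqs)  # per junction 0..n_codons: codon or ""
    for (i in seq_len(n_seqs)) {
      nt <- root_nt
      mut <- runif(length(nt)) < divergence
      if (any(mut))
        nt[mut] <- vapply(nt[mut],
                          function(b) sample(setdiff(bases, b), 1L),
                          character(1))
      cod <- vapply(seq_len(n_codons),
                    function(k) paste(nt[(3 * k - 2):(3 * k)], collapse = ""),
                    character(1))
      u <- runif(n_codons)
      cod[u < indel_rate / 2] <- "---"
      ins <- rep("", n_codons + 1L)
      dup <- which(u >= indel_rate / 2 & u < indel_rate)
      ins[dup + 1L] <- cod[dup]      # duplicate the codon after itself
      body[i, ] <- cod
      inserts[[i]] <- ins
    }
    # assemble: at each junction j (0..n_codons) add one column block per
    # sequence that inserts there, gapped everywhere else
    pieces <- vector("list", n_seqs)
    for (i in seq_len(n_seqs)) pieces[[i]] <- character(0)
    for (j in 0:n_codons) {
      who <- which(vapply(inserts, function(x) nzchar(x[j + 1L]), logical(1)))
      for (w in who) {
        for (i in seq_len(n_seqs))
          pieces[[i]] <- c(pieces[[i]],
                           if (i == w) inserts[[w]][j + 1L] else "---")
      }
      if (j < n_codons)
        for (i in seq_len(n_seqs))
          pieces[[i]] <- c(pieces[[i]], body[i, j + 1L])
    }
    alignment(sprintf("seq%02d", seq_len(n_seqs)),
              vapply(pieces, paste, character(1), collapse = ""), "nt")
  })
}
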