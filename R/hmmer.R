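#' Annotate sequences with an external HMMER engine
#'
#' Fidelity path for [annotate_alignment()]: builds the profile with
#' `hmmbuild --fragthresh 0 --plaplace` (equal sequence weights, Laplace
#' +1 prior) and scores each ungapped sequence with `hmmsearch` under
#' default options, then parses the per-domain alignment display into the
#' four categories: the match line's uppercase letters become `U`,
#' lowercase `L`, `+` becomes `P` and spaces `B`.  Residues outside every
#' reported envelope are `B`; where envelopes overlap, a non-`B` symbol
#' from the higher-scoring envelope wins.  A sequence with no reported
#' hit is annotated all-`B` with a warning.
#'
#' @param aln an amino-acid [alignment()].
#' @param spec a [profile_spec()]; `spec$strategy` selects complete vs
#'   leave-one-out profile construction.
#' @param workdir scratch directory for profile and report files.
#' @return Named list of annotation strings, as [annotate_alignment()].
#' @export
hmmer_annotate <- function(aln, spec = profile_spec(engine = "hmmer"),
                           workdir = tempfile("hmmer")) {
  for (exe in c("hmmbuild", "hmmsearch"))
    if (Sys.which(exe) == "")
      stop("dependency error: '", exe, "' not found on PATH; install ",
           "HMMER or use profile_spec(engine = \"internal\")")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  # hmmsearch queries use safe numeric names to sidestep id parsing issues
  safe_ids <- sprintf("seq%05d", seq_along(aln$ids))
  ungapped <- setNames(degap(aln), safe_ids)

  build_profile <- function(sub_aln, tag) {
    msa_path <- file.path(workdir, paste0("msa_", tag, ".fasta"))
    hmm_path <- file.path(workdir, paste0("profile_", tag, ".hmm"))
    write_fasta(sub_aln, msa_path)
    st <- system2("hmmbuild",
                  c("--amino", "--fragthresh", "0", "--plaplace",
                    hmm_path, msa_path),
                  stdout = FALSE, stderr = FALSE)
    if (st != 0L) stop("engine error: hmmbuild exited with status ", st)
    hmm_path
  }

  search <- function(hmm_path, ids_subset) {
    seq_path <- file.path(workdir, "query.fasta")
    out_path <- file.path(workdir, "search.txt")
    x <- Biostrings::BStringSet(ungapped[ids_subset])
    Biostrings::writeXStringSet(x, seq_path, width = 60L)
    st <- system2("hmmsearch", c("--notextw", "-o", out_path,
                                 hmm_path, seq_path),
                  stdout = FALSE, stderr = FALSE)
    if (st != 0L) stop("engine error: hmmsearch exited with status ", st)
    .parse_hmmsearch(readLines(out_path))
  }

  n <- length(aln$ids)
  out <- vector("list", n)
  if (spec$strategy == "complete") {
    aln_safe <- alignment(safe_ids, aln$seqs, "aa")
    hits <- search(build_profile(aln_safe, "all"), safe_ids)
    for (i in seq_len(n))
      out[[i]] <- .domains_to_annotation(hits[[safe_ids[i]]],
                                         nchar(ungapped[[i]]), aln$ids[i])
  } else {
    for (i in seq_len(n)) {
      sub <- alignment(safe_ids[-i], aln$seqs[-i], "aa")
      hits <- search(build_profile(sub, sprintf("loo%05d", i)), safe_ids[i])
      out[[i]] <- .domains_to_annotation(hits[[safe_ids[i]]],
                                         nchar(ungapped[[i]]), aln$ids[i])
    }
  }
  setNames(out, aln$ids)
}

# Parse an hmmsearch plain-text report into, per query sequence, a list of
# domains: list(score, start, symbols) with start the 1-based residue
# index of the first envelope residue and symbols one category per
# envelope residue.  Relies on the fixed layout of the per-domain
# alignment display: a consensus line, the match line, the target line
# (name, start, sequence, end) and a posterior-probability line.
.parse_hmmsearch <- function(lines) {
  hits <- list()
  cur_seq <- NULL
  cur_score <- NA_real_
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^>> ", ln)) {
      cur_seq <- sub("^>> +(\\S+).*$", "\\1", ln)
      if (is.null(hits[[cur_seq]])) hits[[cur_seq]] <- list()
    } else if (grepl("^ +== domain", ln)) {
      cur_score <- as.numeric(sub("^.*score: +([-0-9.]+) bits.*$", "\\1", ln))
      # locate the target line: first subsequent line whose first token is
      # the current sequence name
      j <- i + 1L
      target_j <- NA_integer_
      while (j <= length(lines) && nzchar(trimws(lines[j]))) {
        tok <- strsplit(trimws(lines[j]), " +")[[1]]
        if (length(tok) >= 4 && tok[1] == cur_seq) { target_j <- j; break }
        j <- j + 1L
      }
      if (!is.na(target_j)) {
        tline <- lines[target_j]
        mline <- lines[target_j - 1L]
        m <- regmatches(tline,
                        regexec("^ *(\\S+) +(\\d+) +(\\S+) +(\\d+) *$", tline))[[1]]
        seq_txt <- m[4]
        start <- as.integer(m[3])
        # string column where the aligned sequence text begins
        off <- regexpr(seq_txt, tline, fixed = TRUE)
        mpad <- paste0(mline, strrep(" ", max(0, off + nchar(seq_txt) - 1 -
                                                nchar(mline))))
        mchars <- strsplit(substr(mpad, off, off + nchar(seq_txt) - 1),
                           "")[[1]]
        tchars <- strsplit(seq_txt, "")[[1]]
        keep <- !(tchars %in% c("-", "."))   # columns that consume a residue
        sym <- vapply(mchars[keep], function(ch) {
          if (ch == "+") "P"
          else if (grepl("^[A-Z]$", ch)) "U"
          else if (grepl("^[a-z]$", ch)) "L"
          else "B"
        }, character(1))
        hits[[cur_seq]][[length(hits[[cur_seq]]) + 1L]] <-
          list(score = cur_score, start = start,
               symbols = paste(sym, collapse = ""))
        i <- target_j + 1L
      }
    }
    i <- i + 1L
  }
  hits
}

# Overlay domain annotations onto an all-'B' backbone; envelopes applied
# in increasing score order so a non-'B' symbol from the highest-scoring
# overlapping envelope ends up on top.
.domains_to_annotation <- function(domains, n_res, seq_id) {
  sym <- rep("B", n_res)
  if (is.null(domains) || length(domains) == 0L) {
    warning("no envelope reported for sequence '", seq_id,
            "'; annotated all-B")
    return(paste(sym, collapse = ""))
  }
  ord <- order(vapply(domains, `[[`, numeric(1), "score"))
  for (d in domains[ord]) {
    s <- strsplit(d$symbols, "")[[1]]
    idx <- d$start + seq_along(s) - 1L
    ok <- idx >= 1 & idx <= n_res
    put <- ok & s != "B"
    sym[idx[put]] <- s[put]
  }
  paste(sym, collapse = "")
}
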