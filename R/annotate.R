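AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Robinson & Robinson (1991) amino-acid background frequencies, the
# standard null composition used by profile-HMM software; normalized to
# sum exactly to 1.
.robinson_freqs <- local({
  f <- c(A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
         G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
         M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
         S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)
  (f / sum(f))[AA20]
})

#' Amino-acid background frequencies
#'
#' @param which `"robinson"` for the Robinson & Robinson (1991)
#'   composition (the default null model of profile-HMM software) or
#'   `"uniform"` for 1/20.
#' @return Named numeric vector over the 20 standard amino acids, summing
#'   to 1.
#' @export
background_freqs <- function(which = c("robinson", "uniform")) {
  which <- match.arg(which)
  if (which == "uniform") setNames(rep(1 / 20, 20), AA20) else .robinson_freqs
}

#' Profile construction and annotation settings
#'
#' Controls how the profile is built from the MSA and how sequences are
#' annotated against it.  Under the `complete` strategy one profile is
#' built from all sequences; under `leave_one_out` the profile for
#' sequence *i* is built from all sequences except *i*.  The internal
#' engine is a deterministic reference implementation of the four-category
#' annotation; the `hmmer` engine shells out to `hmmbuild`/`hmmsearch`.
#'
#' @param strategy `"complete"` or `"leave_one_out"`.
#' @param engine `"internal"` or `"hmmer"`.
#' @param match_gap_threshold columns whose gap fraction is at most this
#'   value are treated as profile match columns by the internal engine;
#'   residues in other (insert) columns are annotated `B`.
#' @param background `"robinson"` or `"uniform"` background composition
#'   for the internal engine's log-odds test.
#' @return An object of class `profile_spec`.
#' @export
profile_spec <- function(strategy = c("complete", "leave_one_out"),
                         engine = c("internal", "hmmer"),
                         match_gap_threshold = 0.5,
                         background = c("robinson", "uniform")) {
  strategy <- match.arg(strategy)
  engine <- match.arg(engine)
  stopifnot(is.numeric(match_gap_threshold),
            match_gap_threshold >= 0, match_gap_threshold <= 1)
  structure(
    list(strategy = strategy, engine = engine,
         match_gap_threshold = match_gap_threshold,
         background = match.arg(background)),
    class = "profile_spec"
  )
}

#' Annotate every sequence of an MSA with four match categories
#'
#' Each ungapped residue of each sequence receives one symbol:
#' \describe{
#'   \item{`U`}{residue equals the profile consensus and the consensus
#'     emission probability exceeds 50\%;}
#'   \item{`L`}{residue equals the consensus, emission probability at most
#'     50\%;}
#'   \item{`P`}{residue differs from the consensus but its emission
#'     probability beats the background (positive log-odds): a
#'     conservative substitution;}
#'   \item{`B`}{blank — negative log-odds, an unknown residue, an insert
#'     column, or a stretch not covered by any search envelope.}
#' }
#'
#' @param aln an amino-acid [alignment()] with at least 2 sequences.
#' @param spec a [profile_spec()].
#' @return Named list (one element per sequence, in alignment order) of
#'   single-character-per-residue annotation strings over `{B,P,L,U}`;
#'   `nchar()` of each equals the residue count of that sequence.
#' @examples
#' aln <- alignment(paste0("s", 1:5), rep("MKLV", 5), "aa")
#' annotate_alignment(aln, profile_spec())
#' @export
annotate_alignment <- function(aln, spec = profile_spec()) {
  stopifnot(inherits(aln, "alignment"))
  if (aln$alphabet != "aa") stop("annotation requires an amino-acid alignment")
  if (length(aln$ids) < 2L) stop("at least 2 sequences are required")
  if (spec$engine == "hmmer") return(hmmer_annotate(aln, spec))
  ann <- vapply(seq_along(aln$ids),
                function(i) internal_engine_annotate(aln, spec, i),
                character(1))
  setNames(as.list(ann), aln$ids)
}

# per-column residue counts over the 20 amino acids (20 x n_cols),
# plus non-gap observation counts; M is the uppercase character matrix
.column_counts <- function(M) {
  counts <- matrix(0L, nrow = 20, ncol = ncol(M),
                   dimnames = list(AA20, NULL))
  for (a in AA20) counts[a, ] <- colSums(M == a)
  list(counts = counts, n_obs = colSums(M != "-"))
}

#' Internal reference annotation engine
#'
#' Deterministic approximation of the display categories of a profile-HMM
#' search, computed directly from column statistics.  Match columns are
#' the alignment columns whose gap fraction (over the profile-building
#' set) is at most `spec$match_gap_threshold`.  Within a match column,
#' emission probabilities use unweighted counts under a Laplace +1 prior,
#' `e(r) = (count(r) + 1) / (n_obs + 20)`; the consensus is the residue
#' maximizing `e` (alphabetic tie-break).  A residue equal to the
#' consensus is `U` if `e > 0.5`, else `L`; otherwise `P` if
#' `log(e(r)/f(r)) > 0` against the background composition `f`, else `B`.
#' Unknown residues (`X`) and residues in insert columns are `B`.
#'
#' @param aln an amino-acid [alignment()].
#' @param spec a [profile_spec()]; `spec$strategy` decides whether the
#'   profile-building set includes sequence `seq_index`.
#' @param seq_index index of the sequence to annotate.
#' @return Annotation string over `{B,P,L,U}` for that sequence.
#' @export
internal_engine_annotate <- function(aln, spec, seq_index) {
  M <- toupper(aln_matrix(aln))
  row <- M[seq_index, ]
  cc <- .column_counts(M)
  counts <- cc$counts
  n_obs <- cc$n_obs
  n_profile_seqs <- nrow(M)
  if (spec$strategy == "leave_one_out") {
    own <- match(row, AA20)                 # NA for gaps and X
    keep <- !is.na(own)
    counts[cbind(own[keep], which(keep))] <-
      counts[cbind(own[keep], which(keep))] - 1L
    n_obs <- n_obs - as.integer(row != "-")
    n_profile_seqs <- n_profile_seqs - 1L
  }
  gap_frac <- 1 - n_obs / n_profile_seqs
  is_match_col <- gap_frac <= spec$match_gap_threshold
  emis <- sweep(counts + 1, 2, n_obs + 20, "/")      # 20 x n_cols
  cons_idx <- apply(emis, 2, which.max)              # ties: lowest index
  cons <- AA20[cons_idx]
  e_cons <- emis[cbind(cons_idx, seq_len(ncol(M)))]
  f <- background_freqs(spec$background)

  res_cols <- which(row != "-")
  sym <- rep("B", length(res_cols))
  r <- row[res_cols]
  known <- r %in% AA20
  mc <- is_match_col[res_cols]
  is_cons <- known & mc & r == cons[res_cols]
  sym[is_cons] <- ifelse(e_cons[res_cols[is_cons]] > 0.5, "U", "L")
  other <- known & mc & !is_cons
  if (any(other)) {
    e_r <- emis[cbind(match(r[other], AA20), res_cols[other])]
    sym[other] <- ifelse(log(e_r / f[r[other]]) > 0, "P", "B")
  }
  paste(sym, collapse = "")
}
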