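#' Four-parameter scoring matrix for the similarity trace
#'
#' The cumulative similarity score moves by one of four elemental scores
#' per residue, keyed by the residue's match category: `c1` for a blank
#' mismatch (`B`), `c2` for a conservative substitution (`P`), `c3` for a
#' low-probability consensus match (`L`) and `c4` for a high-probability
#' consensus match (`U`).  Mismatch scores must be negative and match
#' scores positive.
#'
#' @param c1,c2 negative scores for categories `B` and `P`.
#' @param c3,c4 positive scores for categories `L` and `U`.
#' @return An object of class `scoring_matrix` (named numeric vector).
#' @seealso [matrix_preset()] for the standard presets.
#' @export
scoring_matrix <- function(c1, c2, c3, c4) {
  vals <- c(c1 = c1, c2 = c2, c3 = c3, c4 = c4)
  stopifnot(is.numeric(vals), length(vals) == 4, !anyNA(vals))
  if (!(c1 < 0 && c2 < 0)) stop("c1 and c2 must be negative")
  if (!(c3 > 0 && c4 > 0)) stop("c3 and c4 must be positive")
  structure(vals, class = "scoring_matrix")
}

.presets <- list(
  default                          = c(-0.150, -0.080, 0.150, 0.450),
  species_rich                     = c(-0.175, -0.175, 0.150, 0.400),
  high_specificity                 = c(-0.125, -0.125, 0.175, 0.400),
  species_rich_high_specificity    = c(-0.125, -0.125, 0.150, 0.400),
  v1_8                             = c(-0.300, -0.100, 0.200, 0.500)
)

#' Standard scoring-matrix presets
#'
#' The five standard parameter sets: `default` (optimized across all
#' simulation conditions), `species_rich` (optimized on 50-sequence
#' MSAs), `high_specificity`, `species_rich_high_specificity`, and
#' `v1_8` (the empirically chosen parameters of the earlier tool
#' version).
#'
#' @param name preset name; hyphens and dots are accepted in place of
#'   underscores (e.g. `"species-rich"`, `"v1.8"`).
#' @return A [scoring_matrix()].
#' @examples
#' matrix_preset("default")
#' @export
matrix_preset <- function(name = c("default", "species_rich",
                                   "high_specificity",
                                   "species_rich_high_specificity", "v1_8")) {
  name <- gsub("[-.]", "_", name[1])
  name <- match.arg(name)
  do.call(scoring_matrix, as.list(.presets[[name]]))
}

#' Cumulative similarity trace of an annotated sequence
#'
#' Starting from a maximal score of 1 (perfect fit to the profile), each
#' residue adds its category's elemental score and the running total is
#' clamped to \[0, 1\].  The trace therefore rises where the profile
#' expects the residue and falls where it does not, staying between 0 and
#' 1 inclusive.
#'
#' @param ann annotation string over `{B,P,L,U}` (one element of
#'   [annotate_alignment()]'s result).
#' @param m a [scoring_matrix()].
#' @return Numeric vector of per-residue scores, same length as the
#'   annotation.
#' @examples
#' similarity_trace("UUBBBPLU", matrix_preset("default"))
#' @export
similarity_trace <- function(ann, m = matrix_preset("default")) {
  stopifnot(is.character(ann), length(ann) == 1L)
  if (nchar(ann) == 0L) stop("empty annotation")
  sym <- strsplit(ann, "", fixed = TRUE)[[1]]
  idx <- match(sym, c("B", "P", "L", "U"))
  if (anyNA(idx)) stop("annotation contains symbols outside {B,P,L,U}")
  trace_accumulate(unclass(m)[idx])
}

#' Detect low-similarity segments in a similarity trace
#'
#' A low-similarity segment is a maximal run of positions with score
#' below 1 containing at least one null (zero) score.  Its start is the
#' position after the last score of 1 (or position 1 if the trace never
#' was at 1 before the run); its end is the last null position of the
#' run, except that a run reaching the end of the sequence without
#' returning to 1 ends the segment at the final position.
#'
#' @param trace numeric score vector from [similarity_trace()].
#' @param rule `"last_zero"` implements the boundary rule above (the
#'   default); `"full_run"` extends every detected segment to the whole
#'   sub-1 run, an alternative reading kept for experimentation.
#' @return Data frame with columns `start_res`, `end_res` (1-based
#'   inclusive ungapped residue indices), zero rows when no segment.
#' @export
detect_segments <- function(trace, rule = c("last_zero", "full_run")) {
  rule <- match.arg(rule)
  n <- length(trace)
  below <- trace < 1
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out_s <- integer(0)
  out_e <- integer(0)
  for (k in which(r$values)) {
    run <- starts[k]:ends[k]
    zeros <- run[trace[run] == 0]
    if (length(zeros) == 0L) next
    s <- starts[k]                 # position after the last 1, or 1
    e <- if (rule == "full_run" || ends[k] == n) ends[k] else max(zeros)
    out_s <- c(out_s, s)
    out_e <- c(out_e, e)
  }
  data.frame(start_res = out_s, end_res = out_e)
}

# detected segments for every sequence of an annotated alignment, with
# alignment-column footprints attached
.segments_for_alignment <- function(aln, anns, m, rule = "last_zero") {
  cmap <- coord_map(aln)
  segs <- lapply(seq_along(aln$ids), function(i) {
    d <- detect_segments(similarity_trace(anns[[i]], m), rule = rule)
    if (nrow(d) == 0L) return(NULL)
    d$seq_id <- aln$ids[i]
    d$start_col <- cmap[[i]][d$start_res]
    d$end_col <- cmap[[i]][d$end_res]
    d
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs))
    segs <- data.frame(start_res = integer(0), end_res = integer(0),
                       seq_id = character(0), start_col = integer(0),
                       end_col = integer(0))
  segs$length <- segs$end_res - segs$start_res + 1L
  segs[c("seq_id", "start_res", "end_res", "start_col", "end_col", "length")]
}

#' Detect and mask low-similarity segments in a protein alignment
#'
#' Runs the full pipeline — profile annotation, similarity trace, segment
#' detection — and replaces every residue inside a detected segment with
#' `mask_char` in that sequence only.  Columns are never deleted, so the
#' alignment geometry is preserved.
#'
#' @param aln an amino-acid [alignment()].
#' @param spec a [profile_spec()].
#' @param m a [scoring_matrix()].
#' @param mask_char single character used to mask removed residues;
#'   default the gap character `"-"` (use e.g. `"X"` for visible masking).
#' @param rule segment boundary rule, see [detect_segments()].
#' @return List with elements `alignment` (the masked [alignment()]) and
#'   `segments` (data frame: `seq_id`, `start_res`, `end_res`,
#'   `start_col`, `end_col`, `length`; 1-based inclusive).
#' @examples
#' aln <- alignment(paste0("s", 1:5), rep("MKLVNPQRST", 5), "aa")
#' clean(aln)$segments   # identical sequences: nothing to remove
#' @export
clean <- function(aln, spec = profile_spec(), m = matrix_preset("default"),
                  mask_char = "-", rule = "last_zero") {
  stopifnot(inherits(aln, "alignment"), aln$alphabet == "aa",
            nchar(mask_char) == 1L)
  anns <- annotate_alignment(aln, spec)
  segs <- .segments_for_alignment(aln, anns, m, rule = rule)
  cmap <- coord_map(aln)
  seqs <- strsplit(aln$seqs, "", fixed = TRUE)
  if (nrow(segs) > 0) {
    for (j in seq_len(nrow(segs))) {
      i <- match(segs$seq_id[j], aln$ids)
      cols <- cmap[[i]][segs$start_res[j]:segs$end_res[j]]
      seqs[[i]][cols] <- mask_char
    }
  }
  list(alignment = alignment(aln$ids,
                             vapply(seqs, paste, character(1), collapse = ""),
                             "aa"),
       segments = segs)
}

#' Clean a codon-phased nucleotide alignment
#'
#' Low-similarity segments are detected on the translated protein
#' alignment and reported back onto the nucleotide alignment: each masked
#' residue masks its whole codon.
#'
#' @param nt_aln a codon-phased nucleotide [alignment()].
#' @inheritParams clean
#' @return List with `alignment` (masked nucleotide alignment),
#'   `segments` (protein-level segment table as in [clean()], with
#'   nucleotide column footprint columns `start_col_nt`, `end_col_nt`)
#'   and `aa_alignment` (the masked protein alignment).
#' @export
clean_nt <- function(nt_aln, spec = profile_spec(),
                     m = matrix_preset("default"), mask_char = "-",
                     rule = "last_zero") {
  stopifnot(inherits(nt_aln, "alignment"), nt_aln$alphabet == "nt")
  aa <- translate_alignment(nt_aln)
  res <- clean(aa, spec, m, mask_char = mask_char, rule = rule)
  segs <- res$segments
  cmap_nt <- coord_map(nt_aln)
  seqs <- strsplit(nt_aln$seqs, "", fixed = TRUE)
  segs$start_col_nt <- rep(NA_integer_, nrow(segs))
  segs$end_col_nt <- rep(NA_integer_, nrow(segs))
  if (nrow(segs) > 0) {
    nt_mask <- if (mask_char == "-") "-" else mask_char
    for (j in seq_len(nrow(segs))) {
      i <- match(segs$seq_id[j], nt_aln$ids)
      # residue k occupies ungapped CDS positions 3(k-1)+1 .. 3k
      nt_res <- as.vector(vapply(segs$start_res[j]:segs$end_res[j],
                                 function(k) (3L * (k - 1L) + 1L):(3L * k),
                                 integer(3)))
      cols <- cmap_nt[[i]][nt_res]
      seqs[[i]][cols] <- nt_mask
      segs$start_col_nt[j] <- min(cols)
      segs$end_col_nt[j] <- max(cols)
    }
  }
  list(alignment = alignment(nt_aln$ids,
                             vapply(seqs, paste, character(1), collapse = ""),
                             "nt"),
       segments = segs,
       aa_alignment = res$alignment)
}
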