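#' Residue-level confusion counts of a filter against simulated truth
#'
#' Every ungapped residue of every sequence is one assessment unit: it is
#' truth-positive iff it lies inside a true error span *of its own
#' sequence*, and call-positive iff it lies inside a detected segment of
#' its own sequence.  Sensitivity is `tp / (tp + fn)` (fraction of
#' erroneous residues removed) and specificity `tn / (tn + fp)` (fraction
#' of correct residues kept); both are `NA` when their denominator is 0.
#'
#' @param detected segment table (`seq_id`, `start_res`, `end_res`), e.g.
#'   from [clean()].
#' @param truth truth table (`seq_id`, `start_res`, `end_res`), e.g. from
#'   [build_erroneous_msa()].
#' @param aln the amino-acid [alignment()] both refer to.
#' @param columns optional integer vector of alignment columns to restrict
#'   the assessment to (e.g. the UAR columns from [classify_columns()]);
#'   residues in other columns are not counted.
#' @return List with integer counts `tp`, `fp`, `fn`, `tn` and numeric
#'   `sensitivity`, `specificity`.
#' @export
confusion <- function(detected, truth, aln, columns = NULL) {
  stopifnot(inherits(aln, "alignment"))
  cmap <- coord_map(aln)
  n_res <- vapply(cmap, length, integer(1))
  mask_from <- function(tab) {
    masks <- lapply(n_res, function(n) logical(n))
    if (!is.null(tab) && nrow(tab) > 0) {
      for (j in seq_len(nrow(tab))) {
        i <- match(tab$seq_id[j], aln$ids)
        if (is.na(i)) stop("unknown seq_id: ", tab$seq_id[j])
        if (tab$start_res[j] < 1 || tab$end_res[j] > n_res[i])
          stop("coordinate error: span outside sequence ", tab$seq_id[j])
        masks[[i]][tab$start_res[j]:tab$end_res[j]] <- TRUE
      }
    }
    masks
  }
  pos <- mask_from(truth)
  call <- mask_from(detected)
  keep <- if (is.null(columns)) {
    lapply(n_res, function(n) rep(TRUE, n))
  } else {
    lapply(cmap, function(cols) cols %in% columns)
  }
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(cmap)) {
    p <- pos[[i]][keep[[i]]]; cl <- call[[i]][keep[[i]]]
    tp <- tp + sum(p & cl);   fp <- fp + sum(!p & cl)
    fn <- fn + sum(p & !cl);  tn <- tn + sum(!p & !cl)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Alignment-region stringency settings
#'
#' Entropy/gap cutoff pairs for classifying columns into unambiguously
#' (UAR) and ambiguously (AAR) aligned regions, mirroring the three
#' stringency levels of block-filtering practice: `strict` (0.4, 0.05),
#' `medium` (0.5, 0.2; the usual defaults) and `loose` (0.6, 0.4).
#'
#' @param name `"strict"`, `"medium"` or `"loose"`.
#' @return List with `name`, `entropy_cutoff`, `gap_cutoff`.
#' @export
region_settings <- function(name = c("medium", "strict", "loose")) {
  name <- match.arg(name)
  cut <- switch(name,
                strict = c(0.4, 0.05),
                medium = c(0.5, 0.2),
                loose  = c(0.6, 0.4))
  list(name = name, entropy_cutoff = cut[1], gap_cutoff = cut[2])
}

#' Classify alignment columns as UAR or AAR
#'
#' A built-in entropy/gap classifier: a column is AAR iff its smoothed
#' normalized Shannon entropy exceeds the entropy cutoff or its gap
#' frequency exceeds the gap cutoff; otherwise UAR.  Entropy is computed
#' over the residue distribution of the column's non-gap cells,
#' normalized by `log(20)`, and smoothed by a running mean over a fixed
#' odd window before thresholding.
#'
#' @param aln an amino-acid [alignment()].
#' @param settings a [region_settings()] list.
#' @param window odd smoothing-window width for the entropy track.
#' @return Character vector (`"UAR"`/`"AAR"`), one entry per column.
#' @export
classify_columns <- function(aln, settings = region_settings("medium"),
                             window = 3L) {
  stopifnot(inherits(aln, "alignment"), aln$alphabet == "aa",
            window %% 2L == 1L)
  M <- toupper(aln_matrix(aln))
  n <- ncol(M)
  gap_freq <- colMeans(M == "-")
  ent <- vapply(seq_len(n), function(j) {
    res <- M[M[, j] != "-", j]
    if (length(res) == 0) return(0)
    p <- table(res) / length(res)
    -sum(p * log(p)) / log(20)
  }, numeric(1))
  if (n >= 1 && window > 1) {
    half <- (window - 1L) %/% 2L
    sm <- vapply(seq_len(n), function(j) {
      mean(ent[max(1L, j - half):min(n, j + half)])
    }, numeric(1))
  } else sm <- ent
  ifelse(sm > settings$entropy_cutoff | gap_freq > settings$gap_cutoff,
         "AAR", "UAR")
}

#' Per-column context of an alignment
#'
#' Gap frequency and a substitution-rate proxy per column.  The rate
#' proxy is the mean pairwise difference among the column's non-gap
#' residues (differing pairs / total pairs), labeled a proxy because it
#' is a column-local stand-in for an evolutionary rate estimate; `NA`
#' when fewer than two residues are present.
#'
#' @param aln an amino-acid [alignment()].
#' @return Data frame with columns `col`, `gap_frequency`,
#'   `substitution_rate_proxy`.
#' @export
column_context <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  M <- toupper(aln_matrix(aln))
  n <- ncol(M)
  gap_freq <- colMeans(M == "-")
  rate <- vapply(seq_len(n), function(j) {
    res <- M[M[, j] != "-", j]
    k <- length(res)
    if (k < 2) return(NA_real_)
    tab <- table(res)
    same <- sum(tab * (tab - 1) / 2)
    total <- k * (k - 1) / 2
    (total - same) / total
  }, numeric(1))
  data.frame(col = seq_len(n), gap_frequency = gap_freq,
             substitution_rate_proxy = rate)
}

#' Characterize a detected segment's alignment context
#'
#' Computes the gap frequency of the segment's column span across all
#' sequences, flags the segment as insertion-linked when that frequency
#' is at least 70\%, and computes the mean pairwise identity of the
#' segment against every other sequence over the span.  A pairwise
#' identity is computable only when at least 10\% of the segment residues
#' face a residue (not a gap) in the other sequence, and the mean is
#' reported only when at least 10\% of the pairs are computable
#' (otherwise `NA`).
#'
#' @param seg one-row segment record (`seq_id`, `start_col`, `end_col`).
#' @param aln the amino-acid [alignment()].
#' @return List with `region_gap_frequency`, `insertion_linked`,
#'   `mean_pairwise_identity` (possibly `NA`).
#' @export
characterize_segment <- function(seg, aln) {
  stopifnot(inherits(aln, "alignment"))
  cols <- seg$start_col:seg$end_col
  if (min(cols) < 1 || max(cols) > aln$n_cols)
    stop("coordinate error: segment columns outside the alignment")
  M <- toupper(aln_matrix(aln))
  block <- M[, cols, drop = FALSE]
  gap_freq <- mean(block == "-")
  i <- match(seg$seq_id, aln$ids)
  own <- block[i, ]
  own_res <- own != "-"
  others <- setdiff(seq_len(nrow(M)), i)
  idents <- vapply(others, function(k) {
    facing <- own_res & block[k, ] != "-"
    if (sum(facing) < 0.10 * sum(own_res) || sum(own_res) == 0)
      return(NA_real_)
    mean(own[facing] == block[k, facing])
  }, numeric(1))
  computable <- !is.na(idents)
  mpi <- if (length(idents) > 0 && mean(computable) >= 0.10)
    mean(idents[computable]) else NA_real_
  list(region_gap_frequency = gap_freq,
       insertion_linked = gap_freq >= 0.70,
       mean_pairwise_identity = mpi)
}

#' Simulate–clean–score benchmark over an experiment design
#'
#' For every design cell (error length x number of affected sequences)
#' and replicate: generate a synthetic codon alignment, inject errors,
#' translate and realign, run the cleaner, and score the detected
#' segments against the truth — overall and partitioned into UAR and AAR
#' columns.
#'
#' @param design data frame with columns `length_aa` and `n_errors`.
#' @param reps replicates per cell.
#' @param error_type error type passed to [error_spec()].
#' @param n_seqs,n_codons,divergence,indel_rate fixture parameters for
#'   [generate_fixture_msa()].
#' @param spec a [profile_spec()].
#' @param m a [scoring_matrix()].
#' @param settings a [region_settings()] list for the UAR/AAR partition.
#' @param seed integer seed; the run is fully reproducible.
#' @return Tidy data frame, one row per cell x replicate x region
#'   (`all`, `UAR`, `AAR`) with the confusion counts and rates.
#' @export
run_benchmark <- function(design, reps = 3, error_type = "frameshift",
                          n_seqs = 25, n_codons = 200, divergence = 0.05,
                          indel_rate = 0.01,
                          spec = profile_spec(), m = matrix_preset("default"),
                          settings = region_settings("medium"), seed = 1) {
  stopifnot(is.data.frame(design),
            all(c("length_aa", "n_errors") %in% names(design)))
  out <- list()
  if (reps < 1 || nrow(design) == 0)
    return(data.frame(length_aa = integer(0), n_errors = integer(0),
                      rep = integer(0), region = character(0),
                      tp = integer(0), fp = integer(0), fn = integer(0),
                      tn = integer(0), sensitivity = numeric(0),
                      specificity = numeric(0)))
  counter <- 0L
  for (d in seq_len(nrow(design))) {
    for (r in seq_len(reps)) {
      counter <- counter + 1L
      base_seed <- (seed * 10007L + counter * 131L) %% .Machine$integer.max
      nt <- generate_fixture_msa(n_seqs, n_codons, divergence, indel_rate,
                                 seed = base_seed)
      affected <- with_seed(base_seed + 1L,
                            sample(nt$ids, design$n_errors[d]))
      specs <- lapply(seq_along(affected), function(k)
        error_spec(error_type, affected[k], design$length_aa[d],
                   seed = base_seed + 1L + k))
      sim <- build_erroneous_msa(nt, specs)
      res <- clean(sim$alignment, spec, m)
      regions <- classify_columns(sim$alignment, settings)
      for (reg in c("all", "UAR", "AAR")) {
        cols <- if (reg == "all") NULL else which(regions == reg)
        if (!is.null(cols) && length(cols) == 0) next
        cf <- confusion(res$segments, sim$truth, sim$alignment, cols)
        out[[length(out) + 1L]] <-
          data.frame(length_aa = design$length_aa[d],
                     n_errors = design$n_errors[d], rep = r, region = reg,
                     tp = cf$tp, fp = cf$fp, fn = cf$fn, tn = cf$tn,
                     sensitivity = cf$sensitivity,
                     specificity = cf$specificity)
      }
    }
  }
  do.call(rbind, out)
}

#' Pool confusion counts (micro-average)
#'
#' @param df a [run_benchmark()] result (or subset of it).
#' @return One-row data frame of summed counts with micro-averaged
#'   sensitivity and specificity.
#' @export
pool_confusion <- function(df) {
  tp <- sum(df$tp); fp <- sum(df$fp); fn <- sum(df$fn); tn <- sum(df$tn)
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}
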