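#' Scoring-matrix parameter grid
#'
#' The reference optimization grid: 9 values of `c1` (-0.05 to -0.25 by
#' 0.025), 7 of `c2` (-0.02 to -0.08 by 0.01), 9 of `c3` (0.05 to 0.25 by
#' 0.025) and 5 of `c4` (0.4 to 0.6 by 0.05), for 2835 combinations.
#' Values are materialized from integer step counts (thousandths), never
#' by repeated floating-point addition, so they are exact 3-decimal
#' numbers.
#'
#' @return List of four numeric axes `c1`, `c2`, `c3`, `c4`.
#' @export
default_grid <- function() {
  list(c1 = -(50 + 25 * 0:8) / 1000,
       c2 = -(20 + 10 * 0:6) / 1000,
       c3 = (50 + 25 * 0:8) / 1000,
       c4 = (400 + 50 * 0:4) / 1000)
}

#' Enumerate a parameter grid into scoring matrices
#'
#' Cartesian product in deterministic order: `c1` outermost, `c4`
#' innermost.
#'
#' @param grid a list of four numeric axes as from [default_grid()].
#' @return Data frame with columns `c1`..`c4`, one row per combination;
#'   every row satisfies the sign invariants of [scoring_matrix()].
#' @export
enumerate_grid <- function(grid = default_grid()) {
  stopifnot(all(c("c1", "c2", "c3", "c4") %in% names(grid)))
  g <- expand.grid(c4 = grid$c4, c3 = grid$c3, c2 = grid$c2, c1 = grid$c1,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("c1", "c2", "c3", "c4")]
  rownames(g) <- NULL
  stopifnot(all(g$c1 < 0), all(g$c2 < 0), all(g$c3 > 0), all(g$c4 > 0))
  g
}

#' The characterization experiment design
#'
#' The full-scale design used to characterize filter performance: 4 error
#' lengths (10, 33, 66, 100 aa) crossed with 4 numbers of affected
#' sequences (1, 5, 10, 15), 100 simulations per cell on each of 100 MSAs
#' from each of 4 lineages, 25-sequence subsets.
#'
#' @return Data frame of the 16 cells (`length_aa`, `n_errors`) with
#'   attributes `sims_per_cell` (100), `n_msas` (100), `n_lineages` (4)
#'   and `n_seqs` (25).
#' @seealso [design_totals()] to enumerate its simulation and error
#'   counts.
#' @export
characterization_design <- function() {
  d <- expand.grid(length_aa = c(10L, 33L, 66L, 100L),
                   n_errors = c(1L, 5L, 10L, 15L),
                   KEEP.OUT.ATTRS = FALSE)
  attr(d, "sims_per_cell") <- 100L
  attr(d, "n_msas") <- 100L
  attr(d, "n_lineages") <- 4L
  attr(d, "n_seqs") <- 25L
  d
}

#' Totals implied by an experiment design
#'
#' Enumerates, without running anything, how many simulations a design
#' describes and how many individual errors they introduce (each
#' simulation of a cell introduces `n_errors` errors).
#'
#' @param design a design data frame as from [characterization_design()];
#'   attributes `sims_per_cell`, `n_msas` and `n_lineages` default to 1
#'   when absent.
#' @return List with `n_simulations` and `n_errors`.
#' @export
design_totals <- function(design = characterization_design()) {
  sims <- attr(design, "sims_per_cell"); sims <- if (is.null(sims)) 1L else sims
  msas <- attr(design, "n_msas");        msas <- if (is.null(msas)) 1L else msas
  lin <- attr(design, "n_lineages");     lin <- if (is.null(lin)) 1L else lin
  per_cell <- as.numeric(sims) * msas * lin
  list(n_simulations = nrow(design) * per_cell,
       n_errors = sum(design$n_errors * per_cell))
}

#' The parameter-optimization design
#'
#' The full-scale sampling design of the scoring-matrix optimization: 2
#' source datasets of 100 MSAs each, subsets of 5, 10, 25 and 50
#' sequences each drawn 100 times, with 1 to 5 errors of length 10 to
#' 100 aa per simulated MSA.
#'
#' @return List describing the design, including `n_msas_simulated`.
#' @export
optimization_design <- function() {
  n_datasets <- 2L; n_msas <- 100L
  subset_sizes <- c(5L, 10L, 25L, 50L); draws <- 100L
  list(n_datasets = n_datasets, n_msas = n_msas,
       subset_sizes = subset_sizes, draws_per_subset = draws,
       errors_per_msa = 1:5, error_length_range = c(10L, 100L),
       n_msas_simulated = n_datasets * n_msas * length(subset_sizes) * draws)
}

#' Grid search over scoring-matrix parameters
#'
#' Simulates a set of error-injected MSAs once, annotates them once
#' (annotation does not depend on the scoring matrix), then scores every
#' matrix of the grid on the shared annotations and ranks matrices by an
#' objective combining mean sensitivity and mean specificity.
#'
#' @param grid data frame of matrices ([enumerate_grid()]) or a grid list.
#' @param design data frame (`length_aa`, `n_errors`) of simulation cells.
#' @param reps replicates per design cell.
#' @param objective `"sum"`, `"min"` or `"product"` of (mean sensitivity,
#'   mean specificity); all three are reported, the chosen one ranks.
#' @param error_type,n_seqs,n_codons,divergence,indel_rate fixture and
#'   simulator parameters, as in [run_benchmark()].
#' @param spec a [profile_spec()].
#' @param seed integer seed.
#' @return Data frame, one row per matrix, ranked by the objective
#'   (descending): `c1`..`c4`, `mean_sensitivity`, `mean_specificity`
#'   (macro averages over simulations), `micro_sensitivity`,
#'   `micro_specificity`, `obj_sum`, `obj_min`, `obj_product`.
#' @export
optimize_matrix <- function(grid = enumerate_grid(),
                            design = data.frame(length_aa = c(10L, 30L),
                                                n_errors = c(1L, 2L)),
                            reps = 2, objective = c("sum", "min", "product"),
                            error_type = "frameshift", n_seqs = 25,
                            n_codons = 200, divergence = 0.05,
                            indel_rate = 0.01, spec = profile_spec(),
                            seed = 1) {
  objective <- match.arg(objective)
  if (is.list(grid) && !is.data.frame(grid)) grid <- enumerate_grid(grid)
  if (nrow(grid) == 0) stop("empty grid")
  # simulate + annotate once; traces are recomputed per matrix
  sims <- list()
  counter <- 0L
  for (d in seq_len(nrow(design))) {
    for (r in seq_len(reps)) {
      counter <- counter + 1L
      base_seed <- (seed * 20011L + counter * 271L) %% .Machine$integer.max
      nt <- generate_fixture_msa(n_seqs, n_codons, divergence, indel_rate,
                                 seed = base_seed)
      affected <- with_seed(base_seed + 1L,
                            sample(nt$ids, design$n_errors[d]))
      specs <- lapply(seq_along(affected), function(k)
        error_spec(error_type, affected[k], design$length_aa[d],
                   seed = base_seed + 1L + k))
      sim <- build_erroneous_msa(nt, specs)
      sims[[counter]] <- list(aln = sim$alignment, truth = sim$truth,
                              anns = annotate_alignment(sim$alignment, spec))
    }
  }
  if (length(sims) == 0) stop("empty simulation set: check design/reps")
  score_matrix <- function(mrow) {
    m <- scoring_matrix(mrow[["c1"]], mrow[["c2"]], mrow[["c3"]], mrow[["c4"]])
    sens <- spc <- numeric(length(sims))
    tp <- fp <- fn <- tn <- 0
    for (s in seq_along(sims)) {
      sm <- sims[[s]]
      segs <- .segments_for_alignment(sm$aln, sm$anns, m)
      cf <- confusion(segs, sm$truth, sm$aln)
      sens[s] <- cf$sensitivity; spc[s] <- cf$specificity
      tp <- tp + cf$tp; fp <- fp + cf$fp; fn <- fn + cf$fn; tn <- tn + cf$tn
    }
    c(mean_sensitivity = mean(sens, na.rm = TRUE),
      mean_specificity = mean(spc, na.rm = TRUE),
      micro_sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      micro_specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }
  stats <- t(vapply(seq_len(nrow(grid)),
                    function(i) score_matrix(grid[i, ]),
                    numeric(4)))
  res <- cbind(grid, as.data.frame(stats))
  res$obj_sum <- res$mean_sensitivity + res$mean_specificity
  res$obj_min <- pmin(res$mean_sensitivity, res$mean_specificity)
  res$obj_product <- res$mean_sensitivity * res$mean_specificity
  key <- switch(objective, sum = res$obj_sum, min = res$obj_min,
                product = res$obj_product)
  res <- res[order(-key), ]
  rownames(res) <- NULL
  res
}
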