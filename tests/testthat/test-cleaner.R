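default_m <- matrix_preset("default")

test_that("scoring matrices validate signs and presets resolve by name", {
  expect_error(scoring_matrix(0.1, -0.1, 0.1, 0.1), "negative")
  expect_error(scoring_matrix(-0.1, -0.1, -0.1, 0.1), "positive")
  expect_identical(matrix_preset("species-rich"), matrix_preset("species_rich"))
  expect_identical(matrix_preset("v1.8"), matrix_preset("v1_8"))
})

test_that("the similarity trace accumulates with clamping to [0, 1]", {
  expect_equal(similarity_trace("UUUUU", default_m), rep(1, 5))
  # the canonical blank run: seven decrements of 0.15 reach exactly zero
  expect_equal(similarity_trace("BBBBBBB", default_m),
               c(0.85, 0.70, 0.55, 0.40, 0.25, 0.10, 0.00),
               tolerance = 1e-9)
  expect_identical(similarity_trace("BBBBBBB", default_m)[7], 0)
  expect_equal(similarity_trace("UUBBBPLU", default_m),
               c(1, 1, 0.85, 0.70, 0.55, 0.47, 0.62, 1.00),
               tolerance = 1e-9)
  expect_error(similarity_trace(""), "empty")
  expect_error(similarity_trace("UQU"), "symbols")
})

test_that("the trace kernel matches the naive reference accumulator", {
  set.seed(101)
  for (k in 1:300) {
    m <- random_matrix()
    s <- random_symbols()
    expect_identical(similarity_trace(s, m),
                     naive_trace(strsplit(s, "")[[1]], m))
  }
})

test_that("trace values always stay within [0, 1]", {
  set.seed(102)
  for (k in 1:100) {
    tr <- similarity_trace(random_symbols(), random_matrix())
    expect_gte(min(tr), 0)
    expect_lte(max(tr), 1)
  }
})

test_that("segment boundaries follow the last-1 / last-zero rule", {
  expect_equal(nrow(detect_segments(rep(1, 10))), 0)
  # start after the last 1, end at the last zero of the run
  tr <- similarity_trace(paste(c(rep("U", 3), rep("B", 7), rep("U", 4)),
                               collapse = ""), default_m)
  expect_equal(detect_segments(tr),
               data.frame(start_res = 4L, end_res = 10L))
  # a run reaching the sequence end without returning to 1 ends there
  tr2 <- similarity_trace(paste(c(rep("U", 3), rep("B", 7), "L"),
                                collapse = ""), default_m)
  expect_equal(detect_segments(tr2),
               data.frame(start_res = 4L, end_res = 11L))
  # sub-1 run that never reaches zero is not a segment
  tr3 <- similarity_trace("UUBBBUUU", default_m)
  expect_equal(nrow(detect_segments(tr3)), 0)
  # a trace that starts below 1 starts its segment at position 1
  tr4 <- similarity_trace(paste(rep("B", 8), collapse = ""), default_m)
  expect_equal(detect_segments(tr4),
               data.frame(start_res = 1L, end_res = 8L))
})

test_that("the alternative full-run boundary rule is selectable", {
  tr <- similarity_trace(paste(c(rep("U", 3), rep("B", 7), rep("U", 4)),
                               collapse = ""), default_m)
  expect_equal(detect_segments(tr, rule = "full_run"),
               data.frame(start_res = 4L, end_res = 12L))
})

test_that("no segment can arise from fewer than seven blanks at full score", {
  mk <- function(nb) paste(c(rep("U", 5), rep("B", nb), rep("U", 5)),
                           collapse = "")
  for (nb in 1:6)
    expect_equal(nrow(detect_segments(similarity_trace(mk(nb), default_m))), 0)
  expect_equal(nrow(detect_segments(similarity_trace(mk(7), default_m))), 1)
})

test_that("appending blanks never removes an existing segment", {
  set.seed(103)
  for (k in 1:50) {
    s <- random_symbols(80)
    old <- detect_segments(similarity_trace(s, default_m))
    new <- detect_segments(similarity_trace(paste0(s, "BBBB"), default_m))
    expect_gte(nrow(new), nrow(old))
    if (nrow(old) > 0) {
      for (j in seq_len(nrow(old))) {
        covered <- any(new$start_res <= old$start_res[j] &
                         new$end_res >= old$end_res[j])
        expect_true(covered)
      }
    }
  }
})

test_that("cleaning an alignment of identical sequences changes nothing", {
  aln <- identical_aln(25)
  res <- clean(aln)
  expect_equal(res$alignment$seqs, aln$seqs)
  expect_equal(nrow(res$segments), 0)
})

test_that("cleaning masks a scrambled block in the affected sequence only", {
  sim <- scramble_fixture(seed = 17)
  res <- clean(sim$alignment)
  tr <- sim$truth
  changed <- which(res$alignment$seqs != sim$alignment$seqs)
  expect_equal(sim$alignment$ids[changed], tr$seq_id)
  # at least 80% of the scrambled residues are gone
  cm <- coord_map(sim$alignment)[[tr$seq_id]]
  err_cols <- cm[tr$start_res:tr$end_res]
  before <- strsplit(sim$alignment$seqs[changed], "")[[1]]
  after <- strsplit(res$alignment$seqs[changed], "")[[1]]
  expect_gte(mean(after[err_cols] == "-"), 0.8)
  # masking conservation: removed residues == summed segment lengths
  expect_equal(sum(before != after), sum(res$segments$length))
})

test_that("a second cleaning pass on a single-error fixture removes little", {
  exceptions <- 0L
  for (seed in 1:6) {
    sim <- scramble_fixture(seed = seed)
    first <- clean(sim$alignment)
    second <- clean(first$alignment)
    if (nrow(second$segments) > 0) exceptions <- exceptions + 1L
  }
  expect_lte(exceptions, 1L)
})

test_that("the mask character is configurable", {
  sim <- scramble_fixture(seed = 17)
  res <- clean(sim$alignment, mask_char = "X")
  i <- match(res$segments$seq_id[1], sim$alignment$ids)
  after <- strsplit(res$alignment$seqs[i], "")[[1]]
  cols <- coord_map(sim$alignment)[[i]][
    res$segments$start_res[1]:res$segments$end_res[1]]
  expect_true(all(after[cols] == "X"))
})

test_that("nucleotide cleaning masks whole codons behind each aa residue", {
  nt <- generate_fixture_msa(25, 120, 0.05, 0, seed = 55)
  sim <- build_erroneous_msa(nt, list(error_spec("scramble", "seq03", 25,
                                                 seed = 56)))
  # rebuild the nt alignment carrying the error (no indels -> same geometry)
  specs_cds <- introduce_error(nt, error_spec("scramble", "seq03", 25,
                                              seed = 56))
  nt_err <- transfer_gaps(translate_alignment(nt), specs_cds$cds)
  res <- clean_nt(nt_err)
  expect_gte(nrow(res$segments), 1)
  aa_masked <- sum(res$segments$length)
  nt_before <- strsplit(nt_err$seqs, "")
  nt_after <- strsplit(res$alignment$seqs, "")
  nt_masked <- sum(mapply(function(a, b) sum(a != b), nt_before, nt_after))
  expect_equal(nt_masked, 3 * aa_masked)
  # residue k maps to CDS positions 3(k-1)+1 .. 3k
  seg <- res$segments[1, ]
  i <- match(seg$seq_id, nt_err$ids)
  cm <- coord_map(nt_err)[[i]]
  expect_equal(seg$start_col_nt, cm[3 * (seg$start_res - 1) + 1])
  expect_equal(seg$end_col_nt, cm[3 * seg$end_res])
})

test_that("nucleotide cleaning is the identity when nothing is detected", {
  nt <- generate_fixture_msa(10, 60, 0, 0, seed = 6)
  res <- clean_nt(nt)
  expect_equal(res$alignment$seqs, nt$seqs)
  expect_equal(nrow(res$segments), 0)
})
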