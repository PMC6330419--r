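toy_nt <- function() {
  # 4 sequences x 10 codons, gapless
  generate_fixture_msa(4, 10, 0, 0, seed = 1)
}

test_that("error specifications validate their window", {
  expect_error(error_spec("frameshift", "s", 0), "positive integer")
  nt <- toy_nt()
  expect_error(introduce_error(nt, error_spec("scramble", "nope", 2, seed = 1)),
               "unknown seq_id")
  expect_error(introduce_error(nt, error_spec("scramble", nt$ids[1], 3,
                                              anchor = 9, seed = 1)),
               "placement")
})

test_that("a frameshift corrupts exactly its out-of-frame window", {
  cds <- c(s = "ATGAAAGCTGATTTT")                # MKADF
  for (seed in 1:12) {
    res <- introduce_error(cds, error_spec("frameshift", "s", 2, anchor = 2,
                                           seed = seed))
    mutant <- res$cds[["s"]]
    expect_equal(nchar(mutant), nchar(cds[["s"]]))  # length conserved
    aa0 <- strsplit(translate_cds(cds[["s"]]), "")[[1]]
    aa1 <- strsplit(translate_cds(mutant), "")[[1]]
    expect_equal(aa1[c(1, 4, 5)], aa0[c(1, 4, 5)])  # outside the window
    expect_equal(res$truth$start_res, 2)
    expect_equal(res$truth$end_res, 3)
  }
})

test_that("frameshifts conserve CDS length at random anchors", {
  nt <- generate_fixture_msa(5, 50, 0.05, 0, seed = 2)
  cds <- degap(nt)
  for (seed in 1:10) {
    res <- introduce_error(nt, error_spec("frameshift", "seq02", 8,
                                          seed = seed))
    expect_equal(nchar(res$cds[["seq02"]]), nchar(cds[["seq02"]]))
    # translated differences confined to the truth window
    aa0 <- strsplit(translate_cds(cds[["seq02"]]), "")[[1]]
    aa1 <- strsplit(translate_cds(res$cds[["seq02"]]), "")[[1]]
    diff <- which(aa0 != aa1)
    expect_true(all(diff >= res$truth$start_res & diff <= res$truth$end_res))
  }
})

test_that("scrambling permutes the window nucleotides in place", {
  nt <- toy_nt()
  cds <- degap(nt)
  res <- introduce_error(nt, error_spec("scramble", "seq01", 3, anchor = 4,
                                        seed = 5))
  s0 <- strsplit(cds[["seq01"]], "")[[1]]
  s1 <- strsplit(res$cds[["seq01"]], "")[[1]]
  w <- 10:18                                     # codons 4-6
  expect_equal(sort(s1[w]), sort(s0[w]))         # multiset conserved
  expect_equal(s1[-w], s0[-w])
})

test_that("insertions add a shuffled same-composition segment", {
  nt <- toy_nt()
  cds <- degap(nt)
  res <- introduce_error(nt, error_spec("insertion", "seq01", 4, seed = 7))
  expect_equal(nchar(res$cds[["seq01"]]), nchar(cds[["seq01"]]) + 12)
  expect_equal(res$truth$end_res - res$truth$start_res + 1, 4)
  # removing the inserted window restores the original sequence
  s1 <- strsplit(res$cds[["seq01"]], "")[[1]]
  p <- 3 * (res$truth$anchor - 1) + 1
  expect_equal(paste(s1[-(p:(p + 11))], collapse = ""), cds[["seq01"]])
})

test_that("building an erroneous MSA tracks truth through realignment", {
  nt <- generate_fixture_msa(25, 100, 0.05, 0.01, seed = 12)
  # no errors: ungapped content is just the translation
  none <- build_erroneous_msa(nt, list())
  expect_equal(unname(degap(none$alignment)),
               unname(vapply(degap(nt), translate_cds, character(1))))
  expect_equal(nrow(none$truth), 0)
  # one frameshift of 20 codons
  sim <- build_erroneous_msa(nt, list(error_spec("frameshift", "seq10", 20,
                                                 seed = 13)))
  expect_equal(nrow(sim$truth), 1)
  expect_equal(sim$truth$end_res - sim$truth$start_res + 1, 20)
  # unaffected sequences keep their residue content
  expect_equal(degap(sim$alignment)[-10],
               vapply(degap(nt), translate_cds, character(1))[-10])
  # the column span maps back onto the residue span
  cm <- coord_map(sim$alignment)[["seq10"]]
  expect_equal(cm[sim$truth$start_res], sim$truth$start_col)
  expect_equal(cm[sim$truth$end_res], sim$truth$end_col)
})

test_that("insertion errors open sequence-specific columns when realigning", {
  nt <- generate_fixture_msa(10, 60, 0.03, 0, seed = 14)
  sim <- build_erroneous_msa(nt, list(error_spec("insertion", "seq04", 6,
                                                 seed = 15)))
  aln <- sim$alignment
  expect_equal(aln$n_cols, 66)                  # 60 + inserted block
  cols <- sim$truth$start_col:sim$truth$end_col
  M <- aln_mat <- do.call(rbind, strsplit(aln$seqs, ""))
  expect_true(all(M[-4, cols] == "-"))          # gap in every other sequence
  expect_true(all(M[4, cols] != "-"))
})

test_that("at most one error per sequence is accepted", {
  nt <- toy_nt()
  expect_error(build_erroneous_msa(nt, list(
    error_spec("scramble", "seq01", 2, seed = 1),
    error_spec("frameshift", "seq01", 2, seed = 2))), "one error per")
})

test_that("every stochastic operation is reproducible under its seed", {
  a <- generate_fixture_msa(8, 40, 0.1, 0.02, seed = 99)
  b <- generate_fixture_msa(8, 40, 0.1, 0.02, seed = 99)
  expect_identical(a, b)
  nt <- toy_nt()
  e1 <- introduce_error(nt, error_spec("frameshift", "seq02", 3, seed = 4))
  e2 <- introduce_error(nt, error_spec("frameshift", "seq02", 3, seed = 4))
  expect_identical(e1, e2)
})

test_that("zero divergence yields identical sequences", {
  nt <- generate_fixture_msa(6, 30, 0, 0, seed = 3)
  expect_equal(length(unique(nt$seqs)), 1)
})

test_that("pairwise identity of fixtures matches the closed-form expectation", {
  d <- 0.05
  # two branches: sites agree if both untouched, or both hit the same base
  expected <- (1 - d)^2 + d^2 / 3
  obs <- numeric(100)
  for (k in 1:100) {
    nt <- generate_fixture_msa(2, 60, d, 0, seed = 1000 + k)
    a <- strsplit(nt$seqs[1], "")[[1]]
    b <- strsplit(nt$seqs[2], "")[[1]]
    obs[k] <- mean(a == b)
  }
  expect_lt(abs(mean(obs) - expected), 0.01)
})

test_that("mafft realignment preserves residue content", {
  skip_if(Sys.which("mafft") == "", "MAFFT not on PATH")
  nt <- generate_fixture_msa(8, 50, 0.05, 0, seed = 77)
  sim <- build_erroneous_msa(nt, list(error_spec("insertion", "seq02", 5,
                                                 seed = 78)),
                             aligner = "mafft")
  res <- introduce_error(nt, error_spec("insertion", "seq02", 5, seed = 78))
  aa <- vapply(res$cds, translate_cds, character(1))
  expect_equal(toupper(unname(degap(sim$alignment))),
               toupper(unname(aa[nt$ids])))
})
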