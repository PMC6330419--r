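# Independent naive reference accumulator for the similarity trace:
# per-position loop, clamping to [0, 1] with the same 1e-9 landmark
# snapping contract as the package, coded separately from the package's
# kernel.
naive_trace <- function(symbols, m) {
  inc <- c(B = m[["c1"]], P = m[["c2"]], L = m[["c3"]], U = m[["c4"]])
  s <- 1
  out <- numeric(length(symbols))
  for (i in seq_along(symbols)) {
    s <- s + inc[[symbols[i]]]
    if (s >= 1 - 1e-9) s <- 1
    if (s <= 1e-9) s <- 0
    out[i] <- s
  }
  out
}

# random valid scoring matrix with 3-decimal entries
random_matrix <- function() {
  scoring_matrix(-sample(10:300, 1) / 1000, -sample(10:300, 1) / 1000,
                 sample(10:300, 1) / 1000, sample(10:300, 1) / 1000)
}

random_symbols <- function(max_len = 200) {
  paste(sample(c("B", "P", "L", "U"), sample(1:max_len, 1), replace = TRUE),
        collapse = "")
}

# small gapless alignment of n identical sequences
identical_aln <- function(n = 10, seq = "MKLVNPQRSTWEDF") {
  alignment(sprintf("s%02d", 1:n), rep(seq, n), "aa")
}

# one simulated 25-sequence MSA carrying a single scrambled block
scramble_fixture <- function(seed, length_codons = 30, n_codons = 200,
                             divergence = 0.05, indel_rate = 0.01) {
  nt <- generate_fixture_msa(25, n_codons, divergence, indel_rate,
                             seed = seed)
  target <- sprintf("seq%02d", (seed %% 25) + 1)
  build_erroneous_msa(nt, list(error_spec("scramble", target, length_codons,
                                          seed = seed + 5000L)))
}
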