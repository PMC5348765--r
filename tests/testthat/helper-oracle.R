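# Independent brute-force oracle for the local profile-Viterbi score:
# explicit enumeration of every legal state path (entry at any match state,
# exit at any match state, M/I/D grammar with no I<->D transitions),
# scoring under the same model parameters.  No dynamic programming is
# shared with the implementation under test.

oracle_viterbi_score <- function(profile, protein) {
  x <- retromine:::encode_protein(protein)
  lo <- cbind(profile$logodds, 0)  # column 21: neutral X/*
  K <- nrow(lo)
  L <- length(x)
  if (L == 0L) return(-Inf)
  co <- log2(profile$gap_open)
  ce <- log2(profile$gap_extend)
  best <- -Inf

  # from an M at (residue i, state k) with accumulated score s
  from_m <- function(i, k, s) {
    if (s > best) best <<- s
    if (i < L && k < K) from_m(i + 1L, k + 1L, s + lo[k + 1L, x[i + 1L]])
    if (i < L) from_i(i + 1L, k, s + co)
    if (k < K) from_d(i, k + 1L, s + co)
  }
  from_i <- function(i, k, s) {  # insert after state k, emitted residue i
    if (i < L && k < K) from_m(i + 1L, k + 1L, s + lo[k + 1L, x[i + 1L]])
    if (i < L) from_i(i + 1L, k, s + ce)
  }
  from_d <- function(i, k, s) {  # state k deleted, i residues consumed
    if (i < L && k < K) from_m(i + 1L, k + 1L, s + lo[k + 1L, x[i + 1L]])
    if (k < K) from_d(i, k + 1L, s + ce)
  }
  for (i0 in seq_len(L))
    for (k0 in seq_len(K))
      from_m(i0, k0, lo[k0, x[i0]])
  unname(best)
}

# Random small seed alignment (gap-free) and profile for oracle tests.
random_small_profile <- function(n_states, n_rows = 3L,
                                 threshold = -Inf) {
  rows <- replicate(n_rows, paste(
    sample(retromine:::AA_ALPHABET, n_states, replace = TRUE),
    collapse = ""))
  build_profile(seed_alignment(rows, name = "toy"),
                score_threshold = threshold)
}

random_protein_str <- function(n) {
  paste(sample(retromine:::AA_ALPHABET, n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Best local score regardless of threshold (NA when no alignment exists).
best_score <- function(profile, protein) {
  h <- viterbi_search(profile, protein, threshold = -Inf, max_hits = 1L)
  if (nrow(h) == 0L) -Inf else h$score[[1]]
}
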