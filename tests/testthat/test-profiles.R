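# Profile construction, six-frame translation, and local Viterbi search.

test_that("six-frame translation follows the standard code, stop-agnostic", {
  fr <- translate_six_frames("ATGGCC")
  plus1 <- fr[[which(vapply(fr, `[[`, numeric(1), "frame") == 1)]]
  expect_equal(plus1$protein, "MA")

  fr <- translate_six_frames("ATG")
  minus1 <- fr[[which(vapply(fr, `[[`, numeric(1), "frame") == -1)]]
  expect_equal(minus1$protein, "H")  # reverse complement CAT

  # stops are emitted as '*', N-containing codons as 'X'
  fr <- translate_six_frames("ATGTAAGCCNNT")
  plus1 <- fr[[1]]
  expect_equal(plus1$protein, "M*AX")

  expect_error(translate_six_frames(""), "empty")
  expect_error(translate_six_frames("ACGU"), "U")
})

test_that("frame coordinate maps invert exactly on all six frames", {
  set.seed(101)
  for (rep in 1:100) {
    dna <- random_dna_str(300)
    frames <- translate_six_frames(dna)
    for (fr in frames) {
      np <- nchar(fr$protein)
      if (np == 0L) next
      idx <- unique(c(1L, np, sample(np, min(np, 5L))))
      for (i in idx) {
        g <- frame_to_genome(fr$frame, fr$nt_length, i - 1L, i)
        expect_equal(g[2] - g[1], 3L)
        triple <- substr(dna, g[1] + 1L, g[2])
        if (fr$frame < 0)
          triple <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(triple)))
        expect_equal(
          as.character(Biostrings::translate(Biostrings::DNAString(triple),
                                             no.init.codon = TRUE)),
          substr(fr$protein, i, i))
      }
    }
  }
})

test_that("build_profile selects match columns and normalises emissions", {
  p <- build_profile(seed_alignment(rep("DEDRD", 4), "cons"))
  expect_equal(nrow(p$emissions), 5L)
  expect_gt(p$logodds[1, "D"], 0)

  p2 <- build_profile(seed_alignment(c("A-C", "AGC", "A-C", "A-C"), "gappy"))
  expect_equal(p2$match_columns, c(1L, 3L))  # column 2: gap fraction 0.75

  expect_error(
    build_profile(seed_alignment(c("A-", "-A", "A-", "-A"), "allgap")),
    "no match states")

  sim <- seed_alignments()[["aRNH"]]
  prof <- build_profile(sim)
  expect_true(all(abs(rowSums(prof$emissions) - 1) < 1e-9))
  expect_lt(abs(sum(prof$background) - 1), 1e-9)
  expect_gte(nrow(prof$emissions), 5L)
})

test_that("consensus self-hit spans all match states at the maximal score", {
  set.seed(7)
  prof <- random_small_profile(12, n_rows = 5, threshold = 5)
  consensus <- paste(
    retromine:::AA_ALPHABET[apply(prof$logodds, 1, which.max)],
    collapse = "")
  h <- viterbi_search(prof, consensus)
  expect_equal(nrow(h), 1L)
  expect_equal(h$protein_start, 0L)
  expect_equal(h$protein_end, nchar(consensus))
  expect_equal(h$kstart, 1L)
  expect_equal(h$kend, 12L)
  expect_equal(h$score, sum(apply(prof$logodds, 1, max)), tolerance = 1e-10)
})

test_that("background decoys are rejected at the default threshold", {
  prof <- default_profiles()$aRNH
  set.seed(11)
  fp <- 0L
  for (i in 1:100) {
    decoy <- random_protein_str(200)
    fp <- fp + (nrow(viterbi_search(prof, decoy)) > 0L)
  }
  expect_lte(fp / 100, 0.01)
})

test_that("Viterbi equals brute-force path enumeration on small instances", {
  set.seed(21)
  for (i in 1:60) {
    prof <- random_small_profile(sample(2:5, 1), n_rows = sample(2:4, 1))
    target <- random_protein_str(sample(2:8, 1))
    expect_equal(best_score(prof, target),
                 oracle_viterbi_score(prof, target),
                 tolerance = 1e-9,
                 info = paste("instance", i))
  }
})

test_that("appending residues never decreases the best local score", {
  set.seed(31)
  prof <- random_small_profile(8, n_rows = 4)
  for (i in 1:25) {
    base <- random_protein_str(sample(5:30, 1))
    longer <- paste0(base, random_protein_str(sample(1:10, 1)))
    expect_gte(best_score(prof, longer), best_score(prof, base) - 1e-12)
  }
})

test_that("hit lists are deterministic and non-overlapping", {
  prof <- default_profiles()$aRNH
  tpl <- retromine:::domain_templates()
  target <- paste0(random_protein_str(50), tpl$aRNH,
                   random_protein_str(30), tpl$aRNH, random_protein_str(20))
  h1 <- viterbi_search(prof, target)
  h2 <- viterbi_search(prof, target)
  expect_identical(h1, h2)
  expect_equal(nrow(h1), 2L)
  expect_true(all(h1$protein_end[-nrow(h1)] <= h1$protein_start[-1]))
  expect_true(all(h1$score >= prof$score_threshold))
})

test_that("scan_genome recovers a minus-strand planted domain", {
  prof <- default_profiles()$aRNH
  tpl <- retromine:::domain_templates()
  set.seed(41)
  coding <- retromine:::reverse_translate(tpl$aRNH)  # 420 nt
  minus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(coding)))
  genome <- paste0(random_dna_str(5000), minus, random_dna_str(4580))
  h <- scan_genome(genome, prof, "g")
  expect_equal(nrow(h), 1L)
  expect_lt(h$frame, 0)
  expect_lte(abs(h$genome_start - 5000), 30)
  expect_lte(abs(h$genome_end - 5420), 30)
  expect_equal(h$genome_end - h$genome_start,
               3L * (h$protein_end - h$protein_start))

  expect_equal(nrow(scan_genome(random_dna_str(3000), prof, "bg")), 0L)
})

test_that("a frameshifted planted domain still anchors", {
  prof <- default_profiles()$aRNH
  tpl <- retromine:::domain_templates()
  set.seed(43)
  coding <- retromine:::reverse_translate(tpl$aRNH)
  broken <- paste0(substr(coding, 1, 210), "G", substr(coding, 211, 420))
  genome <- paste0(random_dna_str(2000), broken, random_dna_str(2000))
  h <- scan_genome(genome, prof, "g")
  expect_gte(nrow(h), 1L)
  ov <- any(h$genome_end > 2000 & h$genome_start < 2421)
  expect_true(ov)
})

test_that("profiles round-trip through the text format", {
  prof <- default_profiles()$fmRNH
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$name, prof$name)
  expect_equal(back$match_columns, prof$match_columns)
  expect_equal(back$logodds, prof$logodds, tolerance = 1e-12)
  expect_equal(back$catalytic_states, prof$catalytic_states)
  tgt <- retromine:::domain_templates()$fmRNH
  expect_equal(best_score(back, tgt), best_score(prof, tgt),
               tolerance = 1e-9)
})

test_that("align_to_profile produces a fixed-width implicit alignment", {
  prof <- default_profiles()$aRNH
  v <- retromine:::group_variants()
  aln <- align_to_profile(prof, c(a = v$aRNH$Chronos, b = v$aRNH$L1))
  expect_equal(dim(aln), c(2L, nrow(prof$emissions)))
  # substitution-only variants align gap-free: rows equal the variants
  expect_equal(paste(aln["a", ], collapse = ""), v$aRNH$Chronos)
})
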