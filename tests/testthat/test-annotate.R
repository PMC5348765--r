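# ORF finding, LTR-pair detection, CCHC motifs, catalytic audits and
# architecture strings.

test_that("find_orfs reports maximal ATG-to-stop frames on both strands", {
  set.seed(3)
  prot <- random_protein_str(150)
  orf_nt <- paste0("ATG", retromine:::reverse_translate(prot), "TAA")
  win <- paste0(random_dna_str(500), orf_nt, random_dna_str(500))
  orfs <- find_orfs(win, min_protein_length = 100L)
  hit <- orfs[orfs$start == 500L, , drop = FALSE]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$end, 500L + nchar(orf_nt))
  expect_equal(hit$strand, "+")
  expect_equal(nchar(hit$protein), 151L)  # M + 150 residues, stop excluded

  expect_equal(nrow(find_orfs(strrep("N", 600))), 0L)

  # both template ORFs of an undiverged L1 element are recovered exactly
  tpl <- element_templates()$L1
  orfs <- find_orfs(tpl$dna)
  truth <- tpl$features[tpl$features$type %in% c("ORF1", "ORF2"), ]
  for (i in seq_len(nrow(truth))) {
    m <- orfs[orfs$start == truth$start[i] & orfs$end == truth$end[i], ]
    expect_equal(nrow(m), 1L)
    expect_equal(m$strand, "+")
  }
})

test_that("detect_ltr finds planted repeat pairs down to 85% identity", {
  set.seed(13)
  ltr <- random_dna_str(300)
  inner <- random_dna_str(2000)
  win <- paste0(random_dna_str(1000), ltr, inner, ltr, random_dna_str(1000))
  span <- c(1300L, 1300L + 2000L)
  p <- detect_ltr(win, span)
  expect_false(is.null(p))
  expect_gte(p$identity, 0.99)
  expect_lte(abs(p$ltr5[1] - 1000L), 20L)
  expect_lte(abs(p$ltr5[2] - 1300L), 20L)
  expect_lte(abs(p$ltr3[1] - 3300L), 20L)
  expect_lte(abs(p$ltr3[2] - 3600L), 20L)

  # 85% identity pair still detected at the default thresholds
  ltr2 <- strsplit(ltr, "")[[1]]
  mut <- sample(300, 45)
  for (i in mut) ltr2[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                           ltr2[i]), 1)
  win85 <- paste0(random_dna_str(1000), ltr, inner,
                  paste(ltr2, collapse = ""), random_dna_str(1000))
  p85 <- detect_ltr(win85, span)
  expect_false(is.null(p85))
  expect_gte(p85$identity, 0.8)
  expect_lte(abs(p85$ltr5[1] - 1000L), 20L)

  # no terminal repeats -> nothing
  expect_null(detect_ltr(paste0(random_dna_str(1500), inner,
                                random_dna_str(1500)),
                         c(1500L, 3500L)))
})

test_that("detect_ltr is symmetric under reverse complement", {
  set.seed(17)
  ltr <- random_dna_str(300)
  inner <- random_dna_str(1500)
  win <- paste0(random_dna_str(800), ltr, inner, ltr, random_dna_str(800))
  L <- nchar(win)
  span <- c(1100L, 2600L)
  p <- detect_ltr(win, span)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
  prc <- detect_ltr(rc, c(L - span[2], L - span[1]))
  expect_false(is.null(p))
  expect_false(is.null(prc))
  # the 5' repeat of the mirrored window is the mirrored 3' repeat
  expect_equal(prc$ltr5, c(L - p$ltr3[2], L - p$ltr3[1]), tolerance = 25)
  expect_equal(prc$ltr3, c(L - p$ltr5[2], L - p$ltr5[1]), tolerance = 25)
})

test_that("find_cchc matches the zinc-knuckle spacing pattern", {
  expect_equal(find_cchc("CAACTTTTHTTTTC"), 0L)
  expect_equal(find_cchc(paste0("AAA", "CAACTTTTHTTTTC", "AAA")), 3L)
  expect_equal(find_cchc(strrep("A", 50)), integer(0))
  # the L1 template's knuckle lies upstream (N-terminal) of its aRNH
  tpl <- element_templates()$L1
  orf2 <- tpl$orf_proteins$ORF2
  pos <- find_cchc(orf2)
  expect_gte(length(pos), 1L)
  arnh_start <- regexpr(retromine:::group_variants()$aRNH$L1, orf2,
                        fixed = TRUE)[[1]]
  expect_true(any(pos < arnh_start - 1L))
})

test_that("catalytic audit reads D-E-D-R/H-D off the state path", {
  profs <- default_profiles()
  tpl <- retromine:::domain_templates()
  h <- viterbi_search(profs$aRNH, tpl$aRNH)
  audit <- audit_catalytic_residues(h[1, ], profs$aRNH, tpl$aRNH)
  expect_equal(audit$residues, c("D", "E", "D", "R", "D"))
  expect_false(audit$degenerate)

  h <- viterbi_search(profs$fmRNH, tpl$fmRNH)
  audit <- audit_catalytic_residues(h[1, ], profs$fmRNH, tpl$fmRNH)
  expect_equal(audit$residues, c("D", "E", "D", "H", "D"))
  expect_false(audit$degenerate)

  # aRNH with a mutated catalytic site is flagged
  broken <- retromine:::set_positions(tpl$aRNH, 10L, "A")
  h <- viterbi_search(profs$aRNH, broken)
  audit <- audit_catalytic_residues(h[1, ], profs$aRNH, broken)
  expect_equal(audit$residues[1], "A")
  expect_true(audit$degenerate)

  # profile without catalytic metadata refuses
  expect_error(audit_catalytic_residues(h[1, ], profs$RT_LTR, broken),
               "catalytic")
})

test_that("architecture strings order domains and flag fusions", {
  doms <- data.frame(
    profile_name = c("INT", "PR", "aRNH", "RT_LTR", "gRNH", "CHD"),
    protein_start = c(700L, 0L, 500L, 120L, 380L, 960L),
    protein_end = c(950L, 100L, 640L, 360L, 500L, 1010L),
    stringsAsFactors = FALSE)
  arch <- architecture_string(doms)
  expect_equal(arch$labels, c("PR", "RT", "gRH", "aRH", "IN", "CHD"))
  expect_true(arch$dual_rnh)
  expect_true(arch$int_chd_fusion)

  # invariant to input order
  set.seed(23)
  arch2 <- architecture_string(doms[sample(nrow(doms)), ])
  expect_equal(arch2, arch)

  # CHD far from INT is not a fusion
  doms$protein_start[doms$profile_name == "CHD"] <- 1400L
  expect_false(architecture_string(doms)$int_chd_fusion)

  expect_equal(architecture_string(doms[0, ])$labels, character(0))
})
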