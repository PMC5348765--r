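# Window expansion, locus merging, RT classification, group assignment,
# fmRNH mining and count tables.

test_that("expand_window clamps at contig edges", {
  anchor <- data.frame(genome_start = 12000L, genome_end = 12450L)
  expect_equal(expand_window(anchor, 30000L), c(2000L, 22450L))
  anchor <- data.frame(genome_start = 500L, genome_end = 800L)
  expect_equal(expand_window(anchor, 30000L), c(0L, 10800L))
  anchor <- data.frame(genome_start = 100L, genome_end = 200L)
  expect_equal(expand_window(anchor, 250L), c(0L, 250L))
})

make_locus <- function(start, end, frame = 1L, score = 100,
                       kstart = 1L, kend = 140L, genome_id = "g") {
  anchor <- empty_anchor()
  anchor[1, c("genome_start", "genome_end", "frame", "score",
              "kstart", "kend")] <-
    list(start, end, frame, score, kstart, kend)
  list(genome_id = genome_id, anchor = anchor,
       window = c(max(0, start - 10000), end + 10000))
}

empty_anchor <- function() {
  h <- data.frame(profile_name = "aRNH", target_id = "g", frame = 1L,
                  protein_start = 0L, protein_end = 1L,
                  genome_start = 0L, genome_end = 3L, score = 0,
                  kstart = 1L, kend = 1L, path = "M",
                  stringsAsFactors = FALSE)
  h
}

test_that("merge_anchor_windows collapses duplicates, keeps neighbours", {
  # same position seen in two frames: one locus, best anchor kept
  dup <- list(make_locus(1000, 1400, frame = 1L, score = 50),
              make_locus(1010, 1410, frame = 2L, score = 80))
  merged <- merge_anchor_windows(dup)
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$anchor$score, 80)

  # two anchors 100 nt apart in the same frame stay separate
  near <- list(make_locus(1000, 1400, frame = 1L),
               make_locus(1500, 1900, frame = 1L))
  expect_length(merge_anchor_windows(near), 2L)

  # frameshift fragments: different frames, small gap, complementary
  # profile-state coverage -> one locus
  frag <- list(make_locus(1000, 1200, frame = 1L, score = 60,
                          kstart = 1L, kend = 66L),
               make_locus(1230, 1400, frame = 2L, score = 40,
                          kstart = 70L, kend = 126L))
  expect_length(merge_anchor_windows(frag), 1L)

  # two distinct nearby copies in different frames both cover the whole
  # profile and stay separate
  two <- list(make_locus(1000, 1420, frame = 1L, score = 200),
              make_locus(1700, 2120, frame = 2L, score = 210))
  expect_length(merge_anchor_windows(two), 2L)

  expect_length(merge_anchor_windows(list()), 0L)
})

test_that("classify_locus splits loci by co-localized RT evidence", {
  profs <- default_profiles()
  tpl <- element_templates()
  expect_equal(
    classify_locus(tpl$Chronos$dna, profs$RT_LTR,
                   profs$RT_nonLTR)$classification,
    "LTR_RT")
  expect_equal(
    classify_locus(tpl$L1$dna, profs$RT_LTR,
                   profs$RT_nonLTR)$classification,
    "NONLTR_RT")
  # a lone cellular aRNH gene has no RT anywhere in its window
  cls <- classify_locus(tpl$aRNH_cell$dna, profs$RT_LTR, profs$RT_nonLTR)
  expect_equal(cls$classification, "INDIVIDUAL_RNH")
  expect_equal(nrow(cls$rt_hits), 0L)
})

test_that("assign_group picks the right reference or stays unassigned", {
  refs <- group_references()
  tpl <- element_templates()
  set.seed(5)
  q_chronos <- retromine:::mutate_protein(tpl$Chronos$orf_proteins$ORF2, 0.1)
  expect_equal(assign_group(q_chronos, refs, chd_present = TRUE), "Chronos")
  q_archon <- retromine:::mutate_protein(tpl$Archon$orf_proteins$ORF2, 0.1)
  expect_equal(assign_group(q_archon, refs, chd_present = FALSE), "Archon")
  q_utopia <- retromine:::mutate_protein(tpl$Utopia$orf_proteins$ORF, 0.1)
  expect_equal(assign_group(q_utopia, refs), "Utopia")
  expect_equal(assign_group(random_protein_str(300), refs), "unassigned")
})

test_that("mine_fmrnh reports 1 kb-flank individual loci", {
  profs <- default_profiles()
  tpl <- element_templates()
  set.seed(9)
  genome <- paste0(random_dna_str(5000), tpl$fmRNH$dna, random_dna_str(5000))
  gene_len <- nchar(tpl$fmRNH$dna)
  loci <- mine_fmrnh(genome, "g", profs)
  expect_length(loci, 1L)
  l <- loci[[1]]
  expect_equal(l$classification, "INDIVIDUAL_RNH")
  expect_equal(l$group, "fmRNH")
  expect_equal(l$window[1], l$anchor$genome_start - 1000L)
  expect_equal(l$window[2], l$anchor$genome_end + 1000L)

  expect_length(mine_fmrnh(random_dna_str(4000), "g", profs), 0L)

  # gene at the contig edge: clamped flank
  edge <- paste0(tpl$fmRNH$dna, random_dna_str(3000))
  le <- mine_fmrnh(edge, "g", profs)
  expect_length(le, 1L)
  expect_equal(le[[1]]$window[1], 0L)
})

test_that("every anchor ends in exactly one locus with consistent class", {
  profs <- default_profiles()
  spec <- data.frame(group = c("Chronos", "L1", "aRNH_cell"),
                     count = c(1L, 1L, 1L), divergence = 0.03)
  g <- build_genome(spec, 40000, seed = 77, genome_id = "g")
  loci <- mine_genome(g$sequence, "g", profs)
  expect_length(loci, 3L)
  for (l in loci) {
    expect_true(l$anchor$genome_start >= l$window[1])
    expect_true(l$anchor$genome_end <= l$window[2])
    expect_equal(l$classification == "INDIVIDUAL_RNH",
                 nrow(l$rt_hits) == 0L)
  }
  expect_setequal(vapply(loci, `[[`, character(1), "classification"),
                  c("LTR_RT", "NONLTR_RT", "INDIVIDUAL_RNH"))
})

test_that("count_table matches an independent recount, zeros as dashes", {
  df <- data.frame(
    genome_id = c("g1", "g1", "g1", "g1", "g1", "g1", "g2"),
    group = c("Chronos", "Chronos", "Chronos", "L1", "L1", "fmRNH",
              "Utopia"),
    stringsAsFactors = FALSE)
  tab <- count_table(df, genome_ids = c("g1", "g2"))
  expect_equal(unname(tab["g1", c("Chronos", "Archon", "L1", "Utopia",
                                  "fmRNH")]),
               c(3L, 0L, 2L, 0L, 1L))
  expect_equal(sum(tab["g1", ]), 6L)
  expect_equal(sum(tab["g2", ]), 1L)
  # independent recount
  for (g in rownames(tab))
    for (cc in colnames(tab))
      expect_equal(tab[g, cc],
                   sum(df$genome_id == g & df$group == cc))
  # empty input keeps genome rows, all zero
  tab0 <- count_table(df[0, ], genome_ids = c("g1", "g2"))
  expect_equal(sum(tab0), 0L)
  expect_equal(rownames(tab0), c("g1", "g2"))
  # zero rendered as '-'
  path <- tempfile()
  on.exit(unlink(path))
  write_count_table(tab, path)
  txt <- readLines(path)
  expect_true(any(grepl("\t-", txt)))
})
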