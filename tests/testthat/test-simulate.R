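# Synthetic templates, copy mutation, genome assembly and truth scoring.

test_that("element templates match their stated architectures", {
  tpl <- element_templates()
  expect_equal(tpl$Chronos$architecture,
               c("PR", "RT", "gRH", "aRH", "IN", "CHD"))
  expect_equal(tpl$Archon$architecture, c("PR", "RT", "gRH", "aRH", "IN"))
  expect_equal(tpl$L1$architecture, c("EN", "RT", "CCHC", "aRH"))
  expect_equal(tpl$Utopia$architecture, c("RT", "aRH", "RLE"))
  # LTR groups carry terminal repeats; the repeats are identical copies
  for (g in c("Chronos", "Archon")) {
    f <- tpl[[g]]$features
    l5 <- f[f$type == "LTR5", ]
    l3 <- f[f$type == "LTR3", ]
    expect_equal(substr(tpl[[g]]$dna, l5$start + 1, l5$end),
                 substr(tpl[[g]]$dna, l3$start + 1, l3$end))
  }
  # domain sub-features translate back to their protein segments
  f <- tpl$Utopia$features
  arnh <- f[f$type == "domain:aRNH", ]
  nt <- substr(tpl$Utopia$dna, arnh$start + 1, arnh$end)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           no.init.codon = TRUE))
  expect_equal(aa, retromine:::group_variants()$aRNH$Utopia)
})

test_that("mutate_copy hits its divergence and is seed-reproducible", {
  tpl <- element_templates()$Utopia
  same <- mutate_copy(tpl, 0, indel_rate = 0, seed = 5)
  expect_identical(same$dna, tpl$dna)
  expect_identical(same$features, tpl$features)

  a <- mutate_copy(tpl, 0.1, seed = 8)
  b <- mutate_copy(tpl, 0.1, seed = 8)
  expect_identical(a$dna, b$dna)
  expect_false(identical(a$dna, tpl$dna))

  # realized substitution rate within binomial bounds on a 10 kb template
  set.seed(6)
  long <- list(dna = random_dna_str(10000),
               features = element_templates()$Utopia$features[0, ])
  mut <- mutate_copy(long, 0.1, indel_rate = 0, seed = 12)
  x <- strsplit(long$dna, "")[[1]]
  y <- strsplit(mut$dna, "")[[1]]
  p <- mean(x != y)
  expect_gte(p, 0.08)
  expect_lte(p, 0.12)

  # targeted catalytic degradation changes the audited residues
  chron <- mutate_copy(element_templates()$Chronos, 0, indel_rate = 0,
                       seed = 3, target_catalytic = "aRNH")
  f <- chron$features[chron$features$type == "domain:aRNH", ]
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(
    substr(chron$dna, f$start + 1, f$end)), no.init.codon = TRUE))
  res <- strsplit(aa, "")[[1]][retromine:::RNH_CATALYTIC_POSITIONS]
  expect_false(identical(res, c("D", "E", "D", "R", "D")))
})

test_that("build_genome plants the requested copies with exact truth", {
  spec <- data.frame(group = c("Chronos", "L1", "fmRNH"),
                     count = c(3L, 2L, 1L), divergence = 0.02)
  g <- build_genome(spec, 100000, seed = 21, genome_id = "gx")
  expect_equal(nrow(g$truth), 6L)
  planted <- sum(g$truth$end - g$truth$start)
  expect_equal(nchar(g$sequence), 100000L + planted)
  expect_true(all(g$truth$start >= 0 & g$truth$end <= nchar(g$sequence)))
  # non-overlapping insertions
  tr <- g$truth[order(g$truth$start), ]
  expect_true(all(head(tr$end, -1) <= tail(tr$start, -1)))
  # the planted copy really sits at the truth interval
  cp <- mutate_copy(element_templates()[[tr$group[1]]], 0.02,
                    seed = retromine:::child_seed(21, 1))
  # same seed, same genome
  g2 <- build_genome(spec, 100000, seed = 21, genome_id = "gx")
  expect_identical(g$sequence, g2$sequence)
  expect_identical(g$truth, g2$truth)

  # empty spec: pure background
  g0 <- build_genome(spec[0, ], 5000, seed = 2)
  expect_equal(nchar(g0$sequence), 5000L)
  expect_equal(nrow(g0$truth), 0L)

  # background GC is controlled
  g25 <- build_genome(spec[0, ], 500000, gc = 0.25, seed = 9)
  comp <- table(strsplit(g25$sequence, "")[[1]])
  gc <- (comp[["G"]] + comp[["C"]]) / 500000
  expect_gte(gc, 0.24)
  expect_lte(gc, 0.26)

  expect_error(build_genome(data.frame(group = "Chronos", count = 5L,
                                       divergence = 0),
                            10000, seed = 1),
               "infeasible")
})

test_that("evaluate_predictions applies the 50% reciprocal-overlap rule", {
  truth <- data.frame(genome_id = "g", start = c(100L, 5000L),
                      end = c(1100L, 6000L), label = c("A", "B"))
  # predictions identical to truth
  ev <- evaluate_predictions(truth, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(unname(diag(ev$confusion)), c(1L, 1L))

  # no predictions: recall 0, precision reported 1 with a flag
  ev0 <- evaluate_predictions(truth[0, ], truth)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 1)
  expect_true(ev0$precision_undefined)

  # a 40%-overlap prediction is a miss
  shifted <- data.frame(genome_id = "g", start = 700L, end = 1700L,
                        label = "A")
  ev40 <- evaluate_predictions(shifted, truth)
  expect_equal(ev40$n_matched, 0L)
  expect_equal(ev40$recall, 0)
})

test_that("seed alignments regenerate deterministically from templates", {
  s1 <- seed_alignments()
  s2 <- seed_alignments()
  expect_identical(s1, s2)
  # the shipped extdata seed alignments are exactly the regenerated ones
  for (fam in c("aRNH", "RT_LTR")) {
    shipped <- read_seed_alignment(
      system.file("extdata", "seeds", paste0(fam, ".fasta"),
                  package = "retromine"), name = fam)
    expect_equal(shipped$rows, s1[[fam]]$rows)
  }
  expect_setequal(names(s1), names(retromine:::DOMAIN_LENGTHS))
  for (sd in s1) {
    expect_gte(length(sd$rows), 2L)
    expect_equal(length(unique(nchar(sd$rows))), 1L)
  }
  # profiles built from them self-detect every undiverged domain
  profs <- default_profiles()
  tpl <- retromine:::domain_templates()
  for (fam in names(retromine:::DOMAIN_LENGTHS)) {
    h <- viterbi_search(profs[[fam]], tpl[[fam]])
    expect_equal(nrow(h), 1L)
  }
})
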