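# Synthetic-genome simulator: fixed protein/nucleotide templates for the
# four element architectures plus RT-free cellular RNH genes, divergence-
# controlled copy mutation, genome assembly with planted copies, and
# precision/recall scoring against the planted truth.
#
# All templates are synthetic: generated once from a fixed internal seed
# with canonical motifs embedded (D-E-D-R-D for aRNH, D-E-D-H-D for fmRNH,
# a CCHC zinc knuckle, a YVDD-like RT motif), so no third-party database
# sequence ships with the package and audit operations have exact
# expectations.

.retromine_cache <- new.env(parent = emptyenv())

TEMPLATE_SEED <- 600451L

# Domain lengths (aa) and catalytic layout shared by the RNH families.
DOMAIN_LENGTHS <- c(PR = 100L, RT_LTR = 240L, RT_nonLTR = 260L, gRNH = 130L,
                    aRNH = 140L, fmRNH = 140L, INT = 250L, CHD = 50L,
                    EN = 200L, RLE = 150L)
RNH_CATALYTIC_POSITIONS <- c(10L, 45L, 70L, 110L, 130L)
ARNH_CATALYTIC <- c("D", "E", "D", "R", "D")
FMRNH_CATALYTIC <- c("D", "E", "D", "H", "D")
GRNH_CATALYTIC <- c("N", "Q", "S", "K", "T")  # degenerate, non-canonical
RT_MOTIF_POS <- 150L                          # YVDD at 150..153 in both RTs

random_protein <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Substitute a fraction of residues, never touching `protect` (1-based).
mutate_protein <- function(protein, rate, protect = integer(0)) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(aa)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) aa[i] <- sample(setdiff(AA_ALPHABET, aa[i]), 1L)
  paste(aa, collapse = "")
}

set_positions <- function(protein, positions, residues) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  aa[positions] <- residues
  paste(aa, collapse = "")
}

# Base protein templates, one per profiled domain family, plus the CCHC
# zinc-knuckle segment (a motif, not a profile).
domain_templates <- function() {
  if (!is.null(.retromine_cache$domains)) return(.retromine_cache$domains)
  tpl <- with_seed(TEMPLATE_SEED, {
    base <- lapply(DOMAIN_LENGTHS, random_protein)
    base$aRNH <- set_positions(base$aRNH, RNH_CATALYTIC_POSITIONS,
                               ARNH_CATALYTIC)
    base$fmRNH <- set_positions(base$fmRNH, RNH_CATALYTIC_POSITIONS,
                                FMRNH_CATALYTIC)
    base$gRNH <- set_positions(base$gRNH, RNH_CATALYTIC_POSITIONS,
                               GRNH_CATALYTIC)
    base$RT_LTR <- set_positions(base$RT_LTR, RT_MOTIF_POS + 0:3,
                                 c("Y", "V", "D", "D"))
    base$RT_nonLTR <- set_positions(base$RT_nonLTR, RT_MOTIF_POS + 0:3,
                                    c("Y", "V", "D", "D"))
    cchc <- strsplit(random_protein(14L), "", fixed = TRUE)[[1]]
    cchc[c(1L, 4L, 9L, 14L)] <- c("C", "C", "H", "C")
    base$CCHC <- paste(cchc, collapse = "")
    base
  })
  .retromine_cache$domains <- tpl
  tpl
}

# Per-group domain variants.  Groups diverge from the family base template
# by fixed substitution loads (catalytic/motif residues protected) so that
# one family profile detects all groups while group identity remains
# resolvable by alignment and phylogeny.
group_variants <- function() {
  if (!is.null(.retromine_cache$variants)) return(.retromine_cache$variants)
  base <- domain_templates()
  v <- with_seed(TEMPLATE_SEED + 1L, {
    mk_arnh <- function(rate) mutate_protein(base$aRNH, rate,
                                             RNH_CATALYTIC_POSITIONS)
    mk_rt <- function(tpl, rate) mutate_protein(tpl, rate,
                                                RT_MOTIF_POS + 0:3)
    list(
      aRNH = list(Chronos = mk_arnh(0.18), Archon = mk_arnh(0.18),
                  L1 = mk_arnh(0.18), Utopia = mk_arnh(0.18),
                  cell = mk_arnh(0.28), outgroup = mk_arnh(0.30)),
      RT = list(Chronos = mk_rt(base$RT_LTR, 0.18),
                Archon = mk_rt(base$RT_LTR, 0.18),
                L1 = mk_rt(base$RT_nonLTR, 0.18),
                Utopia = mk_rt(base$RT_nonLTR, 0.18))
    )
  })
  .retromine_cache$variants <- v
  v
}

# Reverse-translate a protein to DNA with uniformly sampled synonymous
# codons (stop codons excluded from the table).
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

reverse_translate <- function(protein) {
  tab <- codons_by_aa()
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(aa, function(a) {
    cods <- tab[[a]]
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, character(1)), collapse = "")
}

# Assemble one ORF: ATG + codons + TAA.  `segments` is a named list of
# protein segments; returns nt string plus a feature table of the domain
# sub-intervals in ORF-local nt coordinates (0-based half-open).
build_orf <- function(segments) {
  prot <- paste(unlist(segments), collapse = "")
  nt <- paste0("ATG", reverse_translate(prot), "TAA")
  feats <- NULL
  aa_off <- 0L
  for (nm in names(segments)) {
    len <- nchar(segments[[nm]])
    fam <- sub("[0-9]+$", "", nm)
    if (fam %in% c(names(DOMAIN_LENGTHS), "CCHC")) {
      feats <- rbind(feats, data.frame(
        type = paste0("domain:", fam),
        start = 3L + 3L * aa_off, end = 3L + 3L * (aa_off + len),
        stringsAsFactors = FALSE))
    }
    aa_off <- aa_off + len
  }
  list(nt = nt, protein = paste0("M", prot), features = feats)
}

linkers <- function(n, len = 15L) {
  setNames(lapply(seq_len(n), function(i) random_protein(len)),
           paste0("linker", seq_len(n)))
}

#' Element and gene templates of the simulated world
#'
#' Returns the fixed synthetic templates for the four aRNH-carrying
#' retrotransposon architectures and the two RT-free cellular gene types:
#' * `Chronos`: LTR + ORF1(gag) + ORF2 `PR-RT-gRH-aRH-IN-CHD` + LTR,
#' * `Archon`: as Chronos but without the chromodomain,
#' * `L1`: ORF1 + ORF2 `EN-RT-CCHC-aRH` with the aRNH C-terminal,
#' * `Utopia`: single ORF `RT-aRH-RLE`,
#' * `aRNH_cell`: a lone cellular aRNH gene,
#' * `fmRNH`: a lone Fungi/Metazoa-type RNH gene.
#'
#' Each template carries its nucleotide sequence, a feature table of ORFs,
#' LTRs and domain sub-intervals (0-based half-open), and the expected
#' domain architecture labels.
#'
#' @return Named list of `element_template` objects.
#' @export
element_templates <- function() {
  if (!is.null(.retromine_cache$templates)) return(.retromine_cache$templates)
  base <- domain_templates()
  v <- group_variants()
  out <- with_seed(TEMPLATE_SEED + 2L, {
    ltr_chronos <- random_dna(300L)
    ltr_archon <- random_dna(300L)
    spacer <- function() random_dna(60L)

    mk_ltr_element <- function(group, ltr, with_chd) {
      gag <- random_protein(300L)
      lk <- linkers(6L)
      segs <- c(list(PR = base$PR), lk[1], list(RT_LTR = v$RT[[group]]),
                lk[2], list(gRNH = base$gRNH), lk[3],
                list(aRNH = v$aRNH[[group]]), lk[4],
                list(INT = base$INT))
      arch <- c("PR", "RT", "gRH", "aRH", "IN")
      if (with_chd) {
        segs <- c(segs, lk[5], list(CHD = base$CHD))
        arch <- c(arch, "CHD")
      }
      orf1 <- build_orf(list(GAG = gag))
      orf2 <- build_orf(segs)
      sp <- spacer()
      dna <- paste0(ltr, orf1$nt, sp, orf2$nt, ltr)
      o1 <- nchar(ltr)
      o2 <- o1 + nchar(orf1$nt) + nchar(sp)
      feats <- rbind(
        data.frame(type = c("LTR5", "ORF1", "ORF2", "LTR3"),
                   start = c(0L, o1, o2, o2 + nchar(orf2$nt)),
                   end = c(nchar(ltr), o1 + nchar(orf1$nt),
                           o2 + nchar(orf2$nt),
                           o2 + nchar(orf2$nt) + nchar(ltr)),
                   stringsAsFactors = FALSE),
        transform(orf2$features, start = start + o2, end = end + o2))
      structure(list(group = group, dna = dna, features = feats,
                     orf_proteins = list(ORF1 = orf1$protein,
                                         ORF2 = orf2$protein),
                     ltr_length = nchar(ltr), architecture = arch,
                     class_truth = "LTR_RT"),
                class = "element_template")
    }

    mk_l1 <- function() {
      orf1 <- build_orf(list(ORF1p = random_protein(300L)))
      lk <- linkers(4L)
      segs <- c(list(EN = base$EN), lk[1],
                list(RT_nonLTR = v$RT$L1), lk[2],
                list(CCHC = base$CCHC), lk[3],
                list(aRNH = v$aRNH$L1))
      orf2 <- build_orf(segs)
      sp <- spacer()
      dna <- paste0(orf1$nt, sp, orf2$nt, strrep("A", 20L))
      o2 <- nchar(orf1$nt) + nchar(sp)
      feats <- rbind(
        data.frame(type = c("ORF1", "ORF2"),
                   start = c(0L, o2),
                   end = c(nchar(orf1$nt), o2 + nchar(orf2$nt)),
                   stringsAsFactors = FALSE),
        transform(orf2$features, start = start + o2, end = end + o2))
      structure(list(group = "L1", dna = dna, features = feats,
                     orf_proteins = list(ORF1 = orf1$protein,
                                         ORF2 = orf2$protein),
                     ltr_length = 0L,
                     architecture = c("EN", "RT", "CCHC", "aRH"),
                     class_truth = "NONLTR_RT"),
                class = "element_template")
    }

    mk_utopia <- function() {
      lk <- linkers(2L)
      segs <- c(list(RT_nonLTR = v$RT$Utopia), lk[1],
                list(aRNH = v$aRNH$Utopia), lk[2],
                list(RLE = base$RLE))
      orf <- build_orf(segs)
      feats <- rbind(
        data.frame(type = "ORF", start = 0L, end = nchar(orf$nt),
                   stringsAsFactors = FALSE),
        orf$features)
      structure(list(group = "Utopia", dna = orf$nt, features = feats,
                     orf_proteins = list(ORF = orf$protein),
                     ltr_length = 0L,
                     architecture = c("RT", "aRH", "RLE"),
                     class_truth = "NONLTR_RT"),
                class = "element_template")
    }

    mk_gene <- function(group, prot, fam) {
      orf <- build_orf(setNames(list(prot), fam))
      feats <- rbind(
        data.frame(type = "ORF", start = 0L, end = nchar(orf$nt),
                   stringsAsFactors = FALSE),
        orf$features)
      structure(list(group = group, dna = orf$nt, features = feats,
                     orf_proteins = list(ORF = orf$protein),
                     ltr_length = 0L, architecture = fam,
                     class_truth = "INDIVIDUAL_RNH"),
                class = "element_template")
    }

    list(Chronos = mk_ltr_element("Chronos", ltr_chronos, TRUE),
         Archon = mk_ltr_element("Archon", ltr_archon, FALSE),
         L1 = mk_l1(),
         Utopia = mk_utopia(),
         aRNH_cell = mk_gene("aRNH_cell", v$aRNH$cell, "aRNH"),
         fmRNH = mk_gene("fmRNH", base$fmRNH, "fmRNH"))
  })
  .retromine_cache$templates <- out
  out
}

#' @export
print.element_template <- function(x, ...) {
  cat(sprintf("element_template '%s': %d nt, architecture %s\n",
              x$group, nchar(x$dna), paste(x$architecture, collapse = "-")))
  invisible(x)
}

#' Reference proteins for group assignment
#'
#' One representative coding protein per element group (the pol/ORF2
#' protein of the undiverged template), used as alignment subjects by
#' [assign_group()]; the analogue of seeding a similarity search with
#' known representative elements.
#'
#' @return Named list of protein strings.
#' @export
group_references <- function() {
  tpl <- element_templates()
  list(Chronos = tpl$Chronos$orf_proteins$ORF2,
       Archon = tpl$Archon$orf_proteins$ORF2,
       L1 = tpl$L1$orf_proteins$ORF2,
       Utopia = tpl$Utopia$orf_proteins$ORF)
}

#' Reference aRNH domain proteins per retrotransposon group
#'
#' Two slightly diverged copies per group (3% substitutions), so each
#' group forms a proper reference clade in the individual-aRNH clustering.
#'
#' @return Named character vector of aRNH domain proteins.
#' @export
arnh_references <- function() {
  if (!is.null(.retromine_cache$arnh_refs)) return(.retromine_cache$arnh_refs)
  v <- group_variants()
  refs <- with_seed(TEMPLATE_SEED + 3L, {
    out <- character(0)
    for (g in c("Chronos", "Archon", "L1", "Utopia")) {
      out[paste0(g, "_ref1")] <- v$aRNH[[g]]
      out[paste0(g, "_ref2")] <- mutate_protein(v$aRNH[[g]], 0.03,
                                                RNH_CATALYTIC_POSITIONS)
    }
    out
  })
  .retromine_cache$arnh_refs <- refs
  refs
}

#' Mutate an element copy to a target nucleotide divergence
#'
#' Substitutions are placed uniformly at the stated per-site rate (each
#' substituted site changes to one of the three other bases); short indels
#' (length 1-3, insertion or deletion with equal probability) are placed
#' at `indel_rate` per site.  Feature coordinates are projected through
#' the indels.  Catalytic residues of the RNH domains can be protected
#' from substitution, or targeted (forced to a non-canonical residue) to
#' build degenerate-active-site cases.
#'
#' @param template an [element_templates()] entry, or any list with `dna`
#'   and `features`.
#' @param divergence per-site substitution probability in `[0, 0.5]`.
#' @param indel_rate per-site indel probability; defaults to 1% of the
#'   substitution rate.
#' @param seed integer seed; the same seed reproduces the copy exactly.
#' @param protect_catalytic if TRUE, nucleotide positions of RNH catalytic
#'   codons are excluded from mutation.
#' @param target_catalytic optional domain family name (e.g. `"gRNH"`)
#'   whose catalytic codons are forcibly mutated to encode a different
#'   residue.
#' @return List with `dna`, projected `features`, and realized `nsub`,
#'   `nindel` counts.
#' @export
mutate_copy <- function(template, divergence, indel_rate = NULL, seed = 1L,
                        protect_catalytic = FALSE, target_catalytic = NULL) {
  stopifnot(divergence >= 0, divergence <= 0.5)
  if (is.null(indel_rate)) indel_rate <- divergence * 0.01
  dna <- strsplit(template$dna, "", fixed = TRUE)[[1]]
  feats <- template$features
  with_seed(seed, {
    cat_nt <- integer(0)
    rnh_feats <- feats[feats$type %in%
                         paste0("domain:", c("aRNH", "fmRNH", "gRNH")), ,
                       drop = FALSE]
    if (nrow(rnh_feats) > 0L) {
      for (i in seq_len(nrow(rnh_feats))) {
        codon_starts <- rnh_feats$start[i] +
          3L * (RNH_CATALYTIC_POSITIONS - 1L)
        cat_nt <- c(cat_nt, as.vector(outer(0:2, codon_starts, "+")) + 1L)
      }
    }
    # substitutions
    sites <- which(runif(length(dna)) < divergence)
    if (protect_catalytic) sites <- setdiff(sites, cat_nt)
    for (i in sites) dna[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                              dna[i]), 1L)
    nsub <- length(sites)
    # targeted catalytic degradation
    if (!is.null(target_catalytic)) {
      tf <- feats[feats$type == paste0("domain:", target_catalytic), ,
                  drop = FALSE]
      tab <- codons_by_aa()
      for (i in seq_len(nrow(tf))) {
        for (p in RNH_CATALYTIC_POSITIONS) {
          cs <- tf$start[i] + 3L * (p - 1L)
          cur <- paste(dna[(cs + 1L):(cs + 3L)], collapse = "")
          cur_aa <- as.character(Biostrings::GENETIC_CODE[cur])
          new_aa <- sample(setdiff(AA_ALPHABET, cur_aa), 1L)
          new_cod <- sample(tab[[new_aa]], 1L)
          dna[(cs + 1L):(cs + 3L)] <- strsplit(new_cod, "", fixed = TRUE)[[1]]
        }
      }
    }
    # indels, applied right to left so positions stay valid
    n_indel <- sum(runif(length(dna)) < indel_rate)
    nindel <- n_indel
    if (n_indel > 0L) {
      pos <- sort(sample(length(dna), n_indel), decreasing = TRUE)
      lens <- sample(1:3, n_indel, replace = TRUE)
      is_ins <- runif(n_indel) < 0.5
      for (j in seq_len(n_indel)) {
        p <- pos[j]
        if (is_ins[j]) {
          ins <- sample(c("A", "C", "G", "T"), lens[j], replace = TRUE)
          dna <- append(dna, ins, after = p)
          d <- lens[j]
          cut <- p
        } else {
          del_end <- min(length(dna), p + lens[j] - 1L)
          d <- -(del_end - p + 1L)
          dna <- dna[-(p:del_end)]
          cut <- p - 1L
        }
        feats$start <- ifelse(feats$start > cut,
                              pmax(cut, feats$start + d), feats$start)
        feats$end <- ifelse(feats$end > cut,
                            pmax(cut, feats$end + d), feats$end)
      }
    }
    list(dna = paste(dna, collapse = ""), features = feats,
         nsub = nsub, nindel = nindel)
  })
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Build a synthetic genome with planted elements
#'
#' Generates an i.i.d. background sequence at the stated GC content and
#' inserts mutated copies of the requested templates at uniformly drawn,
#' non-overlapping insertion points on random strands.  The final genome
#' length is the background length plus the summed copy lengths.
#'
#' @param plant_spec data.frame with columns `group` (a template name from
#'   [element_templates()]), `count`, `divergence`.
#' @param background_length background nucleotides.
#' @param gc background GC fraction.
#' @param seed integer seed; the same seed gives a byte-identical genome
#'   and truth.
#' @param genome_id identifier recorded in the truth table.
#' @return List with `genome_id`, `sequence`, `truth` (one row per planted
#'   copy: `genome_id, group, class_truth, start, end, strand, divergence`,
#'   0-based half-open) and `features` (per-copy domain/ORF/LTR
#'   sub-intervals in genome coordinates, keyed by `element_id`).
#' @export
build_genome <- function(plant_spec, background_length, gc = 0.5,
                         seed = 1L, genome_id = "genome_1") {
  tpl <- element_templates()
  bad <- setdiff(plant_spec$group, names(tpl))
  if (length(bad) > 0L) stop("unknown template group: ", bad[[1]])
  n_total <- sum(plant_spec$count)
  with_seed(seed, {
    copies <- list()
    k <- 0L
    for (r in seq_len(nrow(plant_spec))) {
      for (cc in seq_len(plant_spec$count[r])) {
        k <- k + 1L
        cp <- mutate_copy(tpl[[plant_spec$group[r]]],
                          plant_spec$divergence[r],
                          seed = child_seed(seed, k))
        cp$group <- plant_spec$group[r]
        cp$class_truth <- tpl[[plant_spec$group[r]]]$class_truth
        cp$divergence <- plant_spec$divergence[r]
        cp$strand <- sample(c("+", "-"), 1L)
        copies[[k]] <- cp
      }
    }
    total_planted <- sum(vapply(copies, function(cp) nchar(cp$dna),
                                numeric(1)))
    if (n_total > 0L && total_planted >= background_length)
      stop("infeasible packing: planted length exceeds background")
    background <- random_dna(background_length, gc = gc)
    points <- sort(sample(0:background_length, n_total, replace = FALSE))
    truth <- NULL
    feat_all <- NULL
    pieces <- character(0)
    prev <- 0L
    offset <- 0L
    for (k in seq_along(copies)) {
      cp <- copies[[k]]
      el_len <- nchar(cp$dna)
      dna <- cp$dna
      feats <- cp$features
      if (cp$strand == "-") {
        dna <- revcomp_chr(dna)
        s <- el_len - feats$end
        feats$end <- el_len - feats$start
        feats$start <- s
      }
      pieces <- c(pieces, substr(background, prev + 1L, points[k]), dna)
      gstart <- points[k] + offset
      truth <- rbind(truth, data.frame(
        genome_id = genome_id, element_id = sprintf("%s_el%02d", genome_id, k),
        group = cp$group, class_truth = cp$class_truth,
        start = gstart, end = gstart + el_len, strand = cp$strand,
        divergence = cp$divergence, stringsAsFactors = FALSE))
      if (nrow(feats) > 0L)
        feat_all <- rbind(feat_all, data.frame(
          genome_id = genome_id,
          element_id = sprintf("%s_el%02d", genome_id, k),
          type = feats$type, start = feats$start + gstart,
          end = feats$end + gstart, strand = cp$strand,
          stringsAsFactors = FALSE))
      prev <- points[k]
      offset <- offset + el_len
    }
    pieces <- c(pieces, substr(background, prev + 1L, background_length))
    if (is.null(truth))
      truth <- data.frame(genome_id = character(0), element_id = character(0),
                          group = character(0), class_truth = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), divergence = numeric(0),
                          stringsAsFactors = FALSE)
    list(genome_id = genome_id, sequence = paste(pieces, collapse = ""),
         truth = truth, features = feat_all)
  })
}

#' Simulate a set of genomes with a shared planting scheme
#'
#' @param n_genomes number of genomes.
#' @param plant_spec as in [build_genome()]; applied to every genome.
#' @param background_length,gc background parameters.
#' @param seed base seed; genome `i` uses a derived child seed.
#' @return List with `genomes` (named list of sequences), `truth` and
#'   `features` (row-bound across genomes).
#' @export
simulate_genomes <- function(n_genomes, plant_spec, background_length,
                             gc = 0.5, seed = 1L) {
  sims <- lapply(seq_len(n_genomes), function(i)
    build_genome(plant_spec, background_length, gc = gc,
                 seed = child_seed(seed, 1000 + i),
                 genome_id = sprintf("genome_%d", i)))
  list(genomes = setNames(lapply(sims, `[[`, "sequence"),
                          vapply(sims, `[[`, character(1), "genome_id")),
       truth = do.call(rbind, lapply(sims, `[[`, "truth")),
       features = do.call(rbind, lapply(sims, `[[`, "features")))
}

#' Score predictions against the planted truth
#'
#' A prediction matches a truth record when both are on the same genome
#' and their intervals overlap reciprocally by at least `min_overlap`.
#' Matching is greedy by decreasing overlap, one-to-one.  With no
#' predictions, precision is undefined and reported as 1 with
#' `precision_undefined = TRUE`.
#'
#' @param predictions data.frame with `genome_id, start, end, label`.
#' @param truth data.frame with `genome_id, start, end, label`.
#' @param min_overlap reciprocal-overlap threshold (default 0.5).
#' @return List: `precision`, `recall`, `n_matched`, `matches` (indices and
#'   labels of matched pairs), `confusion` (truth x prediction label table
#'   over matches), `precision_undefined`.
#' @export
evaluate_predictions <- function(predictions, truth, min_overlap = 0.5) {
  np <- nrow(predictions)
  nt <- nrow(truth)
  cand <- NULL
  for (i in seq_len(np)) {
    same <- which(truth$genome_id == predictions$genome_id[i])
    for (j in same) {
      ro <- reciprocal_overlap(predictions$start[i], predictions$end[i],
                               truth$start[j], truth$end[j])
      if (ro >= min_overlap)
        cand <- rbind(cand, data.frame(pred = i, truth = j, overlap = ro))
    }
  }
  matches <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(-cand$overlap), , drop = FALSE]
    used_p <- logical(np)
    used_t <- logical(nt)
    for (r in seq_len(nrow(cand))) {
      i <- cand$pred[r]; j <- cand$truth[r]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- TRUE
        used_t[j] <- TRUE
        matches <- rbind(matches, data.frame(
          pred = i, truth = j, overlap = cand$overlap[r],
          pred_label = predictions$label[i], truth_label = truth$label[j],
          stringsAsFactors = FALSE))
      }
    }
  }
  n_matched <- if (is.null(matches)) 0L else nrow(matches)
  precision_undefined <- np == 0L
  list(
    precision = if (precision_undefined) 1 else n_matched / np,
    recall = if (nt == 0L) 1 else n_matched / nt,
    n_matched = n_matched,
    matches = matches,
    confusion = if (n_matched > 0L)
      table(truth = matches$truth_label, prediction = matches$pred_label)
    else table(truth = character(0), prediction = character(0)),
    precision_undefined = precision_undefined
  )
}

#' Seed alignments derived from the package's own domain templates
#'
#' For every profiled domain family, the seed alignment is the base
#' template plus `n_copies` substitution-only mutated copies (so the rows
#' align trivially, gap-free).  These are the alignments from which
#' [default_profiles()] are built; real externally curated alignments can
#' be supplied through [read_seed_alignment()] instead.
#'
#' @param n_copies mutated copies per family (default 9).
#' @param sub_rate per-residue substitution rate of the copies (default
#'   0.08).
#' @return Named list of [seed_alignment()] objects.
#' @export
seed_alignments <- function(n_copies = 9L, sub_rate = 0.08) {
  base <- domain_templates()
  fams <- names(DOMAIN_LENGTHS)
  out <- with_seed(TEMPLATE_SEED + 4L, {
    lapply(setNames(fams, fams), function(f) {
      protect <- if (f %in% c("aRNH", "fmRNH", "gRNH"))
        RNH_CATALYTIC_POSITIONS
      else if (f %in% c("RT_LTR", "RT_nonLTR")) RT_MOTIF_POS + 0:3
      else integer(0)
      rows <- c(base[[f]], vapply(seq_len(n_copies), function(i)
        mutate_protein(base[[f]], sub_rate, protect), character(1)))
      seed_alignment(rows, name = f, source = "synthetic template family")
    })
  })
  out
}

#' Default domain profiles of the package
#'
#' Profiles for all ten domain families, built from [seed_alignments()].
#' RNH-family profiles carry the catalytic match-state indices used by
#' [audit_catalytic_residues()].  Cached per session.
#'
#' @param score_threshold bit-score threshold applied to every profile.
#' @return Named list of `domain_profile` objects.
#' @export
default_profiles <- function(score_threshold = 30) {
  key <- paste0("profiles_", score_threshold)
  if (!is.null(.retromine_cache[[key]])) return(.retromine_cache[[key]])
  seeds <- seed_alignments()
  profs <- lapply(seeds, function(sd) {
    cat_cols <- if (sd$name %in% c("aRNH", "fmRNH", "gRNH"))
      RNH_CATALYTIC_POSITIONS
    else NULL
    build_profile(sd, score_threshold = score_threshold,
                  catalytic_columns = cat_cols)
  })
  .retromine_cache[[key]] <- profs
  profs
}
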