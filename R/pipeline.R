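# End-to-end driver: simulate (or read) genomes, build profiles, mine,
# annotate, cluster individual aRNHs, and write the report bundle.

# Demo planting scheme derived from a config.
config_plant_spec <- function(cfg) {
  data.frame(
    group = c("Chronos", "Archon", "L1", "Utopia", "aRNH_cell", "fmRNH"),
    count = c(rep(cfg$n_per_group, 4L), cfg$n_cell_arnh, cfg$n_fmrnh),
    divergence = cfg$divergence,
    stringsAsFactors = FALSE)
}

#' Run the full mining pipeline
#'
#' Executes all stages in order: obtain genomes (simulated with planted
#' elements, or read from `config$genomes_fasta`), build the default
#' domain profiles, mine aRNH-anchored loci and fmRNH genes, annotate
#' every locus, cluster the RT-free individual aRNHs against the
#' retrotransposon reference aRNHs, and write the report bundle to
#' `out_dir`: `loci.gff`, `loci.tsv`, `annotations.gff`, `counts.tsv`,
#' `trees.nwk`, `evaluation.tsv` (when truth is available), and
#' `run.log`.  Reruns with the same configuration produce byte-identical
#' outputs.
#'
#' @param config a [default_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with `loci` (annotated locus list),
#'   `loci_df`, `counts`, `clustering`, `evaluation` and `files`.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  stopifnot(inherits(config, "retromine_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- genomes ---------------------------------------------------------
  truth <- NULL
  sim <- NULL
  genomes <- stage("genomes", {
    if (is.null(config$genomes_fasta)) {
      sim <- simulate_genomes(config$n_genomes, config_plant_spec(config),
                              config$genome_length, gc = config$gc,
                              seed = config$seed)
      truth <- sim$truth
      write_fasta(sim$genomes, file.path(out_dir, "genomes.fasta"))
      write_truth_gff(sim, file.path(out_dir, "truth.gff"))
      sim$genomes
    } else {
      read_fasta(config$genomes_fasta)
    }
  })
  if (!is.null(config$truth_gff)) {
    tg <- read_gff(config$truth_gff)
    tg <- tg[tg$type == "retrotransposon" | tg$type == "gene", , drop = FALSE]
    truth <- data.frame(genome_id = tg$seqid, group = tg$group,
                        class_truth = tg$class_truth,
                        start = tg$start, end = tg$end,
                        stringsAsFactors = FALSE)
  }
  say("genomes: %d sequences, %.0f nt total", length(genomes),
      sum(nchar(genomes)))

  # -- profiles --------------------------------------------------------
  profiles <- stage("profiles",
                    default_profiles(config$score_threshold))
  say("profiles: %d families at %.1f bits", length(profiles),
      config$score_threshold)

  # -- mining ----------------------------------------------------------
  loci <- stage("mining", {
    out <- list()
    for (g in names(genomes)) {
      la <- mine_genome(genomes[[g]], g, profiles,
                        half_width = config$arnh_half_width,
                        min_identity = config$group_min_identity,
                        min_ratio = config$group_min_ratio)
      lf <- mine_fmrnh(genomes[[g]], g, profiles,
                       flank = config$fmrnh_flank)
      out <- c(out, la, lf)
    }
    out
  })
  say("mining: %d loci (%d RT-associated, %d individual)",
      length(loci),
      sum(vapply(loci, function(l) l$classification != "INDIVIDUAL_RNH",
                 logical(1))),
      sum(vapply(loci, function(l) l$classification == "INDIVIDUAL_RNH",
                 logical(1))))

  # -- annotation ------------------------------------------------------
  loci <- stage("annotation", lapply(loci, function(l)
    annotate_locus(l, genomes[[l$genome_id]], profiles,
                   min_protein_length = config$orf_min_length,
                   ltr_min_len = config$ltr_min_len,
                   ltr_min_identity = config$ltr_min_identity,
                   chd_gap = config$chd_gap)))
  say("annotation: %d loci annotated", length(loci))

  # -- individual-aRNH clustering --------------------------------------
  clustering <- NULL
  loci <- stage("phylo", {
    ind <- which(vapply(loci, function(l)
      identical(l$group, "individual_aRNH"), logical(1)))
    if (length(ind) > 0L) {
      prots <- vapply(ind, function(i) {
        l <- loci[[i]]
        win <- substr(genomes[[l$genome_id]], l$window[1] + 1L,
                      l$window[2])
        hit_proteins(win, shift_back(l$anchor, l$window[1]), margin = 0L)
      }, character(1))
      names(prots) <- sprintf("ind_%03d", seq_along(ind))
      clustering <- cluster_individual_arnh(
        prots, profiles$aRNH, support_threshold = config$support_threshold,
        n_reps = config$bootstrap_reps,
        seed = child_seed(config$seed, 77))
      for (j in seq_along(ind))
        loci[[ind[j]]]$group <- paste0("aRNH_", clustering$labels[[j]])
    }
    loci
  })
  say("phylo: %d individual aRNHs clustered",
      if (is.null(clustering)) 0L else length(clustering$labels))

  # -- reports ---------------------------------------------------------
  files <- stage("reports", {
    loci_df <- loci_table(loci)
    counts <- count_table(loci_df, genome_ids = names(genomes))
    f <- list(
      loci_tsv = write_tsv(loci_df, file.path(out_dir, "loci.tsv")),
      loci_gff = write_loci_gff(loci, file.path(out_dir, "loci.gff")),
      ann_gff = write_annotation_gff(loci,
                                     file.path(out_dir, "annotations.gff")),
      counts = write_count_table(counts, file.path(out_dir, "counts.tsv")))
    trees <- list()
    if (!is.null(clustering) && !is.null(clustering$tree))
      trees$individual_aRNH <- clustering$tree
    if (length(trees) > 0L)
      f$trees <- write_trees(trees, file.path(out_dir, "trees.nwk"))
    if (!is.null(truth)) {
      pred <- loci_table(loci)
      ev <- evaluate_predictions(
        data.frame(genome_id = pred$genome_id, start = pred$span_start,
                   end = pred$span_end, label = pred$classification,
                   stringsAsFactors = FALSE),
        data.frame(genome_id = truth$genome_id, start = truth$start,
                   end = truth$end, label = truth$class_truth,
                   stringsAsFactors = FALSE))
      ev_df <- data.frame(metric = c("precision", "recall", "n_matched",
                                     "n_predicted", "n_truth"),
                          value = c(ev$precision, ev$recall, ev$n_matched,
                                    nrow(pred), nrow(truth)))
      f$evaluation <- write_tsv(ev_df, file.path(out_dir, "evaluation.tsv"))
      say("evaluation: precision %.3f recall %.3f", ev$precision,
          ev$recall)
      attr(f, "evaluation") <- ev
    }
    f
  })
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(loci = loci, loci_df = loci_table(loci),
                 counts = count_table(loci_table(loci),
                                      genome_ids = names(genomes)),
                 clustering = clustering,
                 evaluation = attr(files, "evaluation"),
                 files = files, log = log_lines))
}

# Truth tables -> GFF3 (element parents plus domain/ORF/LTR children).
write_truth_gff <- function(sim, path) {
  el <- sim$truth
  feats <- data.frame(
    seqid = el$genome_id,
    type = ifelse(el$class_truth == "INDIVIDUAL_RNH", "gene",
                  "retrotransposon"),
    start = el$start, end = el$end, strand = el$strand,
    ID = el$element_id, Parent = NA_character_,
    group = el$group, class_truth = el$class_truth,
    divergence = el$divergence,
    stringsAsFactors = FALSE)
  if (!is.null(sim$features) && nrow(sim$features) > 0L) {
    fx <- sim$features
    feats <- rbind(feats, data.frame(
      seqid = fx$genome_id,
      type = sub("^domain:", "", paste0(fx$type, "_part")),
      start = fx$start, end = fx$end, strand = fx$strand,
      ID = paste0(fx$element_id, "_", seq_len(nrow(fx))),
      Parent = fx$element_id, group = NA_character_,
      class_truth = NA_character_, divergence = NA_real_,
      stringsAsFactors = FALSE))
  }
  write_gff(feats, path)
}

write_loci_gff <- function(loci, path) {
  rows <- NULL
  for (i in seq_along(loci)) {
    l <- loci[[i]]
    id <- sprintf("locus_%03d", i)
    rows <- rbind(rows,
      data.frame(seqid = l$genome_id, type = "candidate_locus",
                 start = l$element_span[1], end = l$element_span[2],
                 strand = "*", ID = id, Parent = NA_character_,
                 Name = l$group, classification = l$classification,
                 score = NA_real_, stringsAsFactors = FALSE),
      data.frame(seqid = l$genome_id, type = "protein_match",
                 start = l$anchor$genome_start, end = l$anchor$genome_end,
                 strand = "*", ID = paste0(id, "_anchor"), Parent = id,
                 Name = l$anchor$profile_name,
                 classification = NA_character_,
                 score = l$anchor$score, stringsAsFactors = FALSE))
    if (nrow(l$rt_hits) > 0L)
      rows <- rbind(rows, data.frame(
        seqid = l$genome_id, type = "protein_match",
        start = l$rt_hits$genome_start, end = l$rt_hits$genome_end,
        strand = "*",
        ID = sprintf("%s_rt%d", id, seq_len(nrow(l$rt_hits))),
        Parent = id, Name = l$rt_hits$profile_name,
        classification = NA_character_, score = l$rt_hits$score,
        stringsAsFactors = FALSE))
  }
  if (is.null(rows))
    rows <- data.frame(seqid = character(0), type = character(0),
                       start = integer(0), end = integer(0))
  write_gff(rows, path)
}

write_annotation_gff <- function(loci, path) {
  rows <- NULL
  for (i in seq_along(loci)) {
    l <- loci[[i]]
    id <- sprintf("element_%03d", i)
    rows <- rbind(rows, data.frame(
      seqid = l$genome_id, type = "mobile_genetic_element",
      start = l$element_span[1], end = l$element_span[2], strand = "*",
      ID = id, Parent = NA_character_, Name = l$group,
      architecture = paste(l$architecture$labels, collapse = "-"),
      score = NA_real_, stringsAsFactors = FALSE))
    if (!is.null(l$domain_hits) && nrow(l$domain_hits) > 0L)
      rows <- rbind(rows, data.frame(
        seqid = l$genome_id, type = "protein_match",
        start = l$domain_hits$genome_start, end = l$domain_hits$genome_end,
        strand = "*",
        ID = sprintf("%s_dom%d", id, seq_len(nrow(l$domain_hits))),
        Parent = id, Name = l$domain_hits$profile_name,
        architecture = NA_character_, score = l$domain_hits$score,
        stringsAsFactors = FALSE))
    if (!is.null(l$orfs) && nrow(l$orfs) > 0L)
      rows <- rbind(rows, data.frame(
        seqid = l$genome_id, type = "open_reading_frame",
        start = l$orfs$start, end = l$orfs$end, strand = l$orfs$strand,
        ID = sprintf("%s_orf%d", id, seq_len(nrow(l$orfs))),
        Parent = id, Name = NA_character_,
        architecture = NA_character_, score = NA_real_,
        stringsAsFactors = FALSE))
    if (!is.null(l$ltr_pair))
      rows <- rbind(rows, data.frame(
        seqid = l$genome_id, type = "long_terminal_repeat",
        start = c(l$ltr_pair$ltr5[1], l$ltr_pair$ltr3[1]),
        end = c(l$ltr_pair$ltr5[2], l$ltr_pair$ltr3[2]), strand = "*",
        ID = paste0(id, c("_ltr5", "_ltr3")), Parent = id,
        Name = NA_character_, architecture = NA_character_,
        score = rep(100 * l$ltr_pair$identity, 2L),
        stringsAsFactors = FALSE))
  }
  if (is.null(rows))
    rows <- data.frame(seqid = character(0), type = character(0),
                       start = integer(0), end = integer(0))
  write_gff(rows, path)
}
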