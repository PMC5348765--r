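# Four-step mining: anchor on aRNH hits, expand windows, detect
# co-localized RT evidence, split loci into LTR-RT / non-LTR-RT /
# individual-RNH, assign group identity, and tabulate counts per genome.

#' Expand an anchor hit into a candidate window
#'
#' The window reaches `half_width` nucleotides to each side of the anchor,
#' clamped at the contig edges ("when possible").
#'
#' @param anchor one-row hit data.frame (needs `genome_start`,
#'   `genome_end`).
#' @param genome_length contig length in nt.
#' @param half_width expansion per side; 10,000 nt for aRNH anchors,
#'   1,000 nt for fmRNH.
#' @return Integer `c(start, end)`, 0-based half-open.
#' @export
expand_window <- function(anchor, genome_length, half_width = 10000L) {
  s <- anchor$genome_start
  e <- anchor$genome_end
  stopifnot(s >= 0, e <= genome_length, e > s)
  c(max(0L, as.integer(s - half_width)),
    min(as.integer(genome_length), as.integer(e + half_width)))
}

#' Merge candidate loci whose anchors duplicate one another
#'
#' Anchors with more than 50% reciprocal genome overlap (typically the
#' same domain seen in two frames) are collapsed to the best-scoring one.
#' Anchors in *different* frames within `merge_gap` nt of each other are
#' also collapsed: a frameshift inside a degenerate domain splits one
#' anchor into two adjacent partial hits on different frames.  Nearby
#' anchors in the same frame remain separate loci (tandem copies).
#'
#' @param loci list of candidate loci (each with `$anchor` one-row hit and
#'   `$window`).
#' @param merge_gap maximum gap for collapsing different-frame anchor
#'   fragments (default 600 nt).
#' @return Filtered list, sorted by anchor genome start.
#' @export
merge_anchor_windows <- function(loci, merge_gap = 600L) {
  if (length(loci) == 0L) return(loci)
  sc <- vapply(loci, function(l) l$anchor$score, numeric(1))
  ord <- order(-sc)
  keep <- list()
  for (i in ord) {
    li <- loci[[i]]
    dup <- FALSE
    for (lk in keep) {
      if (!identical(lk$genome_id, li$genome_id)) next
      ro <- reciprocal_overlap(li$anchor$genome_start, li$anchor$genome_end,
                               lk$anchor$genome_start, lk$anchor$genome_end)
      gap <- max(li$anchor$genome_start, lk$anchor$genome_start) -
        min(li$anchor$genome_end, lk$anchor$genome_end)
      # frameshift fragments cover complementary profile states; two
      # distinct nearby copies both cover (nearly) all states
      state_ov <- min(li$anchor$kend, lk$anchor$kend) -
        max(li$anchor$kstart, lk$anchor$kstart) + 1L
      complementary <- state_ov <= 0.5 * min(
        li$anchor$kend - li$anchor$kstart + 1L,
        lk$anchor$kend - lk$anchor$kstart + 1L)
      if (ro > 0.5 ||
          (li$anchor$frame != lk$anchor$frame && gap <= merge_gap &&
           complementary)) {
        dup <- TRUE
        break
      }
    }
    if (!dup) keep[[length(keep) + 1L]] <- li
  }
  keep[order(vapply(keep, function(l) l$anchor$genome_start, numeric(1)))]
}

#' Classify a candidate window by reverse-transcriptase evidence
#'
#' Scans the window with both RT profiles.  No hit from either profile
#' gives `INDIVIDUAL_RNH`; hits from exactly one profile give that class;
#' when both profiles hit, the class of the higher-scoring RT hit wins
#' (ties resolve to `LTR_RT`, with a message).
#'
#' @param window_sequence DNA string of the expanded window.
#' @param rt_ltr_profile,rt_nonltr_profile RT domain profiles.
#' @param frames optional precomputed [translate_six_frames()] of the
#'   window.
#' @return List with `classification` (one of `LTR_RT`, `NONLTR_RT`,
#'   `INDIVIDUAL_RNH`) and `rt_hits` (hit data.frame in window
#'   coordinates).
#' @export
classify_locus <- function(window_sequence, rt_ltr_profile,
                           rt_nonltr_profile, frames = NULL) {
  if (is.null(frames)) frames <- translate_six_frames(window_sequence)
  h_ltr <- scan_frames(frames, rt_ltr_profile, target_id = "window")
  h_non <- scan_frames(frames, rt_nonltr_profile, target_id = "window")
  rt_hits <- rbind(h_ltr, h_non)
  if (nrow(rt_hits) == 0L)
    return(list(classification = "INDIVIDUAL_RNH", rt_hits = rt_hits))
  best_ltr <- if (nrow(h_ltr) > 0L) max(h_ltr$score) else -Inf
  best_non <- if (nrow(h_non) > 0L) max(h_non$score) else -Inf
  cls <- if (best_ltr > best_non) "LTR_RT"
         else if (best_non > best_ltr) "NONLTR_RT"
         else {
           message("RT score tie; resolving to LTR_RT")
           "LTR_RT"
         }
  list(classification = cls, rt_hits = rt_hits)
}

# Best local-alignment score and identity of a query protein set against
# one reference.  Queries are scanned as-is (stops allowed); the best
# scoring query wins.
best_alignment <- function(queries, reference, submat) {
  best <- list(score = -Inf, identity = 0)
  ref <- Biostrings::AAString(reference)
  for (q in queries) {
    if (nchar(q) < 10L) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), ref, type = "local",
      substitutionMatrix = submat, gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(aln)
    if (sc > best$score)
      best <- list(score = sc, identity = Biostrings::pid(aln) / 100)
  }
  best
}

# BLOSUM62 extended with neutral rows/columns for '*' and 'X' so translated
# frames with stops can be aligned directly.
blosum62_ext <- function() {
  if (!is.null(.retromine_cache$blosum)) return(.retromine_cache$blosum)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  m <- data_env$BLOSUM62
  .retromine_cache$blosum <- m
  m
}

#' Assign a classified locus to an element group
#'
#' Aligns the locus proteins locally (BLOSUM62, affine gaps) against every
#' group reference; the best-scoring group wins when its identity reaches
#' `min_identity` and its score exceeds the runner-up by `min_ratio`.
#' When the two best references are Chronos and Archon, the presence of a
#' chromodomain hit overrides the ranking (CHD present implies Chronos,
#' absent implies Archon) since these two Ty3/Gypsy groups differ exactly
#' by the INT-CHD fusion.
#'
#' @param locus_proteins character vector of candidate coding proteins
#'   (e.g. translated segments under the locus's domain hits).
#' @param references named list of group reference proteins
#'   ([group_references()]).
#' @param min_identity minimum alignment identity (default 0.35).
#' @param min_ratio minimum best/second-best score ratio (default 1.2).
#' @param chd_present optional logical: chromodomain hit in the locus.
#' @return Group label, or `"unassigned"`.
#' @export
assign_group <- function(locus_proteins, references,
                         min_identity = 0.35, min_ratio = 1.2,
                         chd_present = NA) {
  if (length(references) == 0L) stop("references must be non-empty")
  submat <- blosum62_ext()
  res <- lapply(references, function(r)
    best_alignment(locus_proteins, r, submat))
  scores <- vapply(res, `[[`, numeric(1), "score")
  ord <- order(-scores)
  top <- ord[1]
  if (!is.finite(scores[top])) return("unassigned")
  gypsy_pair <- length(scores) >= 2L &&
    setequal(names(references)[ord[1:2]], c("Chronos", "Archon"))
  if (gypsy_pair && isTRUE(chd_present)) top <- which(names(references) == "Chronos")
  if (gypsy_pair && identical(chd_present, FALSE))
    top <- which(names(references) == "Archon")
  if (res[[top]]$identity < min_identity) return("unassigned")
  second <- if (length(scores) >= 2L) max(scores[-top]) else -Inf
  ratio_ok <- second <= 0 || scores[top] / second >= min_ratio ||
    (gypsy_pair && !is.na(chd_present))
  if (!ratio_ok) return("unassigned")
  names(references)[top]
}

# Keep the connected component of hits containing the anchor interval:
# hits are chained when their genome intervals lie within `link_gap` nt of
# each other.  A ±10 kb window can contain a neighboring element; only
# evidence chained to the anchor belongs to this locus.
chain_hits <- function(hits, anchor_start, anchor_end, link_gap = 1200L) {
  if (nrow(hits) == 0L) return(hits)
  iv <- rbind(data.frame(s = anchor_start, e = anchor_end),
              data.frame(s = hits$genome_start, e = hits$genome_end))
  n <- nrow(iv)
  ord <- order(iv$s, iv$e)
  comp <- integer(n)
  cur <- 0L
  reach <- -Inf
  for (i in ord) {
    if (iv$s[i] > reach + link_gap) cur <- cur + 1L
    comp[i] <- cur
    reach <- max(reach, iv$e[i])
  }
  hits[comp[-1] == comp[1], , drop = FALSE]
}

# Translated protein segments under a set of genome-coordinate hits,
# padded by `margin` residues, taken from the hit's own frame.
hit_proteins <- function(sequence, hits, margin = 50L, frames = NULL) {
  if (nrow(hits) == 0L) return(character(0))
  if (is.null(frames)) frames <- translate_six_frames(sequence)
  frame_of <- vapply(frames, `[[`, numeric(1), "frame")
  out <- character(0)
  for (i in seq_len(nrow(hits))) {
    fr <- frames[[match(hits$frame[i], frame_of)]]
    a <- max(0L, hits$protein_start[i] - margin)
    b <- min(nchar(fr$protein), hits$protein_end[i] + margin)
    out <- c(out, substr(fr$protein, a + 1L, b))
  }
  out
}

#' Mine one genome for aRNH-anchored loci
#'
#' The four mining steps: (1) scan the genome with the aRNH profile;
#' (2) expand each anchor to a window of `half_width` per side;
#' (3) scan each window with both RT profiles; (4) classify each locus as
#' LTR-RT, non-LTR-RT or individual aRNH, and assign RT-positive loci to a
#' group by reference alignment (with CHD arbitration for Chronos/Archon).
#'
#' @param sequence genome/contig DNA string.
#' @param genome_id identifier for reporting.
#' @param profiles named profile list ([default_profiles()]); `aRNH`,
#'   `RT_LTR`, `RT_nonLTR` and `CHD` are used here.
#' @param references group references ([group_references()]).
#' @param half_width window expansion per side (default 10,000 nt).
#' @param min_identity,min_ratio group-assignment thresholds.
#' @param link_gap maximum nt gap when chaining domain hits to the anchor;
#'   evidence further away (a neighboring element caught in the wide
#'   window) does not count for this locus.
#' @return List of candidate loci; each locus is a list with `genome_id`,
#'   `anchor` (one-row hit), `window` (`c(start, end)`), `rt_hits`,
#'   `chd_hits`, `classification`, `group` and `element_span` (initially
#'   the anchor/domain hull, refined by [annotate_locus()]).
#' @export
mine_genome <- function(sequence, genome_id, profiles,
                        references = group_references(),
                        half_width = 10000L,
                        min_identity = 0.35, min_ratio = 1.2,
                        link_gap = 1200L) {
  L <- nchar(sequence)
  anchors <- scan_genome(sequence, profiles$aRNH, target_id = genome_id)
  loci <- lapply(seq_len(nrow(anchors)), function(i) {
    anchor <- anchors[i, , drop = FALSE]
    list(genome_id = genome_id, anchor = anchor,
         window = expand_window(anchor, L, half_width))
  })
  loci <- merge_anchor_windows(loci)
  # clip each window at the midpoint toward the nearest neighboring
  # anchor, so adjacent elements do not pool evidence
  if (length(loci) > 1L) {
    a_starts <- vapply(loci, function(l) l$anchor$genome_start, numeric(1))
    a_ends <- vapply(loci, function(l) l$anchor$genome_end, numeric(1))
    for (i in seq_along(loci)) {
      lb <- a_ends[a_ends <= a_starts[i]]
      rb <- a_starts[a_starts >= a_ends[i]]
      w <- loci[[i]]$window
      if (length(lb) > 0L)
        w[1] <- max(w[1], as.integer((max(lb) + a_starts[i]) %/% 2))
      if (length(rb) > 0L)
        w[2] <- min(w[2], as.integer((a_ends[i] + min(rb)) %/% 2 + 1L))
      loci[[i]]$window <- w
    }
  }
  lapply(loci, function(locus) {
    win <- substr(sequence, locus$window[1] + 1L, locus$window[2])
    frames <- translate_six_frames(win)
    cls <- classify_locus(win, profiles$RT_LTR, profiles$RT_nonLTR,
                          frames = frames)
    chd <- scan_frames(frames, profiles$CHD, target_id = genome_id)
    # a wide window can cover a neighboring element: only RT/CHD evidence
    # chained (gaps <= link_gap) to the anchor counts for this locus
    anchor_w <- shift_back(locus$anchor, locus$window[1])
    rt_linked <- chain_hits(cls$rt_hits, anchor_w$genome_start,
                            anchor_w$genome_end, link_gap)
    chd_linked <- chain_hits(chd, anchor_w$genome_start,
                             anchor_w$genome_end, link_gap)
    locus$rt_hits <- to_genome_coords(rt_linked, locus$window[1])
    locus$chd_hits <- to_genome_coords(chd_linked, locus$window[1])
    if (nrow(rt_linked) == 0L) {
      locus$classification <- "INDIVIDUAL_RNH"
      locus$group <- "individual_aRNH"
      locus$element_span <- project_domain_span(
        locus$anchor, nrow(profiles$aRNH$emissions), L)
    } else {
      best_ltr <- max(c(-Inf, rt_linked$score[
        rt_linked$profile_name == profiles$RT_LTR$name]))
      best_non <- max(c(-Inf, rt_linked$score[
        rt_linked$profile_name == profiles$RT_nonLTR$name]))
      locus$classification <- if (best_ltr >= best_non) "LTR_RT"
                              else "NONLTR_RT"
      qp <- c(hit_proteins(win, rt_linked, frames = frames),
              hit_proteins(win, anchor_w, frames = frames))
      locus$group <- assign_group(
        qp, references, min_identity = min_identity, min_ratio = min_ratio,
        chd_present = nrow(chd_linked) > 0L)
      dom <- rbind(locus$rt_hits, locus$anchor, locus$chd_hits)
      locus$element_span <- c(min(dom$genome_start), max(dom$genome_end))
    }
    locus
  })
}

# Shift window-coordinate hits into genome coordinates.
to_genome_coords <- function(hits, window_start) {
  if (nrow(hits) > 0L) {
    hits$genome_start <- hits$genome_start + window_start
    hits$genome_end <- hits$genome_end + window_start
  }
  hits
}

# Express a genome-coordinate anchor in window coordinates.
shift_back <- function(anchor, window_start) {
  anchor$genome_start <- anchor$genome_start - window_start
  anchor$genome_end <- anchor$genome_end - window_start
  anchor
}

#' Mine fmRNH genes
#'
#' As the aRNH scan, but with the fmRNH profile and 1,000 nt flanks; every
#' locus is by construction an RT-free individual RNH of family `fmRNH`.
#'
#' @inheritParams mine_genome
#' @param flank window expansion per side (default 1,000 nt).
#' @return List of candidate loci with classification `INDIVIDUAL_RNH` and
#'   group `fmRNH`.
#' @export
mine_fmrnh <- function(sequence, genome_id, profiles, flank = 1000L) {
  L <- nchar(sequence)
  anchors <- scan_genome(sequence, profiles$fmRNH, target_id = genome_id)
  loci <- lapply(seq_len(nrow(anchors)), function(i) {
    anchor <- anchors[i, , drop = FALSE]
    list(genome_id = genome_id, anchor = anchor,
         window = expand_window(anchor, L, flank),
         rt_hits = empty_hits(), chd_hits = empty_hits(),
         classification = "INDIVIDUAL_RNH", group = "fmRNH",
         element_span = project_domain_span(
           anchor, nrow(profiles$fmRNH$emissions), L))
  })
  merge_anchor_windows(loci)
}

#' Locus list as a flat table
#'
#' @param loci list of candidate loci from [mine_genome()]/[mine_fmrnh()].
#' @return data.frame with one row per locus.
#' @export
loci_table <- function(loci) {
  if (length(loci) == 0L)
    return(data.frame(genome_id = character(0), anchor_profile = character(0),
                      anchor_start = integer(0), anchor_end = integer(0),
                      window_start = integer(0), window_end = integer(0),
                      span_start = integer(0), span_end = integer(0),
                      anchor_score = numeric(0), n_rt_hits = integer(0),
                      classification = character(0), group = character(0),
                      architecture = character(0),
                      catalytic_audit = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(loci, function(l) data.frame(
    genome_id = l$genome_id, anchor_profile = l$anchor$profile_name,
    anchor_start = l$anchor$genome_start, anchor_end = l$anchor$genome_end,
    window_start = l$window[1], window_end = l$window[2],
    span_start = l$element_span[1], span_end = l$element_span[2],
    anchor_score = l$anchor$score, n_rt_hits = nrow(l$rt_hits),
    classification = l$classification, group = l$group,
    architecture = if (is.null(l$architecture)) NA_character_
      else paste(l$architecture$labels, collapse = "-"),
    catalytic_audit = if (is.null(l$catalytic_audit) ||
                            length(l$catalytic_audit) == 0L) NA_character_
      else paste(vapply(l$catalytic_audit, function(a)
        paste0(a$profile, ":", paste(a$residues, collapse = "")),
        character(1)), collapse = ";"),
    stringsAsFactors = FALSE)))
}

#' Per-genome element count table
#'
#' Counts classified loci per genome and category.  RT-associated groups
#' (Chronos, Archon, L1, Utopia) form the first column block; RT-free
#' categories (individual aRNH clades and fmRNH) follow, mirroring the
#' usual presentation of per-species element inventories.
#'
#' @param loci_df flat locus table ([loci_table()]), or a data.frame with
#'   `genome_id` and `group`.
#' @param genome_ids optional genome universe (keeps all-zero rows).
#' @return Integer matrix, rows = genomes, columns = categories; row sums
#'   equal the number of classified loci per genome.
#' @export
count_table <- function(loci_df, genome_ids = NULL) {
  core <- c("Chronos", "Archon", "L1", "Utopia")
  if (is.null(genome_ids)) genome_ids <- unique(loci_df$genome_id)
  extra <- setdiff(unique(loci_df$group), core)
  extra <- extra[order(match(extra, c("unassigned", "individual_aRNH",
                                      "fmRNH"), nomatch = 0), extra)]
  cats <- c(core, extra)
  m <- matrix(0L, nrow = length(genome_ids), ncol = length(cats),
              dimnames = list(genome_ids, cats))
  if (nrow(loci_df) > 0L) {
    tab <- table(factor(loci_df$genome_id, levels = genome_ids),
                 factor(loci_df$group, levels = cats))
    m[] <- as.integer(tab)
  }
  m
}

#' Write a count table as TSV, rendering zeros as '-'
#'
#' @param counts matrix from [count_table()].
#' @param path output file.
#' @export
write_count_table <- function(counts, path) {
  disp <- matrix(as.character(counts), nrow = nrow(counts),
                 dimnames = dimnames(counts))
  disp[counts == 0L] <- "-"
  df <- data.frame(genome_id = rownames(counts), disp, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
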