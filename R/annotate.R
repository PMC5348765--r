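# Structural characterization of classified loci: ORF calling, LTR-pair
# detection by flank self-alignment, zinc-knuckle and chromodomain
# detection, catalytic-residue auditing, and domain-architecture strings.

#' Find open reading frames in a window
#'
#' Reports every maximal ATG-to-stop reading frame on both strands whose
#' protein (including the initial M, excluding the stop) reaches
#' `min_protein_length`.  "Maximal" means the first ATG after the previous
#' in-frame stop; nested later starts within the same stop-to-stop segment
#' are not reported separately.
#'
#' @param window_sequence DNA string.
#' @param min_protein_length minimum protein length in residues
#'   (default 100).
#' @return data.frame with `start`, `end` (0-based half-open window
#'   coordinates of ATG..stop inclusive of the stop codon), `strand`,
#'   `frame`, `protein`.
#' @export
find_orfs <- function(window_sequence, min_protein_length = 100L) {
  frames <- translate_six_frames(window_sequence)
  out <- NULL
  for (fr in frames) {
    prot <- fr$protein
    if (nchar(prot) == 0L) next
    aa <- strsplit(prot, "", fixed = TRUE)[[1]]
    stops <- c(which(aa == "*"), length(aa) + 1L)
    seg_start <- 1L
    for (sp in stops) {
      if (sp > seg_start) {
        seg <- seg_start:(sp - 1L)
        m <- seg[aa[seg] == "M"]
        if (length(m) > 0L && sp <= length(aa)) {  # needs a real stop
          first_m <- m[1]
          plen <- sp - first_m
          if (plen >= min_protein_length) {
            g <- frame_to_genome(fr$frame, fr$nt_length, first_m - 1L, sp)
            out <- rbind(out, data.frame(
              start = g[1], end = g[2],
              strand = if (fr$frame > 0) "+" else "-",
              frame = fr$frame,
              protein = paste(aa[first_m:(sp - 1L)], collapse = ""),
              stringsAsFactors = FALSE))
          }
        }
      }
      seg_start <- sp + 1L
    }
  }
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      protein = character(0), stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Detect a long-terminal-repeat pair by flank self-alignment
#'
#' Aligns the sequence upstream of `candidate_span` against the sequence
#' downstream of it (each flank capped at `max_flank`) with a local
#' nucleotide Smith-Waterman alignment.  The best alignment is reported as
#' an LTR pair when it is at least `min_len` long and at least
#' `min_identity` identical.
#'
#' @param window_sequence DNA string containing the element.
#' @param candidate_span `c(start, end)` of the ORF region, 0-based
#'   half-open in window coordinates.
#' @param min_len minimum alignment length in nt (default 100).
#' @param min_identity minimum identity fraction (default 0.8).
#' @param max_flank flank length examined on each side (default 5000 nt).
#' @return `NULL`, or a list with `ltr5`, `ltr3` (`c(start, end)` window
#'   coordinates), `identity` and `length`.
#' @export
detect_ltr <- function(window_sequence, candidate_span, min_len = 100L,
                       min_identity = 0.8, max_flank = 5000L) {
  L <- nchar(window_sequence)
  s <- max(0L, candidate_span[1])
  e <- min(L, candidate_span[2])
  up_start <- max(0L, s - max_flank)
  dn_end <- min(L, e + max_flank)
  if (s - up_start < min_len || dn_end - e < min_len) return(NULL)
  up <- substr(window_sequence, up_start + 1L, s)
  dn <- substr(window_sequence, e + 1L, dn_end)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(up), Biostrings::DNAString(dn), type = "local",
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
  alen <- Biostrings::nchar(aln)
  ident <- Biostrings::pid(aln) / 100
  if (alen < min_len || ident < min_identity) return(NULL)
  p <- aln@pattern@range
  q <- aln@subject@range
  list(
    ltr5 = c(up_start + BiocGenerics::start(p) - 1L,
             up_start + BiocGenerics::end(p)),
    ltr3 = c(e + BiocGenerics::start(q) - 1L, e + BiocGenerics::end(q)),
    identity = ident, length = alen)
}

#' Locate CCHC zinc-knuckle motifs in a protein
#'
#' Matches the retroviral-type knuckle pattern `C-x(2)-C-x(4)-H-x(4)-C`
#' (spacings configurable).
#'
#' @param protein protein string.
#' @param spacing integer vector of the three inter-residue gaps
#'   (default `c(2, 4, 4)`).
#' @return Integer vector of 0-based match start positions.
#' @export
find_cchc <- function(protein, spacing = c(2L, 4L, 4L)) {
  pat <- sprintf("C.{%d}C.{%d}H.{%d}C", spacing[1], spacing[2], spacing[3])
  m <- gregexpr(pat, protein)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Audit the catalytic residues of an RNH domain hit
#'
#' Reads, from the hit's Viterbi state path, the target residue aligned to
#' each of the profile's five catalytic match states (the D-E-D-R/H-D
#' layout of type-I RNases H).  Deleted states report `-`.  The audit is
#' `degenerate` when any position deviates from the canonical pattern;
#' the semiconservative fourth site accepts R for aRNH, H for fmRNH, and
#' is unconstrained for the Ty3/Gypsy gRNH.
#'
#' @param rnh_hit one-row hit data.frame from [viterbi_search()] /
#'   [scan_genome()] (needs `path`, `kstart`, `protein_start`).
#' @param profile the RNH profile the hit came from; must carry
#'   `catalytic_states`.
#' @param protein the protein string the hit was found on.
#' @return List with `residues` (length-5 character vector), `canonical`
#'   (length-5 logical) and `degenerate` (TRUE when any position is
#'   non-canonical).
#' @export
audit_catalytic_residues <- function(rnh_hit, profile, protein) {
  if (is.null(profile$catalytic_states))
    stop("profile has no catalytic state metadata")
  if (is.null(rnh_hit$path) || is.na(rnh_hit$path) || !nzchar(rnh_hit$path))
    stop("hit lacks a state path")
  states <- strsplit(rnh_hit$path, "", fixed = TRUE)[[1]]
  k <- rnh_hit$kstart
  r <- rnh_hit$protein_start + 1L  # 1-based residue index
  found <- setNames(rep("-", 5L), NULL)
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  for (st in states) {
    if (st == "M") {
      idx <- match(k, profile$catalytic_states)
      if (!is.na(idx)) found[idx] <- aa[r]
      k <- k + 1L
      r <- r + 1L
    } else if (st == "I") {
      r <- r + 1L
    } else {
      idx <- match(k, profile$catalytic_states)
      if (!is.na(idx)) found[idx] <- "-"
      k <- k + 1L
    }
  }
  expected4 <- switch(profile$name, aRNH = "R", fmRNH = "H", NA_character_)
  canonical <- c(found[1] == "D", found[2] == "E", found[3] == "D",
                 if (is.na(expected4)) TRUE else found[4] == expected4,
                 found[5] == "D")
  list(residues = found, canonical = canonical,
       degenerate = !all(canonical))
}

# Display labels used in architecture strings.
ARCH_LABELS <- c(PR = "PR", RT_LTR = "RT", RT_nonLTR = "RT", gRNH = "gRH",
                 aRNH = "aRH", fmRNH = "fmRH", INT = "IN", CHD = "CHD",
                 EN = "EN", RLE = "RLE", CCHC = "CCHC")

#' Order domain hits into an architecture string
#'
#' Sorts domain labels by their protein coordinate and returns the ordered
#' label vector (e.g. `PR, RT, gRH, aRH, IN, CHD` for a Chronos pol).  The
#' result is invariant to the input order of the hits.  Adjacency helpers:
#' a dual-RNH element is `gRH` immediately followed by `aRH`; an INT-CHD
#' fusion is `CHD` within `chd_gap` residues after `IN`.
#'
#' @param domains data.frame with columns `profile_name` and
#'   `protein_start` (any coordinate system that orders the domains; one
#'   ORF's protein coordinates in the common case), optionally
#'   `protein_end`.
#' @param chd_gap max residue gap for the INT-CHD fusion call
#'   (default 300).
#' @return List with `labels` (ordered display labels), `dual_rnh`
#'   and `int_chd_fusion` flags.
#' @export
architecture_string <- function(domains, chd_gap = 300L) {
  if (nrow(domains) == 0L)
    return(list(labels = character(0), dual_rnh = FALSE,
                int_chd_fusion = FALSE))
  ord <- order(domains$protein_start)
  domains <- domains[ord, , drop = FALSE]
  labels <- unname(ARCH_LABELS[domains$profile_name])
  labels[is.na(labels)] <- domains$profile_name[is.na(labels)]
  dual <- FALSE
  fusion <- FALSE
  for (i in seq_len(length(labels) - 1L)) {
    if (labels[i] == "gRH" && labels[i + 1L] == "aRH") dual <- TRUE
    if (labels[i] == "IN" && labels[i + 1L] == "CHD" &&
        !is.null(domains$protein_end) &&
        domains$protein_start[i + 1L] - domains$protein_end[i] <= chd_gap)
      fusion <- TRUE
  }
  list(labels = labels, dual_rnh = dual, int_chd_fusion = fusion)
}

#' Annotate a classified locus structurally
#'
#' Finds ORFs in the locus window, scans every annotation profile over the
#' window, locates CCHC motifs on the ORF proteins, audits the catalytic
#' residues of each RNH-family hit, detects an LTR pair around the ORF
#' region (LTR-RT loci only), and assembles the ordered domain
#' architecture.  The locus's `element_span` is refined to the hull of its
#' domain hits, overlapping ORFs, and LTR pair.
#'
#' @param locus a candidate locus from [mine_genome()].
#' @param sequence the genome sequence the locus lives on.
#' @param profiles named profile list ([default_profiles()]).
#' @param min_protein_length ORF threshold (default 100 aa).
#' @param ltr_min_len,ltr_min_identity LTR-pair thresholds.
#' @param chd_gap INT-CHD fusion gap (default 300 residues).
#' @param link_gap maximum nt gap when chaining domain hits to the anchor
#'   (evidence of a neighboring element in the same window is excluded).
#' @return The locus, extended with `orfs`, `domain_hits` (all profiles,
#'   genome coordinates), `architecture`, `cchc_sites`, `catalytic_audit`
#'   and `ltr_pair`.
#' @export
annotate_locus <- function(locus, sequence, profiles,
                           min_protein_length = 100L, ltr_min_len = 100L,
                           ltr_min_identity = 0.8, chd_gap = 300L,
                           link_gap = 1200L) {
  win <- substr(sequence, locus$window[1] + 1L, locus$window[2])
  frames <- translate_six_frames(win)
  orfs <- find_orfs(win, min_protein_length)
  ann_profiles <- switch(
    locus$classification,
    LTR_RT = c("PR", "RT_LTR", "gRNH", "aRNH", "INT", "CHD"),
    NONLTR_RT = c("EN", "RT_nonLTR", "aRNH", "RLE"),
    INDIVIDUAL_RNH = if (identical(locus$group, "fmRNH")) "fmRNH" else "aRNH")
  hits <- do.call(rbind, lapply(ann_profiles, function(p)
    scan_frames(frames, profiles[[p]], target_id = locus$genome_id)))
  # the wide window may cover a neighboring element: keep only hits
  # chained to the anchor
  anchor_w <- shift_back(locus$anchor, locus$window[1])
  hits <- chain_hits(hits, anchor_w$genome_start, anchor_w$genome_end,
                     link_gap)
  # catalytic audit per RNH-family hit, on the hit's own frame translation
  frame_of <- vapply(frames, `[[`, numeric(1), "frame")
  audits <- list()
  rnh_rows <- which(hits$profile_name %in% c("aRNH", "fmRNH", "gRNH"))
  for (i in rnh_rows) {
    prot <- frames[[match(hits$frame[i], frame_of)]]$protein
    audits[[length(audits) + 1L]] <- c(
      list(profile = hits$profile_name[i],
           genome_start = hits$genome_start[i] + locus$window[1]),
      audit_catalytic_residues(hits[i, , drop = FALSE],
                               profiles[[hits$profile_name[i]]], prot))
  }
  # CCHC on ORF proteins (fall back to frame translations when ORFs are
  # broken by divergence)
  cchc <- NULL
  for (j in seq_len(nrow(orfs))) {
    pos <- find_cchc(orfs$protein[j])
    if (length(pos) > 0L)
      cchc <- rbind(cchc, data.frame(orf = j, protein_pos = pos))
  }
  # element ORFs: overlapping, or within 500 nt of, the domain-hit hull
  dom_hull <- if (nrow(hits) > 0L) {
    proj <- lapply(seq_len(nrow(hits)), function(i)
      project_domain_span(hits[i, , drop = FALSE],
                          nrow(profiles[[hits$profile_name[i]]]$emissions),
                          nchar(win)))
    c(min(vapply(proj, `[[`, numeric(1), 1)),
      max(vapply(proj, `[[`, numeric(1), 2)))
  } else c(anchor_w$genome_start, anchor_w$genome_end)
  el_orf <- if (identical(locus$classification, "INDIVIDUAL_RNH")) {
    # a lone RNH gene: only ORFs that mostly overlap the domain itself
    # (a neighboring background ORF must not stretch the gene span)
    ov <- pmin(orfs$end, dom_hull[2]) - pmax(orfs$start, dom_hull[1])
    orfs[ov >= 0.5 * (orfs$end - orfs$start), , drop = FALSE]
  } else {
    orfs[orfs$end > dom_hull[1] - 500L &
           orfs$start < dom_hull[2] + 500L, , drop = FALSE]
  }
  # LTR pair flanking the element ORF region (LTR-RT only)
  ltr <- NULL
  if (identical(locus$classification, "LTR_RT")) {
    span <- if (nrow(el_orf) > 0L)
      c(min(min(el_orf$start), dom_hull[1]),
        max(max(el_orf$end), dom_hull[2]))
    else dom_hull
    ltr <- detect_ltr(win, span, min_len = ltr_min_len,
                      min_identity = ltr_min_identity)
  }
  # architecture from the dominant frame's hits, ordered along the element
  arch <- list(labels = character(0), dual_rnh = FALSE,
               int_chd_fusion = FALSE)
  if (nrow(hits) > 0L) {
    fr_counts <- table(hits$frame)
    dom_frame <- as.integer(names(fr_counts)[which.max(fr_counts)])
    fh <- hits[hits$frame == dom_frame, , drop = FALSE]
    arch_in <- data.frame(profile_name = fh$profile_name,
                          protein_start = fh$protein_start,
                          protein_end = fh$protein_end,
                          stringsAsFactors = FALSE)
    # CCHC motifs on the same frame, as zero-width architecture entries
    fr <- frames[[match(dom_frame, frame_of)]]
    for (pos in find_cchc(fr$protein)) {
      if (pos >= min(fh$protein_start) && pos <= max(fh$protein_end))
        arch_in <- rbind(arch_in, data.frame(
          profile_name = "CCHC", protein_start = pos,
          protein_end = pos + 14L, stringsAsFactors = FALSE))
    }
    arch <- architecture_string(arch_in, chd_gap = chd_gap)
  }
  hits_g <- to_genome_coords(hits, locus$window[1])
  orfs_g <- orfs
  if (nrow(orfs_g) > 0L) {
    orfs_g$start <- orfs_g$start + locus$window[1]
    orfs_g$end <- orfs_g$end + locus$window[1]
  }
  # refined element span: domain hull, plus element ORFs, plus LTRs
  span <- dom_hull + locus$window[1]
  if (nrow(el_orf) > 0L)
    span <- c(min(span[1], min(el_orf$start) + locus$window[1]),
              max(span[2], max(el_orf$end) + locus$window[1]))
  if (!is.null(ltr))
    span <- c(min(span[1], ltr$ltr5[1] + locus$window[1]),
              max(span[2], ltr$ltr3[2] + locus$window[1]))
  locus$orfs <- orfs_g
  locus$domain_hits <- hits_g
  locus$architecture <- arch
  locus$cchc_sites <- cchc
  locus$catalytic_audit <- audits
  locus$ltr_pair <- if (is.null(ltr)) NULL else
    list(ltr5 = ltr$ltr5 + locus$window[1], ltr3 = ltr$ltr3 + locus$window[1],
         identity = ltr$identity, length = ltr$length)
  locus$element_span <- span
  locus
}
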