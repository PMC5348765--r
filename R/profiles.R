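#' Seed alignment for a protein domain family
#'
#' A seed alignment is a small gapped multiple alignment of amino-acid
#' sequences from one domain family (e.g. aRNH, fmRNH, the RT of LTR
#' retrotransposons).  It is the sole input from which a position-specific
#' [build_profile()] model is estimated.
#'
#' @param rows character vector of gapped amino-acid strings, all the same
#'   length, alphabet restricted to the 20 amino acids plus `-`.
#' @param name domain-family label, e.g. `"aRNH"`.
#' @param source free-text provenance note.
#' @return An object of class `seed_alignment`.
#' @export
seed_alignment <- function(rows, name, source = "unspecified") {
  rows <- as.character(rows)
  if (length(rows) < 2L) stop("seed alignment needs at least 2 rows")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("seed alignment rows differ in length")
  if (w == 0L) stop("empty input")
  ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "-]*$"), rows)
  if (!all(ok)) stop("seed alignment contains a non amino-acid character")
  structure(list(name = name, rows = rows, source = source),
            class = "seed_alignment")
}

#' Read a seed alignment from aligned FASTA
#'
#' @param path path to an aligned (equal-width, gapped) protein FASTA file.
#' @param name family label; defaults to the file name without extension.
#' @param source provenance note recorded on the object.
#' @return A [seed_alignment()].
#' @export
read_seed_alignment <- function(path, name = NULL, source = path) {
  aa <- Biostrings::readAAStringSet(path)
  if (is.null(name))
    name <- sub("\\.(fa|fasta|afa)$", "", basename(path), ignore.case = TRUE)
  seed_alignment(as.character(aa), name = name, source = source)
}

#' Write a seed alignment as aligned FASTA
#'
#' @param seed a [seed_alignment()].
#' @param path output file.
#' @export
write_seed_alignment <- function(seed, path) {
  ids <- sprintf("%s_%02d", seed$name, seq_along(seed$rows))
  writeLines(as.vector(rbind(paste0(">", ids), seed$rows)), path)
  invisible(path)
}

#' @export
print.seed_alignment <- function(x, ...) {
  cat(sprintf("seed_alignment '%s': %d rows x %d columns (%s)\n",
              x$name, length(x$rows), nchar(x$rows[[1]]), x$source))
  invisible(x)
}

#' Build a position-specific domain profile from a seed alignment
#'
#' Alignment columns whose gap fraction is below `gap_fraction_cutoff`
#' become match states.  Per-state emission probabilities are estimated
#' from the observed residue counts with a background-proportional
#' pseudocount, `(counts + pseudocount * background) / (n + pseudocount)`
#' where `n` is the number of non-gap residues in the column, and stored as
#' log-odds (bits) against the background.  Insertions and deletions are
#' modelled with a single global open/extend probability pair, giving a
#' Plan7-style local model with uniform entry and exit.
#'
#' @param seed a [seed_alignment()].
#' @param gap_fraction_cutoff columns with gap fraction strictly below this
#'   become match states (default 0.5).
#' @param pseudocount total pseudocount weight added per column (default 1).
#' @param score_threshold default bit-score threshold for reported hits.
#'   The package default (30 bits) is calibrated so that a six-frame scan
#'   of a 500 kb random genome yields essentially no false anchors; see the
#'   methods vignette.
#' @param background named numeric vector of 20 amino-acid frequencies.
#' @param gap_open,gap_extend insert/delete open and extend probabilities.
#' @param catalytic_columns optional integer vector of 1-based alignment
#'   column indices of catalytic residues (used by
#'   [audit_catalytic_residues()]); they must map to match states.
#' @return An object of class `domain_profile`.
#' @export
build_profile <- function(seed, gap_fraction_cutoff = 0.5, pseudocount = 1,
                          score_threshold = 30, background = AA_BACKGROUND,
                          gap_open = 0.01, gap_extend = 0.4,
                          catalytic_columns = NULL) {
  stopifnot(inherits(seed, "seed_alignment"))
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  mat <- do.call(rbind, strsplit(seed$rows, "", fixed = TRUE))
  gapfrac <- colMeans(mat == "-")
  match_columns <- which(gapfrac < gap_fraction_cutoff)
  if (length(match_columns) == 0L) stop("no match states")
  K <- length(match_columns)
  emissions <- matrix(0, nrow = K, ncol = 20,
                      dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(K)) {
    col <- mat[, match_columns[j]]
    col <- col[col != "-"]
    counts <- table(factor(col, levels = AA_ALPHABET))
    emissions[j, ] <- (as.numeric(counts) + pseudocount * background) /
      (length(col) + pseudocount)
  }
  logodds <- log2(sweep(emissions, 2, background, "/"))
  catalytic_states <- NULL
  if (!is.null(catalytic_columns)) {
    catalytic_states <- match(catalytic_columns, match_columns)
    if (anyNA(catalytic_states))
      stop("catalytic column is not a match state")
  }
  structure(list(
    name = seed$name,
    match_columns = match_columns,
    emissions = emissions,
    logodds = logodds,
    background = background,
    score_threshold = score_threshold,
    gap_open = gap_open,
    gap_extend = gap_extend,
    catalytic_states = catalytic_states,
    nseq = length(seed$rows)
  ), class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf(
    "domain_profile '%s': %d match states, threshold %.1f bits (%d seqs)\n",
    x$name, nrow(x$emissions), x$score_threshold, x$nseq))
  invisible(x)
}

# 21-column emission matrix handed to the C++ decoder: 20 residue log-odds
# plus a zero column for neutral symbols (X and *).
profile_emission_matrix <- function(profile) {
  cbind(profile$logodds, 0)
}

#' Search a protein sequence with a domain profile
#'
#' Runs local Viterbi decoding of `profile` against `protein` and reports
#' all non-overlapping hits scoring at least the threshold, extracted
#' greedily best-first with masking.  `X` and `*` emit at background
#' probability (log-odds 0), so translated genomic frames can be scanned
#' directly without ORF calling.
#'
#' @param profile a [build_profile()] object.
#' @param protein single protein string over the 20 amino acids plus `X`
#'   and `*`.
#' @param threshold bit-score cutoff; defaults to the profile's.
#' @param target_id identifier recorded on the hits.
#' @param max_hits safety cap on the number of reported hits.
#' @return A data.frame with one row per hit: `profile_name`, `target_id`,
#'   `frame` (0 for plain protein input), `protein_start`/`protein_end`
#'   (0-based half-open), `score` (bits), `kstart`/`kend` (1-based first
#'   and last match state), and `path` (the match/insert/delete trace),
#'   sorted by `protein_start`.
#' @export
viterbi_search <- function(profile, protein, threshold = NULL,
                           target_id = NA_character_, max_hits = 10000L) {
  stopifnot(inherits(profile, "domain_profile"))
  if (is.null(threshold)) threshold <- profile$score_threshold
  x <- encode_protein(protein)
  hits <- empty_hits()
  if (length(x) > 0L) {
    res <- viterbi_hits_cpp(profile_emission_matrix(profile), x,
                            log2(profile$gap_open), log2(profile$gap_extend),
                            threshold, as.integer(max_hits))
    n <- length(res$score)
    if (n > 0L) {
      hits <- data.frame(
        profile_name = rep(profile$name, n),
        target_id = rep(target_id, n),
        frame = rep(0L, n),
        protein_start = as.integer(res$protein_start),
        protein_end = as.integer(res$protein_end),
        genome_start = rep(NA_integer_, n),
        genome_end = rep(NA_integer_, n),
        score = res$score,
        kstart = as.integer(res$kstart),
        kend = as.integer(res$kend),
        path = res$path,
        stringsAsFactors = FALSE)
    }
  }
  hits[order(hits$protein_start, -hits$score), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(profile_name = character(0), target_id = character(0),
             frame = integer(0), protein_start = integer(0),
             protein_end = integer(0), genome_start = integer(0),
             genome_end = integer(0), score = numeric(0),
             kstart = integer(0), kend = integer(0), path = character(0),
             stringsAsFactors = FALSE)
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Translation is frame-wise and stop-agnostic: stop codons are emitted as
#' `*` and codons containing `N` as `X`, so degenerate element copies with
#' internal stops or ambiguity remain scannable.  Reverse frames are
#' translated from the reverse complement.  Each frame carries a coordinate
#' offset from which any protein interval can be mapped back to a
#' forward-strand nucleotide interval via [frame_to_genome()].
#'
#' @param sequence single DNA string over `A,C,G,T,N`.
#' @return List of six records, each `list(frame, offset, protein, nt_length)`
#'   where `frame` is in `+1,+2,+3,-1,-2,-3` and `offset` is the 0-based
#'   start of the frame on its own strand.
#' @export
translate_six_frames <- function(sequence) {
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L)
    stop("empty input")
  bad <- regmatches(sequence, regexpr("[^ACGTNacgtn]", sequence))
  if (length(bad) > 0L)
    stop("invalid nucleotide character: '", bad, "'")
  L <- nchar(sequence)
  if (L < 3L) stop("sequence shorter than one codon")
  fwd <- Biostrings::DNAString(toupper(sequence))
  rev <- Biostrings::reverseComplement(fwd)
  out <- vector("list", 6L)
  idx <- 1L
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) fwd else rev
    for (off in 0:2) {
      ncod <- (L - off) %/% 3L
      prot <- if (ncod == 0L) "" else {
        sub <- Biostrings::subseq(s, start = off + 1L, width = 3L * ncod)
        as.character(suppressWarnings(
          Biostrings::translate(sub, if.fuzzy.codon = "X",
                                no.init.codon = TRUE)))
      }
      out[[idx]] <- list(frame = strand * (off + 1L), offset = off,
                         protein = prot, nt_length = L)
      idx <- idx + 1L
    }
  }
  out
}

#' Map a protein interval on a translated frame to genome coordinates
#'
#' @param frame frame number in `+1..+3, -1..-3`.
#' @param nt_length length of the source nucleotide sequence.
#' @param protein_start,protein_end 0-based half-open protein interval.
#' @return Integer vector `c(genome_start, genome_end)`, 0-based half-open
#'   on the forward strand.
#' @export
frame_to_genome <- function(frame, nt_length, protein_start, protein_end) {
  off <- abs(frame) - 1L
  a <- off + 3L * protein_start
  b <- off + 3L * protein_end
  if (frame > 0) c(a, b) else c(nt_length - b, nt_length - a)
}

# Project a partial domain hit to the full extent the profile would cover
# (k states missing at either end extend the genome interval by 3 nt per
# state, respecting the frame's orientation); clamped to [0, nt_length].
project_domain_span <- function(hit, n_states, nt_length) {
  left_states <- hit$kstart - 1L
  right_states <- n_states - hit$kend
  if (hit$frame < 0) {  # genome-left corresponds to the protein C-terminus
    tmp <- left_states
    left_states <- right_states
    right_states <- tmp
  }
  c(max(0L, hit$genome_start - 3L * left_states),
    min(as.integer(nt_length), hit$genome_end + 3L * right_states))
}

# Reciprocal-overlap fraction of two 0-based half-open intervals.
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  if (ov == 0) return(0)
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Scan a genomic sequence with a domain profile
#'
#' Translates all six frames, runs [viterbi_search()] on each, maps hits
#' back to forward-strand genome coordinates, and collapses hits from
#' different frames that overlap by more than 50% reciprocally on the
#' genome to the best-scoring one (a degenerate copy is often visible in
#' several frames).
#'
#' @param sequence DNA string (or `DNAString`).
#' @param profile a [build_profile()] object.
#' @param target_id sequence identifier recorded on hits.
#' @param threshold optional bit-score override.
#' @return Hit data.frame as in [viterbi_search()], with `frame`,
#'   `genome_start` and `genome_end` filled in, sorted by genome position.
#' @export
scan_genome <- function(sequence, profile, target_id = "seq",
                        threshold = NULL) {
  scan_frames(translate_six_frames(sequence), profile,
              target_id = target_id, threshold = threshold)
}

#' Scan precomputed six-frame translations with a profile
#'
#' Workhorse behind [scan_genome()]; callers that scan one window with
#' several profiles can translate once and reuse the frames.
#'
#' @param frames output of [translate_six_frames()].
#' @inheritParams scan_genome
#' @return As [scan_genome()].
#' @export
scan_frames <- function(frames, profile, target_id = "seq",
                        threshold = NULL) {
  hits <- lapply(frames, function(fr) {
    h <- viterbi_search(profile, fr$protein, threshold = threshold,
                        target_id = target_id)
    if (nrow(h) == 0L) return(h)
    h$frame <- fr$frame
    g <- t(mapply(function(ps, pe)
      frame_to_genome(fr$frame, fr$nt_length, ps, pe),
      h$protein_start, h$protein_end))
    h$genome_start <- as.integer(g[, 1])
    h$genome_end <- as.integer(g[, 2])
    h
  })
  hits <- do.call(rbind, hits)
  if (nrow(hits) <= 1L)
    return(hits[order(hits$genome_start), , drop = FALSE])
  hits <- hits[order(-hits$score, hits$genome_start), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (reciprocal_overlap(hits$genome_start[i], hits$genome_end[i],
                             hits$genome_start[j], hits$genome_end[j]) > 0.5) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  hits <- hits[keep, , drop = FALSE]
  hits[order(hits$genome_start), , drop = FALSE]
}

#' Align proteins to a profile's match states
#'
#' Decodes the best local path of each protein through the profile
#' (regardless of threshold) and reads off, for every match state, the
#' aligned residue or `-` when the state is deleted or outside the hit.
#' Insert-state residues are dropped.  The result is a fixed-width implicit
#' multiple alignment, the package's analogue of aligning sequences to a
#' common HMM, and is the input to the phylogenetic operations.
#'
#' @param profile a [build_profile()] object.
#' @param proteins named character vector of protein sequences.
#' @return Character matrix, rows = proteins, columns = match states.
#' @export
align_to_profile <- function(profile, proteins) {
  if (is.null(names(proteins)) || anyNA(names(proteins)))
    stop("proteins must be named")
  K <- nrow(profile$emissions)
  out <- matrix("-", nrow = length(proteins), ncol = K,
                dimnames = list(names(proteins), NULL))
  for (i in seq_along(proteins)) {
    h <- viterbi_search(profile, proteins[[i]], threshold = -Inf,
                        max_hits = 1L)
    if (nrow(h) == 0L) next
    res <- strsplit(substr(proteins[[i]], h$protein_start + 1L,
                           h$protein_end), "", fixed = TRUE)[[1]]
    k <- h$kstart
    r <- 1L
    for (st in strsplit(h$path, "", fixed = TRUE)[[1]]) {
      if (st == "M") {
        out[i, k] <- res[r]
        k <- k + 1L
        r <- r + 1L
      } else if (st == "I") {
        r <- r + 1L
      } else {
        k <- k + 1L
      }
    }
  }
  out
}

#' Write a domain profile as plain text
#'
#' One header block (`# key value` lines) followed by one line per match
#' state: state index, source alignment column, then 20 emission log-odds
#' (bits) in the order `ACDEFGHIKLMNPQRSTVWY`.
#'
#' @param profile a [build_profile()] object.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# name", profile$name),
    paste("# nstates", nrow(profile$emissions)),
    paste("# nseq", profile$nseq),
    paste("# score_threshold", format(profile$score_threshold, digits = 17)),
    paste("# gap_open", format(profile$gap_open, digits = 17)),
    paste("# gap_extend", format(profile$gap_extend, digits = 17)),
    paste("# background", paste(format(profile$background, digits = 17),
                                collapse = " ")),
    paste("# catalytic_states",
          if (is.null(profile$catalytic_states)) "NA"
          else paste(profile$catalytic_states, collapse = " ")),
    paste("# columns state alignment_column",
          paste(AA_ALPHABET, collapse = " "))
  ), con)
  for (j in seq_len(nrow(profile$logodds))) {
    writeLines(paste(j, profile$match_columns[j],
                     paste(format(profile$logodds[j, ], digits = 17),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Read a domain profile written by [write_profile()]
#'
#' @param path profile text file.
#' @return A `domain_profile`.  Emission probabilities are reconstructed
#'   from the stored log-odds and background.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key))]
    if (length(ln) != 1L) stop("malformed profile file: missing ", key)
    sub(paste0("^# ", key, " "), "", ln)
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- lapply(strsplit(body, " +"), as.numeric)
  mat <- do.call(rbind, fields)
  logodds <- mat[, 3:22, drop = FALSE]
  colnames(logodds) <- AA_ALPHABET
  background <- as.numeric(strsplit(get("background"), " +")[[1]])
  names(background) <- AA_ALPHABET
  cat_states <- get("catalytic_states")
  cat_states <- if (identical(cat_states, "NA")) NULL
                else as.integer(strsplit(cat_states, " +")[[1]])
  emissions <- sweep(2^logodds, 2, background, "*")
  structure(list(
    name = get("name"),
    match_columns = as.integer(mat[, 2]),
    emissions = emissions,
    logodds = logodds,
    background = background,
    score_threshold = as.numeric(get("score_threshold")),
    gap_open = as.numeric(get("gap_open")),
    gap_extend = as.numeric(get("gap_extend")),
    catalytic_states = cat_states,
    nseq = as.integer(get("nseq"))
  ), class = "domain_profile")
}

#' Export domain hits as TSV
#'
#' @param hits a hit data.frame from [scan_genome()] or [viterbi_search()].
#' @param path output file.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("target_id", "profile_name", "frame", "genome_start",
            "genome_end", "score")
  write.table(hits[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
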