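# File formats and configuration.  FASTA goes through Biostrings, GFF3
# through rtracklayer/GenomicRanges; coordinates are 0-based half-open
# internally and 1-based closed on GFF output.

#' Read a FASTA file
#'
#' @param path FASTA file (DNA by default).
#' @param type `"DNA"` or `"AA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  xs <- tryCatch(
    if (type == "DNA") Biostrings::readDNAStringSet(path)
    else Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e)))
  out <- as.character(xs)
  names(out) <- sub("\\s.*$", "", names(xs))
  out
}

#' Write sequences as wrapped FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @param width line width (default 60).
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(paste0(">", nm), con)
    s <- sequences[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Write features as GFF3
#'
#' @param features data.frame with `seqid`, `type`, `start`, `end`
#'   (0-based half-open; converted to 1-based closed on output), and
#'   optionally `source`, `score`, `strand`, `ID`, `Parent`, plus any
#'   further attribute columns.
#' @param path output file.
#' @export
write_gff <- function(features, path) {
  if (nrow(features) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = if ("strand" %in% names(features)) features$strand else "*")
  mc <- features[, setdiff(names(features),
                           c("seqid", "start", "end", "strand")),
                 drop = FALSE]
  if (!"source" %in% names(mc)) mc$source <- "retromine"
  if ("Parent" %in% names(mc)) {
    p <- as.character(mc$Parent)
    mc$Parent <- IRanges::CharacterList(lapply(p, function(x)
      if (is.na(x) || !nzchar(x)) character(0) else x))
  }
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file
#'
#' @param path GFF3 file.
#' @return data.frame with `seqid`, `source`, `type`, `start`, `end`
#'   (0-based half-open), `score`, `strand` and attribute columns.
#' @export
read_gff <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF '", path, "': ",
                                          conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  names(df)[names(df) == "seqnames"] <- "seqid"
  df$start <- df$start - 1L  # back to 0-based half-open
  df$width <- NULL
  if ("Parent" %in% names(df))
    df$Parent <- vapply(df$Parent, function(p)
      if (length(p) == 0L) NA_character_ else as.character(p[[1]]),
      character(1))
  df$strand <- as.character(df$strand)
  df$seqid <- as.character(df$seqid)
  df
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults: window
#' half-widths (10,000 nt around aRNH anchors, 1,000 nt around fmRNH),
#' profile score threshold, ORF and LTR thresholds, group-assignment
#' thresholds, bootstrap replicates, and the simulation block used when no
#' input genomes are supplied.
#'
#' @param ... named overrides.
#' @return Named list of class `retromine_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # simulation block (used when genomes_fasta is NULL)
    n_genomes = 2L,
    genome_length = 200000L,
    gc = 0.5,
    divergence = 0.05,
    n_per_group = 2L,
    n_cell_arnh = 1L,
    n_fmrnh = 1L,
    # search
    score_threshold = 30,
    arnh_half_width = 10000L,
    fmrnh_flank = 1000L,
    # annotation
    orf_min_length = 100L,
    ltr_min_len = 100L,
    ltr_min_identity = 0.8,
    chd_gap = 300L,
    # grouping
    group_min_identity = 0.35,
    group_min_ratio = 1.2,
    # phylogenetics
    bootstrap_reps = 100L,
    support_threshold = 60,
    # inputs (optional)
    genomes_fasta = NULL,
    truth_gff = NULL)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad) > 0L) stop("unknown config key: ", bad[[1]])
  cfg[names(ov)] <- ov
  numeric_keys <- setdiff(names(cfg), c("genomes_fasta", "truth_gff"))
  for (k in numeric_keys)
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0)
      stop("config field must be a non-negative number: ", k)
  structure(cfg, class = "retromine_config")
}

#' Read a flat `key: value` configuration file
#'
#' Lines of the form `key: value`; `#` starts a comment; values are
#' coerced to numbers where possible.  Unknown keys are an error.
#'
#' @param path configuration file.
#' @return A [default_config()] with the file's overrides applied.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad) > 0L)
    stop("malformed config at line ", bad[[1]], ": ", lines[bad[[1]]])
  vals <- lapply(kv, function(m) {
    v <- m[[3]]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 2L)
  do.call(default_config, vals)
}
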