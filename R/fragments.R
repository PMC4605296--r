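#' Build a fragment set from a data frame
#'
#' A fragment set is the pipeline's primary input: strandless genomic
#' intervals protected from MNase digestion, stored as a tibble with columns
#' `chrom`, `start`, `end` (0-based half-open) plus the chromosome sizes they
#' must lie within. Records on chromosomes absent from `chrom_sizes`, or
#' extending past a chromosome end, are dropped with a message; if every
#' record of a non-empty input drops, that is an error.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`.
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param provenance Free-text label recording where the fragments came from.
#' @return A `nuc_fragments` tibble (columns `chrom`, `start`, `end`) carrying
#'   `chrom_sizes` and `provenance` attributes and an `n_invalid` attribute
#'   counting dropped records.
#' @export
fragments <- function(df, chrom_sizes, provenance = "") {
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    stop_usage("`df` must have columns chrom, start, end")
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop_usage("`chrom_sizes` must be a named vector of chromosome lengths")
  }
  df <- tibble::as_tibble(df[c("chrom", "start", "end")])
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  n_in <- nrow(df)
  bad_shape <- !nzchar(df$chrom) | !is.finite(df$start) | !is.finite(df$end) |
    df$end <= df$start
  known <- df$chrom %in% names(chrom_sizes)
  in_bounds <- known & !bad_shape
  in_bounds[in_bounds] <- df$start[in_bounds] >= 0L &
    df$end[in_bounds] <= unname(chrom_sizes[df$chrom[in_bounds]])
  ok <- in_bounds & !bad_shape
  n_drop <- n_in - sum(ok)
  if (n_drop > 0) {
    rlang::inform(sprintf("Dropped %d fragment record(s) failing validation against chrom_sizes", n_drop))
  }
  if (n_in > 0 && sum(ok) == 0) {
    stop_input("all fragment records were dropped during validation")
  }
  out <- df[ok, , drop = FALSE]
  structure(out,
    chrom_sizes = chrom_sizes, provenance = provenance, n_invalid = n_drop,
    class = c("nuc_fragments", class(out))
  )
}

#' Chromosome sizes attached to a fragment set
#' @param x A `nuc_fragments` object.
#' @return Named numeric vector of chromosome lengths.
#' @export
chrom_sizes <- function(x) attr(x, "chrom_sizes")

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with columns chromosome name and length (no header).
#' @return Named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  cs <- readr::read_tsv(path, col_names = c("chrom", "size"),
                        col_types = "cd", progress = FALSE)
  stats::setNames(cs$size, cs$chrom)
}

#' Read paired-end MNase fragments
#'
#' Reads fragment intervals from BED-PE (10-column or minimal 6-column
#' mate-pair dialect), a 3-column fragment TSV (`chrom start end`), or a
#' coordinate-indexed BAM. For BED-PE the fragment spans the mate extremes;
#' mate pairs on different chromosomes are dropped and counted. For BAM only
#' primary, proper-pair alignments with both mates mapped are used, taking
#' each leftmost mate's TLEN as the fragment extent. Fragments are strandless;
#' strand columns are ignored.
#'
#' @param path Input file.
#' @param format One of `"bedpe"`, `"fragment-tsv"`, `"bam"`.
#' @param chrom_sizes Named vector of chromosome lengths; records failing
#'   validation against it are dropped with a message.
#' @param keep_duplicates For BAM input, keep reads flagged as PCR/optical
#'   duplicates (default `TRUE`; the conservative choice when upstream
#'   duplicate handling is unknown).
#' @return A [fragments()] tibble.
#' @export
read_fragments <- function(path, format = c("bedpe", "fragment-tsv", "bam"),
                           chrom_sizes, keep_duplicates = TRUE) {
  format <- tryCatch(match.arg(format), error = function(e) {
    stop_usage(sprintf("unknown fragment format '%s'", format[1]))
  })
  if (!file.exists(path)) stop_input(sprintf("cannot read fragment file '%s'", path))
  df <- switch(format,
    "fragment-tsv" = {
      x <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                           col_types = "cii", progress = FALSE)
      tibble::as_tibble(x)
    },
    "bedpe" = read_bedpe_fragments(path),
    "bam" = read_bam_fragments(path, keep_duplicates)
  )
  fragments(df, chrom_sizes, provenance = paste0(format, ":", basename(path)))
}

read_bedpe_fragments <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", blank.lines.skip = TRUE)
  if (ncol(raw) < 6) stop_input("BED-PE requires at least 6 columns")
  chrom1 <- raw[[1]]; chrom2 <- raw[[4]]
  s1 <- suppressWarnings(as.integer(raw[[2]])); e1 <- suppressWarnings(as.integer(raw[[3]]))
  s2 <- suppressWarnings(as.integer(raw[[5]])); e2 <- suppressWarnings(as.integer(raw[[6]]))
  if (anyNA(c(s1, e1, s2, e2))) stop_input("non-numeric coordinate in BED-PE")
  same <- chrom1 == chrom2
  if (any(!same)) {
    rlang::inform(sprintf("Dropped %d mate pair(s) on different chromosomes", sum(!same)))
  }
  tibble(
    chrom = chrom1[same],
    start = pmin(s1, s2)[same],
    end = pmax(e1, e2)[same]
  )
}

read_bam_fragments <- function(path, keep_duplicates) {
  flag <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE,
    isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isDuplicate = if (keep_duplicates) NA else FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "isize", "mrnm"))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  same <- !is.na(b$mrnm) & as.character(b$rname) == as.character(b$mrnm)
  left <- same & !is.na(b$isize) & b$isize > 0
  tibble(
    chrom = as.character(b$rname)[left],
    start = b$pos[left] - 1L,               # SAM POS is 1-based
    end = b$pos[left] - 1L + b$isize[left]
  )
}

#' Fragment-length histogram
#'
#' Tallies fragment lengths (`end - start`) and reports the modal length, the
#' summary behind the familiar protected-fragment size distribution of an
#' MNase library (a ~150 bp mode for mononucleosomes).
#'
#' @param frags A fragment set.
#' @return A tibble (`length`, `count`) of class `nuc_length_hist` with
#'   attributes `total` (fragment count) and `modal_length` (NA when empty;
#'   smallest length on ties).
#' @export
length_histogram <- function(frags) {
  len <- frags$end - frags$start
  if (length(len) == 0) {
    out <- tibble(length = integer(0), count = integer(0))
    return(structure(out, total = 0L, modal_length = NA_integer_,
                     class = c("nuc_length_hist", class(out))))
  }
  tab <- table(len)
  out <- tibble(length = as.integer(names(tab)), count = as.integer(tab))
  out <- dplyr::arrange(out, .data$length)
  modal <- out$length[which.max(out$count)]
  structure(out, total = length(len), modal_length = modal,
            class = c("nuc_length_hist", class(out)))
}

#' Single-nucleosome size filter
#'
#' Retains fragments whose length lies in the closed interval `[lo, hi]`. The
#' default 127-168 bp window selects the fragment population protected by
#' single nucleosomes, excluding sub-nucleosomal protections and dinucleosome
#' inserts. Both bounds are inclusive.
#'
#' @param frags A fragment set.
#' @param lo,hi Length bounds in bp (defaults 127 and 168).
#' @return The filtered fragment set, in input order, with attributes
#'   `n_kept` and `n_dropped` (which always sum to the input size).
#' @export
filter_by_length <- function(frags, lo = 127, hi = 168) {
  if (!is_count(lo) || !is_count(hi) || lo < 1 || lo > hi) {
    stop_usage("size filter requires 1 <= lo <= hi")
  }
  len <- frags$end - frags$start
  keep <- len >= lo & len <= hi
  out <- frags[keep, , drop = FALSE]
  attr(out, "chrom_sizes") <- chrom_sizes(frags)
  attr(out, "provenance") <- attr(frags, "provenance")
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- class(frags)
  out
}

#' Write fragments as 3-column BED
#' @param frags A fragment set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(frags, path) {
  readr::write_tsv(tibble::as_tibble(frags)[c("chrom", "start", "end")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Write a length histogram as 2-column TSV
#' @param hist A [length_histogram()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_length_histogram <- function(hist, path) {
  readr::write_tsv(tibble::as_tibble(hist)[c("length", "count")],
                   path, col_names = FALSE)
  invisible(path)
}
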