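#' Parameters for the synthetic MNase library generator
#'
#' The generator emulates the statistical structure a nucleosome-positioning
#' analysis assumes: a chromosome alternating nucleosome-array blocks (dyads
#' planted every `repeat_length` bp over GC-biased sequence with 10 bp AA/TT
#' phasing under each dyad) and nucleosome-depleted blocks (poly A:T runs at
#' `at_purity`), a protected-fragment library with an ~150 bp length mode and
#' Gaussian dyad jitter, a uniform background-digestion population, and
#' ORC-like scored sites placed inside the depleted blocks.
#'
#' @param chrom_length Target chromosome length in bp (the realized length is
#'   the largest whole number of blocks fitting inside it).
#' @param chrom Chromosome name.
#' @param repeat_length Nucleosome repeat (dyad-to-dyad spacing) in bp
#'   (default 197).
#' @param footprint Nucleosome footprint in bp (default 147).
#' @param array_nucleosomes Nucleosomes per array block (default 10).
#' @param ndr_block_lengths Pool of depleted-block lengths sampled uniformly
#'   (default `c(300, 700)`, a promoter-like and an origin-like size);
#'   `numeric(0)` plants no depleted blocks.
#' @param gc_rich_fraction GC fraction of array-block sequence (default 0.6).
#' @param at_purity A/T fraction of depleted-block sequence (default 0.95).
#' @param n_fragments Library size (default 200000).
#' @param frag_len_mean,frag_len_sd Fragment length law, Normal, rounded,
#'   clipped at 50 bp (defaults 150 and 8).
#' @param dyad_jitter_sd SD of fragment-center scatter around the dyad in bp
#'   (default 20).
#' @param background_fraction Fraction of fragments placed uniformly at
#'   random, emulating background digestion (default 0.1).
#' @param seed Integer seed; identical (params, seed) give byte-identical
#'   output.
#' @return A `sim_params` list.
#' @export
sim_params <- function(chrom_length = 1e6, chrom = "chrS", repeat_length = 197,
                       footprint = 147, array_nucleosomes = 10,
                       ndr_block_lengths = c(300, 700),
                       gc_rich_fraction = 0.6, at_purity = 0.95,
                       n_fragments = 200000, frag_len_mean = 150,
                       frag_len_sd = 8, dyad_jitter_sd = 20,
                       background_fraction = 0.1, seed = 1) {
  stopifnot(chrom_length > 0, repeat_length > 0, footprint > 0,
            array_nucleosomes >= 1, gc_rich_fraction >= 0, gc_rich_fraction <= 1,
            at_purity > 0, at_purity <= 1, frag_len_mean > 0, frag_len_sd >= 0,
            dyad_jitter_sd >= 0, background_fraction >= 0, background_fraction <= 1)
  structure(list(
    chrom_length = as.integer(chrom_length), chrom = chrom,
    repeat_length = as.integer(repeat_length), footprint = as.integer(footprint),
    array_nucleosomes = as.integer(array_nucleosomes),
    ndr_block_lengths = as.integer(ndr_block_lengths),
    gc_rich_fraction = gc_rich_fraction, at_purity = at_purity,
    n_fragments = as.integer(n_fragments), frag_len_mean = frag_len_mean,
    frag_len_sd = frag_len_sd, dyad_jitter_sd = dyad_jitter_sd,
    background_fraction = background_fraction, seed = as.integer(seed)
  ), class = "sim_params")
}

#' Generate a synthetic genome with planted nucleosome architecture
#'
#' Alternates array blocks and depleted blocks per the parameters (see
#' [sim_params()]) and records the full planted truth. Dyads are never placed
#' inside a depleted block (asserted), array sequence carries AA/TT
#' dinucleotides every 10 bp under each dyad, and depleted blocks are built
#' from A/T homopolymer runs (lengths 10-30) degraded to `at_purity` with
#' scattered G/C.
#'
#' @param params A [sim_params()] list.
#' @return A `sim_truth`: `genome` (named character vector), `chrom_sizes`,
#'   `dyads` tibble, `ndr_blocks` tibble, `array_blocks` tibble, `blocks`
#'   tibble (both types, in genomic order), `params`, `seed`.
#' @export
sim_genome <- function(params = sim_params()) {
  p <- params
  ab_len <- p$array_nucleosomes * p$repeat_length
  min_need <- ab_len + if (length(p$ndr_block_lengths)) min(p$ndr_block_lengths) else 0L
  if (p$chrom_length < min_need) {
    stop_usage("chrom_length too short for one array block plus one depleted block")
  }
  with_seed(p$seed, {
    blocks <- list()
    pos <- 0L
    repeat {
      if (pos + ab_len > p$chrom_length) break
      blocks[[length(blocks) + 1]] <- list(type = "array", start = pos, end = pos + ab_len)
      pos <- pos + ab_len
      if (length(p$ndr_block_lengths) == 0) next
      nl <- if (length(p$ndr_block_lengths) == 1) p$ndr_block_lengths else
        sample(p$ndr_block_lengths, 1)
      if (pos + nl + ab_len > p$chrom_length) break
      blocks[[length(blocks) + 1]] <- list(type = "ndr", start = pos, end = pos + nl)
      pos <- pos + nl
    }
    total <- pos
    bases <- character(total)
    dyads <- integer(0)
    half_rep <- p$repeat_length %/% 2L

    for (b in blocks) {
      len <- b$end - b$start
      sel <- (b$start + 1):b$end
      if (b$type == "array") {
        gc <- p$gc_rich_fraction
        bases[sel] <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
        dy <- b$start + half_rep + (0:(p$array_nucleosomes - 1)) * p$repeat_length
        dyads <- c(dyads, dy)
        # ~10 bp AA/TT phasing under each dyad, spaced at the nucleosomal
        # helical repeat (10.1 bp) so successive sites stay rotationally
        # coherent across the footprint
        for (d in dy) {
          at <- d - 73L + as.integer(round(10.1 * (0:14)))
          at <- at[at >= b$start & at + 1L < b$end]
          ww <- sample(c("A", "T"), length(at), replace = TRUE)
          bases[at + 1L] <- ww
          bases[at + 2L] <- ww
        }
      } else {
        # extended poly(dA:dT): homopolymer runs of 10-30 bp, then degraded
        # to at_purity with scattered G/C
        run_len <- integer(0)
        while (sum(run_len) < len) run_len <- c(run_len, sample(10:30, 1))
        run_base <- sample(c("A", "T"), length(run_len), replace = TRUE)
        seq_nd <- rep(run_base, run_len)[seq_len(len)]
        flip <- stats::runif(len) < (1 - p$at_purity)
        seq_nd[flip] <- sample(c("G", "C"), sum(flip), replace = TRUE)
        bases[sel] <- seq_nd
      }
    }
    ndr_blocks <- dplyr::bind_rows(purrr::map(
      purrr::keep(blocks, ~ .x$type == "ndr"),
      ~ tibble(chrom = p$chrom, start = .x$start, end = .x$end,
               length = .x$end - .x$start)))
    if (nrow(ndr_blocks) == 0) {
      ndr_blocks <- tibble(chrom = character(0), start = integer(0),
                           end = integer(0), length = integer(0))
    }
    array_blocks <- dplyr::bind_rows(purrr::map(
      purrr::keep(blocks, ~ .x$type == "array"),
      ~ tibble(chrom = p$chrom, start = .x$start, end = .x$end)))
    block_tbl <- dplyr::bind_rows(purrr::map(
      blocks, ~ tibble(chrom = p$chrom, type = .x$type,
                       start = .x$start, end = .x$end)))

    # planted truth must be internally consistent
    for (k in seq_len(nrow(ndr_blocks))) {
      stopifnot(!any(dyads >= ndr_blocks$start[k] & dyads < ndr_blocks$end[k]))
    }
    structure(list(
      genome = stats::setNames(paste(bases, collapse = ""), p$chrom),
      chrom_sizes = stats::setNames(as.numeric(total), p$chrom),
      dyads = tibble(chrom = p$chrom, pos = dyads),
      ndr_blocks = ndr_blocks,
      array_blocks = array_blocks,
      blocks = block_tbl,
      params = p,
      seed = p$seed
    ), class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %s: %d bp, %d planted dyads, %d depleted blocks (seed %d)\n",
              names(x$genome), nchar(x$genome), nrow(x$dyads),
              nrow(x$ndr_blocks), x$seed))
  invisible(x)
}

#' Sample a synthetic MNase fragment library
#'
#' `1 - background_fraction` of fragments pick a planted dyad uniformly and
#' center on it with Normal jitter; the rest center uniformly over the
#' chromosome. Lengths are Normal (rounded, clipped at 50 bp) and fragments
#' are clipped to the chromosome bounds.
#'
#' @param truth A [sim_genome()] result.
#' @param n_fragments Library size; defaults to the generator parameters.
#' @param seed Seed for the library draw; defaults to the truth seed + 1 so
#'   genome and library are independent but jointly reproducible.
#' @return A [fragments()] tibble with provenance `"synthetic"`.
#' @export
sim_fragments <- function(truth, n_fragments = NULL, seed = NULL) {
  p <- truth$params
  n <- as.integer(n_fragments %||% p$n_fragments)
  if (!is_count(n) || n <= 0) stop_usage("n_fragments must be a positive integer")
  seed <- seed %||% (p$seed + 1L)
  len_chr <- as.integer(truth$chrom_sizes[[1]])
  with_seed(seed, {
    n_bg <- as.integer(round(p$background_fraction * n))
    n_nuc <- n - n_bg
    ctr_nuc <- if (n_nuc > 0) {
      sample(truth$dyads$pos, n_nuc, replace = TRUE) +
        as.integer(round(stats::rnorm(n_nuc, 0, p$dyad_jitter_sd)))
    } else integer(0)
    ctr_bg <- if (n_bg > 0) as.integer(floor(stats::runif(n_bg, 0, len_chr))) else integer(0)
    center <- c(ctr_nuc, ctr_bg)
    len <- pmax(50L, as.integer(round(stats::rnorm(n, p$frag_len_mean, p$frag_len_sd))))
    start <- pmax(0L, center - len %/% 2L)
    end <- pmin(len_chr, start + len)
    ok <- end > start
    fr <- suppressMessages(fragments(
      tibble(chrom = p$chrom, start = start[ok], end = end[ok]),
      truth$chrom_sizes, provenance = "synthetic"))
    fr
  })
}

#' Plant scored feature sites
#'
#' Places ORC-like sites either at the centers of (distinct, randomly chosen)
#' depleted blocks or uniformly over the chromosome, with scores drawn from
#' `score_law`.
#'
#' @param truth A [sim_genome()] result.
#' @param n_sites Number of sites.
#' @param score_law A single number (constant score) or a function `n ->
#'   numeric(n)` (default `Uniform(5, 10)`).
#' @param placement `"ndr"` (default; errors if fewer depleted blocks than
#'   sites) or `"uniform"`.
#' @param seed Seed; defaults to the truth seed + 2.
#' @return A [feature_sites()] tibble.
#' @export
sim_sites <- function(truth, n_sites, score_law = function(n) stats::runif(n, 5, 10),
                      placement = c("ndr", "uniform"), seed = NULL) {
  placement <- match.arg(placement)
  seed <- seed %||% (truth$params$seed + 2L)
  with_seed(seed, {
    centers <- if (placement == "ndr") {
      if (nrow(truth$ndr_blocks) < n_sites) {
        stop_usage("fewer depleted blocks than requested sites")
      }
      blocks <- truth$ndr_blocks[sample(nrow(truth$ndr_blocks), n_sites), ]
      blocks$start + (blocks$end - blocks$start) %/% 2L
    } else {
      as.integer(floor(stats::runif(n_sites, 0, truth$chrom_sizes[[1]])))
    }
    scores <- if (is.function(score_law)) score_law(n_sites) else
      rep(as.numeric(score_law), n_sites)
    feature_sites(tibble(chrom = truth$params$chrom, center = centers,
                         score = scores))
  })
}

#' Planted-footprint indicator track
#'
#' Per-base indicator (0/1) of coverage by a planted nucleosome footprint
#' (dyad +/- footprint/2); the generator's own notion of occupied sequence.
#'
#' @param truth A [sim_genome()] result.
#' @return An `occ_track` of kind `"raw"`.
#' @export
planted_occupancy <- function(truth) {
  p <- truth$params
  len <- as.integer(truth$chrom_sizes[[1]])
  s <- pmax(0L, truth$dyads$pos - p$footprint %/% 2L)
  e <- pmin(len, s + p$footprint)
  d <- tabulate(s + 1L, nbins = len + 1L) - tabulate(e + 1L, nbins = len + 1L)
  occ_track(pmin(cumsum(d)[seq_len(len)], 1), p$chrom, "raw")
}

#' Synthetic in-vitro binding table
#'
#' Emulates a locus-spanning set of naked-DNA fragments with measured
#' relative binding that decreases with planted nucleosome occupancy (an
#' ORC-like preference for nucleosome-disfavored sequence): the fragments are
#' the first `n_fragments` planted blocks in genomic order, and binding is
#' `scale * (1 - f) + Normal(0, noise_sd)` clipped at 0, where `f` is the
#' fragment's planted-footprint coverage fraction.
#'
#' @param truth A [sim_genome()] result.
#' @param n_fragments Number of blocks to use (default 40).
#' @param scale Binding scale (default 10).
#' @param noise_sd Gaussian noise SD on the binding values (default 0.3).
#' @param seed Seed; defaults to the truth seed + 3.
#' @return Tibble `chrom`, `start`, `end`, `binding`.
#' @export
sim_invitro_binding <- function(truth, n_fragments = 40, scale = 10,
                                noise_sd = 0.3, seed = NULL) {
  if (nrow(truth$blocks) < n_fragments) {
    stop_usage("fewer planted blocks than requested fragments")
  }
  seed <- seed %||% (truth$params$seed + 3L)
  blk <- truth$blocks[seq_len(n_fragments), ]
  occ <- planted_occupancy(truth)
  cs <- c(0, cumsum(occ$values))
  f <- (cs[blk$end + 1] - cs[blk$start + 1]) / (blk$end - blk$start)
  with_seed(seed, {
    tibble(chrom = blk$chrom, start = blk$start, end = blk$end,
           binding = pmax(0, scale * (1 - f) + stats::rnorm(n_fragments, 0, noise_sd)))
  })
}

#' Write fragments as minimal 6-column BED-PE
#'
#' Each fragment is emitted as a mate pair of 50 bp reads at its two ends
#' (overlapping for fragments under 100 bp), the minimal mate-pair dialect
#' [read_fragments()] accepts.
#'
#' @param frags A fragment set.
#' @param path Output path.
#' @param read_len Mate read length (default 50).
#' @return `path`, invisibly.
#' @export
write_fragments_bedpe <- function(frags, path, read_len = 50) {
  out <- tibble(
    chrom1 = frags$chrom, start1 = frags$start,
    end1 = pmin(frags$end, frags$start + read_len),
    chrom2 = frags$chrom, start2 = pmax(frags$start, frags$end - read_len),
    end2 = frags$end
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write / read the planted-truth sidecar
#'
#' A plain-text record of the planted truth (not the genome sequence, which
#' goes to FASTA): `#param` lines with the generator parameters, then one
#' line per planted feature (`dyad`, `ndr`, `array`).
#'
#' @param truth A [sim_genome()] result.
#' @param path Output path.
#' @return `path`, invisibly (writer); a list with `params` (character),
#'   `dyads`, `ndr_blocks`, `array_blocks` tibbles (reader).
#' @export
write_truth_sidecar <- function(truth, path) {
  p <- truth$params
  scalars <- p[!vapply(p, function(v) length(v) > 1, logical(1))]
  lines <- c(
    sprintf("#param\t%s\t%s", names(scalars), vapply(scalars, as.character, character(1))),
    sprintf("#param\tndr_block_lengths\t%s", paste(p$ndr_block_lengths, collapse = ",")),
    sprintf("dyad\t%s\t%d", truth$dyads$chrom, truth$dyads$pos),
    sprintf("ndr\t%s\t%d\t%d", truth$ndr_blocks$chrom, truth$ndr_blocks$start,
            truth$ndr_blocks$end),
    sprintf("array\t%s\t%d\t%d", truth$array_blocks$chrom,
            truth$array_blocks$start, truth$array_blocks$end)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth_sidecar
#' @export
read_truth_sidecar <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(fields, `[[`, character(1), 1)
  get3 <- function(t) {
    f <- fields[tag == t]
    if (length(f) == 0) return(tibble(chrom = character(0), start = integer(0),
                                      end = integer(0)))
    tibble(chrom = vapply(f, `[[`, character(1), 2),
           start = as.integer(vapply(f, `[[`, character(1), 3)),
           end = as.integer(vapply(f, `[[`, character(1), 4)))
  }
  dy <- fields[tag == "dyad"]
  list(
    params = stats::setNames(
      vapply(fields[tag == "#param"], `[[`, character(1), 3),
      vapply(fields[tag == "#param"], `[[`, character(1), 2)),
    dyads = tibble(chrom = vapply(dy, `[[`, character(1), 2),
                   pos = as.integer(vapply(dy, `[[`, character(1), 3))),
    ndr_blocks = get3("ndr"),
    array_blocks = get3("array")
  )
}
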