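#' Sequence-preference model parameters
#'
#' The nucleosome sequence-preference model combines two well-established
#' signals: a ~10 bp periodic preference for flexible A/T-containing
#' dinucleotides (which lets DNA bend anisotropically around the octamer) and
#' a strong penalty for poly(dA:dT) runs (stiff DNA that resists wrapping).
#' Equilibrium occupancy then follows from steric exclusion of fixed-length
#' particles (a hard-rod / Tonks-gas ensemble).
#'
#' @param footprint Nucleosome length L in bp (default 147).
#' @param period Dinucleotide phasing period p in bp (default 10.1, the
#'   helical repeat of nucleosomal DNA).
#' @param alpha Weight of the periodicity term (>= 0, default 1).
#' @param beta Weight of the poly(dA:dT) penalty (>= 0, default 4).
#' @param mu Chemical potential: log statistical weight per placed nucleosome
#'   (default 0).
#' @return A `seq_pref_model` list.
#' @export
seq_pref_model <- function(footprint = 147, period = 10.1, alpha = 1,
                           beta = 4, mu = 0) {
  stopifnot(footprint >= 2, period > 0, alpha >= 0, beta >= 0,
            is.finite(alpha), is.finite(beta), is.finite(mu))
  structure(list(L = as.integer(footprint), p = period, alpha = alpha,
                 beta = beta, mu = mu), class = "seq_pref_model")
}

# Uppercase character scalar -> list of logical base indicators.
seq_indicators <- function(seq) {
  if (inherits(seq, "XString")) seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1) stop_usage("`seq` must be a single DNA string")
  b <- charToRaw(toupper(seq))
  list(
    A = b == charToRaw("A"), C = b == charToRaw("C"),
    G = b == charToRaw("G"), T = b == charToRaw("T"),
    n = length(b)
  )
}

#' Per-position nucleosome binding energy
#'
#' For each possible nucleosome start `i` (0-based; the particle occupies
#' `[i, i + L)`), computes the dimensionless energy
#' `E(i) = -alpha * s_per(i) + beta * f_AT5(i)` where
#' `s_per(i) = (1/L) * sum_j cos(2*pi*(j - (L-2)/2)/p) * d(i + j)` over the
#' L-1 dinucleotide positions `j = 0..L-2`, with `d = +1` for WW dinucleotides
#' (AA, AT, TA, TT), `-1` for SS (CC, CG, GC, GG), 0 otherwise (the cosine is
#' anchored at the dyad, making the kernel palindromic, so the energy is
#' strand-symmetric: reverse-complementing the sequence reverses the energy
#' profile), and
#' `f_AT5(i)` is the fraction of the L-4 five-mers inside the footprint that
#' are AAAAA or TTTTT. Lower energy means a more favorable position.
#' Dinucleotides or 5-mers touching an ambiguous base (N) contribute 0 and
#' never count as poly A/T; footprints containing any N are flagged.
#'
#' @param seq DNA string (alphabet A, C, G, T, N; case-insensitive).
#' @param model A [seq_pref_model()].
#' @return An `energy_track`: list with `E` (length `nchar(seq) - L + 1`),
#'   `L`, `N` (sequence length), `contains_n` (logical per start).
#' @export
nucleosome_energy <- function(seq, model = seq_pref_model()) {
  si <- seq_indicators(seq)
  L <- model$L
  if (si$n < L) stop_usage("sequence shorter than the nucleosome footprint")
  isW <- si$A | si$T
  isS <- si$C | si$G
  n <- si$n
  d <- numeric(n - 1)
  d[isW[-n] & isW[-1]] <- 1
  d[isS[-n] & isS[-1]] <- -1
  kern <- cos(2 * pi * ((0:(L - 2)) - (L - 2) / 2) / model$p)
  # sliding dot product of d with the cosine kernel:
  # convolve(x, y, type = "filter")[i] = sum_j x[i+j-1] * y[j]
  s_per <- as.numeric(stats::convolve(d, kern, type = "filter")) / L

  if (L >= 5) {
    a5 <- (moving_sum(si$A, 5) == 5) | (moving_sum(si$T, 5) == 5)
    f_at5 <- moving_sum(as.numeric(a5), L - 4) / (L - 4)
  } else {
    f_at5 <- numeric(n - L + 1)   # no 5-mer fits inside the footprint
  }

  isN <- !(isW | isS)
  contains_n <- moving_sum(as.numeric(isN), L) > 0

  structure(list(E = -model$alpha * s_per + model$beta * f_at5,
                 L = L, N = n, contains_n = contains_n),
            class = "energy_track")
}

#' @export
print.energy_track <- function(x, ...) {
  cat(sprintf("<energy_track> %d start positions (L=%d)  E in [%.3g, %.3g]\n",
              length(x$E), x$L, min(x$E), max(x$E)))
  invisible(x)
}

#' Equilibrium nucleosome occupancy by hard-rod dynamic programming
#'
#' Treats nucleosomes as non-overlapping rods of length L on the sequence,
#' each placement at start `i` carrying statistical weight
#' `w(i) = exp(mu - E(i))`, and computes the exact equilibrium ensemble by
#' partition-function recursion: forward partial sums
#' `F(b) = F(b-1) + w(b-L+1) * F(b-L)` (with `F(-1) = 1`), the mirrored
#' backward sums `R(b)`, and
#' `start_prob(i) = F(i-1) * w(i) * R(i+L) / Z` with `Z = F(N-1)`. Per-base
#' occupancy is the sum of start probabilities whose footprint covers the
#' base. All arithmetic is in log space (log-sum-exp), so the partition
#' function cannot overflow on long sequences.
#'
#' @param E An [nucleosome_energy()] track (finite energies).
#' @param model The [seq_pref_model()] supplying `mu` (and `L`, which must
#'   match the track).
#' @return A `pred_occupancy`: list with `occ` (per-base coverage
#'   probability, length N), `start_prob` (per-start probability, length
#'   N - L + 1), `L`, `log_z`.
#' @export
equilibrium_occupancy <- function(E, model = seq_pref_model()) {
  if (!inherits(E, "energy_track")) stop_usage("`E` must be an energy_track")
  if (model$L != E$L) stop_usage("model footprint does not match the energy track")
  if (any(!is.finite(E$E))) stop_input("non-finite energy")
  L <- E$L
  N <- E$N
  M <- length(E$E)           # = N - L + 1 start positions
  logw <- model$mu - E$E

  lf <- numeric(N)           # lf[j] = log F(base j-1)
  for (j in seq_len(N)) {
    t1 <- if (j >= 2) lf[j - 1] else 0
    if (j >= L) {
      i <- j - L + 1L        # 1-based start index
      t2 <- logw[i] + (if (i >= 2) lf[i - 1] else 0)
      m <- max(t1, t2)
      lf[j] <- m + log1p(exp(min(t1, t2) - m))
    } else {
      lf[j] <- t1
    }
  }
  lr <- numeric(N + 1)       # lr[j] = log R(base j-1); lr[N+1] = log R(N) = 0
  for (j in seq(N, 1)) {
    t1 <- lr[j + 1]
    if (j <= M) {
      t2 <- logw[j] + lr[j + L]    # R(base j-1+L) lives at lr[j+L]; lr[N+1] = 0
      m <- max(t1, t2)
      lr[j] <- m + log1p(exp(min(t1, t2) - m))
    } else {
      lr[j] <- t1
    }
  }
  log_z <- lf[N]

  # R(i + L) for 0-based start i = i1 - 1 lives at lr[i1 + L]
  i1 <- seq_len(M)
  log_sp <- ifelse(i1 >= 2, lf[pmax(i1 - 1, 1)], 0) + logw +
    lr[i1 + L] - log_z
  sp <- exp(log_sp)

  cs <- c(0, cumsum(sp))
  b <- 0:(N - 1)
  occ <- cs[pmin(b, M - 1) + 2] - cs[pmax(0, b - L + 1) + 1]
  structure(list(occ = occ, start_prob = sp, L = L, log_z = log_z),
            class = "pred_occupancy")
}

#' @export
print.pred_occupancy <- function(x, ...) {
  cat(sprintf("<pred_occupancy> %d bp  mean occ=%.3f  E[nucleosomes]=%.2f\n",
              length(x$occ), mean(x$occ), sum(x$start_prob)))
  invisible(x)
}

#' Predict nucleosome occupancy from sequence
#'
#' Convenience wrapper: [nucleosome_energy()] followed by
#' [equilibrium_occupancy()].
#'
#' @inheritParams nucleosome_energy
#' @return A `pred_occupancy`.
#' @export
predict_occupancy <- function(seq, model = seq_pref_model()) {
  equilibrium_occupancy(nucleosome_energy(seq, model), model)
}

#' Sliding-window nucleotide composition
#'
#' Base fractions over centered sliding windows (step 1). Fractions are taken
#' over unambiguous bases only; windows of pure N yield NA. For window `w`,
#' the window at center `c` spans `[c - floor(w/2), c - floor(w/2) + w)` and
#' centers run over every position with a full window.
#'
#' @param seq DNA string.
#' @param window Window size in bp (default 50).
#' @return A `composition_track` tibble: `pos` (0-based window center), `fA`,
#'   `fC`, `fG`, `fT`.
#' @export
nucleotide_composition <- function(seq, window = 50) {
  si <- seq_indicators(seq)
  if (si$n < window) stop_usage("sequence shorter than the composition window")
  denom <- moving_sum(as.numeric(si$A | si$C | si$G | si$T), window)
  denom[denom == 0] <- NA_real_
  out <- tibble(
    pos = window %/% 2 + 0:(si$n - window),
    fA = moving_sum(as.numeric(si$A), window) / denom,
    fC = moving_sum(as.numeric(si$C), window) / denom,
    fG = moving_sum(as.numeric(si$G), window) / denom,
    fT = moving_sum(as.numeric(si$T), window) / denom
  )
  structure(out, window = window, class = c("composition_track", class(out)))
}

#' Find poly(dA:dT) tracts
#'
#' `mode = "pure"` reports maximal runs consisting only of A/T with length at
#' least `min_len`. `mode = "windowed"` reports maximal intervals in which
#' every length-`window` subwindow has A/T fraction at least `purity`
#' (tolerating isolated non-A/T interruptions), trimmed to the outermost A/T
#' bases; intervals whose expansions overlap are merged. Tracts are sorted,
#' non-overlapping, and carry their realized A/T purity.
#'
#' @param seq DNA string.
#' @param min_len Minimum reported tract length in bp (default 20).
#' @param mode `"pure"` or `"windowed"`.
#' @param purity Minimum per-subwindow A/T fraction for windowed mode, in
#'   (0, 1] (default 0.9).
#' @param window Subwindow length for windowed mode (default 20).
#' @return Tibble `start`, `end` (0-based half-open), `length`, `purity`.
#' @export
find_polyat_tracts <- function(seq, min_len = 20, mode = c("pure", "windowed"),
                               purity = 0.9, window = 20) {
  mode <- match.arg(mode)
  if (!is.numeric(purity) || purity <= 0 || purity > 1) {
    stop_usage("purity must lie in (0, 1]")
  }
  si <- seq_indicators(seq)
  isAT <- si$A | si$T
  empty <- tibble(start = integer(0), end = integer(0), length = integer(0),
                  purity = numeric(0))
  if (si$n == 0) return(empty)

  if (mode == "pure") {
    r <- rle(isAT)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths >= min_len
    if (!any(keep)) return(empty)
    return(tibble(start = starts[keep], end = ends[keep],
                  length = r$lengths[keep], purity = 1))
  }

  if (si$n < window) return(empty)
  ok <- moving_sum(as.numeric(isAT), window) / window >= purity
  r <- rle(ok)
  ends_s <- cumsum(r$lengths)
  starts_s <- ends_s - r$lengths     # 0-based first subwindow start of the run
  keep <- which(r$values)
  if (length(keep) == 0) return(empty)
  iv <- tibble(start = starts_s[keep], end = ends_s[keep] - 1L + window)
  # merge expansions that overlap
  iv <- dplyr::arrange(iv, .data$start)
  merged <- list(c(iv$start[1], iv$end[1]))
  for (k in seq_len(nrow(iv))[-1]) {
    last <- merged[[length(merged)]]
    if (iv$start[k] < last[2]) {
      merged[[length(merged)]][2] <- max(last[2], iv$end[k])
    } else {
      merged[[length(merged) + 1]] <- c(iv$start[k], iv$end[k])
    }
  }
  rows <- purrr::map(merged, function(m) {
    s <- m[1]; e <- m[2]
    while (s < e && !isAT[s + 1]) s <- s + 1
    while (e > s && !isAT[e]) e <- e - 1
    if (e - s < min_len) return(NULL)
    tibble(start = as.integer(s), end = as.integer(e),
           length = as.integer(e - s), purity = mean(isAT[(s + 1):e]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences, one per record.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Write a genome FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write predicted occupancy (or an energy track) as TSV
#' @param x A `pred_occupancy` or `energy_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seqpref_tsv <- function(x, path) {
  readr::write_tsv(tidy(x), path, col_names = TRUE)
  invisible(path)
}
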