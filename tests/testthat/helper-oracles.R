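# Independent oracles and shared fixtures. Oracles are deliberately naive
# (enumeration, direct summation) and never share code with the package.

# --- hard-rod enumeration oracle ------------------------------------------
# Exhaustively enumerates every non-overlapping placement of L-rods on a
# lattice of N sites and marginalizes the start probabilities.
enum_start_prob <- function(E, L, mu, N) {
  M <- N - L + 1
  all_cfg <- list(integer(0))
  frontier <- list(integer(0))
  while (length(frontier)) {
    nxt <- list()
    for (cfg in frontier) {
      last_end <- if (length(cfg)) max(cfg) + L else 0
      if (last_end <= M - 1) {
        for (i in last_end:(M - 1)) {
          c2 <- c(cfg, i)
          all_cfg[[length(all_cfg) + 1]] <- c2
          nxt[[length(nxt) + 1]] <- c2
        }
      }
    }
    frontier <- nxt
  }
  w <- exp(mu - E)
  Z <- 0
  sp <- numeric(M)
  for (cfg in all_cfg) {
    wt <- prod(w[cfg + 1])
    Z <- Z + wt
    if (length(cfg)) sp[cfg + 1] <- sp[cfg + 1] + wt
  }
  sp / Z
}

# energy_track constructor bypassing sequence parsing, for synthetic E vectors
manual_energy_track <- function(E, L, N) {
  structure(list(E = E, L = as.integer(L), N = as.integer(N),
                 contains_n = rep(FALSE, length(E))),
            class = "energy_track")
}

# --- direct discrete-Fourier-sum oracle -----------------------------------
# Low-pass reconstruction from explicitly summed DFT coefficients.
dft_lowpass_oracle <- function(x, k) {
  n <- length(x)
  kept <- if (k >= 2) c(0:(k - 1), (n - k + 1):(n - 1)) else 0
  t <- 0:(n - 1)
  y <- rep(0 + 0i, n)
  for (f in kept) {
    Xf <- sum(x * exp(-2i * pi * f * t / n))
    y <- y + Xf * exp(2i * pi * f * t / n)
  }
  Re(y) / n
}

# --- direct per-start energy oracle ---------------------------------------
direct_energy_oracle <- function(seq, model) {
  L <- model$L
  b <- strsplit(toupper(seq), "")[[1]]
  n <- length(b)
  dd <- function(k) {
    di <- paste0(b[k + 1], b[k + 2])
    if (di %in% c("AA", "AT", "TA", "TT")) 1
    else if (di %in% c("CC", "CG", "GC", "GG")) -1
    else 0
  }
  vapply(0:(n - L), function(i) {
    sper <- sum(vapply(0:(L - 2), function(j) cos(2 * pi * (j - (L - 2) / 2) / model$p) * dd(i + j),
                       numeric(1))) / L
    f5 <- sum(vapply(i:(i + L - 5), function(k) {
      paste(b[(k + 1):(k + 5)], collapse = "") %in% c("AAAAA", "TTTTT")
    }, logical(1))) / (L - 4)
    -model$alpha * sper + model$beta * f5
  }, numeric(1))
}

# --- misc -----------------------------------------------------------------
# distance from each a to its nearest b (both sorted or not)
nearest_dist <- function(a, b) {
  b <- sort(b)
  i <- findInterval(a, b)
  pmin(abs(a - b[pmax(i, 1)]), abs(a - b[pmin(i + 1, length(b))]))
}

reverse_complement <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# --- shared simulations (built once per test run) -------------------------
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache, inherits = FALSE)
}

medium_truth <- function() cached("mt", sim_genome(
  sim_params(chrom_length = 150000, n_fragments = 30000, seed = 11)))

medium_frags <- function() cached("mf", suppressMessages(
  filter_by_length(sim_fragments(medium_truth()))))

medium_peaks <- function() cached("mp", {
  fr <- medium_frags()
  raw <- coverage_track(fr, "chrS", mode = "dyad")
  call_peaks(fft_smooth(raw), raw, fr)
})
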