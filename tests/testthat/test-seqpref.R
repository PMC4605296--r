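test_that("homopolymer energies follow the closed form", {
  m <- seq_pref_model()
  L <- m$L
  csum <- sum(cos(2 * pi * ((0:(L - 2)) - (L - 2) / 2) / m$p)) / L

  polyA <- nucleosome_energy(strrep("A", 200), m)
  expect_equal(polyA$E, rep(-m$alpha * csum + m$beta, 200 - L + 1))

  polyG <- nucleosome_energy(strrep("G", 200), m)
  expect_equal(polyG$E, rep(m$alpha * csum, 200 - L + 1))

  expect_error(nucleosome_energy(strrep("A", 100), m), class = "nucmap_usage_error")
})

test_that("phased AA dinucleotides lower the in-phase energy (direct-sum oracle)", {
  m <- seq_pref_model(footprint = 40, period = 10, alpha = 1, beta = 4)
  b <- rep("C", 200)
  for (k in seq(1, 191, by = 10)) b[k:(k + 1)] <- "A"   # AA at 0-based 0,10,20,...
  s <- paste(b, collapse = "")
  et <- nucleosome_energy(s, m)
  expect_equal(et$E, direct_energy_oracle(s, m), tolerance = 1e-12)
  # 0-based start 10 puts every planted AA at phase 0; start 15 at phase pi
  expect_lt(et$E[11], et$E[16])
})

test_that("energy is invariant under reverse complement", {
  set.seed(41)
  s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  m <- seq_pref_model(footprint = 50)
  e1 <- nucleosome_energy(s, m)$E
  e2 <- nucleosome_energy(reverse_complement(s), m)$E
  expect_equal(sort(e1), sort(e2), tolerance = 1e-12)
  expect_equal(e2, rev(e1), tolerance = 1e-12)
})

test_that("a single-position lattice reduces to the two-state weight", {
  et <- manual_energy_track(0.7, 5, 5)
  g <- equilibrium_occupancy(et, seq_pref_model(footprint = 5, mu = 0.2))
  w <- exp(0.2 - 0.7)
  expect_equal(g$start_prob, w / (1 + w), tolerance = 1e-12)
  expect_equal(g$occ, rep(w / (1 + w), 5), tolerance = 1e-12)
})

test_that("the empty-lattice limit empties the sequence", {
  et <- manual_energy_track(rep(0, 96), 5, 100)
  g <- equilibrium_occupancy(et, seq_pref_model(footprint = 5, mu = -50))
  expect_true(all(g$occ <= 1e-20))
})

test_that("the DP matches exhaustive enumeration and its own summation identity", {
  set.seed(42)
  worst <- 0
  for (rep in 1:10) {
    N <- sample(3:12, 1)
    L <- 3L
    E <- rnorm(N - L + 1)
    mu <- rnorm(1)
    g <- equilibrium_occupancy(manual_energy_track(E, L, N),
                               seq_pref_model(footprint = L, mu = mu))
    worst <- max(worst, max(abs(g$start_prob - enum_start_prob(E, L, mu, N))))
    occ2 <- vapply(0:(N - 1), function(b) {
      sum(g$start_prob[(max(0, b - L + 1):min(b, N - L)) + 1])
    }, numeric(1))
    expect_equal(g$occ, occ2, tolerance = 1e-9)
    expect_true(all(g$occ >= 0 & g$occ <= 1 + 1e-12))
    expect_lte(sum(g$start_prob), N / L + 1e-9)
  }
  expect_lt(worst, 1e-9)
})

test_that("mean occupancy is monotone in the chemical potential", {
  # per-base occupancy is NOT monotone for inhomogeneous hard rods (higher
  # density can favor tilings that exclude a locally favorable position);
  # the grand-canonical identity d E[N]/d mu = Var(N) >= 0 makes the mean
  # occupancy monotone, and that is the property asserted here
  set.seed(43)
  for (rep in 1:5) {
    E <- rnorm(80)
    et <- manual_energy_track(E, 10, 89)
    means <- vapply(c(-2, 0, 2), function(mu) {
      mean(equilibrium_occupancy(et, seq_pref_model(footprint = 10, mu = mu))$occ)
    }, numeric(1))
    expect_true(all(diff(means) >= -1e-12))
  }
})

test_that("predicted occupancy is depleted over planted poly A:T blocks", {
  truth <- medium_truth()
  po <- predict_occupancy(truth$genome[[1]])
  at_idx <- unlist(mapply(function(s, e) (s + 1):e,
                          truth$ndr_blocks$start, truth$ndr_blocks$end))
  gc_idx <- unlist(mapply(function(s, e) (s + 1):e,
                          truth$array_blocks$start, truth$array_blocks$end))
  expect_lt(mean(po$occ[at_idx]), mean(po$occ[gc_idx]))
})

test_that("composition windows count bases and exclude ambiguity codes", {
  ct <- nucleotide_composition(strrep("A", 100))
  expect_true(all(ct$fA == 1))
  expect_equal(nrow(ct), 51)
  expect_equal(ct$pos[1], 25)

  ct4 <- nucleotide_composition(strrep("ACGT", 25), window = 48)
  expect_true(all(abs(ct4$fA - 0.25) < 1e-12))
  expect_true(all(abs(ct4$fG - 0.25) < 1e-12))

  # direct count oracle at window 50 on a random sequence with N bases
  set.seed(44)
  b <- sample(c("A", "C", "G", "T", "N"), 300, TRUE, prob = c(.24, .24, .24, .24, .04))
  s <- paste(b, collapse = "")
  ct5 <- nucleotide_composition(s, window = 50)
  i <- 100   # 0-based window start for some interior center
  win <- b[(i + 1):(i + 50)]
  ctr <- i + 25
  row <- ct5[ct5$pos == ctr, ]
  expect_equal(row$fA, sum(win == "A") / sum(win != "N"))
  expect_equal(row$fT, sum(win == "T") / sum(win != "N"))
  sums <- ct5$fA + ct5$fC + ct5$fG + ct5$fT
  expect_true(all(abs(sums - 1) < 1e-9))

  expect_error(nucleotide_composition("ACGT", window = 50),
               class = "nucmap_usage_error")
})

test_that("pure poly A:T tracts are maximal runs above the length floor", {
  s <- paste0(strrep("G", 10), strrep("AT", 40), strrep("G", 10))
  tr <- find_polyat_tracts(s, mode = "pure")
  expect_equal(nrow(tr), 1)
  expect_equal(tr$start, 10L)
  expect_equal(tr$end, 90L)
  expect_equal(tr$length, 80L)

  split <- paste0(strrep("A", 19), "G", strrep("A", 19))
  expect_equal(nrow(find_polyat_tracts(split, mode = "pure")), 0)
  w <- find_polyat_tracts(split, mode = "windowed", purity = 0.9)
  expect_equal(nrow(w), 1)
  expect_equal(c(w$start, w$end), c(0L, 39L))
  expect_equal(w$purity, 38 / 39)
})

test_that("pure-mode tracts equal a regular-expression scan oracle", {
  set.seed(45)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE,
                    prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
  tr <- find_polyat_tracts(s, min_len = 10, mode = "pure")
  m <- gregexpr("[AT]{10,}", s)[[1]]
  expect_equal(tr$start, as.integer(m) - 1L)
  expect_equal(tr$length, attr(m, "match.length"))
  expect_error(find_polyat_tracts(s, purity = 2, mode = "windowed"),
               class = "nucmap_usage_error")
})

test_that("FASTA round-trips through Biostrings", {
  g <- c(chrA = "ACGTACGTAAATTTGGGCCC", chrB = "TTTTAAAA")
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, f)
  expect_equal(read_genome_fasta(f), g)
})
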