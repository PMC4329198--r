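test_that("infeasible configurations are rejected before anything is generated", {
  expect_error(sim_config(read_length = 5000, genome_length = 2000), "read_length")
  expect_error(sim_config(marker_length = 2000, genome_length = 1000), "marker_length")
  expect_error(sim_config(composition = c(0.5, 0.5)), "weight")
  expect_error(sim_config(host_fraction = 1.2), "host_fraction")
  expect_error(sim_config(error_rate = 0.5), "error_rate")
  expect_error(sim_config(marker_copies_per_genome = 10, marker_length = 5000,
                          genome_length = 30000), "copies")
})

test_that("generation is byte-identical for the same seed and differs across seeds", {
  cfg <- sim_config(seed = 61, n_reads = 500, host_length = 20000,
                    genome_length = 5000, marker_length = 300,
                    read_length = 80, error_rate = 0.01)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  simulate_dataset(cfg, out_dir = d1)
  simulate_dataset(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  cfg2 <- sim_config(seed = 62, n_reads = 500, host_length = 20000,
                     genome_length = 5000, marker_length = 300,
                     read_length = 80, error_rate = 0.01)
  d3 <- file.path(tempdir(), "sim_c")
  simulate_dataset(cfg2, out_dir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "reads.fastq"))),
                         unname(tools::md5sum(file.path(d3, "reads.fastq")))))
})

test_that("truth table, reads file, and marker embedding are mutually consistent", {
  cfg <- sim_config(seed = 63, n_reads = 800, host_length = 20000,
                    genome_length = 5000, marker_length = 300,
                    read_length = 80, host_fraction = 0.5, error_rate = 0.01)
  dir <- file.path(tempdir(), "sim_d")
  sim <- simulate_dataset(cfg, out_dir = dir)

  expect_equal(nrow(sim$truth), nrow(sim$reads))
  fq <- read_reads(file.path(dir, "reads.fastq"))
  expect_equal(fq$read_id, sim$reads$read_id)
  expect_equal(fq$sequence, sim$reads$sequence)
  expect_true(all(!is.na(sim$truth$genus[sim$truth$origin == "FUNGAL"])))
  expect_true(all(is.na(sim$truth$genus[sim$truth$origin == "HOST"])))

  # markers really sit in the genomes at the recorded coordinates
  for (i in seq_len(nrow(sim$marker_coords))) {
    mc <- sim$marker_coords[i, ]
    g <- sim$genomes[sim$genomes$record_id == mc$genome_id, ]
    expect_equal(substr(g$sequence, mc$start, mc$end),
                 sim$markers$sequence[sim$markers$genus == g$genus])
  }

  # the written reference files reload to the in-memory sets
  back <- read_reference_set(file.path(dir, "markers.fasta"),
                             file.path(dir, "markers_taxonomy.tsv"))
  expect_equal(back$sequence, sim$markers$sequence)
  expect_equal(back$genus, sim$markers$genus)
})

test_that("host/fungal split and realized error counts follow their sampling models", {
  cfg <- sim_config(seed = 64, n_reads = 100000, host_length = 50000,
                    genome_length = 10000, marker_length = 500,
                    read_length = 100, host_fraction = 0.83,
                    error_rate = 0.01)
  sim <- simulate_dataset(cfg)

  # host fraction within binomial 3 sigma of 0.83
  p <- cfg$host_fraction
  n <- cfg$n_reads
  obs <- mean(sim$truth$origin == "HOST")
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))

  # per-read error counts ~ Binomial(L, e): chi-squared goodness of fit
  e <- cfg$error_rate
  L <- cfg$read_length
  tab <- tabulate(sim$truth$n_errors + 1L, nbins = L + 1L)
  probs <- dbinom(0:L, L, e)
  cut <- 5L  # pool the sparse tail
  obs_k <- c(tab[1:cut], sum(tab[-(1:cut)]))
  exp_p <- c(probs[1:cut], 1 - sum(probs[1:cut]))
  gof <- suppressWarnings(chisq.test(obs_k, p = exp_p))
  expect_gt(gof$p.value, 1e-3)

  # composition of fungal reads within multinomial 3 sigma of the weights
  ft <- sim$truth[sim$truth$origin == "FUNGAL", ]
  nf <- nrow(ft)
  for (g in seq_along(cfg$composition)) {
    w <- cfg$composition[g]
    obs_w <- mean(ft$genus == sprintf("Genus%02d", g))
    expect_lt(abs(obs_w - w), 3 * sqrt(w * (1 - w) / nf))
  }
})

test_that("expected marker-read fraction: closed form, caps, and Monte-Carlo check", {
  cfg <- sim_config(seed = 65, genome_length = 10000, marker_length = 500,
                    read_length = 100)
  expect_equal(expected_marker_read_fraction(cfg), (500 + 99) / 10000)

  whole <- sim_config(seed = 65, genome_length = 1000, marker_length = 999,
                      read_length = 100)
  expect_equal(expected_marker_read_fraction(whole), 1)

  # Monte-Carlo placement simulation (uniform starts, overlap test)
  set.seed(66)
  G <- 10000L; m <- 500L; L <- 100L
  m_start <- 4000L; m_end <- m_start + m - 1L
  starts <- sample.int(G - L + 1L, 1e6, replace = TRUE)
  mc <- mean(starts <= m_end & (starts + L - 1L) >= m_start)
  f <- expected_marker_read_fraction(cfg)
  # 3 sigma of the MC estimate plus the small edge-effect term (~ f*(L-1)/G)
  tol <- 3 * sqrt(f * (1 - f) / 1e6) + f * (L - 1) / G
  expect_lt(abs(mc - f), tol)
})

test_that("fungal reads fully inside a marker copy are recovered by the matcher", {
  cfg <- sim_config(seed = 67, n_reads = 5000, host_fraction = 0,
                    genome_length = 8000, marker_length = 500,
                    read_length = 100, error_rate = 0)
  sim <- simulate_dataset(cfg)
  idx <- build_index(sim$markers, 16)
  hits <- align_reads(sim$reads[, 1:2], idx, 1.0)
  inside <- sim$truth$read_id[sim$truth$within_marker]
  expect_setequal(matched_reads(hits), inside)
  # observed within-marker rate agrees with the exact containment probability
  p_within <- (cfg$marker_length - cfg$read_length + 1) /
    (cfg$genome_length - cfg$read_length + 1)
  expect_lt(abs(mean(sim$truth$within_marker) - p_within),
            3 * sqrt(p_within * (1 - p_within) / nrow(sim$truth)))
})
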