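test_that("mismatch budget floors the identity allowance", {
  expect_identical(mismatch_budget(100, 0.95), 5L)
  expect_identical(mismatch_budget(76, 0.95), 3L)   # floor(3.8)
  expect_identical(mismatch_budget(100, 1.0), 0L)
  expect_identical(mismatch_budget(10, 0.9), 1L)    # fp-safe floor
  expect_error(mismatch_budget(100, 0), "identity")
  expect_error(mismatch_budget(100, 1.2), "identity")
})

test_that("seed index posting counts equal sum(len - k + 1)", {
  set.seed(21)
  one <- reference_set("r1", "ACGTACGT", "P;S;C;O;F;G;SP")
  expect_equal(index_stats(build_index(one, k = 8))$n_postings, 1)
  lens <- sample(30:90, 20, replace = TRUE)
  rs <- reference_set(sprintf("r%02d", 1:20),
                      vapply(lens, random_seq, ""),
                      rep("P;S;C;O;F;G;SP", 20))
  k <- 12L
  expect_equal(index_stats(build_index(rs, k))$n_postings,
               sum(lens - k + 1))
  # identical sequences under different ids both contribute postings
  twin <- reference_set(c("a", "b"), rep(random_seq(40), 2),
                        rep("P;S;C;O;F;G;SP", 2))
  expect_equal(index_stats(build_index(twin, 16))$n_postings, 2 * 25)
  short <- reference_set("s", "ACGTACGT", "P;S;C;O;F;G;SP")
  expect_error(build_index(short, k = 16), "exceeds")
})

test_that("exact substrings hit once with identity 1, on either strand", {
  set.seed(22)
  rs <- reference_set(c("m1", "m2"), c(random_seq(200), random_seq(200)),
                      rep("P;S;C;O;F;G;SP", 2))
  idx <- build_index(rs, k = 16)
  frag <- substr(rs$sequence[1], 51, 100)
  h <- align_read("q", frag, idx, 0.95)
  expect_equal(nrow(h), 1L)
  expect_equal(h$ref_id, "m1")
  expect_equal(h$offset, 50L)
  expect_equal(h$strand, "+")
  expect_equal(h$mismatches, 0L)
  expect_equal(h$identity, 1.0)
  h2 <- align_read("q2", revcomp(frag), idx, 0.95)
  expect_equal(normalize_hits(h2)[, c("ref_id", "offset", "mismatches")],
               normalize_hits(h)[, c("ref_id", "offset", "mismatches")])
  expect_equal(h2$strand, "-")
})

test_that("best stratum keeps only minimal-mismatch placements", {
  set.seed(23)
  base <- random_seq(60)
  # same ref twice: an exact copy and a 2-mismatch copy of the query region
  rs <- reference_set(c("exact", "near"),
                      c(base, mutate_at(base, 2)),
                      rep("P;S;C;O;F;G;SP", 2))
  idx <- build_index(rs, k = 8)
  h <- align_read("q", base, idx, 0.9)  # budget 6: both admissible
  expect_true(all(h$mismatches == 0L))
  expect_equal(sort(unique(h$ref_id)), "exact")
})

test_that("seeded aligner equals the exhaustive-offset oracle on random fixtures", {
  set.seed(24)
  rs <- reference_set(sprintf("ref%02d", 1:5),
                      vapply(rep(150, 5), random_seq, ""),
                      rep("P;S;C;O;F;G;SP", 5))
  idx <- build_index(rs, k = 8)  # 40-bp reads: L >= k*(b+1) = 8*3 = 24
  reads <- character(60)
  for (i in 1:60) {
    if (i <= 40) {  # planted with 0-3 mutations, either strand
      r <- sample(5, 1)
      off <- sample(150 - 40 + 1, 1)
      frag <- substr(rs$sequence[r], off, off + 39)
      frag <- mutate_at(frag, sample(0:3, 1))
      if (runif(1) < 0.5) frag <- revcomp(frag)
      reads[i] <- frag
    } else reads[i] <- random_seq(40)
  }
  for (t in c(1.0, 0.97, 0.95)) {
    hits <- align_reads(setNames(reads, sprintf("q%02d", 1:60)), idx, t)
    for (i in 1:60) {
      mine <- normalize_hits(hits[hits$read_id == sprintf("q%02d", i), ,
                                  drop = FALSE])
      ora <- oracle_hitset(oracle_mm(reads[i], rs), 40L, t)
      ora <- normalize_hits(ora)
      expect_equal(mine, ora, info = sprintf("read %d at t=%.2f", i, t))
    }
  }
})

test_that("reads shorter than the seed are unmatched with a warning, not an error", {
  set.seed(25)
  rs <- reference_set("r1", random_seq(100), "P;S;C;O;F;G;SP")
  idx <- build_index(rs, k = 16)
  expect_warning(h <- align_reads(c(tiny = "ACGTACGT"), idx, 0.95),
                 "shorter")
  expect_equal(nrow(h), 0L)
})

test_that("host subtraction removes exactly the perfect-match reads and is idempotent", {
  set.seed(26)
  host <- reference_set("host", random_seq(5000), "")
  hidx <- build_index(host, k = 16)

  # all reads verbatim host substrings -> all removed
  starts <- sample(5000 - 80 + 1, 50)
  host_reads <- data.frame(
    read_id = sprintf("h%02d", 1:50),
    sequence = substring(host$sequence, starts, starts + 79),
    stringsAsFactors = FALSE)
  sub <- subtract_host(host_reads, hidx)
  expect_equal(unname(sub$counts["unmapped"]), 0L)
  expect_equal(unname(sub$counts["host_matched"]), 50L)

  # foreign reads share no k-mer -> none removed; counts conserve
  mixed <- rbind(host_reads,
                 data.frame(read_id = sprintf("f%02d", 1:30),
                            sequence = vapply(rep(80, 30), random_seq, ""),
                            stringsAsFactors = FALSE))
  sub2 <- subtract_host(mixed, hidx)
  expect_equal(unname(sub2$counts["host_matched"]), 50L)
  expect_equal(sort(sub2$unmapped$read_id), sprintf("f%02d", 1:30))
  expect_equal(unname(sub2$counts["total"]),
               unname(sub2$counts["host_matched"] + sub2$counts["unmapped"]))

  # idempotent
  sub3 <- subtract_host(sub2$unmapped, hidx)
  expect_equal(sub3$unmapped$read_id, sub2$unmapped$read_id)
  expect_equal(unname(sub3$counts["host_matched"]), 0L)

  # empty stream
  sub4 <- subtract_host(mixed[0, ], hidx)
  expect_equal(unname(sub4$counts), c(0L, 0L, 0L))
})

test_that("error-free synthetic mix: unmapped set equals the non-host truth subset", {
  cfg <- sim_config(seed = 27, n_reads = 3000, host_length = 30000,
                    genome_length = 6000, marker_length = 300,
                    read_length = 80, host_fraction = 0.8, error_rate = 0)
  sim <- simulate_dataset(cfg)
  host <- reference_set("host_genome", sim$host, "")
  sub <- subtract_host(sim$reads[, c("read_id", "sequence")],
                       build_index(host, 16))
  fungal_ids <- sim$truth$read_id[sim$truth$origin == "FUNGAL"]
  expect_setequal(sub$unmapped$read_id, fungal_ids)
})

test_that("matched sets are nested across thresholds and invariant to strand flips", {
  set.seed(28)
  rs <- reference_set(sprintf("r%d", 1:3),
                      vapply(rep(300, 3), random_seq, ""),
                      rep("P;S;C;O;F;G;SP", 3))
  idx <- build_index(rs, k = 16)
  reads <- vapply(1:150, function(i) {
    r <- sample(3, 1)
    off <- sample(300 - 100 + 1, 1)
    mutate_at(substr(rs$sequence[r], off, off + 99), sample(0:7, 1))
  }, "")
  names(reads) <- sprintf("q%03d", seq_along(reads))
  matched <- lapply(c(1.0, 0.99, 0.97, 0.95), function(t)
    sort(matched_reads(align_reads(reads, idx, t))))
  for (i in 1:3) expect_true(all(matched[[i]] %in% matched[[i + 1]]))

  flipped <- setNames(revcomp(reads), names(reads))
  m1 <- sort(matched_reads(align_reads(reads, idx, 0.95)))
  m2 <- sort(matched_reads(align_reads(flipped, idx, 0.95)))
  expect_equal(m1, m2)
})
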