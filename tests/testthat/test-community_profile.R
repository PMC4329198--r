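test_that("agreement is evaluated per rank: shared class, distinct genera", {
  set.seed(31)
  rs <- yeast_fixture()
  # read hitting Candida (x2 refs) only -> FC1 at genus
  h_cand <- data.frame(read_id = "r1", ref_id = c("cand1", "cand2", "cand1"),
                       stringsAsFactors = FALSE)
  a <- assign_reads(h_cand, rs, "genus")
  expect_equal(a$status, "FC1")
  expect_equal(a$taxon, "Candida")

  # read hitting Candida and Pichia -> MULTI at genus, FC1 at class
  h_mix <- data.frame(read_id = "r2", ref_id = c("cand1", "pich1"),
                      stringsAsFactors = FALSE)
  expect_equal(assign_reads(h_mix, rs, "genus")$status, "MULTI")
  ac <- assign_reads(h_mix, rs, "class")
  expect_equal(ac$status, "FC1")
  expect_equal(ac$taxon, "Saccharomycetes")

  # no hits -> UNMATCHED
  empty <- h_mix[0, ]
  au <- assign_reads(empty, rs, "genus", read_ids = "r3")
  expect_equal(au$status, "UNMATCHED")

  # unresolvable ref id is a hard error
  bad <- data.frame(read_id = "r4", ref_id = "nope")
  expect_error(assign_reads(bad, rs, "genus"), "nope")
})

test_that("UNKNOWN-rank hits are ignored in the vote; all-UNKNOWN reads are unassignable", {
  rs <- reference_set(c("k1", "k2", "u1"),
                      c("ACGTACGTAC", "GGGGCCCCAA", "TTTTAAAACC"),
                      c("P;S;C;O;F;GenA;sp", "P;S;C;O;F;GenA;sp2", "P;S;C"))
  h <- data.frame(read_id = c("r1", "r1", "r2"),
                  ref_id = c("k1", "u1", "u1"), stringsAsFactors = FALSE)
  a <- assign_reads(h, rs, "genus")
  expect_equal(a$status[a$read_id == "r1"], "FC1")  # UNKNOWN hit ignored
  expect_equal(a$taxon[a$read_id == "r1"], "GenA")
  expect_equal(a$status[a$read_id == "r2"], "MULTI")  # unassignable
})

test_that("FC1 profiles count one read each; FCT catalogues every taxon hit", {
  set.seed(32)
  rs <- yeast_fixture()
  h <- data.frame(
    read_id = c(sprintf("c%02d", 1:10), "m1", "m1"),
    ref_id = c(rep("cand1", 10), "cand1", "clad1"),
    stringsAsFactors = FALSE)
  asn <- assign_reads(h, rs, "genus", read_ids = c(unique(h$read_id), "un1"))
  fc1 <- build_profile(asn, "FC1")
  expect_equal(unname(fc1$counts["Candida"]), 10L)
  expect_equal(sum(fc1$counts), sum(asn$status == "FC1"))
  fct <- build_profile(asn, "FCT")
  expect_setequal(names(fct$counts), c("Candida", "Cladosporium"))
  expect_equal(unname(fct$counts["Candida"]), 11L)  # 10 FC1 + the MULTI read
  # FC1 taxa are a subset of FCT taxa
  expect_true(all(names(fc1$counts) %in% names(fct$counts)))
  # mode/rank mismatch
  expect_error(build_profile(asn, "FC1", rank = "class"), "rank")
})

test_that("relative abundance is defined for FC1 only and sums to one", {
  rs <- yeast_fixture()
  asn <- assign_reads(
    data.frame(read_id = sprintf("r%03d", 1:1000),
               ref_id = rep(c("cand1", "pich1", "clad1", "cand2"),
                            c(884, 46, 37, 33))),
    rs, "species")
  prof <- build_profile(asn, "FC1")
  ra <- relative_abundance(prof)
  expect_equal(sum(ra), 1, tolerance = 1e-9)
  expect_equal(unname(ra["Candida_sp"]), 0.884)
  expect_equal(unname(ra["Pichia_sp"]), 0.046)
  expect_equal(unname(ra["Cladosporium_sp"]), 0.037)
  expect_equal(unname(ra["Candida_sp2"]), 0.033)

  single <- build_profile(assign_reads(
    data.frame(read_id = "a", ref_id = "cand1"), rs, "genus"), "FC1")
  expect_equal(unname(relative_abundance(single)), 1.0)

  fct <- build_profile(asn, "FCT")
  expect_error(relative_abundance(fct), "FCT")
  none <- build_profile(assign_reads(
    data.frame(read_id = character(), ref_id = character()), rs, "genus",
    read_ids = "x"), "FC1")
  expect_error(relative_abundance(none), "empty")
})

test_that("FC1 at genus implies FC1 at every higher rank (consistent lineages)", {
  cfg <- sim_config(seed = 33, n_reads = 4000, n_fungal_genera = 6,
                    composition = rep(1 / 6, 6), host_fraction = 0,
                    genome_length = 6000, marker_length = 400,
                    read_length = 80, error_rate = 0.01)
  sim <- simulate_dataset(cfg)
  idx <- build_index(sim$markers, 16)
  hits <- align_reads(sim$reads[, 1:2], idx, 0.95)
  a_gen <- assign_reads(hits, sim$markers, "genus")
  for (rank in c("phylum", "subphylum", "class")) {
    a_hi <- assign_reads(hits, sim$markers, rank)
    m <- match(a_gen$read_id, a_hi$read_id)
    expect_true(all(a_hi$status[m][a_gen$status == "FC1"] == "FC1"))
  }
})

test_that("confusable markers produce MULTI reads whose taxa all enter FCT", {
  cfg <- sim_config(seed = 34, n_reads = 3000, host_fraction = 0,
                    genome_length = 6000, marker_length = 400,
                    read_length = 80, error_rate = 0,
                    confusable_distance = 2L)
  sim <- simulate_dataset(cfg)
  idx <- build_index(sim$markers, 16)
  hits <- align_reads(sim$reads[, 1:2], idx, 0.95)
  asn <- assign_reads(hits, sim$markers, "genus")
  expect_gt(sum(asn$status == "MULTI"), 0)
  fc1 <- build_profile(asn, "FC1")
  fct <- build_profile(asn, "FCT")
  expect_true(all(names(fc1$counts) %in% names(fct$counts)))
  expect_gte(length(fct$counts), length(fc1$counts))
})

test_that("error-free reads give identical sweeps at every threshold; rows and ratios check out", {
  cfg <- sim_config(seed = 35, n_reads = 3000, host_fraction = 0,
                    genome_length = 6000, marker_length = 400,
                    read_length = 80, error_rate = 0)
  sim <- simulate_dataset(cfg)
  idx <- build_index(sim$markers, 16)
  sw <- threshold_sweep(sim$reads[, 1:2], idx, sim$markers, rank = "genus")
  expect_equal(nrow(sw$summary), 4L)
  expect_equal(length(unique(sw$summary$matched_reads)), 1L)
  expect_equal(length(unique(sw$summary$richness)), 1L)
  expect_equal(sw$summary$matched_ratio,
               sw$summary$matched_reads / nrow(sim$reads))
  expect_error(threshold_sweep(sim$reads[, 1:2], idx, sim$markers,
                               thresholds = c(0.95, 0.97)), "decreasing")
})

test_that("with errors, matched counts and richness grow as the threshold relaxes", {
  cfg <- sim_config(seed = 36, n_reads = 6000, n_fungal_genera = 8,
                    composition = rep(1 / 8, 8), host_fraction = 0,
                    genome_length = 6000, marker_length = 400,
                    read_length = 100, error_rate = 0.02)
  sim <- simulate_dataset(cfg)
  idx <- build_index(sim$markers, 16)
  sw <- threshold_sweep(sim$reads[, 1:2], idx, sim$markers, rank = "genus")
  expect_true(all(diff(sw$summary$matched_reads) >= 0))
  expect_true(all(diff(sw$summary$richness) >= 0))
  # nested matched sets
  for (i in 1:3)
    expect_true(all(sw$matched_ids[[i]] %in% sw$matched_ids[[i + 1]]))
  # richness ratio loosest/strictest is a number >= 1
  r <- sw$summary$richness[4] / max(sw$summary$richness[1], 1L)
  expect_gte(r, 1)
  # overlap table covers all threshold pairs
  expect_equal(nrow(sw$overlap), choose(4, 2))
  expect_true(all(sw$overlap$shared + sw$overlap$unique_a ==
                    sw$summary$richness[match(sw$overlap$threshold_a,
                                              sprintf("%.2f", sw$summary$threshold))]))
})
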