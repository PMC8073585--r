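# Synthetic proteome and XIC generation with known ground truth.

test_that("generated proteomes are deterministic and plant peptides", {
  planted <- data.frame(accession = "SYN001", peptide = "GADVWFK")
  p1 <- generate_proteome(3, planted = planted, seed = 9)
  p2 <- generate_proteome(3, planted = planted, seed = 9)
  expect_identical(p1, p2)
  p3 <- generate_proteome(3, planted = planted, seed = 10)
  expect_false(identical(p1$sequence, p3$sequence))
  expect_true(grepl("GADVWFK", p1$sequence[1], fixed = TRUE))
})

test_that("a planted peptide is recovered by digestion and uniqueness", {
  planted <- data.frame(accession = "SYN002", peptide = "WESGYNTR")
  prot <- generate_proteome(4, planted = planted, seed = 21)
  d <- digest_protein(prot[prot$accession == "SYN002", ])
  surv <- filter_peptides(d, 5, 14)
  expect_true("WESGYNTR" %in% surv$sequence)
  v <- screen_uniqueness(
    data.frame(sequence = "WESGYNTR", parent_accession = "SYN002"), prot)
  expect_true(v$is_unique)
})

test_that("planting the same peptide twice breaks uniqueness", {
  planted <- data.frame(accession = c("SYN001", "SYN003"),
                        peptide = c("GADVWFK", "GADVWFK"))
  prot <- generate_proteome(3, planted = planted, seed = 33)
  v <- screen_uniqueness(
    data.frame(sequence = "GADVWFK", parent_accession = "SYN001"), prot)
  expect_false(v$is_unique)
})

test_that("non-tryptic or oversized plants are rejected", {
  expect_error(generate_proteome(2, planted = data.frame(
    accession = "SYN001", peptide = "AAAG"), seed = 1), "end in K or R")
  expect_error(generate_proteome(2, length_range = c(10L, 10L),
                                 planted = data.frame(
    accession = "SYN001", peptide = "AAAAAAAAAAAAAAAAAAAK"), seed = 1),
    "longer than")
})

test_that("simulation is deterministic for a fixed seed", {
  profile <- data.frame(peptide = "GADVWFK", group = "g",
                        true_ratio = 1, dropout = 0)
  s1 <- simulate_xics(simulation_config(profile, 2, seed = 4))
  s2 <- simulate_xics(simulation_config(profile, 2, seed = 4))
  expect_identical(s1, s2)
})

test_that("zero noise and zero jitter recover the true ratio exactly", {
  profile <- data.frame(peptide = c("GADVWFK", "WESGYNTR"), group = "g",
                        true_ratio = c(1, 4), dropout = 0)
  cfg <- simulation_config(profile, samples_per_group = 2, seed = 6,
                           noise_cv = 0, noise_baseline = 0,
                           rt_jitter_sd = 0)
  sim <- simulate_xics(cfg)
  q <- quantify_xics(sim$xic)
  m <- merge(q, sim$truth, by = c("sample_id", "peptide"))
  expect_true(all(m$detected))
  expect_equal(m$light_to_heavy_ratio, m$true_ratio, tolerance = 1e-9)
})

test_that("full dropout in one group yields an absent call there", {
  profile <- data.frame(peptide = "GADVWFK", group = c("g1", "g2"),
                        true_ratio = c(1.5, 1.5), dropout = c(0, 1))
  sim <- simulate_xics(simulation_config(profile, 3, seed = 8))
  q <- quantify_xics(sim$xic)
  tab <- call_detection(q, sim$manifest)
  expect_equal(tab$g1, "+")
  expect_equal(tab$g2, "-")
  expect_true(all(!sim$truth$detectable[sim$truth$group == "g2"]))
})

test_that("the ground-truth manifest matches the traces one-to-one", {
  profile <- data.frame(peptide = c("GADVWFK", "WESGYNTR"),
                        group = "g", true_ratio = 1, dropout = 0)
  sim <- simulate_xics(simulation_config(profile, 3, seed = 12))
  xkeys <- unique(sim$xic[, c("sample_id", "peptide")])
  tkeys <- sim$truth[, c("sample_id", "peptide")]
  expect_equal(nrow(merge(xkeys, tkeys)), nrow(tkeys))
  expect_equal(nrow(xkeys), nrow(tkeys))
})

test_that("a tenfold contrast at n = 15 is flagged in almost every rep", {
  profile <- data.frame(peptide = "GADVWFK",
                        group = c("GP", "SGR", "AGR"),
                        true_ratio = c(0.5, 5, 0.5), dropout = 0)
  flagged <- vapply(1:20, function(s) {
    sim <- simulate_xics(simulation_config(profile, 15, seed = s))
    q <- quantify_xics(sim$xic)
    cmp <- compare_groups(q, sim$manifest)
    pr <- cmp$pairs
    row <- pr[pr$group1 == "GP" & pr$group2 == "SGR", ]
    isTRUE(row$p_adjusted < 0.05)
  }, logical(1))
  expect_gte(mean(flagged), 0.95)
})

test_that("the bundled fixture is internally consistent", {
  fx <- make_paper_fixture()
  expect_equal(length(fx$panel$targets), 18L)
  expect_equal(nrow(fx$detection_reference), 18L)
  # detection profile mirrors the +/- reference exactly
  for (i in seq_len(nrow(fx$detection_reference))) {
    for (g in c("healthy", "inflamed")) {
      row <- fx$detection_profile[
        fx$detection_profile$peptide == fx$detection_reference$peptide[i] &
          fx$detection_profile$group == g, ]
      expect_equal(row$true_ratio > 0, fx$detection_reference[[g]][i] == "+")
    }
  }
  # region profile covers the six quantifiable peptides in three regions
  expect_setequal(unique(fx$region_profile$group), c("GP", "SGR", "AGR"))
  expect_equal(nrow(fx$region_profile), 18L)
})
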