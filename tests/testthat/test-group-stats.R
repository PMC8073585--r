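# Kruskal-Wallis, Dunn post hoc and the normality gate.

test_that("Kruskal-Wallis H matches the hand-ranked example", {
  kw <- kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2L)
})

test_that("identical observations give H = 0, p = 1", {
  kw <- kruskal_wallis(c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(kw$H, 0)
  expect_equal(kw$p_value, 1)
})

test_that("H agrees with the independent reference on random data", {
  set.seed(2)
  for (i in 1:100) {
    v <- round(rnorm(30), 1)  # rounding induces ties
    g <- sample(c("a", "b", "c"), 30, replace = TRUE)
    if (min(table(g)) == 0 || sd(v) == 0) next
    kw <- kruskal_wallis(v, g)
    ref <- stats::kruskal.test(v, factor(g))
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(kw$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(5)
  v <- rlnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  h0 <- kruskal_wallis(v, g)$H
  expect_equal(kruskal_wallis(log(v), g)$H, h0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(rank(v), g)$H, h0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(exp(v), g)$H, h0, tolerance = 1e-12)
})

test_that("Dunn z matches the manual formula on a 3-group design", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  dn <- dunn_posthoc(v, g, adjustment = "none")
  # hand computation: Rbar_a = 2, Rbar_c = 8, N = 9, no ties
  # z = (2 - 8) / sqrt(9 * 10 / 12 * (1/3 + 1/3)) = -6 / sqrt(5)
  z_ac <- dn$z[dn$group1 == "a" & dn$group2 == "c"]
  expect_equal(z_ac, -6 / sqrt(5), tolerance = 1e-12)
  expect_equal(dn$p_raw[dn$group1 == "a" & dn$group2 == "c"],
               2 * pnorm(-6 / sqrt(5)), tolerance = 1e-12)
})

test_that("Dunn z is antisymmetric and identical groups give z = 0", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- c("a", "a", "a", "b", "b", "b")
  dn <- dunn_posthoc(v, g)
  expect_equal(dn$z, 0)
  expect_equal(dn$p_raw, 1)
  # reversing the comparison order negates z, leaves p unchanged
  v2 <- c(10, 20, 30, 40, 50, 60)
  dn_ab <- dunn_posthoc(v2, g, adjustment = "none")      # pair (a, b)
  dn_ba <- dunn_posthoc(rev(v2), rev(g), adjustment = "none")  # pair (b, a)
  expect_equal(dn_ab$z, -dn_ba$z, tolerance = 1e-12)
  expect_equal(dn_ab$p_raw, dn_ba$p_raw, tolerance = 1e-12)
})

test_that("adjusted Dunn p-values are never below the raw ones", {
  set.seed(9)
  v <- rlnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  for (adj in c("bonferroni", "holm")) {
    dn <- dunn_posthoc(v, g, adjustment = adj)
    expect_true(all(dn$p_adjusted >= dn$p_raw - 1e-15))
  }
})

test_that("pairs with an empty group are skipped and flagged", {
  v <- c(1, 2, 3, 4, 5, 6, NA, NA)
  g <- c("a", "a", "a", "b", "b", "b", "c", "c")
  dn <- dunn_posthoc(v, g)
  expect_true(all(dn$skipped[dn$group1 == "c" | dn$group2 == "c"]))
  expect_false(any(dn$skipped[dn$group1 == "a" & dn$group2 == "b"]))
})

test_that("the normality gate rejects heavy-skewed data and flags tiny groups", {
  set.seed(101)
  skewed <- rlnorm(50, sdlog = 2)
  gate <- shapiro_wilk_gate(c(skewed, rnorm(10)),
                            c(rep("sk", 50), rep("nm", 10)))
  tab <- gate$table
  expect_true(tab$rejects[tab$group == "sk"])
  expect_equal(gate$route, "nonparametric")
  # n = 2 is untestable and forces the nonparametric route
  g2 <- shapiro_wilk_gate(c(1, 2, rnorm(20)),
                          c("tiny", "tiny", rep("big", 20)))
  expect_false(g2$table$testable[g2$table$group == "tiny"])
  expect_equal(g2$route, "nonparametric")
  # the route is deterministic for fixed input
  expect_equal(shapiro_wilk_gate(skewed, rep("sk", 50))$route,
               shapiro_wilk_gate(skewed, rep("sk", 50))$route)
})

test_that("compare_groups claims significance only with enough detections", {
  set.seed(77)
  quant <- data.frame(
    sample_id = sprintf("s%02d", 1:30),
    peptide = "GADVWFK",
    coelutes = TRUE, detected = TRUE,
    light_to_heavy_ratio = c(rlnorm(15, log(0.2), 0.2),
                             rlnorm(15, log(5), 0.2)),
    apex_delta = 0)
  # leave only 2 detections in a third group
  quant <- rbind(quant, data.frame(
    sample_id = c("t1", "t2"), peptide = "GADVWFK", coelutes = TRUE,
    detected = TRUE, light_to_heavy_ratio = c(1, 1.2), apex_delta = 0))
  man <- data.frame(sample_id = c(sprintf("s%02d", 1:30), "t1", "t2"),
                    group = c(rep(c("GP", "SGR"), each = 15), "AGR", "AGR"))
  cmp <- compare_groups(quant, man)
  pr <- cmp$pairs
  expect_true(pr$claimable[pr$group1 == "GP" & pr$group2 == "SGR"])
  expect_false(any(pr$claimable[pr$group1 == "AGR" | pr$group2 == "AGR"]))
  expect_equal(pr$stars[pr$group1 == "GP" & pr$group2 == "SGR"], "***")
})

test_that("stars follow the 0.05 / 0.01 / 0.001 thresholds", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0009, NA)),
               c("", "*", "**", "***", NA))
})
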