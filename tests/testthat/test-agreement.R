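test_that("two-way ICC matches hand-computed ANOVA on the worked example", {
  p <- paired(c(1, 2, 3), c(2, 3, 4))
  cons <- icc_two_way(p, "consistency")
  agr <- icc_two_way(p, "agreement")
  expect_equal(cons$estimate, 1)
  expect_equal(agr$estimate, 2 / 3, tolerance = 1e-12)
  expect_identical(cons$status, "ok")

  ident <- paired(c(1, 5, 9, 2), c(1, 5, 9, 2))
  expect_equal(icc_two_way(ident, "consistency")$estimate, 1)
  expect_equal(icc_two_way(ident, "agreement")$estimate, 1)
})

test_that("ICC agrees with an independent aov() mean-squares oracle", {
  set.seed(2)
  for (i in 1:5) {
    n <- 50
    base <- rnorm(n)
    p <- paired(base + rnorm(n, 0, 0.5), 0.3 + base + rnorm(n, 0, 0.5))
    df <- data.frame(
      y = c(p$value_a, p$value_b),
      subj = factor(rep(seq_len(n), 2)),
      rater = factor(rep(c("a", "b"), each = n))
    )
    ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    k <- 2
    exp_cons <- (msr - mse) / (msr + (k - 1) * mse)
    exp_agr <- (msr - mse) /
      (msr + (k - 1) * mse + (k / n) * max(msc - mse, 0))
    expect_equal(icc_two_way(p, "consistency")$estimate, exp_cons,
                 tolerance = 1e-10)
    expect_equal(icc_two_way(p, "agreement")$estimate, exp_agr,
                 tolerance = 1e-10)
  }
})

test_that("a constant offset spares consistency but penalizes agreement", {
  set.seed(3)
  for (i in 1:10) {
    base <- rnorm(8, 10, 3)
    p0 <- paired(base + rnorm(8, 0, 0.3), base + rnorm(8, 0, 0.3))
    d <- runif(1, 0.5, 3)
    p1 <- p0
    p1$value_a <- p1$value_a + d
    expect_equal(icc_two_way(p1, "consistency")$estimate,
                 icc_two_way(p0, "consistency")$estimate, tolerance = 1e-9)
    expect_lt(icc_two_way(p1, "agreement")$estimate,
              icc_two_way(p0, "agreement")$estimate)
    expect_lte(icc_two_way(p1, "agreement")$estimate,
               icc_two_way(p1, "consistency")$estimate + 1e-12)
    expect_equal(bland_altman(p1)$mean_diff - bland_altman(p0)$mean_diff, d,
                 tolerance = 1e-12)
  }
})

test_that("ICC confidence intervals bracket the estimate", {
  set.seed(4)
  base <- rnorm(30, 5, 2)
  p <- paired(base + rnorm(30, 0, 0.5), 0.4 + base + rnorm(30, 0, 0.5))
  for (type in c("consistency", "agreement")) {
    r <- icc_two_way(p, type)
    expect_lte(r$conf_low, r$estimate)
    expect_gte(r$conf_high, r$estimate)
  }
})

test_that("zero between-eye variance yields a named undefined status", {
  p <- paired(rep(2, 5), rep(2, 5))
  r <- icc_two_way(p, "consistency")
  expect_identical(r$status, "undefined_between_variance")
  expect_true(is.na(r$estimate))
  expect_error(icc_two_way(paired(1:2, 2:3), "consistency"),
               class = "drusevol_bad_paired")
})

test_that("Bland-Altman summaries match hand calculations", {
  p <- paired(c(2, 3), c(1, 2))
  ba <- bland_altman(p)
  expect_equal(ba$mean_diff, 1)
  expect_equal(ba$mean_of_averages, 2)
  expect_equal(ba$std_mean_diff, 0.5)

  off <- paired(c(1.01, 2.01, 3.01), c(1, 2, 3))
  ba2 <- bland_altman(off)
  expect_equal(ba2$mean_diff, 0.01)
  expect_equal(ba2$sd_diff, 0)
  expect_equal(ba2$loa_low, 0.01)
  expect_equal(ba2$loa_high, 0.01)

  # swapping roles negates the mean difference, keeps |standardized|
  sw <- paired(c(1, 2), c(2, 3))
  expect_equal(bland_altman(sw)$mean_diff, -1)
  expect_equal(abs(bland_altman(sw)$std_mean_diff), 0.5)

  zero <- paired(c(0.1, -0.1), c(-0.1, 0.1))
  expect_identical(bland_altman(zero)$status, "degenerate_zero_mean")
})

test_that("paired RMSE follows its definition and dominates the mean", {
  expect_equal(paired_rmse(paired(c(1, 5), c(1, 5))), 0)
  expect_equal(paired_rmse(paired(c(1, 5), c(1, 2))), sqrt(4.5),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    p <- paired(rnorm(6), rnorm(6))
    expect_gte(paired_rmse(p) + 1e-12, abs(bland_altman(p)$mean_diff))
  }
})

test_that("Wilcoxon signed-rank matches exact enumeration", {
  p <- paired(1:6 + 10, rep(10, 6))  # six positive differences 1..6
  r <- wilcoxon_signed_rank(p)
  expect_equal(r$statistic, 21)
  expect_equal(r$p_value, 2 / 64)
  expect_true(r$exact)

  sym <- paired(c(0, 2), c(1, 1))  # differences -1, +1
  expect_equal(wilcoxon_signed_rank(sym)$p_value, 1)

  degen <- paired(c(1, 2, 3), c(1, 2, 3))
  rd <- wilcoxon_signed_rank(degen)
  expect_true(rd$degenerate)
  expect_equal(rd$p_value, 1)
})

test_that("Wilcoxon exact p matches base R and the normal branch at n = 25", {
  set.seed(6)
  for (i in 1:5) {
    a <- rnorm(25)
    b <- rnorm(25)
    p <- paired(a, b)
    r_exact <- wilcoxon_signed_rank(p)
    expect_true(r_exact$exact)
    ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                               exact = TRUE))
    expect_equal(r_exact$p_value, ref$p.value, tolerance = 1e-10)
    r_norm <- wilcoxon_signed_rank(p, exact_max = 0)
    expect_lt(abs(r_exact$p_value - r_norm$p_value), 0.01)
  }
})

test_that("Jonckheere-Terpstra detects a perfect ordered separation", {
  r <- jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 12)
  expect_equal(r$p_value, 1 / 90, tolerance = 1e-12)
  expect_true(r$exact)
})

test_that("Jonckheere-Terpstra handles ties and reversals", {
  # all-constant groups, large enough for the normal branch: J at half-max
  const <- list(rep(1, 4), rep(1, 4), rep(1, 4))
  r <- jonckheere_terpstra(const)
  expect_equal(r$statistic, 0.5 * (3 * 16))
  expect_equal(r$p_value, 0.5)

  # reversing the group order maps J to max - J
  set.seed(7)
  g <- list(rnorm(4), rnorm(5), rnorm(3))
  j_fwd <- jonckheere_terpstra(g)$statistic
  j_rev <- jonckheere_terpstra(rev(g))$statistic
  max_j <- 4 * 5 + 4 * 3 + 5 * 3
  expect_equal(j_fwd + j_rev, max_j)

  expect_error(jonckheere_terpstra(list(1:3)), class = "drusevol_bad_groups")
})

test_that("Jonckheere-Terpstra exact and normal branches agree near n = 10", {
  set.seed(8)
  for (i in 1:5) {
    g <- list(rnorm(3), rnorm(3), rnorm(4))
    pe <- jonckheere_terpstra(g)$p_value
    pn <- jonckheere_terpstra(g, exact_max = 0)$p_value
    expect_lt(abs(pe - pn), 0.05)
  }
})

test_that("high-risk kappa reproduces the 2x2 hand calculation", {
  ident <- paired(c(0.1, 0.01, 0.2), c(0.09, 0.02, 0.3))
  r <- kappa_high_risk(ident, 0.05, 0.05)
  expect_equal(r$kappa, 1)
  expect_equal(r$percent_agreement, 100)

  # 2x2 table 40/5/5/50 at n = 100
  a <- c(rep(0.05, 45), rep(0.01, 55))
  b <- c(rep(0.05, 40), rep(0.01, 5), rep(0.05, 5), rep(0.01, 50))
  r2 <- kappa_high_risk(paired(a, b), 0.03, 0.03)
  expect_equal(r2$percent_agreement, 90)
  expect_equal(r2$kappa, (0.9 - 0.505) / (1 - 0.505), tolerance = 1e-12)

  # independent classifications have kappa near zero
  set.seed(9)
  big <- paired(runif(4000), runif(4000))
  expect_lt(abs(kappa_high_risk(big, 0.5, 0.5)$kappa), 0.05)

  onecell <- paired(rep(1, 4), rep(1, 4))
  expect_identical(kappa_high_risk(onecell, 0.5, 0.5)$status,
                   "undefined_chance_agreement")
  expect_error(kappa_high_risk(ident, 0), class = "drusevol_bad_cutoff")
})

test_that("agreement_report stratifies into the expected subgroups", {
  set.seed(10)
  n <- 24
  stage <- rep(c("no_amd", "eamd", "iamd"), each = 8)
  rpd <- stage == "iamd" & rep(c(TRUE, FALSE), 12)
  base <- abs(rnorm(n, 0.1, 0.08))
  p <- paired(base + rnorm(n, 0, 0.01), base * 0.6 + rnorm(n, 0, 0.01),
              stage = stage, rpd = rpd)
  rep_tbl <- agreement_report(p, cutoff_a = 0.083, cutoff_b = 0.03)
  expect_setequal(
    rep_tbl$subgroup,
    c("all", "no_amd", "eamd", "iamd", "iamd_no_rpd", "iamd_rpd")
  )
  expect_true(all(c("icc_consistency", "mean_diff", "rmse", "wilcoxon_p",
                    "kappa", "percent_agreement") %in% names(rep_tbl)))
  expect_identical(rep_tbl$n[rep_tbl$subgroup == "iamd"], 8L)
})
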