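test_that("Fisher exact matches full hypergeometric enumeration", {
  # published subgroup male-sex counts: 3/7 vs 3/4, printed to 3 d.p.
  tab1 <- rbind(c(3, 4), c(3, 1))
  expect_equal(round(fisher_exact(tab1), 3), 0.545)
  expect_equal(fisher_exact(tab1), fisher_enumeration(tab1), tolerance = 1e-12)

  tab2 <- rbind(c(6, 5), c(9, 2))
  expect_equal(fisher_exact(tab2), fisher_enumeration(tab2), tolerance = 1e-12)
  expect_equal(round(fisher_exact(tab2), 3), 0.361)

  set.seed(17)
  for (i in 1:25) {
    tb <- matrix(stats::rpois(4, 5) + (i %% 2), 2, 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(fisher_exact(tb), fisher_enumeration(tb), tolerance = 1e-12)
    # symmetry under row and column swaps
    expect_equal(fisher_exact(tb[2:1, ]), fisher_exact(tb), tolerance = 1e-12)
    expect_equal(fisher_exact(tb[, 2:1]), fisher_exact(tb), tolerance = 1e-12)
  }

  expect_error(fisher_exact(rbind(c(0, 0), c(1, 2))), "margins")
  expect_error(fisher_exact(rbind(c(1.5, 2), c(1, 2))), "integers")
})

test_that("the gated two-group comparison behaves correctly under the null and the alternative", {
  x <- c(1, 2, 3, 4.5, 5, 6.5, 7, 8, 9, 10.5)
  expect_equal(compare_groups(x, x)$p, 1)
  # a clearly non-normal identical pair goes down the exact rank path
  xs <- c(0.01, 0.02, 0.05, 0.1, 1, 4, 20, 90, 400, 2000) - 5
  cmp <- suppressWarnings(compare_groups(xs, xs + 1e-9))
  expect_identical(cmp$test, "mann-whitney")
  expect_gt(cmp$p, 0.5)  # epsilon shift moves U only slightly off center

  expect_warning(cmp2 <- compare_groups(rep(2, 5), rep(2, 5)), "constant")
  expect_equal(cmp2$p, 1)

  # order swap leaves p unchanged
  set.seed(23)
  a <- stats::rnorm(11); b <- stats::rnorm(11, 0.5)
  expect_equal(compare_groups(a, b)$p, compare_groups(b, a)$p, tolerance = 1e-12)

  # Mann-Whitney p invariant under monotone transformation of pooled data
  ae <- exp(stats::rnorm(8, sd = 2)); be <- exp(stats::rnorm(8, 3, 2))
  skew <- suppressWarnings(compare_groups(ae^3, be^3))
  skew2 <- suppressWarnings(compare_groups(log(ae^3), log(be^3)))
  if (skew$test == "mann-whitney" && skew2$test == "mann-whitney") {
    expect_equal(skew$p, skew2$p, tolerance = 1e-12)
  }

  # type-I error calibration on large normal samples
  rej <- 0
  for (i in 1:1000) {
    set.seed(30000 + i)
    rej <- rej + (compare_groups(stats::rnorm(50), stats::rnorm(50))$p < 0.05)
  }
  expect_gt(rej / 1000, 0.025)
  expect_lt(rej / 1000, 0.075)

  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("empirical power of the gated test matches the noncentral-t oracle", {
  # effect: 0.42 +/- 0.12 vs 0.29 +/- 0.11, n = 11 per group
  ncp <- 0.13 / sqrt((0.12^2 + 0.11^2) / 11)
  df <- 20
  tc <- stats::qt(0.975, df)
  oracle <- 1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)

  n_rep <- 1500
  rej <- 0
  for (i in seq_len(n_rep)) {
    set.seed(60000 + i)
    xx <- stats::rnorm(11, 0.42, 0.12)
    yy <- stats::rnorm(11, 0.29, 0.11)
    rej <- rej + (suppressWarnings(compare_groups(xx, yy))$p < 0.05)
  }
  expect_lt(abs(rej / n_rep - oracle), 0.02)
})

test_that("Pearson correlation follows the product-moment formula", {
  x <- c(0.3, 1, 2.2, 3, 4.7, 6)
  expect_equal(correlate(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(correlate(x, -x)$r, -1, tolerance = 1e-12)

  set.seed(8)
  a <- stats::rnorm(22); b <- 0.5 * a + stats::rnorm(22)
  ct <- correlate(a, b)
  # independent direct evaluation of r and its t-based p-value
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t_stat <- r_direct * sqrt((22 - 2) / (1 - r_direct^2))
  expect_equal(ct$r, r_direct, tolerance = 1e-12)
  expect_equal(ct$p, 2 * stats::pt(-abs(t_stat), 20), tolerance = 1e-12)
  expect_true(ct$r >= -1 && ct$r <= 1)

  # affine invariance with positive slope
  expect_equal(correlate(3 * a + 2, 0.1 * b - 7)$r, ct$r, tolerance = 1e-12)

  expect_error(correlate(a, b[1:10]), "equal length")
  expect_error(correlate(rep(1, 5), 1:5), "zero-variance")
})

test_that("cohort reports carry the full variable set and outcome arithmetic", {
  co <- simulate_cohort(11, seed = 4)
  rep <- suppressWarnings(cohort_report(co$records))
  expect_equal(rep$header, "stable n = 11 / rapid n = 11")
  expect_equal(nrow(rep$groups), 10)
  expect_setequal(
    rep$groups$variable,
    c("Age [years]", "Male sex", "Initial aortic diameter [mm]",
      "TL/DA area ratio", "Entry tear size [mm2]", "Number of re-entry tears",
      "Tortuosity", "FL flow [%]", "Peak TAWSS (entry tear) [Pa]",
      "TAWSS x margins (entry tear) [Pa mm]"))
  expect_true(all(rep$groups$p >= 0 & rep$groups$p <= 1, na.rm = TRUE))

  # cohort of identical patients: every p is 1 or undefined
  r1 <- co$records[rep_len(1, 22), ]
  r1$group <- rep(c("stable", "rapid"), each = 11)
  r1$subgroup <- "n/a"
  rep_id <- suppressWarnings(cohort_report(r1))
  expect_true(all(is.na(rep_id$groups$p) | rep_id$groups$p == 1))

  # published outcome arithmetic: 9 re-interventions and 8 deaths of 22
  rr <- co$records
  rr$reintervention <- c(rep(TRUE, 9), rep(FALSE, 13))
  rr$death <- c(rep(TRUE, 8), rep(FALSE, 14))
  o <- outcome_rates(rr)
  expect_equal(o$reintervention_pct, 41)
  expect_equal(o$death_pct, 36)

  expect_error(cohort_report(co$records[, 1:4]), "missing columns")
})
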