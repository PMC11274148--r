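test_that("synthesized fields respect flow shares, mass split and configured offsets", {
  g <- fixture_geometry()

  # TL share 0.45 of descending flow -> 55% FL flow at systolic peak
  f45 <- synthesize_fields(g$mesh, tl_flow_share = 0.45,
                           params = coarse_params(noise_sd = 0))
  expect_equal(fl_flow_fraction(f45$planes), 55, tolerance = 1e-9)

  # flux conservation at every plane and time sample
  h <- decompose_waveform(aortic_waveform(), 8)
  q_desc <- 0.55 * reconstruct_waveform(h, f45$planes$times, 0.8)
  tot <- f45$planes$q_tl + f45$planes$q_fl
  expect_lt(max(abs(sweep(tot, 2, q_desc))), 1e-12 * max(abs(q_desc)))

  # constant +200 Pa FL-TL offset passes straight through
  f200 <- synthesize_fields(g$mesh, fl_dp = 200,
                            params = coarse_params(noise_sd = 0))
  ph <- cardiac_phases(aortic_waveform())
  pp <- pressure_difference_profile(f200$planes, ph)
  expect_true(all(abs(as.matrix(pp[, -1]) - 200) < 1e-9))

  # no reversal and no noise -> OSI identically zero
  f0 <- synthesize_fields(g$mesh, fl_osc = 0,
                          params = coarse_params(noise_sd = 0))
  expect_lt(max(compute_hwd(f0$wss)$osi), 1e-12)

  # noise-free vectors are tangent to the surface
  nrm <- g$mesh$vertex_normal
  for (i in c(1, 8, 16)) {
    dots <- rowSums(f0$wss$values[, i, ] * nrm)
    expect_lt(max(abs(dots)), 1e-9 * max(abs(f0$wss$values)))
  }

  expect_error(synthesize_fields(g$mesh, tl_flow_share = 1.5), "tl_flow_share")
  expect_error(flow_waveform(c(0, 0.1), c(1, 1), period = -1), "positive")
})

test_that("false lumen is more oscillatory than the true lumen across patients", {
  set.seed(99)
  fracs <- stats::runif(12, 0.15, 0.6)
  wins <- 0
  for (i in seq_along(fracs)) {
    p <- coarse_params(flap_angle_fraction = fracs[i], seed = i)
    gg <- build_dissected_geometry(p)
    mm <- compute_hwd(synthesize_fields(gg$mesh)$wss)
    ss <- region_summary(mm, gg$mesh, regions = c("TL", "FL"))
    wins <- wins + (ss$mean_osi[ss$region == "FL"] >
                      ss$mean_osi[ss$region == "TL"])
  }
  expect_gte(wins / length(fracs), 0.95)
})

test_that("simulated cohorts are reproducible and match the configured world", {
  co1 <- simulate_cohort(11, seed = 42)
  co2 <- simulate_cohort(11, seed = 42)
  expect_identical(co1$records, co2$records)
  expect_identical(co1$diameters, co2$diameters)
  expect_false(identical(co1$records, simulate_cohort(11, seed = 43)$records))

  r <- co1$records
  expect_equal(nrow(r), 22)
  expect_equal(mean(r$group == "rapid"), 0.5)
  expect_true(all(r$tl_da_ratio > 0 & r$tl_da_ratio < 1))
  expect_true(all(r$fl_flow_pct >= 0 & r$fl_flow_pct <= 100))

  # growth labels recovered from the diameter tables match the drawn group
  labs <- vapply(r$id, function(id) classify_growth(co1$diameters[[id]])$label,
                 character(1))
  expect_identical(unname(labs), ifelse(r$group == "rapid", "rapid", "stable"))

  # feature means within 3 published sd of the published group means
  pub <- list(tl_da = c(0.42, 0.12, 0.29, 0.11), tort = c(1.38, 0.29, 1.38, 0.34),
              fl = c(55, 20, 63, 15), tear = c(144.8, 173.7, 210.0, 182.6))
  cols <- c(tl_da = "tl_da_ratio", tort = "tortuosity", fl = "fl_flow_pct",
            tear = "tear_area_mm2")
  for (nm in names(pub)) {
    st <- mean(r[[cols[nm]]][r$group == "stable"])
    ra <- mean(r[[cols[nm]]][r$group == "rapid"])
    expect_lt(abs(st - pub[[nm]][1]), 3 * pub[[nm]][2])
    expect_lt(abs(ra - pub[[nm]][3]), 3 * pub[[nm]][4])
  }

  # adverse stratum drawn with larger tears and higher FL flow: the strata
  # differ by ~210 mm^2 and ~16 points, so the direction is stable once a
  # few cohorts are pooled
  pool <- do.call(rbind, lapply(1:15, function(s) {
    simulate_cohort(11, seed = 200 + s)$records
  }))
  pst <- pool[pool$group == "stable", ]
  expect_gt(mean(pst$tear_area_mm2[pst$subgroup == "adverse"]),
            mean(pst$tear_area_mm2[pst$subgroup == "favorable"]))
  expect_gt(mean(pst$fl_flow_pct[pst$subgroup == "adverse"]),
            mean(pst$fl_flow_pct[pst$subgroup == "favorable"]))

  # outcome flags follow the deterministic risk-score rule
  sc <- (r$fl_flow_pct / 100 - 0.55) / 0.18 + (r$tortuosity - 1.38) / 0.30 +
    0.5 * log(r$tear_area_mm2 / 150)
  expect_identical(r$death, sc >= 1)
  expect_identical(r$reintervention, sc >= 0.4)

  expect_error(simulate_cohort(1), "n_per_group")
  bad <- cohort_effects()
  bad$stable$tl_da_sd <- -0.1
  expect_error(simulate_cohort(11, bad), "negative sd")
})

test_that("null-effect cohorts are exchangeable and effect cohorts recover the coupling", {
  # type-I error of the TL/DA comparison under exchangeable groups
  # (moderate replicate count here; the tighter calibration check runs in
  # the acceptance suite)
  rej <- 0
  n_rep <- 150
  for (i in seq_len(n_rep)) {
    co <- simulate_cohort(11, cohort_effects(null = TRUE), seed = 5000 + i)
    st <- co$records$tl_da_ratio[co$records$group == "stable"]
    ra <- co$records$tl_da_ratio[co$records$group == "rapid"]
    rej <- rej + (suppressWarnings(compare_groups(st, ra))$p < 0.05)
  }
  expect_gt(rej / n_rep, 0.005)
  expect_lt(rej / n_rep, 0.12)

  # tear-area -> FL-flow coupling recovered at the configured r = 0.55
  rs <- vapply(seq_len(200), function(i) {
    co <- simulate_cohort(11, seed = 9000 + i)
    correlate(co$records$tear_area_mm2, co$records$fl_flow_pct)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.55), 0.05)
})
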