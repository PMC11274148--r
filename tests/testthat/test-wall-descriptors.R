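test_that("descriptors match hand-computed canonical fields", {
  # constant tau = (2,0,0) Pa
  m1 <- compute_hwd(const_wss(rbind(c(2, 0, 0))))
  expect_equal(m1$tawss, 2, tolerance = 1e-12)
  expect_equal(m1$osi, 0, tolerance = 1e-12)
  expect_equal(m1$rrt, 0.5, tolerance = 1e-12)

  # perfect reversal: (1,0,0) then (-1,0,0)
  n_t <- 16
  a <- array(0, c(1, n_t, 3))
  a[1, , 1] <- rep(c(1, -1), each = n_t / 2)
  m2 <- compute_hwd(wss_series(seq(0, 0.8, length.out = n_t + 1)[1:n_t], a))
  expect_equal(m2$tawss, 1, tolerance = 1e-12)
  expect_equal(m2$osi, 0.5, tolerance = 1e-12)
  expect_true(m2$undefined)
  expect_identical(m2$rrt, Inf)

  # orthogonal direction switch: OSI = (1 - sqrt(2)/2)/2
  a3 <- array(0, c(1, n_t, 3))
  a3[1, 1:(n_t / 2), 1] <- 1
  a3[1, (n_t / 2 + 1):n_t, 2] <- 1
  m3 <- compute_hwd(wss_series(seq(0, 0.8, length.out = n_t + 1)[1:n_t], a3))
  expect_equal(m3$osi, 0.5 * (1 - sqrt(2) / 2), tolerance = 1e-10)

  # NaN input names the offending vertex
  a3[1, 2, 1] <- NA
  expect_error(compute_hwd(wss_series(seq(0, 0.8, length.out = n_t + 1)[1:n_t], a3)),
               "vertex id")
  expect_error(compute_hwd(const_wss(rbind(c(1, 0, 0)), n_t = 4)), "8 time")
})

test_that("descriptor identities hold on random and generated fields", {
  set.seed(31)
  n_t <- 32
  tt <- seq(0, 0.8, length.out = n_t + 1)[1:n_t]
  a <- array(stats::rnorm(50 * n_t * 3), c(50, n_t, 3))
  m <- compute_hwd(wss_series(tt, a))
  expect_true(all(m$osi >= 0 & m$osi <= 0.5))
  fin <- !m$undefined
  expect_true(all(abs(m$rrt[fin] * (1 - 2 * m$osi[fin]) * m$tawss[fin] - 1) < 1e-10))

  # cyclic rotation of the time grid leaves descriptors unchanged
  sh <- 7
  a_rot <- a[, c((sh + 1):n_t, 1:sh), , drop = FALSE]
  m_rot <- compute_hwd(wss_series(tt, a_rot))
  expect_equal(m_rot$tawss, m$tawss, tolerance = 1e-12)
  expect_equal(m_rot$osi, m$osi, tolerance = 1e-12)

  # Womersley-driven non-reversing field: OSI vanishes
  fields0 <- synthesize_fields(fixture_geometry()$mesh,
                               params = coarse_params(noise_sd = 0),
                               fl_osc = 0)
  m0 <- compute_hwd(fields0$wss)
  expect_lt(max(m0$osi), 1e-10)

  # refinement consistency on a smooth harmonic field
  smooth_field <- function(n_t) {
    tt <- seq(0, 0.8, length.out = n_t + 1)[1:n_t]
    a <- array(0, c(1, n_t, 3))
    a[1, , 1] <- 1.5 + sin(2 * pi * tt / 0.8) + 0.3 * cos(4 * pi * tt / 0.8)
    compute_hwd(wss_series(tt, a))$tawss
  }
  expect_lt(abs(smooth_field(64) - smooth_field(32)) / smooth_field(32), 0.001)
})

test_that("region summaries are area-weighted with explicit absent regions", {
  mesh <- flat_two_region_mesh()
  map1 <- compute_hwd(const_wss(matrix(rep(c(1, 0, 0), each = 8), 8, 3)))
  rs <- region_summary(map1, mesh)
  expect_equal(rs$mean_tawss, c(1, 1))
  expect_equal(rs$peak_tawss, c(1, 1))

  # two equal-area regions at TAWSS 1 and 3: global mean 2
  vals <- matrix(0, 8, 3)
  vals[mesh$vertex_region == "TL", 1] <- 1
  vals[mesh$vertex_region == "FL", 1] <- 3
  map2 <- compute_hwd(const_wss(vals))
  rs2 <- region_summary(map2, mesh)
  expect_equal(mean(rs2$mean_tawss), 2, tolerance = 1e-12)
  mesh_one <- mesh
  mesh_one$vertex_region <- rep("TL", 8)
  g_mean <- region_summary(map2, mesh_one)
  expect_equal(g_mean$mean_tawss, 2, tolerance = 1e-12)

  rs3 <- region_summary(map2, mesh, regions = c("TL", "tear_margin"))
  expect_false(rs3$present[rs3$region == "tear_margin"])
  expect_true(is.na(rs3$mean_tawss[rs3$region == "tear_margin"]))
  # peak >= mean for every present region
  ok <- rs2$present
  expect_true(all(rs2$peak_tawss[ok] >= rs2$mean_tawss[ok] - 1e-12))
})

test_that("tear-margin statistic is peak TAWSS times perimeter", {
  mesh <- flat_two_region_mesh(regions = c("tear_margin", "TL"))
  vals <- matrix(0, 8, 3)
  vals[mesh$vertex_region == "tear_margin", 1] <- c(8, 5, 3, 2)
  map <- compute_hwd(const_wss(vals))
  tear30 <- tear_metrics(30 / pi, 30 / pi)  # perimeter exactly 30 mm
  expect_equal(tear30$perimeter, 30, tolerance = 1e-12)
  expect_equal(tear_margin_tawss(map, tear30, mesh), 240, tolerance = 1e-10)

  # linearity: doubling the shear doubles the statistic
  map2 <- compute_hwd(const_wss(2 * vals))
  expect_equal(tear_margin_tawss(map2, tear30, mesh),
               2 * tear_margin_tawss(map, tear30, mesh), tolerance = 1e-10)

  # line-integral variant uses the margin mean
  expect_equal(tear_margin_tawss(map, tear30, mesh, method = "line_integral"),
               mean(c(8, 5, 3, 2)) * 30, tolerance = 1e-10)

  # favorable-outcome-like magnitudes: 6.7 Pa peak on a 9.2 mm tear
  vals2 <- matrix(0, 8, 3)
  vals2[mesh$vertex_region == "tear_margin", 1] <- 6.7
  map3 <- compute_hwd(const_wss(vals2))
  stat <- tear_margin_tawss(map3, tear_metrics(9.2, 9.2), mesh)
  expect_equal(stat, 6.7 * pi * 9.2, tolerance = 1e-10)
  expect_equal(stat, 194, tolerance = 0.01)

  plain <- flat_two_region_mesh()  # no margin labels
  expect_error(tear_margin_tawss(map, tear30, plain), "tear_margin")
})
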