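test_that("tortuosity matches closed forms and is invariant to rigid motion", {
  straight <- centerline(cbind(0, 0, c(0, 5, 10)))
  expect_equal(tortuosity(straight), 1.0, tolerance = 1e-12)

  th <- seq(0, pi, length.out = 1000)
  semi <- centerline(cbind(cos(th), sin(th), 0))
  expect_equal(tortuosity(semi), pi / 2, tolerance = 1e-4)

  # one helix turn, r = 1, pitch 2*pi: arc 2*pi*sqrt(2) over chord 2*pi
  s <- seq(0, 2 * pi, length.out = 2000)
  helix <- centerline(cbind(cos(s), sin(s), s))
  expect_equal(tortuosity(helix), sqrt(2), tolerance = 1e-4)

  # invariance: rotation + translation + uniform scaling
  set.seed(7)
  for (i in 1:5) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2)); ang <- stats::runif(1, 0, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    sc <- stats::runif(1, 0.2, 5)
    moved <- centerline(sc * helix$points %*% Rm +
                          matrix(stats::rnorm(3), 2000, 3, byrow = TRUE))
    expect_equal(tortuosity(moved), tortuosity(helix), tolerance = 1e-9)
  }

  closed <- centerline(cbind(cos(c(th, rev(th))), sin(c(th, -rev(th))), 0))
  expect_error(tortuosity(closed), "coincident")
})

test_that("tear metrics follow the mean-diameter circle (with ellipse alternative)", {
  t1 <- tear_metrics(10, 10)
  expect_equal(t1$area, pi * 25, tolerance = 1e-12)
  expect_equal(t1$perimeter, 10 * pi, tolerance = 1e-12)

  t2 <- tear_metrics(20, 10)
  expect_equal(t2$area, pi * 15^2 / 4, tolerance = 1e-12)  # d = 15 mm
  expect_equal(t2$area, 176.71, tolerance = 1e-4)

  # symmetry in (h, w)
  expect_equal(tear_metrics(20, 10)$area, tear_metrics(10, 20)$area)
  expect_equal(tear_metrics(20, 10)$perimeter, tear_metrics(10, 20)$perimeter)

  t3 <- tear_metrics(20, 10, method = "ellipse")
  expect_equal(t3$area, pi * 20 * 10 / 4, tolerance = 1e-12)

  expect_error(tear_metrics(0, 10), "> 0")
  expect_error(tear_metrics(10, -1), "> 0")
})

test_that("growth classification uses inclusive endpoint slopes", {
  tab <- diameter_table(c(0, 2), rbind(c(30, 30, 30), c(36, 31, 31)))
  g <- classify_growth(tab)
  expect_equal(unname(g$rates[1]), 3.0)
  expect_identical(g$label, "rapid")  # threshold inclusive

  tab2 <- diameter_table(c(0, 1), rbind(c(35, 35, 35), c(36, 36, 36)))
  expect_identical(classify_growth(tab2)$label, "stable")
  expect_equal(classify_growth(tab2)$max_rate, 1.0)

  tab3 <- diameter_table(c(0, 5), rbind(c(30, 30, 30),
                                        c(30 + 5 * 1.2, 30 + 5 * 4.6,
                                          30 + 5 * 0.5)))
  g3 <- classify_growth(tab3)
  expect_equal(g3$max_rate, 4.6, tolerance = 1e-12)
  expect_identical(g3$label, "rapid")

  expect_error(diameter_table(0.5, rbind(c(30, 30, 30))), "2 scans")

  # monotone: inflating any follow-up diameter never flips rapid -> stable
  set.seed(11)
  for (i in 1:20) {
    d2 <- c(30, 30, 30) + stats::runif(3, 0, 10)
    base <- classify_growth(diameter_table(c(0, 2), rbind(c(30, 30, 30), d2)))
    j <- sample.int(3, 1)
    d2b <- d2; d2b[j] <- d2b[j] + stats::runif(1, 0, 5)
    more <- classify_growth(diameter_table(c(0, 2), rbind(c(30, 30, 30), d2b)))
    if (base$label == "rapid") expect_identical(more$label, "rapid")
  }
})

test_that("cross-section areas recover tube and flap ground truth", {
  tube <- build_dissected_geometry(
    dissection_params(centerline_amplitude = 0, flap_angle_fraction = 1,
                      n_theta = 64, ds = 4))
  a <- section_areas(tube$mesh, tube$centerline, 100)
  expect_equal(a$total_area, pi * 15^2, tolerance = 0.005)
  expect_equal(a$tl_area, a$total_area)
  expect_equal(a$fl_area, 0)
  expect_equal(a$equiv_diameter, 30, tolerance = 0.005)

  g3 <- build_dissected_geometry(coarse_params(flap_angle_fraction = 0.3))
  a3 <- section_areas(g3$mesh, g3$centerline, 100)
  expect_equal(a3$tl_area / a3$total_area, 0.30, tolerance = 0.02)
  expect_equal(a3$tl_area + a3$fl_area, a3$total_area, tolerance = 0.02)

  expect_error(section_areas(g3$mesh, g3$centerline, 1e4), "outside")
})

test_that("TL/DA ratio averages the three plane ratios", {
  g <- build_dissected_geometry(coarse_params(flap_angle_fraction = 0.42))
  r <- tl_da_ratio(g$mesh, g$centerline)
  expect_equal(r, 0.42, tolerance = 0.02)

  s3 <- c(0.15, 0.5, 0.85) * max(g$centerline$arclength)
  per_plane <- vapply(s3, function(s) {
    a <- section_areas(g$mesh, g$centerline, s)
    a$tl_area / (a$tl_area + a$fl_area)
  }, numeric(1))
  expect_equal(r, mean(per_plane), tolerance = 1e-12)

  tube <- build_dissected_geometry(
    dissection_params(centerline_amplitude = 0, flap_angle_fraction = 1,
                      n_theta = 24, ds = 5))
  expect_equal(tl_da_ratio(tube$mesh, tube$centerline), 1.0)
})

test_that("geometry construction is deterministic and validates the tear", {
  p <- coarse_params(seed = 7)
  g1 <- build_dissected_geometry(p)
  g2 <- build_dissected_geometry(p)
  expect_identical(g1$mesh, g2$mesh)
  expect_identical(g1$centerline, g2$centerline)

  expect_error(build_dissected_geometry(coarse_params(tear_width = 40)),
               "flap")
  expect_error(build_dissected_geometry(coarse_params(tear_arclength = 2)),
               "tear")
  expect_error(dissection_params(flap_angle_fraction = 0), "flap_angle_fraction")
  expect_error(dissection_params(da_radius = -1), "> 0")

  # tear rim exists and is labeled
  expect_gt(sum(g1$mesh$vertex_region == "tear_margin"), 0)
  # every vertex has exactly one label from the documented set
  expect_true(all(g1$mesh$vertex_region %in%
                    c("ascending", "arch", "branch1", "branch2", "branch3",
                      "TL", "FL", "tear_margin")))
})
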