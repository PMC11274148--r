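# shared coarse fixtures, built once per test run

coarse_params <- function(tear_height = 20, tear_width = 12,
                          tear_arclength = 50, ...) {
  dissection_params(n_theta = 24, ds = 5, flap_n = 8,
                    tear_height = tear_height, tear_width = tear_width,
                    tear_arclength = tear_arclength, ...)
}

# default coarse dissected geometry + fields (noise-free variants derived
# in the tests that need them)
.fix <- new.env()

fixture_geometry <- function() {
  if (is.null(.fix$geom)) .fix$geom <- build_dissected_geometry(coarse_params())
  .fix$geom
}

fixture_fields <- function() {
  if (is.null(.fix$fields)) .fix$fields <- synthesize_fields(fixture_geometry()$mesh)
  .fix$fields
}

# minimal hand-built flat strip (4 columns x 2 rows of vertices) split into
# two mirror-symmetric regions of exactly equal vertex-area weight - for
# region_summary arithmetic checks
flat_two_region_mesh <- function(regions = c("TL", "FL")) {
  v <- cbind(rep(0:3, 2), rep(c(0, 1), each = 4), 0)
  quads <- lapply(1:3, function(j) rbind(c(j, j + 1, j + 5), c(j, j + 5, j + 4)))
  tr <- do.call(rbind, quads)
  lab <- rep(rep(regions, each = 2), 2)
  structure(list(vertices = v, triangles = tr,
                 vertex_region = lab,
                 triangle_component = rep("wall", nrow(tr)),
                 outlet_caps = list(), vertex_axial = NULL,
                 vertex_normal = NULL, vertex_s = rep(NA_real_, 8),
                 params = NULL),
            class = "aorta_mesh")
}

# constant-in-time wss series from a per-vertex 3-vector matrix
const_wss <- function(vec_mat, n_t = 16, period = 0.8) {
  n_v <- nrow(vec_mat)
  a <- array(0, c(n_v, n_t, 3))
  for (k in 1:3) a[, , k] <- matrix(vec_mat[, k], n_v, n_t)
  wss_series(seq(0, period, length.out = n_t + 1)[1:n_t], a, period)
}

# independent brute-force two-sided Fisher oracle: enumerate all 2x2 tables
# with the observed margins, hypergeometric probabilities from choose()
fisher_enumeration <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(ks, function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  }, numeric(1))
  p_obs <- pr[ks == tab[1, 1]]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}
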