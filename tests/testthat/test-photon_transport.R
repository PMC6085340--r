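# conventions for the shared slab fixture: 40 x 40 x 24 mm at 1 mm,
# homogeneous mu_a = 0.01 /mm, mu_s' = 1.0 /mm; source on the top face
slab_src <- c(17.5, 19.5, 0)
slab_det <- c(27.5, 19.5, 0)   # d_SD = 10 mm

test_that("fluence is linear in source strength and zero without a source", {
  m <- test_slab(); op <- test_slab_op()
  f0 <- solve_fluence(m, slab_src, 805, strength = 0, op = op)
  expect_true(all(f0$values == 0))
  f1 <- solve_fluence(m, slab_src, 805, op = op)
  f2 <- solve_fluence(m, slab_src, 805, strength = 2, op = op)
  expect_equal(f2$values, 2 * f1$values, tolerance = 1e-12)
})

test_that("slab fluence matches the semi-infinite closed form within 5%", {
  m <- test_slab(); op <- test_slab_op()
  fl <- solve_fluence(m, slab_src, 805, op = op)
  depths <- seq(2.5, 13.5, by = 1)          # voxel centers, 2-14 mm range
  num <- sapply(depths, function(z) fl$values[18, 20, ceiling(z)])
  ana <- oracle_fluence(0, depths)
  expect_lt(max(abs(num / ana - 1)), 0.05)
})

test_that("detected partial current matches the reflectance closed form within 10%", {
  m <- test_slab(); op <- test_slab_op()
  fl <- solve_fluence(m, slab_src, 805, op = op)
  I10 <- detected_intensity(fl, slab_det, method = "partial_current")
  expect_lt(abs(I10 / oracle_reflectance(10) - 1), 0.10)
  expect_gt(I10, 0)
  expect_error(detected_intensity(fl, c(20, 20, 12), "partial_current"),
               "boundary|interior")
})

test_that("intensity and PMDF are reciprocal under source-detector exchange", {
  m <- test_slab(); op <- test_slab_op()
  p1 <- compute_pmdf(m, slab_src, slab_det, 805, op = op)
  p2 <- compute_pmdf(m, slab_det, slab_src, 805, op = op)
  expect_lt(abs(p1$intensity / p2$intensity - 1), 1e-6)
  expect_lt(max(abs(p1$values - p2$values)) / max(p1$values), 1e-6)
  expect_true(all(p1$values >= 0))
})

test_that("PMDF is banana-shaped: on-axis midpoint beats 10 mm off-axis", {
  m <- test_slab(); op <- test_slab_op()
  p <- compute_pmdf(m, slab_src, slab_det, 805, op = op)
  mid_on <- p$values[23, 20, 3]    # between the optodes, 2.5 mm deep
  mid_off <- p$values[23, 30, 3]   # 10 mm lateral of the axis
  expect_gt(mid_on, mid_off)
})

test_that("PMDF sum equals the -dlnI/dmua finite-difference oracle within 2%", {
  m <- test_slab(); op <- test_slab_op()
  p <- compute_pmdf(m, slab_src, slab_det, 805, op = op)
  dm <- 1e-5
  I_at <- function(mu_a) {
    mm <- build_layered_phantom(c(gray = 23), grid_shape = c(40, 40, 24),
                                voxel_size = 1,
                                optics = uniform_optics(mu_a = mu_a))
    compute_pmdf(mm, slab_src, slab_det, 805)$intensity
  }
  fd <- -(log(I_at(oracle_mua + dm)) - log(I_at(oracle_mua - dm))) / (2 * dm)
  expect_lt(abs(sum(p$values) / fd - 1), 0.02)
})

test_that("partial path lengths partition the mean path length", {
  ph <- test_phantom()
  src <- project_to_surface(ph, ph$landmarks$hand_knob) + c(-5, 0, 0)
  det <- src + c(10, 0, 0)
  s <- compute_ssp(compute_pmdf(ph, src, det, 805), ph)
  expect_lt(abs(sum(s$partial_path) - s$l_mean) / s$l_mean, 1e-6)
  expect_lt(abs(sum(s$ssp) - s$l_mean) / s$l_mean, 1e-12)
  expect_lte(s$regional_l_gray, s$partial_path[["gray"]])
  expect_error(compute_ssp(compute_pmdf(ph, src, det, 805), ph,
                           landmark = "nope"), "nope")
})

test_that("a single-distance sweep equals a direct SSP computation", {
  ph <- test_phantom()
  sw <- sweep_sd_distance(ph, distances = 10, alignments = "parallel",
                          wavelength = 805)
  expect_equal(nrow(sw), 1L)
  proj <- project_to_surface(ph, ph$landmarks$hand_knob)
  direct <- compute_ssp(
    compute_pmdf(ph, proj - c(5, 0, 0), proj + c(5, 0, 0), 805), ph)
  expect_equal(sw$l_mean, direct$l_mean, tolerance = 1e-10)
  expect_equal(sw$l_gray, unname(direct$partial_path["gray"]),
               tolerance = 1e-10)
  expect_equal(sw$regional_l_gray, direct$regional_l_gray,
               tolerance = 1e-10)
})

test_that("sweep is monotone on the layered phantom and rejects bad placements", {
  ph <- test_phantom()
  sw <- sweep_sd_distance(ph, distances = c(5, 10, 15),
                          alignments = c("parallel", "orthogonal"),
                          wavelength = 805)
  for (al in c("parallel", "orthogonal")) {
    s <- sw[sw$alignment == al, ]
    expect_true(all(diff(s$intensity) < 0))
    expect_true(all(diff(s$l_gray) > 0))
  }
  # flat slab has no preferred axis: alignments agree closely
  a <- sw[sw$alignment == "parallel", ]; b <- sw[sw$alignment == "orthogonal", ]
  expect_lt(max(abs(a$intensity / b$intensity - 1)), 0.15)
  expect_error(sweep_sd_distance(ph, distances = c(5, 200)), "200")
  expect_error(sweep_sd_distance(ph, distances = c(10, 5)), "increasing")
})

test_that("max sensitivity map dominates every member field", {
  ph <- test_phantom()
  op <- diffusion_operator(ph, 805)
  proj <- project_to_surface(ph, ph$landmarks$hand_knob)
  s1 <- compute_ssp(compute_pmdf(ph, proj - c(5, 0, 0), proj + c(5, 0, 0),
                                 805, op = op), ph)
  s2 <- compute_ssp(compute_pmdf(ph, proj - c(0, 5, 0), proj + c(0, 5, 0),
                                 805, op = op), ph)
  mm <- max_sensitivity_map(list(s1, s2))
  expect_true(all(mm >= s1$ssp) && all(mm >= s2$ssp))
  expect_equal(max_sensitivity_map(list(s1)), s1$ssp)
  expect_error(max_sensitivity_map(list()), "at least one")
})

test_that("halving the voxel size changes the mean path length by < 3%", {
  lmean_at <- function(h) {
    m <- build_layered_phantom(c(gray = 15), grid_shape = c(24, 24, 16) / h,
                               voxel_size = h, optics = uniform_optics())
    sum(compute_pmdf(m, c(8.5, 11.5, 0), c(15.5, 11.5, 0), 805)$values)
  }
  expect_lt(abs(lmean_at(0.5) / lmean_at(1) - 1), 0.03)
})

test_that("sources in open air are rejected", {
  m <- test_slab()
  expect_error(solve_fluence(m, c(20, 20, -15), 805), "air")
})
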