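test_that("centerline sampling is uniform and exact on simple curves", {
  sp <- centerline_spec("line", p0 = c(0, 0), p1 = c(1, 0),
                        width_mm = 0.05, vessel_class = "artery",
                        n_samples = 101)
  pts <- sample_centerline(sp)
  expect_equal(pts[, 1], seq(0, 1, by = 0.01))
  expect_equal(pts[, 2], rep(0, 101))

  arc <- centerline_spec("circular_arc", center = c(0, 0), radius = 0.5,
                         theta0 = 0, theta1 = pi, width_mm = 0.05,
                         vessel_class = "vein", n_samples = 101)
  pa <- sample_centerline(arc)
  d <- sqrt(rowSums(diff(pa)^2))
  expect_lt((max(d) - min(d)) / mean(d), 0.01)

  # zero-amplitude sinusoid degenerates to the line
  sz <- centerline_spec("sinusoid", p0 = c(0, 0), p1 = c(1, 0),
                        amplitude = 0, frequency = 2, width_mm = 0.05,
                        vessel_class = "artery", n_samples = 101)
  expect_equal(unname(sample_centerline(sz)), unname(pts), tolerance = 1e-9)

  expect_error(centerline_spec("line", p0 = c(0, 0), p1 = c(0, 0),
                               width_mm = 0.05, vessel_class = "artery"),
               "degenerate")
})

test_that("analytic truth matches closed-form circle and line geometry", {
  ln <- centerline_spec("line", p0 = c(0, 0), p1 = c(1, 0.5),
                        width_mm = 0.05, vessel_class = "artery")
  tr <- analytic_truth(ln)
  expect_equal(tr$tsc, 0)
  expect_equal(tr$mdac, 0)
  expect_equal(tr$arc_length_mm, tr$chord_length_mm)

  r <- 0.5
  arc <- semicircle_spec(r, theta0 = 0)
  ta <- analytic_truth(arc)
  expect_equal(ta$chord_length_mm, 1.0, tolerance = 1e-8)
  expect_equal(ta$arc_length_mm, pi * r, tolerance = 1e-8)
  expect_equal(ta$tsc, pi * r / r^2, tolerance = 1e-6)
  expect_equal(ta$tsc_lc, 1 / r^2, tolerance = 1e-6)
  expect_equal(ta$tsc_lx, pi * r / r^2 / (2 * r), tolerance = 1e-6)
  expect_equal(unique(round(ta$curvature, 8)), 1 / r)
})

test_that("arc length always dominates chord length on random specs", {
  set.seed(11)
  for (i in 1:25) {
    kind <- sample(c("line", "circular_arc", "sinusoid", "cubic_bezier"), 1)
    sp <- switch(kind,
      line = centerline_spec("line", p0 = runif(2, -1, 1), p1 = runif(2, -1, 1) + 0.05,
                             width_mm = 0.05, vessel_class = "artery"),
      circular_arc = centerline_spec("circular_arc", center = runif(2, -0.3, 0.3),
                                     radius = runif(1, 0.2, 1),
                                     theta0 = runif(1, 0, 6), theta1 = runif(1, 6.1, 9),
                                     width_mm = 0.05, vessel_class = "artery"),
      sinusoid = centerline_spec("sinusoid", p0 = runif(2, -1, 0), p1 = runif(2, 0.1, 1),
                                 amplitude = runif(1, 0, 0.3), frequency = runif(1, 0, 3),
                                 width_mm = 0.05, vessel_class = "artery"),
      cubic_bezier = centerline_spec("cubic_bezier",
                                     control = matrix(runif(8, -1, 1), 4, 2),
                                     width_mm = 0.05, vessel_class = "artery"))
    tr <- analytic_truth(sp, m = 2001)
    expect_gte(tr$arc_length_mm + 1e-9, tr$chord_length_mm)
    expect_gte(tr$tsc, 0)
  }
})

test_that("rasterized ribbons paint the pixels within half a width", {
  pitch <- PITCH
  p0 <- c(-50 * pitch, 0.3 * pitch)
  p1 <- c(50 * pitch, 0.3 * pitch)
  sp <- centerline_spec("line", p0 = p0, p1 = p1, width_mm = 5 * pitch,
                        vessel_class = "artery", n_samples = 101)
  ras <- rasterize_specs(list(sp))
  oracle <- naive_ribbon_count(p0, p1, 5 * pitch, c(304, 304), pitch)
  expect_equal(ras$truth$painted_px, oracle)
  # ~ 100 px x 5 px rectangle plus rounded end caps
  expect_lt(abs(ras$truth$painted_px - (500 + pi * 2.5^2)) / 500, 0.02)

  expect_equal(sum(rasterize_specs(list())$map$classes), 0)

  a <- rasterize_specs(list(sp), dropout = 0.3, seed = 9)
  b <- rasterize_specs(list(sp), dropout = 0.3, seed = 9)
  expect_identical(a$map$classes, b$map$classes)

  expect_error(rasterize_specs(list(
    centerline_spec("line", p0 = c(0, 0), p1 = c(1, 0), width_mm = 0.004,
                    vessel_class = "artery"))), "below one pixel")
  expect_error(rasterize_specs(list(
    centerline_spec("line", p0 = c(0, 0), p1 = c(3, 0), width_mm = 0.05,
                    vessel_class = "artery"))), "field of view")
})

test_that("overlapping artery and vein ribbons become junctions", {
  h <- centerline_spec("line", p0 = c(-0.5, 0), p1 = c(0.5, 0),
                       width_mm = 0.05, vessel_class = "artery")
  v <- centerline_spec("line", p0 = c(0, -0.5), p1 = c(0, 0.5),
                       width_mm = 0.05, vessel_class = "vein")
  ras <- rasterize_specs(list(h, v))
  cl <- ras$map$classes
  expect_gt(sum(cl == 3L), 0)
  expect_gt(sum(cl == 1L), 0)
  expect_gt(sum(cl == 2L), 0)
})

test_that("cohort specs validate their design parameters", {
  expect_error(cohort_spec(eyes_per_group = 0), "at least 2")
  expect_error(cohort_spec(vd_fovea = 1.2), "strictly in")
  expect_error(cohort_spec(effects = data.frame(group = "nope",
                                                zone = "para_I",
                                                delta_vd = 0.1)))
})

test_that("cohorts are reproducible and hit their density targets", {
  cs <- cohort_spec(eyes_per_group = 3, seed = 21)
  a <- generate_cohort(cs)
  b <- generate_cohort(cs)
  expect_identical(lapply(a$maps, `[[`, "classes"),
                   lapply(b$maps, `[[`, "classes"))
  expect_equal(a$manifest$group,
               rep(c("control", "NDR", "NPDR"), each = 3))

  zps <- list(OS = build_zones(c(304, 304), PITCH, "OS"),
              OD = build_zones(c(304, 304), PITCH, "OD"))
  rel <- c()
  for (eid in names(a$maps)) {
    m <- a$maps[[eid]]
    zp <- zps[[m$laterality]]
    tg <- a$targets[a$targets$eye_id == eid, ]
    for (z in zone_names()) {
      zm <- zp$zones == match(z, c("outside", zone_names())) - 1L
      vd <- vessel_density(binary_mask(m, "all"), zm)
      tgt <- tg$target_vd_artery[tg$zone == z] + tg$target_vd_vein[tg$zone == z]
      rel <- c(rel, vd / tgt - 1)
    }
  }
  expect_lt(max(abs(rel)), 0.12)
  expect_lt(abs(mean(rel)), 0.05)
})
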