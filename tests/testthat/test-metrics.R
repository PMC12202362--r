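test_that("pixel-count metrics follow their defining ratios", {
  mask <- matrix(FALSE, 100, 100)
  zone <- matrix(TRUE, 100, 100)
  mask[1:5, 1:100] <- TRUE
  expect_equal(vessel_density(mask, zone), 0.05)
  expect_equal(vessel_density(zone, zone), 1)
  expect_equal(vessel_density(matrix(FALSE, 100, 100), zone), 0)
  expect_true(is.na(vessel_density(mask, matrix(FALSE, 100, 100))))
  expect_error(vessel_density(mask, matrix(TRUE, 5, 5)), "mismatch")

  skel <- matrix(FALSE, 100, 100); skel[3, 1:100] <- TRUE
  expect_equal(vessel_diameter_index(mask, skel, zone), 5)
  expect_equal(vessel_length_fraction(skel, zone), 0.01)
  expect_true(is.na(vessel_diameter_index(mask, matrix(FALSE, 100, 100), zone)))
  # 1-px path has caliber exactly 1
  expect_equal(vessel_diameter_index(skel, skel, zone), 1)
})

test_that("VDI tracks ribbon width and VLF never exceeds VD", {
  zone <- matrix(TRUE, 304, 304)
  for (w_px in c(3, 6)) {
    sp <- centerline_spec("line", p0 = c(-1.2, 0.1), p1 = c(1.2, 0.1),
                          width_mm = w_px * PITCH, vessel_class = "artery")
    ras <- rasterize_specs(list(sp))
    mask <- binary_mask(ras$map, "all")
    sk <- skeletonize(mask)
    vdi <- vessel_diameter_index(mask, sk, zone)
    expect_lt(abs(vdi - w_px) / w_px, 0.12)
    expect_lte(vessel_length_fraction(sk, zone), vessel_density(mask, zone))
  }
})

test_that("box-counting dimension calibrates on lines and filled squares", {
  line <- matrix(FALSE, 256, 256); line[128, ] <- TRUE
  expect_lt(abs(fractal_dimension(line) - 1), 0.05)
  sq <- matrix(FALSE, 256, 256); sq[33:224, 33:224] <- TRUE
  expect_lt(abs(fractal_dimension(sq) - 2), 0.05)
  expect_true(is.na(fractal_dimension(matrix(FALSE, 64, 64))))
})

test_that("track lengths follow the polyline definitions", {
  p <- cbind(0:100, rep(0, 101))
  expect_equal(curve_length(p), 100)
  expect_equal(curve_length(rbind(c(0, 0), c(1, 1))), sqrt(2))
  expect_equal(chord_length(rbind(c(0, 0), c(3, 4))), 5)
  expect_error(curve_length(matrix(0, 1, 2)), "at least 2")

  r <- 50
  th <- seq(0, pi, length.out = ceiling(pi * r) + 1)
  semi <- cbind(r * cos(th), r * sin(th))
  expect_lt(abs(curve_length(semi) - pi * r) / (pi * r), 0.01)
  expect_lt(abs(chord_length(semi) - 2 * r), 1)

  set.seed(3)
  for (i in 1:10) {
    rp <- cbind(cumsum(runif(30, -1, 1)), cumsum(runif(30, -1, 1)))
    expect_gte(curve_length(rp) + 1e-12, chord_length(rp))
  }
})

test_that("curvature profiles recover analytic curvature on clean tracks", {
  straight <- cbind(seq(0, 60, by = 1), rep(2, 61))
  expect_true(all(abs(curvature_profile(straight)$curvature) < 1e-10))

  r <- 50
  th <- seq(0, pi, length.out = ceiling(pi * r) + 1)
  circ <- cbind(r * cos(th), r * sin(th))
  prof <- curvature_profile(circ, sigma = 2)
  interior <- 10:(length(prof$curvature) - 9)
  expect_lt(max(abs(abs(prof$curvature[interior]) * r - 1)), 0.05)
  # similarity: doubling coordinates halves curvature
  prof2 <- curvature_profile(circ * 2, sigma = 2)
  int2 <- 10:(length(prof2$curvature) - 9)
  expect_lt(max(abs(abs(prof2$curvature[int2]) * 2 * r - 1)), 0.05)

  expect_error(curvature_profile(circ[1:4, ]), "at least 5")
  expect_error(curvature_profile(rbind(c(0, 0), c(0, 0), c(1, 0), c(2, 0),
                                       c(3, 0))), "coincident")
})

test_that("squared-curvature tortuosity matches circle closed forms", {
  straight <- cbind(seq(0, 60, by = 1), rep(0, 61))
  expect_equal(total_squared_curvature(straight), 0, tolerance = 1e-12)
  expect_equal(tsc_lx(straight), 0, tolerance = 1e-12)
  expect_equal(tsc_lc(straight), 0, tolerance = 1e-12)

  r <- 50
  th <- seq(0, pi, length.out = ceiling(pi * r) + 1)
  semi <- cbind(r * cos(th), r * sin(th))
  expect_lt(abs(tsc_lc(semi) * r^2 - 1), 0.05)
  expect_lt(abs(tsc_lx(semi) * 2 * r^2 / pi - 1), 0.05)
  expect_lte(tsc_lc(semi), tsc_lx(semi))  # LC >= LX
})

test_that("mean direction angle change matches rotation-rate geometry", {
  straight <- cbind(0:30, rep(0, 31))
  expect_equal(mdac(straight), 0)

  r <- 100
  th <- seq(0, 2 * pi * 0.8, length.out = ceiling(2 * pi * r * 0.8) + 1)
  circ <- cbind(r * cos(th), r * sin(th))
  ds <- curve_length(circ) / (nrow(circ) - 1)
  expect_lt(abs(mdac(circ, step = 5) / (5 * ds / r) - 1), 0.10)

  corner <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(mdac(corner, step = 1), pi / 2)

  short <- cbind(0:5, rep(0, 6))
  expect_true(is.na(mdac(short, step = 5)))
})

test_that("tortuosity rises monotonically with injected sinusoid amplitude", {
  # gentle-tortuosity regime: at high amplitude x frequency the true
  # pixel-scale MDAC itself saturates and turns over
  amps <- c(0.005, 0.05, 0.1, 0.2)
  res <- t(vapply(amps, function(a) {
    sp <- centerline_spec("sinusoid", p0 = c(-1.2, 0), p1 = c(1.2, 0),
                          amplitude = a, frequency = 1, width_mm = 0.05,
                          vessel_class = "artery", n_samples = 300)
    tr <- longest_track(sp)
    c(mdac = mdac(tr, 5, sigma = 3),
      tsc_lc = tsc_lc(tr, method = "denoised"),
      tsc_lx = tsc_lx(tr, method = "denoised"))
  }, numeric(3)))
  expect_true(all(diff(res[, "mdac"]) > 0))
  expect_true(all(diff(res[, "tsc_lc"]) > 0))
  expect_true(all(diff(res[, "tsc_lx"]) > 0))
})

test_that("zone records respect containment, additivity and units", {
  sp <- centerline_spec("circular_arc", center = c(0, 0), radius = 1,
                        theta0 = pi / 3, theta1 = 2 * pi / 3,
                        width_mm = 0.05, vessel_class = "artery",
                        n_samples = 200)  # superior sector arc
  ras <- rasterize_specs(list(sp))
  mt <- metrics_by_zone(ras$map)
  art <- mt[mt$vessel_class == "artery", ]
  expect_gt(art$vd[art$zone == "para_S"], 0)
  for (z in c("fovea", "para_I", "para_N", "para_T"))
    expect_equal(art$vd[art$zone == z], 0)
  # additivity of class densities per zone
  co <- generate_cohort(cohort_spec(eyes_per_group = 2, seed = 13))
  m <- co$maps[[1]]
  mt2 <- metrics_by_zone(m)
  for (z in zone_names()) {
    sub <- mt2[mt2$zone == z, ]
    vd_all <- sub$vd[sub$vessel_class == "all"]
    vd_a <- sub$vd[sub$vessel_class == "artery"]
    vd_v <- sub$vd[sub$vessel_class == "vein"]
    zp <- build_zones(c(304, 304), PITCH, m$laterality)
    zm <- zp$zones == match(z, c("outside", zone_names())) - 1L
    junc <- sum((m$classes == 3L) & zm) / sum(zm)
    expect_equal(vd_all, vd_a + vd_v + junc, tolerance = 1e-12)
  }
  expect_equal(mt2$vdi_um, mt2$vdi_px * m$pixel_pitch_mm * 1000)
  # determinism
  expect_identical(metrics_by_zone(m), mt2)
})

test_that("whole-image metrics are stable under 90-degree rotation", {
  ras <- rasterize_specs(list(
    centerline_spec("sinusoid", p0 = c(-1.1, -0.2), p1 = c(1.1, 0.3),
                    amplitude = 0.12, frequency = 1.5, width_mm = 0.06,
                    vessel_class = "artery", n_samples = 250)))
  m <- ras$map
  rotcl <- t(m$classes)[, nrow(m$classes):1]
  mrot <- label_map(rotcl, m$pixel_pitch_mm, m$laterality, "rot")
  a <- metrics_by_zone(m)
  b <- metrics_by_zone(mrot)
  ia <- a[a$zone == "image" & a$vessel_class == "artery", ]
  ib <- b[b$zone == "image" & b$vessel_class == "artery", ]
  for (col in c("vd", "vdi_px", "vlf", "fd", "mdac", "lc_px", "tsc_lc"))
    expect_lt(abs(ib[[col]] - ia[[col]]) / max(abs(ia[[col]]), 1e-9), 0.02)
})

test_that("production metrics agree with brute-force oracles", {
  set.seed(77)
  for (rep in 1:6) {
    ras <- random_phantom()
    zp <- build_zones(dim(ras$map$classes), ras$map$pixel_pitch_mm, "OS")
    mask <- binary_mask(ras$map, "all")
    sk <- skeletonize(mask)
    zm <- zp$zones == 2L  # para_S
    expect_equal(vessel_density(mask, zm), naive_vd(mask, zm), tolerance = 1e-12)
    expect_equal(vessel_length_fraction(sk, zm), naive_vlf(sk, zm),
                 tolerance = 1e-12)
    expect_equal(fractal_dimension(sk), naive_fd(sk), tolerance = 1e-9)
    tks <- extract_tracks(skeleton_graph(sk), min_length = 11)
    if (length(tks) > 0) {
      p <- tks[[1]]$points
      expect_equal(curve_length(p), naive_lc(p), tolerance = 1e-9)
      expect_equal(chord_length(p), naive_lx(p), tolerance = 1e-12)
      expect_equal(mdac(p, 4), naive_mdac(p, 4), tolerance = 1e-12)
    }
  }
})
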