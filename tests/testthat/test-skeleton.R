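test_that("thinning produces a one-pixel medial curve inside the mask", {
  mask <- matrix(FALSE, 60, 140)
  mask[28:32, 11:110] <- TRUE           # 5 x 100 ribbon
  sk <- skeletonize(mask)
  expect_true(all(mask[sk]))            # subset of the mask
  expect_true(all(which(sk, arr.ind = TRUE)[, 1] == 30))  # center row
  # thinning erodes roughly half a width at each open end
  expect_gte(sum(sk), 94)
  expect_lte(sum(sk), 100)
  expect_identical(skeletonize(sk), sk) # idempotent

  single <- matrix(FALSE, 10, 10); single[5, 5] <- TRUE
  expect_identical(skeletonize(single), single)
  expect_equal(sum(skeletonize(matrix(FALSE, 5, 5))), 0)
})

test_that("graphs decompose paths, junctions and disjoint components", {
  straight <- matrix(FALSE, 20, 60); straight[10, 5:55] <- TRUE
  g <- skeleton_graph(straight)
  expect_equal(sum(g$nodes$type == "endpoint"), 2)
  expect_length(g$edges, 1)
  expect_equal(nrow(g$edges[[1]]$path), 51)

  Y <- matrix(FALSE, 60, 60)
  for (k in 0:20) Y[30 - k, 30] <- TRUE
  for (k in 1:20) Y[30 + k, 30 - k] <- TRUE
  for (k in 1:20) Y[30 + k, 30 + k] <- TRUE
  gy <- skeleton_graph(Y)
  expect_equal(sum(gy$nodes$type == "endpoint"), 3)
  expect_equal(sum(gy$nodes$type == "branch"), 1)
  expect_length(gy$edges, 3)

  two <- matrix(FALSE, 30, 30)
  two[5, 2:25] <- TRUE; two[20, 2:25] <- TRUE
  gt <- skeleton_graph(two)
  expect_length(gt$edges, 2)
  expect_equal(nrow(gt$nodes), 4)
})

test_that("edges plus nodes cover the skeleton exactly once", {
  set.seed(5)
  for (rep in 1:5) {
    ras <- random_phantom()
    sk <- skeletonize(binary_mask(ras$map, "all"))
    g <- skeleton_graph(sk)
    node_keys <- paste(g$nodes$r, g$nodes$c)
    interior <- unlist(lapply(g$edges, function(e) {
      p <- e$path
      keep <- !(paste(p[, 1], p[, 2]) %in% node_keys)
      paste(p[keep, 1], p[keep, 2])
    }))
    expect_false(any(duplicated(interior)))  # no pixel in two edges
    covered <- unique(c(node_keys, interior))
    all_px <- which(sk, arr.ind = TRUE)
    expect_setequal(covered, paste(all_px[, 1], all_px[, 2]))
  }
})

test_that("cycles without endpoints are cut and flagged as loops", {
  ring <- matrix(FALSE, 40, 40)
  th <- seq(0, 2 * pi, length.out = 200)
  for (i in seq_along(th))
    ring[round(20 + 12 * cos(th[i])), round(20 + 12 * sin(th[i]))] <- TRUE
  g <- skeleton_graph(skeletonize(ring))
  expect_length(g$edges, 1)
  expect_true(g$edges[[1]]$is_loop)
})

test_that("tracks filter by length and inherit class and zone by majority", {
  long <- matrix(FALSE, 30, 80)
  long[15, 5:75] <- TRUE                # long path
  long[10:14, 40] <- TRUE               # 5-px spur
  g <- skeleton_graph(long)
  tks <- extract_tracks(g, min_length = 10)
  expect_length(tks, 2)                 # spur (6 px incl branch) dropped
  expect_true(all(vapply(tks, function(t) t$n >= 10, logical(1))))

  art <- centerline_spec("line", p0 = c(-1, 0.5), p1 = c(1, 0.5),
                         width_mm = 0.05, vessel_class = "artery")
  ven <- centerline_spec("line", p0 = c(-1, -0.5), p1 = c(1, -0.5),
                         width_mm = 0.05, vessel_class = "vein")
  ras <- rasterize_specs(list(art, ven))
  zp <- build_zones(c(304, 304), PITCH, "OS")
  sk <- skeletonize(binary_mask(ras$map, "all"))
  tks2 <- extract_tracks(skeleton_graph(sk), min_length = 11,
                         map = ras$map, zones = zp)
  cls <- vapply(tks2, `[[`, character(1), "vessel_class")
  expect_equal(sort(cls), c("artery", "vein"))
})

test_that("track decomposition commutes with 90-degree rotation", {
  ras <- rasterize_specs(list(
    centerline_spec("sinusoid", p0 = c(-1, 0.2), p1 = c(1, 0.5),
                    amplitude = 0.1, frequency = 1.5, width_mm = 0.05,
                    vessel_class = "artery", n_samples = 200)))
  sk <- skeletonize(binary_mask(ras$map, "all"))
  skr <- t(sk)[, nrow(sk):1]            # rotate the skeleton raster
  key <- function(g) sort(vapply(g$edges, function(e)
    paste(sort(paste(e$path[, 1], e$path[, 2])), collapse = ";"),
    character(1)))
  g1 <- skeleton_graph(sk)
  g2 <- skeleton_graph(skr)
  # map rotated tracks back: (r, c) -> (c, nr + 1 - r)
  nr <- nrow(sk)
  back <- sort(vapply(g2$edges, function(e) {
    p <- cbind(nr + 1 - e$path[, 2], e$path[, 1])
    paste(sort(paste(p[, 1], p[, 2])), collapse = ";")
  }, character(1)))
  expect_identical(key(g1), back)
})
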