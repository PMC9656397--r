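test_that("region area counts pixels and scales with pixel size", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  expect_equal(region_area(sq, 1), 100)
  expect_equal(region_area(sq, 2.5), 100 * 2.5^2)
  disk <- make_disk(100)
  expect_lt(abs(region_area(disk) / (pi * 100^2) - 1), 0.01)
  expect_error(region_area(matrix(FALSE, 3, 3)), class = "colonymorph_empty_region")
})

test_that("perimeter estimators match their conventions", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  expect_equal(region_perimeter(sq, method = "corner"), 40)
  px1 <- matrix(FALSE, 3, 3); px1[2, 2] <- TRUE
  expect_equal(region_perimeter(px1, method = "corner"), 4)
  expect_equal(region_perimeter(px1, method = "weighted"), 4)
  disk <- make_disk(200)
  expect_lt(abs(region_perimeter(disk) / (2 * pi * 200) - 1), 0.02)
  # linear scaling in pixel size
  expect_equal(region_perimeter(disk, 3), 3 * region_perimeter(disk, 1))
  # two components must be rejected
  two <- matrix(FALSE, 10, 10); two[2:3, 2:3] <- TRUE; two[7:8, 7:8] <- TRUE
  expect_error(region_perimeter(two), class = "colonymorph_multi_component")
})

test_that("fitted ellipse matches analytic moments and the area convention", {
  disk <- make_disk(100)
  ax <- ellipse_axes(disk)
  expect_lt(abs(ax[["minor"]] / 200 - 1), 0.01)
  n <- 120
  xs <- seq_len(n) - 0.5 - n / 2
  ell <- outer(xs, xs, function(y, x) (x / 40)^2 + (y / 20)^2) <= 1
  axe <- ellipse_axes(ell)
  expect_lt(abs(axe[["minor"]] / 40 - 1), 0.02)
  expect_lt(abs(axe[["major"]] / 80 - 1), 0.02)
  # area-match convention: pi/4 * major * minor = region area
  expect_equal(pi / 4 * axe[["major"]] * axe[["minor"]], region_area(ell),
               tolerance = 1e-6)
  # degenerate collinear region
  line <- matrix(FALSE, 5, 9); line[3, 2:8] <- TRUE
  expect_warning(axl <- ellipse_axes(line), "degenerate")
  expect_equal(axl[["minor"]], 0)
})

test_that("Feret diameters follow the pixel-corner convention", {
  rect <- matrix(FALSE, 40, 60); rect[11:30, 11:40] <- TRUE  # 20 x 30 px
  fd <- feret_diameters(rect)
  expect_equal(fd[["feret_d"]], sqrt(20^2 + 30^2))
  expect_equal(fd[["min_feret_d"]], 20)
  fd2 <- feret_diameters(rect, pixel_size = 0.5)
  expect_equal(fd2[["feret_d"]], sqrt(20^2 + 30^2) / 2)
  px1 <- matrix(FALSE, 3, 3); px1[2, 2] <- TRUE
  expect_equal(feret_diameters(px1)[["feret_d"]], sqrt(2))
})

test_that("rotating calipers equal exhaustive pairwise search on random blobs", {
  for (s in 1:50) {
    blob <- make_blob(s, r_base = sample(8:20, 1), irregularity = runif(1, 0, 0.45))
    fd <- feret_diameters(blob)
    expect_equal(fd[["feret_d"]], brute_force_feret(blob), tolerance = 1e-12)
    expect_lte(fd[["min_feret_d"]], fd[["feret_d"]])
    expect_equal(fd[["min_feret_d"]], angle_scan_min_feret(blob),
                 tolerance = 5e-3)
  }
})

test_that("shape factor is the isoperimetric quotient", {
  expect_equal(shape_factor(pi, 2 * pi), 1)
  expect_equal(shape_factor(1, 4), pi / 4)
  disk <- make_disk(200)
  sf <- shape_factor(region_area(disk), region_perimeter(disk))
  expect_gt(sf, 0.97); expect_lt(sf, 1.03)
  expect_error(shape_factor(-1, 4))
  expect_error(shape_factor(1, 0))
})

test_that("AIS is the footprint-minus-cells subtraction", {
  lab <- matrix(0L, 120, 120)
  fp <- matrix(FALSE, 120, 120)
  fp[11:110, 11:110] <- TRUE              # 10,000 px footprint
  lab[11:110, 11:100] <- 1L               # 9,000 px of cells
  img <- colony_image(lab, fp, pixel_size = 1)
  expect_equal(colony_ais(img), 1000)
  # tessellated colony: zero AIS
  lab2 <- matrix(0L, 60, 60); fp2 <- matrix(FALSE, 60, 60)
  fp2[6:55, 6:55] <- TRUE
  lab2[6:55, 6:30] <- 1L; lab2[6:55, 31:55] <- 2L
  expect_equal(colony_ais(colony_image(lab2, fp2)), 0)
  # cells outside the footprint are a consistency error
  expect_error(colony_image(lab2, matrix(FALSE, 60, 60)),
               class = "colonymorph_footprint_mismatch")
})

test_that("measure_image yields one record per cell plus a colony record", {
  img <- tiny_colony_image()
  m <- measure_image(img)
  expect_equal(sum(m$unit == "cell"), 3)
  expect_equal(sum(m$unit == "colony"), 1)
  co <- m[m$unit == "colony", ]
  expect_gte(co$area, sum(m$area[m$unit == "cell"]))
  expect_true(is.na(m$ais[m$unit == "cell"][1]))
  expect_equal(co$ais, co$area - sum(m$area[m$unit == "cell"]))
  expect_true(all(m$line == "L1"))
  expect_true(all(m$min_feret_d <= m$feret_d))
  # scale equivariance: lengths x s, areas x s^2 exactly
  img2 <- tiny_colony_image(pixel_size = 2)
  m2 <- measure_image(img2)
  expect_equal(m2$area, 4 * m$area)
  expect_equal(m2$perimeter, 2 * m$perimeter)
  expect_equal(m2$feret_d, 2 * m$feret_d)
  expect_equal(m2$shape_factor, m$shape_factor)
})

test_that("descriptors are invariant under lossless 90-degree rotation", {
  blob <- make_blob(99, r_base = 18)
  rot <- t(blob)[ncol(blob):1, ]
  for (f in list(region_area, region_perimeter,
                 function(m, p = 1) feret_diameters(m, p)[["feret_d"]],
                 function(m, p = 1) ellipse_axes(m, p)[["minor"]])) {
    expect_equal(f(blob), f(rot))
  }
})

test_that("arbitrary-angle re-rasterization agrees within a few percent", {
  # the same analytic blob rasterized at 0 and 30 degrees
  rasterize <- function(rot) {
    n <- 140
    xs <- seq_len(n) - 0.5 - n / 2
    X <- matrix(xs, n, n, byrow = TRUE); Y <- matrix(xs, n, n)
    Xr <- X * cos(rot) + Y * sin(rot); Yr <- -X * sin(rot) + Y * cos(rot)
    th <- atan2(Yr, Xr)
    sqrt(Xr^2 + Yr^2) <= 45 * (1 + 0.2 * cos(3 * th))
  }
  a <- rasterize(0); b <- rasterize(pi / 6)
  expect_lt(abs(region_area(a) / region_area(b) - 1), 0.03)
  expect_lt(abs(region_perimeter(a) / region_perimeter(b) - 1), 0.03)
  fa <- feret_diameters(a); fb <- feret_diameters(b)
  expect_lt(abs(fa[["feret_d"]] / fb[["feret_d"]] - 1), 0.03)
  expect_lt(abs(fa[["min_feret_d"]] / fb[["min_feret_d"]] - 1), 0.03)
})
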