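# Shared fixtures, built in code.

# Rasterized disk of radius r px, pixel centres at half-integers.
make_disk <- function(r, pad = 10) {
  n <- 2 * r + 2 * pad
  xs <- seq_len(n) - 0.5 - n / 2
  outer(xs, xs, function(y, x) sqrt(x^2 + y^2)) <= r
}

# Random star-convex blob (smooth radial Fourier profile), guaranteed
# connected; used as oracle fodder for the Feret tests.
make_blob <- function(seed, r_base = 15, irregularity = 0.3) {
  set.seed(seed)
  amps <- rnorm(5) / (2:6)
  ph <- runif(5, 0, 2 * pi)
  prof <- function(theta) {
    s <- rep(0, length(theta))
    for (k in seq_along(amps)) s <- s + amps[k] * cos((k + 1) * theta + ph[k])
    1 + irregularity * s / max(abs(s))
  }
  n <- ceiling(2 * r_base * (1 + irregularity)) + 10
  xs <- seq_len(n) - 0.5 - n / 2
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(xs, n, n)
  sqrt(X^2 + Y^2) <= r_base * prof(atan2(Y, X))
}

# Independent brute-force Feret oracle: max pairwise distance over ALL
# boundary-pixel corner points (no hull, no calipers).
brute_force_feret <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- mask
  nb <- p[1:nr, 2:(nc + 1)] + p[3:(nr + 2), 2:(nc + 1)] +
    p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 3:(nc + 2)]
  bd <- which(mask & nb < 4)
  r <- (bd - 1) %% nr + 1
  c_ <- (bd - 1) %/% nr + 1
  pts <- unique(cbind(c(c_ - 1, c_, c_ - 1, c_), c(r - 1, r - 1, r, r)))
  max(stats::dist(pts))
}

# Min caliper width oracle by fine angle scan of projection extents.
angle_scan_min_feret <- function(mask, n_angles = 3600) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- mask
  nb <- p[1:nr, 2:(nc + 1)] + p[3:(nr + 2), 2:(nc + 1)] +
    p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 3:(nc + 2)]
  bd <- which(mask & nb < 4)
  r <- (bd - 1) %% nr + 1
  c_ <- (bd - 1) %/% nr + 1
  pts <- unique(cbind(c(c_ - 1, c_, c_ - 1, c_), c(r - 1, r - 1, r, r)))
  th <- seq(0, pi, length.out = n_angles)
  widths <- vapply(th, function(a) {
    pr <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    max(pr) - min(pr)
  }, numeric(1))
  min(widths)
}

# Feature table with a single informative descriptor (standardized shift
# `delta` on `informative`), everything else exchangeable noise.
planted_records <- function(n_per_group, informative, delta, seed,
                            informative2 = NULL) {
  params <- descriptor_names("colony")
  # scales chosen away from the generator's clipping and ordering bounds
  # (shape factor in (0, 1], ais well below area, min Feret below Feret), so
  # the seven columns stay independent by construction
  mu <- c(area = 50, perimeter = 30, minor_axis = 10, feret_d = 20,
          min_feret_d = 12, shape_factor = 0.5, ais = 3)[params]
  sd <- stats::setNames(rep(1, length(params)), params)
  sd["shape_factor"] <- 0.04
  gm <- rbind(
    data.frame(line = "L1", phenotype = "good", as.list(mu)),
    data.frame(line = "L1", phenotype = "bad", as.list(mu))
  )
  for (p in c(informative, informative2)) {
    gm[gm$phenotype == "bad", p] <- mu[[p]] + delta * sd[[p]]
  }
  sigma <- diag(sd^2)
  dimnames(sigma) <- list(params, params)
  generate_feature_table(gm, sigma, n_per_group, seed)
}

# Hand-built 3-cell colony image: footprint square with three rectangular
# cells inside.
tiny_colony_image <- function(pixel_size = 1) {
  lab <- matrix(0L, 40, 40)
  fp <- matrix(FALSE, 40, 40)
  fp[5:35, 5:35] <- TRUE
  lab[8:15, 8:15] <- 1L
  lab[20:30, 8:14] <- 2L
  lab[10:28, 20:32] <- 3L
  colony_image(lab, fp, pixel_size = pixel_size,
               meta = list(line = "L1", passage = 5L, time_h = 24,
                           phenotype = "good", clonality = "clonal"))
}
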