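# Synthetic labeled colony images. A colony is a blob-shaped footprint
# (radial Fourier perturbation of a disk, optionally with narrow spikes)
# tessellated into cells by an anisotropically weighted Voronoi diagram of
# dart-thrown seed points. Intercellular space is carved by shrinking each
# cell toward its seed; the shrink factor is tuned by a short deterministic
# bisection so the realized gap fraction lands within +/-0.005 of target.

#' Phenotype preset for the synthetic colony generator
#'
#' Describes the morphological regime of a colony phenotype class. The
#' `"good"` preset emulates a healthy undifferentiated colony: tightly packed
#' small cells, near-round, smooth well-defined edge. The `"bad"` preset
#' emulates differentiation signs: loosely packed cells with free
#' intercellular space, elongated outlier cells, and a spiky irregular edge.
#'
#' @param label `"good"` or `"bad"`.
#' @param gap_fraction Target fraction of the colony footprint that is free
#'   intercellular space (AIS / footprint area), in `[0, 1)`.
#' @param cell_elongation Target mean major/minor axis ratio of cells (>= 1).
#' @param boundary_irregularity Relative amplitude of the colony-edge radial
#'   perturbation (0 = smooth circle-like edge).
#' @param cell_diameter_mean,cell_diameter_sd Cell diameter distribution in
#'   um; hPSC cells are small, 10-16 um across.
#' @param n_spikes Number of narrow boundary spikes added to the colony edge
#'   (a feature of the bad phenotype).
#' @param elongated_outlier_frac Fraction of cells drawn with doubled
#'   elongation (bad-phenotype outliers).
#' @return An object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(label = c("good", "bad"),
                           gap_fraction = if (label == "good") 0.04 else 0.14,
                           cell_elongation = if (label == "good") 1.15 else 1.6,
                           boundary_irregularity = if (label == "good") 0.03 else 0.12,
                           cell_diameter_mean = 13,
                           cell_diameter_sd = 1.5,
                           n_spikes = if (label == "good") 0L else 6L,
                           elongated_outlier_frac = if (label == "good") 0 else 0.1) {
  label <- match.arg(label)
  if (gap_fraction < 0 || gap_fraction >= 1) {
    abort("`gap_fraction` must be in [0, 1).", class = "colonymorph_domain")
  }
  if (cell_elongation < 1) abort("`cell_elongation` must be >= 1.")
  if (boundary_irregularity < 0) abort("`boundary_irregularity` must be >= 0.")
  stopifnot_scalar_number(cell_diameter_mean, "cell_diameter_mean", positive = TRUE)
  structure(
    list(label = label, gap_fraction = gap_fraction,
         cell_elongation = cell_elongation,
         boundary_irregularity = boundary_irregularity,
         cell_diameter_mean = cell_diameter_mean,
         cell_diameter_sd = cell_diameter_sd,
         n_spikes = as.integer(n_spikes),
         elongated_outlier_frac = elongated_outlier_frac),
    class = "phenotype_spec"
  )
}

#' Default phenotype presets
#'
#' The two default phenotype regimes (`good`, `bad`). Under the defaults the
#' good preset has the lower gap fraction, lower elongation and smoother
#' boundary.
#'
#' @return Named list of two [phenotype_spec()] objects.
#' @export
default_phenotypes <- function() {
  list(good = phenotype_spec("good"), bad = phenotype_spec("bad"))
}

#' Cell-line preset for the synthetic generator
#'
#' A line is characterized by a monotone colony-growth curve (colony area as
#' a function of hours post-plating) and a per-time shape-factor trend used
#' by the tabular generator.
#'
#' @param name Line name.
#' @param area_24h Colony area at 24 h, um^2.
#' @param growth_per_day Multiplicative area growth per 24 h (>= 1, so the
#'   growth curve is non-decreasing).
#' @param shape_factor_trend Named numeric per-time-bin additive offset for
#'   the colony shape factor (bins `"24"`, `"48"`, `"72-120"`).
#' @return An object of class `line_spec` with a `colony_area_at(t)` function.
#' @export
line_spec <- function(name, area_24h = 3e4, growth_per_day = 1.7,
                      shape_factor_trend = c(`24` = 0, `48` = 0, `72-120` = 0)) {
  stopifnot_scalar_number(area_24h, "area_24h", positive = TRUE)
  if (growth_per_day < 1) abort("`growth_per_day` must be >= 1 (non-decreasing growth).")
  force(area_24h); force(growth_per_day)
  structure(
    list(name = name,
         area_24h = area_24h,
         growth_per_day = growth_per_day,
         colony_area_at = function(t) area_24h * growth_per_day^((t - 24) / 24),
         shape_factor_trend = shape_factor_trend),
    class = "line_spec"
  )
}

#' Default line presets
#'
#' Three synthetic lines mirroring a typical comparison design: an embryonic-stem-like
#' line with larger colonies at all times (`ES1`) and two induced lines with
#' close, smaller baselines (`IPS1`, `IPS2`) but different shape-factor
#' dynamics.
#'
#' @return Named list of three [line_spec()] objects.
#' @export
default_lines <- function() {
  list(
    ES1  = line_spec("ES1",  area_24h = 4.5e4, growth_per_day = 1.8,
                     shape_factor_trend = c(`24` = 0, `48` = 0.05, `72-120` = 0)),
    IPS1 = line_spec("IPS1", area_24h = 2.8e4, growth_per_day = 1.6,
                     shape_factor_trend = c(`24` = 0, `48` = 0, `72-120` = 0)),
    IPS2 = line_spec("IPS2", area_24h = 2.6e4, growth_per_day = 1.65,
                     shape_factor_trend = c(`24` = 0, `48` = 0.03, `72-120` = 0.06))
  )
}

#' Labeled colony image container
#'
#' Bundles a cell label raster (0 = background, k > 0 = cell k, contiguous),
#' a binary colony footprint, the pixel size, per-image metadata and, for
#' synthetic images, the generating ground truth.
#'
#' @param cell_labels Integer matrix of cell labels.
#' @param footprint Logical matrix, same dimensions.
#' @param pixel_size um per pixel (> 0).
#' @param meta Named list: `line`, `passage`, `time_h`, `phenotype`,
#'   `clonality` (missing entries allowed).
#' @param truth Optional [phenotype_spec()] used to generate the image.
#' @return Object of class `colony_image`.
#' @export
colony_image <- function(cell_labels, footprint, pixel_size = 1,
                         meta = list(), truth = NULL) {
  if (!is.matrix(cell_labels)) abort("`cell_labels` must be a matrix.")
  storage.mode(cell_labels) <- "integer"
  footprint <- as_mask(footprint)
  if (!all(dim(cell_labels) == dim(footprint))) {
    abort("`cell_labels` and `footprint` must have identical dimensions.")
  }
  stopifnot_scalar_number(pixel_size, "pixel_size", positive = TRUE)
  if (any(cell_labels > 0L & !footprint)) {
    abort("every cell pixel must lie inside the colony footprint.",
          class = "colonymorph_footprint_mismatch")
  }
  labs <- sort(unique(cell_labels[cell_labels > 0L]))
  if (length(labs) && !identical(labs, seq_len(max(labs)))) {
    abort("cell labels must be contiguous positive integers 1..K.")
  }
  structure(list(cell_labels = cell_labels, footprint = footprint,
                 pixel_size = pixel_size, meta = meta, truth = truth),
            class = "colony_image")
}

#' @export
print.colony_image <- function(x, ...) {
  cat(sprintf("<colony_image> %d x %d px @ %g um/px, %d cells, gap %.3f\n",
              nrow(x$cell_labels), ncol(x$cell_labels), x$pixel_size,
              max(x$cell_labels),
              1 - sum(x$cell_labels > 0) / sum(x$footprint)))
  invisible(x)
}

# Radial boundary function r(theta) for the footprint: smooth low-order
# Fourier perturbation plus optional narrow Gaussian spikes.
make_radial_profile <- function(irregularity, n_spikes) {
  amps <- stats::rnorm(7) / (2:8)
  phases <- stats::runif(7, 0, 2 * pi)
  spike_pos <- stats::runif(n_spikes, 0, 2 * pi)
  spike_amp <- stats::runif(n_spikes, 0.5, 1)
  function(theta) {
    s <- rep(0, length(theta))
    for (k in seq_along(amps)) {
      s <- s + amps[k] * cos((k + 1) * theta + phases[k])
    }
    if (max(abs(s)) > 0) s <- s / max(abs(s))
    if (n_spikes > 0) {
      for (j in seq_len(n_spikes)) {
        d <- atan2(sin(theta - spike_pos[j]), cos(theta - spike_pos[j]))
        s <- s + 2 * spike_amp[j] * exp(-(d / 0.08)^2)
      }
    }
    1 + irregularity * s
  }
}

#' Generate a synthetic labeled colony image
#'
#' Draws a colony footprint sized from the line's growth curve at `time_h`,
#' fills it with cells by an anisotropically weighted Voronoi tessellation of
#' dart-thrown seeds (per-cell random orientation, size and elongation), and
#' carves intercellular space by shrinking each cell toward its seed until
#' the realized gap fraction matches `pheno$gap_fraction` (within +/-0.005 by
#' construction; the contract is +/-0.03). With `gap_fraction = 0` the cells
#' tessellate the footprint exactly and the AIS is exactly 0. The function is
#' a pure function of its arguments: the same seed gives a bit-identical
#' raster.
#'
#' @param line A [line_spec()].
#' @param pheno A [phenotype_spec()].
#' @param time_h Hours post-plating, in 24..120.
#' @param seed Integer seed.
#' @param pixel_size um per pixel (default 1).
#' @param min_dim Minimum raster dimension (default 512).
#' @param max_dim Maximum raster dimension; a colony whose target area cannot
#'   fit raises a sizing error.
#' @param meta Extra metadata merged into the image metadata.
#' @return A [colony_image()] with `truth = pheno`.
#' @export
generate_colony_image <- function(line, pheno, time_h, seed,
                                  pixel_size = 1, min_dim = 512L,
                                  max_dim = 2048L, meta = list()) {
  stopifnot(inherits(line, "line_spec"), inherits(pheno, "phenotype_spec"))
  if (time_h < 24 || time_h > 120) abort("`time_h` must be in 24..120.")
  if (pheno$gap_fraction >= 1) abort("`gap_fraction` must be < 1.",
                                     class = "colonymorph_domain")
  target_area <- line$colony_area_at(time_h) / pixel_size^2  # px^2
  r0 <- sqrt(target_area / pi)
  dim_needed <- ceiling(2 * r0 * (1 + 2 * pheno$boundary_irregularity) + 20)
  dim <- max(min_dim, dim_needed)
  if (dim > max_dim) {
    abort(sprintf(
      "target colony area %.0f px^2 needs a %d px raster, above max_dim = %d.",
      target_area, dim_needed, max_dim), class = "colonymorph_sizing")
  }
  with_seed(seed, {
    profile <- make_radial_profile(pheno$boundary_irregularity, pheno$n_spikes)
    # scale the base radius so the enclosed area of r(theta) hits the target
    th <- seq(0, 2 * pi, length.out = 721L)[-721L]
    rel <- profile(th)
    area_rel <- mean(rel^2) * pi  # area enclosed by r0 * rel(theta)
    r_base <- sqrt(target_area / area_rel)
    cx <- dim / 2; cy <- dim / 2
    xs <- seq_len(dim) - 0.5
    X <- matrix(xs, dim, dim, byrow = TRUE) - cx
    Y <- matrix(xs, dim, dim) - cy
    theta <- atan2(Y, X)
    rad <- sqrt(X^2 + Y^2)
    footprint <- rad <= r_base * profile(theta)
    foot_idx <- which(footprint)
    A_foot <- length(foot_idx)
    if (A_foot < 9) abort("footprint degenerate; increase target area.")

    # --- seed points by dart throwing -----------------------------------
    d_mean <- pheno$cell_diameter_mean / pixel_size
    cell_area <- pi * (d_mean / 2)^2
    n_cells <- max(1L, round(A_foot * (1 - pheno$gap_fraction) / cell_area))
    min_gap <- 0.75 * d_mean
    nr <- dim
    fy <- (foot_idx - 1L) %% nr + 0.5
    fx <- (foot_idx - 1L) %/% nr + 0.5
    seeds <- matrix(NA_real_, n_cells, 2L)
    got <- 0L
    tries <- 0L
    max_tries <- 60L * n_cells
    while (got < n_cells && tries < max_tries) {
      tries <- tries + 1L
      j <- sample.int(A_foot, 1L)
      p <- c(fx[j], fy[j])
      ok <- TRUE
      if (got > 0L) {
        d2 <- (seeds[seq_len(got), 1] - p[1])^2 + (seeds[seq_len(got), 2] - p[2])^2
        ok <- min(d2) >= min_gap^2
      }
      if (ok) { got <- got + 1L; seeds[got, ] <- p }
    }
    seeds <- seeds[seq_len(got), , drop = FALSE]
    n_cells <- got

    # --- per-cell anisotropy and size ------------------------------------
    elong <- rep(pheno$cell_elongation, n_cells) *
      exp(stats::rnorm(n_cells, 0, 0.08))
    if (pheno$elongated_outlier_frac > 0) {
      n_out <- round(pheno$elongated_outlier_frac * n_cells)
      if (n_out > 0) {
        out_i <- sample.int(n_cells, n_out)
        elong[out_i] <- elong[out_i] * 2
      }
    }
    elong <- pmax(elong, 1)
    diam <- pmax(stats::rnorm(n_cells, d_mean,
                              pheno$cell_diameter_sd / pixel_size), d_mean / 3)
    angle <- stats::runif(n_cells, 0, pi)

    # --- anisotropic weighted Voronoi assignment -------------------------
    # track the nearest and second-nearest seed distances: intercellular
    # space is carved along the near-bisector channel where the two are close
    dmin <- matrix(Inf, dim, dim)
    dmin2 <- matrix(Inf, dim, dim)
    lab0 <- matrix(0L, dim, dim)
    box_r <- ceiling(3 * max(diam) * sqrt(max(elong)))
    for (i in seq_len(n_cells)) {
      sx <- seeds[i, 1]; sy <- seeds[i, 2]
      c0 <- max(1L, floor(sx - box_r)); c1 <- min(dim, ceiling(sx + box_r))
      r0_ <- max(1L, floor(sy - box_r)); r1 <- min(dim, ceiling(sy + box_r))
      xs_ <- (c0:c1) - 0.5; ys_ <- (r0_:r1) - 0.5
      DX <- matrix(xs_ - sx, length(ys_), length(xs_), byrow = TRUE)
      DY <- matrix(ys_ - sy, length(ys_), length(xs_))
      ca <- cos(angle[i]); sa <- sin(angle[i])
      u <- DX * ca + DY * sa          # along the major axis
      v <- -DX * sa + DY * ca
      e <- sqrt(elong[i])
      d <- sqrt((u / e)^2 + (v * e)^2) / diam[i]
      sub_d <- dmin[r0_:r1, c0:c1]
      sub_d2 <- dmin2[r0_:r1, c0:c1]
      sub_l <- lab0[r0_:r1, c0:c1]
      new_first <- d < sub_d
      new_second <- !new_first & d < sub_d2
      sub_d2[new_first] <- sub_d[new_first]
      sub_d2[new_second] <- d[new_second]
      sub_d[new_first] <- d[new_first]
      sub_l[new_first] <- i
      dmin[r0_:r1, c0:c1] <- sub_d
      dmin2[r0_:r1, c0:c1] <- sub_d2
      lab0[r0_:r1, c0:c1] <- sub_l
    }
    lab0[!footprint] <- 0L
    # any footprint pixel left unassigned (outside all boxes): nearest seed
    left <- which(footprint & lab0 == 0L)
    if (length(left)) {
      ly <- (left - 1L) %% nr + 0.5; lx <- (left - 1L) %/% nr + 0.5
      for (j in seq_along(left)) {
        d2 <- (seeds[, 1] - lx[j])^2 + (seeds[, 2] - ly[j])^2
        lab0[left[j]] <- which.min(d2)
      }
      dmin2[left] <- Inf
    }

    # --- gap carving along near-bisector channels ------------------------
    margin <- (dmin2 - dmin)[foot_idx]  # metric distance to the bisector
    lab00 <- lab0[foot_idx]
    carve <- function(beta) {
      lab <- matrix(0L, dim, dim)
      keep <- margin >= beta
      lab[foot_idx[keep]] <- lab00[keep]
      lab
    }
    gap_of <- function(lab) 1 - sum(lab > 0L) / A_foot
    target <- pheno$gap_fraction
    if (target == 0) {
      lab <- enforce_connected_cells(lab0, fill_tessellation = TRUE)
    } else {
      # beta = target quantile of the margin distribution carves almost
      # exactly the target fraction; bisect to absorb stray-pixel cleanup
      lo <- 0
      hi <- stats::quantile(margin, min(target * 3 + 0.05, 1), names = FALSE)
      beta <- stats::quantile(margin, target, names = FALSE)
      lab <- NULL
      for (it in 1:12) {
        lab_try <- enforce_connected_cells(carve(beta))
        g <- gap_of(lab_try)
        lab <- lab_try
        if (abs(g - target) <= 0.004) break
        if (g > target) hi <- beta else lo <- beta
        beta <- (lo + hi) / 2
      }
    }
    labs_present <- sort(unique(lab[lab > 0L]))
    if (length(labs_present) == 0L) abort("generator produced no cells.")
    relab <- integer(max(labs_present))
    relab[labs_present] <- seq_along(labs_present)
    pos <- lab > 0L
    lab[pos] <- relab[lab[pos]]

    md <- utils::modifyList(
      list(line = line$name, passage = NA_integer_, time_h = time_h,
           phenotype = pheno$label, clonality = NA_character_),
      meta
    )
    colony_image(lab, footprint, pixel_size = pixel_size, meta = md,
                 truth = pheno)
  })
}

# Keep, for every label, only its largest 4-connected component. Stray pixels
# become background, or (when the image must remain a tessellation) are
# reabsorbed into an adjacent cell.
enforce_connected_cells <- function(lab, fill_tessellation = FALSE) {
  nr <- nrow(lab); nc <- ncol(lab)
  comp <- lab > 0L  # coverage before stray removal
  idx_all <- which(lab > 0L)
  lab_of <- lab[idx_all]
  rows <- (idx_all - 1L) %% nr + 1L
  cols <- (idx_all - 1L) %/% nr + 1L
  for (k in sort(unique(lab_of))) {
    sel <- lab_of == k
    r <- rows[sel]; c_ <- cols[sel]
    sub <- matrix(0L, diff(range(r)) + 1L, diff(range(c_)) + 1L)
    sub[cbind(r - min(r) + 1L, c_ - min(c_) + 1L)] <- 1L
    blobs <- EBImage::bwlabel(sub)
    nb <- max(blobs)
    if (nb > 1L) {
      sizes <- tabulate(blobs[blobs > 0L], nbins = nb)
      keep <- which.max(sizes)
      stray <- blobs[cbind(r - min(r) + 1L, c_ - min(c_) + 1L)] != keep
      lab[idx_all[sel][stray]] <- 0L
    }
  }
  if (fill_tessellation) {
    # reassign background pixels created above to a 4-neighbour cell
    for (pass in 1:8) {
      holes <- which(lab == 0L & comp)
      if (!length(holes)) break
      r <- (holes - 1L) %% nr + 1L
      c_ <- (holes - 1L) %/% nr + 1L
      assigned <- FALSE
      for (j in seq_along(holes)) {
        nbr <- c(
          if (r[j] > 1L) lab[holes[j] - 1L] else 0L,
          if (r[j] < nr) lab[holes[j] + 1L] else 0L,
          if (c_[j] > 1L) lab[holes[j] - nr] else 0L,
          if (c_[j] < nc) lab[holes[j] + nr] else 0L
        )
        nbr <- nbr[nbr > 0L]
        if (length(nbr)) {
          lab[holes[j]] <- nbr[[1L]]
          assigned <- TRUE
        }
      }
      if (!assigned) break
    }
  }
  lab
}
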