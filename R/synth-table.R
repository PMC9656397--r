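# Synthetic per-colony / per-cell feature tables: multivariate-normal draws
# of the seven descriptors around per-(line, phenotype) group means, a
# tabular stand-in for a measured morphology dataset.

#' Generate a synthetic morphology feature table
#'
#' Draws `n_per_group` morphology records per (line, phenotype) group from a
#' multivariate normal with the given group means and covariance. Shape
#' factor samples are clipped to (0, 1]; all other descriptors are truncated
#' below at a small positive floor so records satisfy the positivity
#' invariants.
#'
#' @param group_means Data frame with columns `line`, `phenotype` and one
#'   column per descriptor (see [descriptor_names()]); one row per group.
#' @param group_cov Covariance matrix (descriptors x descriptors, symmetric
#'   positive semi-definite), or a named list of such matrices keyed
#'   `"<line>.<phenotype>"`.
#' @param n_per_group Records per group (>= 2).
#' @param seed Integer seed.
#' @param unit `"colony"` or `"cell"` (sets which descriptors are present).
#' @param time_h Vector of plating times cycled over records (metadata).
#' @param passage Vector of passages cycled over records (metadata).
#' @param clonality_prob Probability a record is labeled `"clonal"` (the
#'   clonality label is independent of the descriptors: it carries
#'   expression effects only, not morphological ones).
#' @return Tibble of morphology records with metadata columns.
#' @export
generate_feature_table <- function(group_means, group_cov, n_per_group, seed,
                                   unit = c("colony", "cell"),
                                   time_h = c(24, 48),
                                   passage = c(13L, 25L, 40L),
                                   clonality_prob = 0.5) {
  unit <- match.arg(unit)
  params <- descriptor_names(unit)
  if (!is.data.frame(group_means) ||
      !all(c("line", "phenotype", params) %in% names(group_means))) {
    abort(paste0("`group_means` must contain columns line, phenotype and ",
                 paste(params, collapse = ", "), "."))
  }
  if (!is.numeric(n_per_group) || n_per_group < 2) {
    abort("`n_per_group` must be >= 2.", class = "colonymorph_domain")
  }
  n_per_group <- as.integer(n_per_group)
  get_cov <- function(key) {
    s <- if (is.list(group_cov) && !is.data.frame(group_cov)) {
      group_cov[[key]]
    } else {
      group_cov
    }
    if (is.null(s)) abort(sprintf("no covariance for group %s.", key))
    s <- as.matrix(s)
    if (nrow(s) != length(params) || ncol(s) != length(params)) {
      abort("covariance dimensions must match the number of descriptors.")
    }
    if (max(abs(s - t(s))) > 1e-8 * max(1, max(abs(s)))) {
      abort("covariance must be symmetric.", class = "colonymorph_domain")
    }
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      abort("covariance must be positive semi-definite.",
            class = "colonymorph_domain")
    }
    s
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(group_means)), function(i) {
      g <- group_means[i, ]
      key <- paste(g$line, g$phenotype, sep = ".")
      mu <- as.numeric(g[params])
      sigma <- get_cov(key)
      x <- MASS::mvrnorm(n_per_group, mu = mu, Sigma = sigma)
      x <- matrix(x, nrow = n_per_group)
      colnames(x) <- params
      x[, "shape_factor"] <- pmin(pmax(x[, "shape_factor"], 1e-6), 1)
      for (p in setdiff(params, "shape_factor")) {
        x[, p] <- pmax(x[, p], 1e-6)
      }
      # record ordering invariants: calipers bound the minor axis, AIS is a
      # strict sub-area of the colony
      x[, "min_feret_d"] <- pmin(x[, "min_feret_d"], x[, "feret_d"])
      x[, "minor_axis"] <- pmin(x[, "minor_axis"], x[, "feret_d"])
      if ("ais" %in% params) {
        x[, "ais"] <- pmin(x[, "ais"], 0.95 * x[, "area"])
      }
      out <- as_tibble(as.data.frame(x))
      out$unit <- unit
      out$line <- g$line
      out$phenotype <- g$phenotype
      out$time_h <- rep_len(time_h, n_per_group)
      out$passage <- rep_len(passage, n_per_group)
      out$clonality <- ifelse(stats::runif(n_per_group) < clonality_prob,
                              "clonal", "nonclonal")
      out
    })
    out <- dplyr::bind_rows(rows)
    out[, c("unit", meta_column_names(), params)]
  })
}

#' Default group means for the synthetic feature table
#'
#' Per-(line, phenotype) means of the seven colony descriptors for the three
#' default lines, at the 24-48 h scale. Bad-phenotype colonies have a larger
#' free intercellular space (AIS), lower shape factor and a shifted size
#' profile; the effect sizes put the default two-class problem at roughly
#' 75\% Bayes accuracy, the regime of expert-phenotype classification.
#'
#' @param unit `"colony"` or `"cell"`.
#' @return Data frame suitable as `group_means` for
#'   [generate_feature_table()].
#' @export
default_feature_means <- function(unit = c("colony", "cell")) {
  unit <- match.arg(unit)
  lines <- c("ES1", "IPS1", "IPS2")
  base <- list(
    ES1  = c(area = 6.0e4, perimeter = 950, minor_axis = 240,
             feret_d = 320, min_feret_d = 250, shape_factor = 0.84),
    IPS1 = c(area = 4.2e4, perimeter = 800, minor_axis = 200,
             feret_d = 270, min_feret_d = 210, shape_factor = 0.82),
    IPS2 = c(area = 4.0e4, perimeter = 790, minor_axis = 195,
             feret_d = 265, min_feret_d = 205, shape_factor = 0.80)
  )
  sds <- descriptor_sds(unit)
  # standardized good-vs-bad shifts, concentrated on ais/shape_factor with
  # smaller contributions from the size descriptors
  z <- c(area = 0.3, perimeter = 0.4, minor_axis = 0.5, feret_d = 0.3,
         min_feret_d = 0.3, shape_factor = 0.8, ais = 0.9)
  rows <- list()
  for (ln in lines) {
    for (ph in c("good", "bad")) {
      mu <- base[[ln]]
      mu <- c(mu, ais = unname(0.06 * mu["area"]))
      sgn <- if (ph == "bad") +1 else -1
      # size descriptors shift in opposite directions for the ES-like line,
      # mirroring line-dependent phenotype effects
      dir <- if (ln == "ES1") -sgn else sgn
      shift <- z * sds / 2  # half-shift each way: total diff = z sd
      mu["ais"] <- mu["ais"] + sgn * shift["ais"]
      mu["shape_factor"] <- mu["shape_factor"] - sgn * shift["shape_factor"]
      for (p in c("area", "perimeter", "minor_axis", "feret_d", "min_feret_d")) {
        mu[p] <- mu[p] + dir * shift[p]
      }
      rows[[paste(ln, ph)]] <- data.frame(line = ln, phenotype = ph,
                                          as.list(mu))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (unit == "cell") {
    # cells: ~13 um diameter scale
    sc <- 13 / 280
    for (p in c("perimeter", "minor_axis", "feret_d", "min_feret_d")) {
      out[[p]] <- out[[p]] * sc
    }
    out$area <- out$area * sc^2
    out$ais <- NULL
  }
  out
}

descriptor_sds <- function(unit = "colony") {
  s <- c(area = 9e3, perimeter = 140, minor_axis = 35, feret_d = 45,
         min_feret_d = 38, shape_factor = 0.06, ais = 1.4e3)
  if (unit == "cell") {
    sc <- 13 / 280
    s[c("perimeter", "minor_axis", "feret_d", "min_feret_d")] <-
      s[c("perimeter", "minor_axis", "feret_d", "min_feret_d")] * sc
    s["area"] <- s["area"] * sc^2
    s <- s[setdiff(names(s), "ais")]
  }
  s
}

#' Default descriptor covariance
#'
#' Diagonal-dominant covariance with moderate positive correlation (0.5)
#' among the five size descriptors, matching the strong size collinearity of
#' real colony data.
#'
#' @param unit `"colony"` or `"cell"`.
#' @return Covariance matrix over [descriptor_names()].
#' @export
default_feature_cov <- function(unit = c("colony", "cell")) {
  unit <- match.arg(unit)
  sds <- descriptor_sds(unit)
  p <- length(sds)
  R <- diag(p)
  dimnames(R) <- list(names(sds), names(sds))
  size <- c("area", "perimeter", "minor_axis", "feret_d", "min_feret_d")
  for (a in size) for (b in size) if (a != b) R[a, b] <- 0.5
  diag(sds) %*% R %*% diag(sds)
}
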