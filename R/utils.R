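#' @importFrom rlang .data abort warn inform
#' @importFrom tibble tibble as_tibble
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All generators route their randomness through this
# so they are pure functions of their arguments.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Half-up rounding to integer percent, the convention used for published
# confusion tables (e.g. 720/1099 = 65.51% -> 66%).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# The seven morphological descriptors, in canonical column order.
#' Names of the seven morphological descriptors
#'
#' Canonical column names used across the package for the seven shape
#' descriptors: `area`, `perimeter`, `minor_axis`, `feret_d`, `min_feret_d`,
#' `shape_factor`, `ais` (`ais` exists for colonies only).
#'
#' @param unit `"colony"` (all seven) or `"cell"` (six; no `ais`).
#' @return Character vector of descriptor column names.
#' @export
descriptor_names <- function(unit = c("colony", "cell")) {
  unit <- match.arg(unit)
  base <- c("area", "perimeter", "minor_axis", "feret_d", "min_feret_d",
            "shape_factor")
  if (unit == "colony") c(base, "ais") else base
}

meta_column_names <- function() {
  c("line", "passage", "time_h", "phenotype", "clonality")
}
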