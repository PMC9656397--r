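make_records <- function(value_by_row) {
  n <- nrow(value_by_row)
  tibble::tibble(
    unit = "colony", line = value_by_row$line,
    passage = 10L, time_h = value_by_row$time_h,
    phenotype = value_by_row$phenotype %||% "good",
    clonality = "clonal",
    area = value_by_row$area, perimeter = 1, minor_axis = 1, feret_d = 2,
    min_feret_d = 1, shape_factor = 0.5, ais = 1
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("dynamics table bins times and reports mean and SEM", {
  d <- expand.grid(line = "L1", time_h = c(24, 48, 72, 96, 120), rep = 1:4)
  d$area <- 7
  recs <- make_records(d)
  dyn <- dynamics_table(recs, "colony")
  a <- dyn[dyn$parameter == "area", ]
  expect_equal(levels(a$time_bin), c("24", "48", "72-120"))
  expect_equal(nrow(a), 3)                      # 96 and 120 pooled into 72-120
  expect_equal(a$n[a$time_bin == "72-120"], 12)
  expect_true(all(a$mean == 7))
  expect_true(all(a$sem == 0))
})

test_that("bin means follow a monotone growth curve", {
  ln <- default_lines()$ES1
  set.seed(1)
  d <- expand.grid(line = "ES1", time_h = c(24, 48, 72, 96, 120), rep = 1:30)
  d$area <- ln$colony_area_at(d$time_h) * exp(rnorm(nrow(d), 0, 0.05))
  dyn <- dynamics_table(make_records(d), "colony")
  a <- dyn$mean[dyn$parameter == "area"]
  expect_true(all(diff(a) > 0))
})

test_that("compare_groups gates on normality and behaves on identical samples", {
  x <- c(1, 2, 3, 4, 5, 6)
  r <- compare_groups(x, x)
  expect_equal(r$p_value, 1, tolerance = 1e-9)
  expect_false(r$significant)
  set.seed(2)
  a <- rnorm(50); b <- rnorm(50, 1)
  r2 <- compare_groups(a, b)
  expect_equal(r2$test_name, "welch_t")         # normal samples use Welch
  expect_true(r2$significant)                   # power > 0.99 at this effect
  skewed <- exp(rnorm(40, 0, 1.5))
  r3 <- compare_groups(skewed, rnorm(40))
  expect_equal(r3$test_name, "mann_whitney")    # log-normal fails the gate
  expect_error(compare_groups(1:2, 1:10),
               class = "colonymorph_insufficient_data")
})

test_that("type-I error of compare_groups is near nominal (quick check)", {
  set.seed(3)
  rej <- mean(replicate(300, {
    compare_groups(rnorm(20), rnorm(20))$significant
  }))
  expect_gt(rej, 0.01); expect_lt(rej, 0.10)
})

test_that("two-way ANOVA detects planted interactions and not additivity", {
  set.seed(4)
  d <- expand.grid(line = c("L1", "L2"), phenotype = c("good", "bad"),
                   rep = 1:30)
  # pure additive, no noise: interaction sum of squares is exactly zero
  d$area <- 2 + (d$line == "L2") * 3 + (d$phenotype == "bad") * 5
  fit <- stats::lm(area ~ line * phenotype, data = d)
  ss <- suppressWarnings(stats::anova(fit)["line:phenotype", "Sum Sq"])
  expect_lt(ss, 1e-20)
  # planted interaction (+/- 0.5 sd alternating pattern), n = 30 per cell
  d$area <- d$area + rnorm(nrow(d)) +
    0.5 * ifelse((d$line == "L2") == (d$phenotype == "bad"), 1, -1)
  r <- two_way_anova(d, "area")
  expect_equal(r$test_name, "anova_interaction")
  expect_true(r$significant)
  # empty/thin design cells are named
  d2 <- d[!(d$line == "L2" & d$phenotype == "bad"), ]
  expect_error(two_way_anova(d2, "area"), "L2")
})

test_that("phenotype screen isolates a planted AIS shift in the 24-48 h window", {
  recs <- planted_records(60, "ais", delta = 1.5, seed = 5)
  scr <- phenotype_screen(recs, "colony")
  expect_true(scr$significant[scr$parameter == "ais"])
  expect_lte(sum(scr$significant[scr$parameter != "ais"]), 1)
  # records outside the window are excluded from the screen
  recs72 <- recs
  recs72$time_h <- 72
  recs72$area <- recs72$area + ifelse(recs72$phenotype == "bad", 100, 0)
  scr2 <- phenotype_screen(dplyr::bind_rows(recs, recs72), "colony")
  expect_false(scr2$significant[scr2$parameter == "area"])
  expect_equal(unique(scr2$n_good + scr2$n_bad), 120)
})

test_that("shuffling phenotype labels destroys screen significance", {
  recs <- planted_records(60, "ais", delta = 1.5, seed = 6)
  set.seed(7)
  recs$phenotype <- sample(recs$phenotype)
  scr <- phenotype_screen(recs, "colony")
  expect_lte(sum(scr$significant), 1)   # ~alpha-level false positives only
})
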