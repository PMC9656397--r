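# Dynamics summaries, normality-gated two-group comparisons, and two-way
# line-by-phenotype ANOVA over the morphology descriptors.

time_bin_levels <- function() c("24", "48", "72-120")

#' Assign plating times to the analysis time bins
#'
#' Times are binned as 24 h, 48 h and a pooled late range 72-120 h (96 h and
#' 120 h records fall into the pooled bin).
#'
#' @param time_h Numeric vector of hours post-plating.
#' @return Factor with levels `"24"`, `"48"`, `"72-120"`.
#' @export
time_bin <- function(time_h) {
  b <- ifelse(time_h < 36, "24", ifelse(time_h < 60, "48", "72-120"))
  factor(b, levels = time_bin_levels())
}

#' Time-binned dynamics summaries
#'
#' Mean and standard error of each descriptor per (line, time bin), the
#' summary underlying growth-dynamics plots.
#'
#' @param records Morphology record tibble (as from [measure_image()] or
#'   [generate_feature_table()]).
#' @param unit `"colony"` or `"cell"`; rows of other units are dropped.
#' @return Tibble with `line`, `time_bin`, `parameter`, `n`, `mean`, `sem`.
#'   Empty (line, bin) combinations are omitted.
#' @export
dynamics_table <- function(records, unit = c("colony", "cell")) {
  unit <- match.arg(unit)
  params <- intersect(descriptor_names(unit), names(records))
  recs <- dplyr::filter(records, .data$unit == !!unit)
  if (!nrow(recs)) abort("no records of the requested unit.")
  recs$time_bin <- time_bin(recs$time_h)
  long <- tidyr::pivot_longer(recs[, c("line", "time_bin", params)],
                              dplyr::all_of(params),
                              names_to = "parameter", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$line, .data$time_bin, .data$parameter),
    n = dplyr::n(),
    mean = mean(.data$value),
    sem = stats::sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$line, .data$time_bin, .data$parameter)
}

# Normality gate: Shapiro-Wilk for n <= 5000 (Anderson-Darling above);
# degenerate (zero-variance) samples are treated as non-normal.
sample_is_normal <- function(x, alpha = 0.05) {
  if (stats::sd(x) == 0) return(FALSE)
  p <- tryCatch({
    if (length(x) <= 5000) stats::shapiro.test(x)$p.value
    else nortest::ad.test(x)$p.value
  }, error = function(e) 0)
  p >= alpha
}

#' Two-group comparison with a normality gate
#'
#' Compares the means of two samples with Welch's t-test when both samples
#' pass a Shapiro-Wilk normality gate (at `gate_alpha`), and with the
#' Mann-Whitney (Wilcoxon rank-sum) test otherwise; which test ran is
#' recorded.
#'
#' @param x,y Numeric samples, each of length >= 3.
#' @param alpha Significance level (default 0.05).
#' @param gate_alpha Level of the normality gate (default 0.05).
#' @return One-row tibble: `test_name` (`"welch_t"` or `"mann_whitney"`),
#'   `statistic`, `p_value`, `significant`.
#' @export
compare_groups <- function(x, y, alpha = 0.05, gate_alpha = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3) {
    abort("each sample needs at least 3 finite observations.",
          class = "colonymorph_insufficient_data")
  }
  normal <- sample_is_normal(x, gate_alpha) && sample_is_normal(y, gate_alpha)
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    res <- tibble(test_name = "welch_t", statistic = unname(tt$statistic),
                  p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    res <- tibble(test_name = "mann_whitney", statistic = unname(wt$statistic),
                  p_value = wt$p.value)
  }
  res$significant <- res$p_value < alpha
  res
}

#' Two-way ANOVA interaction test
#'
#' Tests the line-by-phenotype interaction (or any two factors) for one
#' descriptor with a two-way analysis of variance using Type II sums of
#' squares, which are appropriate for the unbalanced group sizes of colony
#' data.
#'
#' @param records Morphology record tibble.
#' @param response Name of the response descriptor column.
#' @param factors Character vector of two factor column names
#'   (default `c("line", "phenotype")`).
#' @param alpha Significance level.
#' @return One-row tibble: `test_name = "anova_interaction"`, `statistic`
#'   (the interaction F), `p_value`, `significant`, plus `response`.
#' @export
two_way_anova <- function(records, response,
                          factors = c("line", "phenotype"), alpha = 0.05) {
  stopifnot(length(factors) == 2, response %in% names(records))
  d <- records[, c(factors, response)]
  names(d) <- c("f1", "f2", "y")
  d <- d[stats::complete.cases(d), ]
  d$f1 <- factor(d$f1); d$f2 <- factor(d$f2)
  if (nlevels(d$f1) < 2 || nlevels(d$f2) < 2) {
    abort("each factor needs at least 2 levels.")
  }
  tab <- table(d$f1, d$f2)
  if (any(tab < 2)) {
    bad <- which(tab < 2, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "design cell (%s = %s, %s = %s) has fewer than 2 observations.",
      factors[1], rownames(tab)[bad[1]], factors[2], colnames(tab)[bad[2]]))
  }
  fit <- stats::lm(y ~ f1 * f2, data = d)
  a2 <- car::Anova(fit, type = 2)
  row <- grep(":", rownames(a2))
  tibble(test_name = "anova_interaction", response = response,
         statistic = a2[row, "F value"], p_value = a2[row, "Pr(>F)"],
         significant = a2[row, "Pr(>F)"] < alpha)
}

#' Per-line phenotype screen of all descriptors
#'
#' For every (line, descriptor), compares good vs bad phenotype records with
#' [compare_groups()], restricted to the 24-48 h window by default (the
#' window in which phenotype differences are screened). No multiple-testing
#' correction is applied by default, matching per-parameter reporting at
#' alpha = 0.05; Holm correction across descriptors within a line is
#' available.
#'
#' @param records Morphology record tibble with `phenotype` labels.
#' @param unit `"colony"` or `"cell"`.
#' @param time_window Length-2 numeric window of `time_h` kept (inclusive);
#'   `NULL` keeps all records.
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Tibble: `line`, `parameter`, `test_name`, `statistic`, `p_value`,
#'   `significant`, `n_good`, `n_bad`.
#' @export
phenotype_screen <- function(records, unit = c("colony", "cell"),
                             time_window = c(24, 48), alpha = 0.05,
                             adjust = c("none", "holm")) {
  unit <- match.arg(unit)
  adjust <- match.arg(adjust)
  params <- intersect(descriptor_names(unit), names(records))
  recs <- dplyr::filter(records, .data$unit == !!unit)
  if (!is.null(time_window)) {
    recs <- dplyr::filter(recs, .data$time_h >= time_window[1],
                          .data$time_h <= time_window[2])
  }
  if (!nrow(recs)) abort("no records in the requested unit/time window.")
  out <- list()
  for (ln in sort(unique(recs$line))) {
    sub <- recs[recs$line == ln, ]
    if (length(unique(sub$phenotype)) < 2) {
      abort(sprintf("line %s does not contain both phenotypes.", ln))
    }
    res_line <- lapply(params, function(p) {
      g <- sub[[p]][sub$phenotype == "good"]
      b <- sub[[p]][sub$phenotype == "bad"]
      r <- compare_groups(g, b, alpha = alpha)
      r$line <- ln; r$parameter <- p
      r$n_good <- sum(is.finite(g)); r$n_bad <- sum(is.finite(b))
      r
    })
    res_line <- dplyr::bind_rows(res_line)
    if (adjust == "holm") {
      res_line$p_value <- stats::p.adjust(res_line$p_value, "holm")
      res_line$significant <- res_line$p_value < alpha
    }
    out[[ln]] <- res_line
  }
  out <- dplyr::bind_rows(out)
  out[, c("line", "parameter", "test_name", "statistic", "p_value",
          "significant", "n_good", "n_bad")]
}
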