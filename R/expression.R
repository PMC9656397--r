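# Relative gene-expression analysis from qPCR cycle thresholds: reference-
# gene stability screen, 2^-ddCt fold changes versus a designated reference
# group with SEM over biological repeats, and per-gene significance tests.
# Amplification efficiency is fixed at 2 (classical 2^-ddCt).

panel_reference_gene <- function(panel, ref_gene = NULL) {
  rg <- ref_gene %||% attr(panel, "reference_gene")
  if (is.null(rg)) abort("no reference gene: supply `ref_gene` or a panel with a \"reference_gene\" attribute.")
  rg
}

# Technical replicates are averaged first: one Ct per (gene, grouping
# columns, bio_rep).
tech_means <- function(panel, grouping) {
  dplyr::summarise(
    dplyr::group_by(panel, dplyr::across(dplyr::all_of(c("gene", grouping, "bio_rep")))),
    ct = mean(.data$ct), .groups = "drop"
  )
}

#' Reference-gene stability screen
#'
#' Ranks candidate reference genes by the standard deviation of their
#' sample-mean Ct across all samples (a sample = one biological repeat of
#' one group, with technical replicates averaged). The lowest SD is the most
#' stable candidate and is ranked first.
#'
#' @param panel Long-format Ct tibble with columns `gene`, a grouping
#'   column, `bio_rep`, `tech_rep`, `ct`.
#' @param candidates Character vector of candidate gene names; each must be
#'   measured in every sample.
#' @param grouping Name of the grouping column (default `"group"`).
#' @return Tibble (`gene`, `ct_sd`, `rank`) sorted by ascending SD.
#' @export
reference_stability <- function(panel, candidates, grouping = "group") {
  if (!all(candidates %in% panel$gene)) {
    abort(sprintf("candidate gene(s) absent from the panel: %s.",
                  paste(setdiff(candidates, panel$gene), collapse = ", ")))
  }
  tm <- tech_means(panel[panel$gene %in% candidates, ], grouping)
  samples <- unique(tm[, c(grouping, "bio_rep")])
  counts <- table(tm$gene)
  missing <- candidates[counts[candidates] < nrow(samples)]
  if (length(missing)) {
    abort(sprintf("candidate gene(s) missing in some sample: %s.",
                  paste(missing, collapse = ", ")))
  }
  sds <- vapply(candidates, function(g) stats::sd(tm$ct[tm$gene == g]),
                numeric(1))
  out <- tibble(gene = candidates, ct_sd = unname(sds))
  out <- out[order(out$ct_sd, out$gene), ]
  out$rank <- seq_len(nrow(out))
  out
}

stars_for <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

#' Relative expression by 2^-ddCt
#'
#' For each biological repeat, technical replicates are averaged; the delta
#' Ct is the target's mean Ct minus the reference gene's mean Ct in the same
#' sample, and the relative quantity is `2^-dCt`. The fold change of a group
#' is the mean relative quantity over its biological repeats divided by the
#' mean over the reference group's repeats (so the reference group's pooled
#' fold change is exactly 1). SEM is over biological repeats (on the fold
#' scale); per-gene significance of each group against the reference group
#' uses the normality-gated two-group comparison on the per-repeat relative
#' quantities, with the usual star coding (* p<0.05, ** p<0.01, *** p<0.001,
#' **** p<0.0001).
#'
#' @param panel Long-format Ct tibble (`gene`, grouping column, `bio_rep`,
#'   `tech_rep`, `ct`).
#' @param grouping Grouping column name (e.g. `"group"`, `"line"`,
#'   `"clonality"`, `"phenotype"`).
#' @param reference_group Level of `grouping` used as the normalization
#'   reference.
#' @param ref_gene Reference gene; defaults to the panel's
#'   `"reference_gene"` attribute.
#' @param alpha Significance level for the star at `*`.
#' @return Tibble: `gene`, group level, `fold_change`, `sem`, `p_value`,
#'   `stars`, `n_bio`. The reference group's rows carry `p_value = NA`.
#' @export
relative_expression <- function(panel, grouping = "group", reference_group,
                                ref_gene = NULL, alpha = 0.05) {
  rg <- panel_reference_gene(panel, ref_gene)
  if (!grouping %in% names(panel)) {
    abort(sprintf("grouping column `%s` not found.", grouping))
  }
  if (!reference_group %in% panel[[grouping]]) {
    abort(sprintf("reference group `%s` not present.", reference_group))
  }
  tm <- tech_means(panel, grouping)
  ref_ct <- tm[tm$gene == rg, ]
  names(ref_ct)[names(ref_ct) == "ct"] <- "ref_ct"
  targets <- setdiff(unique(tm$gene), rg)
  d <- dplyr::inner_join(tm[tm$gene %in% targets, ],
                         ref_ct[, c(grouping, "bio_rep", "ref_ct")],
                         by = c(grouping, "bio_rep"))
  if (!nrow(d)) abort("no target measurements with a matching reference-gene sample.")
  d$rq <- 2^(-(d$ct - d$ref_ct))
  out <- list()
  for (g in targets) {
    dg <- d[d$gene == g, ]
    ref_rq <- dg$rq[dg[[grouping]] == reference_group]
    if (!length(ref_rq)) {
      abort(sprintf("reference group missing for gene %s.", g))
    }
    ref_mean <- mean(ref_rq)
    for (lev in unique(dg[[grouping]])) {
      rq <- dg$rq[dg[[grouping]] == lev]
      fold <- mean(rq) / ref_mean
      sem <- stats::sd(rq) / sqrt(length(rq)) / ref_mean
      p <- if (lev == reference_group) NA_real_ else {
        tryCatch(compare_groups(rq, ref_rq, alpha = alpha)$p_value,
                 error = function(e) NA_real_)
      }
      out[[paste(g, lev)]] <- tibble(
        gene = g, !!grouping := lev, fold_change = fold, sem = sem,
        p_value = p,
        stars = ifelse(is.na(p), "ns", as.character(stars_for(p))),
        n_bio = length(rq)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Summarize expression direction and significance across groupings
#'
#' The machine analog of reading the expression figures: per gene x grouping
#' x group, whether the gene is over- or under-expressed relative to the
#' reference group and whether the difference is significant.
#'
#' @param results Named list of [relative_expression()] tables, one per
#'   grouping (names are the grouping column names).
#' @param tol Fold changes within `tol` of 1 are reported as direction
#'   `"none"`.
#' @return Tibble: `grouping`, `gene`, `group`, `fold_change`, `direction`
#'   (`"over"`, `"under"`, `"none"`), `significant`. Empty input gives an
#'   empty summary.
#' @export
marker_screen <- function(results, tol = 0.05) {
  if (!length(results)) {
    return(tibble(grouping = character(), gene = character(),
                  group = character(), fold_change = numeric(),
                  direction = character(), significant = logical()))
  }
  rows <- lapply(names(results), function(nm) {
    res <- results[[nm]]
    grp_col <- setdiff(names(res), c("gene", "fold_change", "sem", "p_value",
                                     "stars", "n_bio"))[1]
    sub <- res[!is.na(res$p_value), ]
    if (!nrow(sub)) return(NULL)
    tibble(
      grouping = nm, gene = sub$gene, group = as.character(sub[[grp_col]]),
      fold_change = sub$fold_change,
      direction = ifelse(abs(sub$fold_change - 1) <= tol, "none",
                         ifelse(sub$fold_change > 1, "over", "under")),
      significant = sub$p_value < 0.05
    )
  })
  dplyr::bind_rows(rows)
}
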