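# Synthetic qPCR Ct panels: per-gene, per-group cycle-threshold triplicates
# with planted fold-change effects against a stable reference gene, mirroring
# a triplicate-amplification / three-biological-repeat design.

#' Generate a synthetic qPCR Ct panel
#'
#' Simulates cycle-threshold (Ct) values for a set of target genes across
#' experimental groups, with planted expression fold changes relative to the
#' reference group (the first element of `groups`). A fold change `f` for
#' gene g in group j lowers that gene's expected Ct by `log2(f)` cycles, so
#' the expected `2^-ddCt` of (g, j) against the reference group equals `f`.
#' Gaussian noise of `noise_sd` cycles is added independently to every Ct
#' measurement (reference gene included: its Ct carries the stated noise
#' only, no group effect).
#'
#' @param genes Character vector of target gene names.
#' @param groups Character vector of group labels; the first is the
#'   reference group.
#' @param fold_changes Matrix (genes x groups) of positive fold changes vs
#'   the reference group, or a single number recycled; the reference group's
#'   own column is forced to 1.
#' @param ref_gene_ct Expected Ct of the reference gene (default 10, an
#'   abundant ribosomal RNA).
#' @param base_ct Expected Ct of each target gene in the reference group
#'   (single value or per-gene vector; default 24).
#' @param noise_sd Measurement noise SD in cycles.
#' @param n_bio Biological repeats per group (default 3).
#' @param n_tech Technical replicates per amplification (default 3).
#' @param seed Integer seed.
#' @param ref_gene Name of the reference gene (default `"RN18S"`).
#' @return Tibble in long format: `gene`, `group`, `bio_rep`, `tech_rep`,
#'   `ct`, with the reference gene name in attribute `"reference_gene"`.
#' @export
generate_ct_panel <- function(genes, groups, fold_changes = 1,
                              ref_gene_ct = 10, base_ct = 24,
                              noise_sd = 0.2, n_bio = 3L, n_tech = 3L,
                              seed = 1L, ref_gene = "RN18S") {
  genes <- as.character(genes)
  groups <- as.character(groups)
  if (ref_gene %in% genes) abort("`ref_gene` must not appear in `genes`.")
  fc <- matrix(fold_changes, nrow = length(genes), ncol = length(groups),
               dimnames = list(genes, groups))
  if (any(!is.finite(fc)) || any(fc <= 0)) {
    abort("fold changes must be positive.", class = "colonymorph_domain")
  }
  fc[, 1L] <- 1
  base_ct <- rep_len(base_ct, length(genes))
  n_bio <- as.integer(n_bio); n_tech <- as.integer(n_tech)
  if (n_bio < 1L || n_tech < 1L) abort("`n_bio` and `n_tech` must be >= 1.")
  with_seed(seed, {
    grid <- expand.grid(
      tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
      gene = c(genes, ref_gene), group = groups,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    mu <- numeric(nrow(grid))
    is_ref <- grid$gene == ref_gene
    mu[is_ref] <- ref_gene_ct
    gi <- match(grid$gene[!is_ref], genes)
    gj <- match(grid$group[!is_ref], groups)
    mu[!is_ref] <- base_ct[gi] - log2(fc[cbind(gi, gj)])
    ct <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
    out <- tibble(gene = grid$gene, group = grid$group,
                  bio_rep = grid$bio_rep, tech_rep = grid$tech_rep, ct = ct)
    attr(out, "reference_gene") <- ref_gene
    out
  })
}
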