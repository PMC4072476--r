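#' Run the full allelic-lineage analysis
#'
#' Orchestrates the complete analysis chain on an aligned allele set:
#' ingestion filter (drop sequences with internal stop codons), optional
#' codon-region masking (typically excluding the peptide-binding region
#' so the synonymous clock is read from neutrally evolving sequence),
#' optional recombinant screening, pairwise dN/dS distances, group
#' divergence dating, synonymous-site compatibility analysis and — when a
#' tree is supplied — parsimony mapping with the tree-path recount of
#' synonymous substitution numbers and its TMRCA. Masking is applied
#' *before* the screen: the peptide-binding region's balancing-selection
#' hotspot concentrates legitimate substitutions into a short span, the
#' same spatial signature the regional clustering test looks for, so
#' screening the unmasked gene would flag ordinary PBR divergence as
#' recombination. The run is fully deterministic given its inputs; the
#' configuration is echoed in the result for provenance.
#'
#' @param x An `allele_set` (or named character vector of aligned CDS).
#' @param tree Optional `phylo` tree over (a subset of) the allele names;
#'   enables the parsimony recount.
#' @param groups Optional named character vector or `data.frame(name,
#'   group)` of group labels; defaults to labels stored in `x`.
#' @param mask Optional `region_mask` applied before distance and
#'   compatibility analyses.
#' @param mask_mode `"exclude"` or `"include"`.
#' @param screen Logical: run the recombinant screen first?
#' @param screen_args List of arguments passed to
#'   [screen_recombinants()].
#' @param kappa Transition/transversion bias for site counting; the
#'   string `"estimate"` uses [estimate_kappa()].
#' @param mu Neutral substitution rate per site per year.
#' @param synonymous_only Restrict compatibility and parsimony mapping to
#'   synonymous columns.
#' @param outgroup Optional outgroup tip name for rooting the tree; the
#'   outgroup is excluded from the recount KS matrix.
#' @return An object of class `lineage_run`: list with elements `screen`,
#'   `alleles` (the analysis set after screening/masking), `distances`,
#'   `dating` (group dating tibble), `compat`, `map`, `ks`,
#'   `tmrca_recount_years` and `config`.
#' @export
run_pipeline <- function(x, tree = NULL, groups = NULL,
                         mask = NULL, mask_mode = c("exclude", "include"),
                         screen = TRUE, screen_args = list(),
                         kappa = 1, mu = 1e-9,
                         synonymous_only = TRUE, outgroup = NULL) {
  x <- as_allele_set(x)
  mask_mode <- match.arg(mask_mode)
  x <- drop_nonfunctional(x)

  if (!is.null(mask)) {
    x <- apply_region_mask(x, mask, mode = mask_mode)
  }
  scr <- NULL
  if (isTRUE(screen)) {
    scr <- do.call(screen_recombinants, c(list(x), screen_args))
    x <- scr$retained
  }
  if (identical(kappa, "estimate")) {
    kappa <- estimate_kappa(x)
    if (!is.finite(kappa) || kappa <= 0) kappa <- 1
  }

  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      groups <- setNames(as.character(groups$group), groups$name)
    }
    x$groups <- groups[intersect(names(groups), names(x$seq))]
  }

  dists <- dnds_distances(x, kappa = kappa)
  dating <- NULL
  if (!is.null(x$groups) && length(x$groups)) {
    dating <- date_groups(group_summary(dists), mu = mu)
  }
  compat <- compatibility_report(x, synonymous_only = synonymous_only)

  map <- ks <- NULL
  tmrca_recount <- NA_real_
  if (!is.null(tree)) {
    tips <- intersect(tree$tip.label, names(x$seq))
    if (length(tips) < length(tree$tip.label)) {
      tree <- ape::keep.tip(tree, tips)
    }
    map <- fitch_map(tree, x, synonymous_only = synonymous_only,
                     outgroup = outgroup)
    ks <- ks_matrix(map)
    ingroup <- setdiff(rownames(ks$ks), outgroup)
    ks_max_in <- if (length(ingroup) >= 2L) {
      max(ks$ks[ingroup, ingroup])
    } else {
      ks$ks_max
    }
    ls_mean <- mean(dists$LS_per_seq[intersect(names(dists$LS_per_seq), ingroup)])
    tmrca_recount <- tmrca_from_ks(ks_max_in, ls_mean, mu = mu)
  }

  structure(
    list(
      screen = scr,
      alleles = x,
      distances = dists,
      dating = dating,
      compat = compat,
      map = map,
      ks = ks,
      tmrca_recount_years = tmrca_recount,
      config = list(kappa = kappa, mu = mu,
                    synonymous_only = synonymous_only,
                    mask_mode = if (is.null(mask)) NA_character_ else mask_mode,
                    masked_codons = if (is.null(mask)) integer(0) else mask$positions,
                    screened = isTRUE(screen),
                    outgroup = outgroup)
    ),
    class = "lineage_run"
  )
}

#' @export
print.lineage_run <- function(x, ...) {
  cat("<lineage_run>\n")
  if (!is.null(x$screen)) {
    cat(sprintf("  screen: %d allele(s) removed\n", length(x$screen$removed)))
  }
  cat(sprintf("  alleles analysed: %d x %d nt\n",
              length(x$alleles$seq), x$alleles$alignment_length))
  if (!is.null(x$dating)) {
    for (i in seq_len(nrow(x$dating))) {
      r <- x$dating[i, ]
      cat(sprintf(
        "  group %s: mean dS %.4g (T ~ %d MYA), dS max %.4g (TMRCA ~ %d MYA)\n",
        r$group, r$dS_mean, r$T_mya, r$dS_max, r$TMRCA_mya))
    }
  }
  cat(sprintf("  synonymous-site compatibility: %d informative, %d pairs, %d incompatible\n",
              x$compat$n_informative, x$compat$n_pairs,
              nrow(x$compat$incompatible)))
  if (!is.null(x$ks)) {
    cat(sprintf("  parsimony recount: KSmax %g, TMRCA ~ %s MYA\n",
                x$ks$ks_max,
                format(as_mya(x$tmrca_recount_years))))
  }
  invisible(x)
}
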