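#' Tidy pairwise distances into a long pair table
#'
#' @param x A `pairwise_distances` object.
#' @param ... Unused.
#' @return A tibble with one row per unordered allele pair: `name1`,
#'   `name2`, `dS`, `dN`, `pS`, `pN`.
#' @method tidy pairwise_distances
#' @export
tidy.pairwise_distances <- function(x, ...) {
  n <- length(x$names)
  ij <- which(upper.tri(x$dS), arr.ind = TRUE)
  tibble::tibble(
    name1 = x$names[ij[, 1L]],
    name2 = x$names[ij[, 2L]],
    dS = x$dS[ij],
    dN = x$dN[ij],
    pS = x$pS[ij],
    pN = x$pN[ij]
  )
}

#' One-row summary of a pairwise distance set
#'
#' @param x A `pairwise_distances` object.
#' @param ... Unused.
#' @return A tibble with `n_alleles`, `kappa`, `dS_mean`, `dS_max`,
#'   `dN_mean`, `LS_mean` and `n_saturated`.
#' @method glance pairwise_distances
#' @export
glance.pairwise_distances <- function(x, ...) {
  off_s <- x$dS[upper.tri(x$dS)]
  off_n <- x$dN[upper.tri(x$dN)]
  tibble::tibble(
    n_alleles = length(x$names),
    kappa = x$kappa,
    dS_mean = mean(off_s, na.rm = TRUE),
    dS_max = max(off_s, na.rm = TRUE),
    dN_mean = mean(off_n, na.rm = TRUE),
    LS_mean = mean(x$LS_per_seq),
    n_saturated = nrow(x$saturated)
  )
}

#' Tidy a recombinant screen into its flag table
#'
#' @param x A `screen_result` object.
#' @param ... Unused.
#' @return The tibble of significant allele-pair/window flags, with a
#'   `removed` column marking pairs involving a removed allele.
#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) {
  dplyr::mutate(
    x$flags,
    removed = .data$allele1 %in% x$removed | .data$allele2 %in% x$removed
  )
}

#' One-row summary of a recombinant screen
#'
#' @param x A `screen_result` object.
#' @param ... Unused.
#' @return A tibble with counts of flags and removals plus the effective
#'   per-window threshold used.
#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(
    n_flagged_windows = nrow(x$flags),
    n_flagged_pairs = nrow(dplyr::distinct(x$flags, .data$allele1, .data$allele2)),
    n_removed = length(x$removed),
    n_retained = length(x$retained$seq),
    alpha = x$config$alpha,
    threshold = x$config$threshold
  )
}

#' Tidy a compatibility report into its site-pair table
#'
#' @param x A `compat_report` object.
#' @param ... Unused.
#' @return A tibble of all tested informative-site pairs with a logical
#'   `compatible` column.
#' @method tidy compat_report
#' @export
tidy.compat_report <- function(x, ...) {
  if (x$n_pairs == 0L) {
    return(tibble::tibble(site1 = integer(), site2 = integer(),
                          compatible = logical()))
  }
  prs <- utils::combn(x$informative_sites, 2L)
  bad <- paste(x$incompatible$site1, x$incompatible$site2)
  tibble::tibble(
    site1 = prs[1L, ],
    site2 = prs[2L, ],
    compatible = !(paste(prs[1L, ], prs[2L, ]) %in% bad)
  )
}

#' One-row summary of a compatibility report
#'
#' @param x A `compat_report` object.
#' @param ... Unused.
#' @return A tibble with segregating/singleton/informative site counts
#'   and the incompatible-pair count.
#' @method glance compat_report
#' @export
glance.compat_report <- function(x, ...) {
  tibble::tibble(
    n_segregating = nrow(x$sites),
    n_singleton = sum(x$sites$category == "singleton"),
    n_informative = x$n_informative,
    n_pairs = x$n_pairs,
    n_incompatible = nrow(x$incompatible)
  )
}

#' Tidy a branch change map into a per-branch table
#'
#' @param x A `branch_change_map` object.
#' @param ... Unused.
#' @return A tibble keyed by child node of each branch: `parent`,
#'   `child`, `child_label` (tip name or internal node number) and
#'   `n_changes`.
#' @method tidy branch_change_map
#' @export
tidy.branch_change_map <- function(x, ...) {
  tr <- x$tree
  ntip <- length(tr$tip.label)
  child <- tr$edge[, 2L]
  tibble::tibble(
    parent = tr$edge[, 1L],
    child = child,
    child_label = ifelse(child <= ntip, tr$tip.label[child],
                         paste0("node", child)),
    n_changes = x$edge_counts
  )
}

#' One-row summary of a full pipeline run
#'
#' @param x A `lineage_run` object.
#' @param ... Unused.
#' @return A tibble collecting the headline numbers of the run: alleles
#'   analysed, removals, distance summaries, compatibility counts and the
#'   recount TMRCA when available.
#' @method glance lineage_run
#' @export
glance.lineage_run <- function(x, ...) {
  g <- glance(x$distances)
  tibble::tibble(
    n_alleles = g$n_alleles,
    n_removed = if (is.null(x$screen)) 0L else length(x$screen$removed),
    dS_mean = g$dS_mean,
    dS_max = g$dS_max,
    LS_mean = g$LS_mean,
    n_informative = x$compat$n_informative,
    n_incompatible = nrow(x$compat$incompatible),
    ks_max = if (is.null(x$ks)) NA_real_ else x$ks$ks_max,
    tmrca_recount_years = x$tmrca_recount_years
  )
}

#' Tidy a pipeline run into its group dating table
#'
#' @param x A `lineage_run` object.
#' @param ... Unused.
#' @return The group dating tibble (see [date_groups()]); empty if no
#'   group labels were supplied.
#' @method tidy lineage_run
#' @export
tidy.lineage_run <- function(x, ...) {
  if (is.null(x$dating)) {
    return(tibble::tibble(group = character(), dS_mean = numeric(),
                          dS_max = numeric(), T_mya = numeric(),
                          TMRCA_mya = numeric()))
  }
  x$dating
}
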