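#' Divergence time from per-site synonymous divergence
#'
#' Converts a synonymous divergence `d` (substitutions per synonymous
#' site) into a time in years under the neutral molecular clock,
#' `T = d / (2 mu)`: both diverging alleles accumulate substitutions at
#' rate `mu`, so their divergence grows at `2 mu` per year. With the mean
#' within-group pairwise dS this dates the average allelic split; with the
#' maximum pairwise dS (dSmax) it estimates the group's TMRCA.
#'
#' @param d Synonymous divergence per site (>= 0); vectorised.
#' @param mu Neutral substitution rate per site per year (default `1e-9`,
#'   the commonly used value for MHC loci).
#' @return Time(s) in years.
#' @examples
#' time_from_divergence(0.057) / 1e6 # ~28.5 -> reported as 29 MYA
#' @export
time_from_divergence <- function(d, mu = 1e-9) {
  if (any(is.na(d)) || any(d < 0)) {
    stop("argument error: `d` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) {
    stop("`mu` must be a single positive rate", call. = FALSE)
  }
  d / (2 * mu)
}

#' TMRCA from a parsimony-recounted substitution number
#'
#' The tree-path recount estimator: given the maximum number of
#' synonymous substitutions `ks_max` accumulated along the tree path
#' between any two alleles (from [ks_matrix()]) and the mean number of
#' potential synonymous sites `ls_mean`, the per-site divergence is
#' `ks_max / ls_mean` and the TMRCA follows from the neutral clock as
#' `(ks_max / ls_mean) / (2 mu)`. Because path counting recovers parallel
#' and back substitutions that pairwise comparison conflates, this
#' estimator cross-checks the multiple-hit correction of the
#' distance-based TMRCA.
#'
#' @param ks_max Maximum pairwise path count of synonymous substitutions.
#' @param ls_mean Mean number of potential synonymous sites (> 0).
#' @param mu Neutral substitution rate per site per year.
#' @return TMRCA in years.
#' @examples
#' tmrca_from_ks(13, 223) / 1e6 # ~29.1 -> reported as 29 MYA
#' @export
tmrca_from_ks <- function(ks_max, ls_mean, mu = 1e-9) {
  if (any(is.na(ks_max)) || any(ks_max < 0)) {
    stop("argument error: `ks_max` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(ls_mean) || any(ls_mean <= 0)) {
    stop("argument error: `ls_mean` must be positive", call. = FALSE)
  }
  time_from_divergence(ks_max / ls_mean, mu = mu)
}

#' Round years to integer million-year values, half away from zero
#'
#' The reporting convention used for human-readable dating tables:
#' round-half-up to whole million years (so 28.5 million years prints as
#' 29 MYA and 20.5 as 21 MYA). Machine outputs always retain raw years.
#'
#' @param years Time(s) in years.
#' @return Integer million-year value(s).
#' @export
as_mya <- function(years) {
  floor(years / 1e6 + 0.5)
}

#' Date allelic groups from their synonymous divergence summaries
#'
#' Applies the neutral-clock formulas to a group summary table (from
#' [group_summary()]): the mean within-group dS dates the average allelic
#' divergence (`T`), and the maximum pairwise dS dates the group's TMRCA.
#' Output is the machine twin of a divergence-time report table: raw years
#' plus rounded MYA columns.
#'
#' @param summary A tibble with columns `group`, `dS_mean`, `dS_max` (as
#'   returned by [group_summary()]).
#' @param mu Neutral substitution rate per site per year.
#' @return The input tibble with added columns `T_years`, `TMRCA_years`,
#'   `T_mya`, `TMRCA_mya` and `mu`.
#' @export
date_groups <- function(summary, mu = 1e-9) {
  stopifnot(is.data.frame(summary),
            all(c("group", "dS_mean", "dS_max") %in% names(summary)))
  dplyr::mutate(
    tibble::as_tibble(summary),
    T_years = time_from_divergence(.data$dS_mean, mu = mu),
    TMRCA_years = time_from_divergence(.data$dS_max, mu = mu),
    T_mya = as_mya(.data$T_years),
    TMRCA_mya = as_mya(.data$TMRCA_years),
    mu = mu
  )
}
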