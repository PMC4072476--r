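#' Classify segregating alignment columns
#'
#' Examines every nucleotide column of an aligned in-frame allele set and
#' classifies the variable ones by (i) spectrum category — `singleton`
#' (exactly two states, the minor one carried by a single allele),
#' `informative` (at least two states each carried by at least two
#' alleles, i.e. parsimony-informative), or `other` — and (ii) functional
#' effect: a column is `synonymous` when every observed state leaves the
#' translated amino acid unchanged within each sequence's own codon
#' context, `nonsynonymous` when every context is altered, and `mixed`
#' otherwise (synonymous in some codon backgrounds but not others; such
#' columns are excluded from a synonymous-site tally). Gap and `N` states
#' are ignored in spectra and reported via `n_missing`.
#'
#' @param x An `allele_set`.
#' @param include_invariant If `TRUE`, invariant columns are also listed.
#' @return A tibble with one row per (by default variable) column:
#'   `site` (1-based nucleotide position), `codon`, `codon_pos`,
#'   `n_states`, `spectrum` (e.g. `"T:9/C:1"`), `n_missing`, `category`
#'   and `effect`.
#' @export
classify_sites <- function(x, include_invariant = FALSE) {
  x <- as_allele_set(x)
  m <- .seq_char_matrix(x$seq)
  cm <- .codon_string_matrix(x)
  L <- ncol(m)
  rows <- vector("list", L)
  for (col in seq_len(L)) {
    states <- m[, col]
    obs <- states[states %in% .NUC]
    tab <- sort(table(obs), decreasing = TRUE)
    n_states <- length(tab)
    if (n_states <= 1L && !include_invariant) next
    category <- if (n_states <= 1L) {
      "invariant"
    } else if (n_states == 2L && min(tab) == 1L) {
      "singleton"
    } else if (sum(tab >= 2L) >= 2L) {
      "informative"
    } else {
      "other"
    }
    effect <- NA_character_
    if (n_states >= 2L) {
      codon_i <- (col - 1L) %/% 3L + 1L
      pos_i <- (col - 1L) %% 3L + 1L
      changes <- logical(0)
      for (r in seq_len(nrow(m))) {
        ctx <- cm[r, codon_i]
        if (grepl("[^ACGT]", ctx)) next
        others <- setdiff(names(tab), substr(ctx, pos_i, pos_i))
        if (length(others) == 0L) next
        aa0 <- ml_translate_codon(ctx)
        alt_aa <- vapply(others, function(b) {
          ml_translate_codon(.mutate_codon(ctx, pos_i, b))
        }, character(1L))
        changes <- c(changes, any(alt_aa != aa0))
      }
      effect <- if (length(changes) == 0L) {
        NA_character_
      } else if (!any(changes)) {
        "synonymous"
      } else if (all(changes)) {
        "nonsynonymous"
      } else {
        "mixed"
      }
    }
    rows[[col]] <- tibble::tibble(
      site = col,
      codon = (col - 1L) %/% 3L + 1L,
      codon_pos = (col - 1L) %% 3L + 1L,
      n_states = n_states,
      spectrum = paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                       collapse = "/"),
      n_missing = sum(!states %in% .NUC),
      category = category,
      effect = effect
    )
  }
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0L) {
    out <- tibble::tibble(site = integer(), codon = integer(),
                          codon_pos = integer(), n_states = integer(),
                          spectrum = character(), n_missing = integer(),
                          category = character(), effect = character())
  }
  out
}

#' Four-gamete compatibility of two biallelic sites
#'
#' Two biallelic sites are compatible with a single tree-like mutation
#' history (one mutation per site, no recombination) if and only if at
#' most three of the four possible two-site state combinations (gametes)
#' occur among the sequences. Observing all four gametes requires either
#' recurrent mutation or recombination/gene conversion between the sites.
#'
#' Sequences carrying a gap or `N` at either site are dropped pairwise.
#' Sites with more than two states are reduced to their two major states
#' (ties broken alphabetically) and the reduction is signalled via the
#' `"reduced"` attribute of the result.
#'
#' @param site1,site2 Character vectors of per-sequence states at the two
#'   columns (same order and length).
#' @return `TRUE` if compatible, `FALSE` if all four gametes occur; the
#'   attribute `"reduced"` records whether a multi-allelic site was
#'   reduced.
#' @examples
#' four_gamete_compatible(c("A","A","G","G"), c("A","G","A","G")) # FALSE
#' @export
four_gamete_compatible <- function(site1, site2) {
  if (length(site1) != length(site2)) {
    stop("sites must have the same number of sequences", call. = FALSE)
  }
  keep <- site1 %in% .NUC & site2 %in% .NUC
  s1 <- site1[keep]; s2 <- site2[keep]
  reduced <- FALSE
  major_two <- function(s) {
    tab <- table(s)
    names(tab)[order(-as.integer(tab), names(tab))][1:2]
  }
  if (length(unique(s1)) > 2L) {
    keep2 <- s1 %in% major_two(s1)
    reduced <- TRUE
    s2 <- s2[keep2]; s1 <- s1[keep2]
  }
  if (length(unique(s2)) > 2L) {
    keep2 <- s2 %in% major_two(s2)
    reduced <- TRUE
    s1 <- s1[keep2]; s2 <- s2[keep2]
  }
  gametes <- unique(paste0(s1, s2))
  structure(length(gametes) < 4L, reduced = reduced)
}

#' Pairwise compatibility report over informative sites
#'
#' Classifies all segregating columns (see [classify_sites()]), selects
#' the parsimony-informative biallelic ones — restricted to synonymous
#' columns when `synonymous_only = TRUE`, the relevant set when asking
#' whether synonymous variation fits a single tree — and applies the
#' four-gamete test to every unordered pair. Incompatible pairs point to
#' recombination/gene conversion or recurrent (parallel/back) mutation.
#'
#' @param x An `allele_set`.
#' @param synonymous_only Restrict to columns classified `synonymous`.
#' @return An object of class `compat_report`: list with the full `sites`
#'   classification tibble, `informative_sites` (columns entering the
#'   test), `n_informative`, `n_pairs`, `incompatible` (tibble of
#'   incompatible site pairs), and `excluded_multiallelic` (informative
#'   columns with > 2 states, reported but not tested).
#' @export
compatibility_report <- function(x, synonymous_only = TRUE) {
  x <- as_allele_set(x)
  sites <- classify_sites(x)
  inf <- dplyr::filter(sites, .data$category == "informative")
  if (synonymous_only) {
    inf <- dplyr::filter(inf, !is.na(.data$effect),
                         .data$effect == "synonymous")
  }
  multi <- dplyr::filter(inf, .data$n_states > 2L)
  inf <- dplyr::filter(inf, .data$n_states == 2L)
  cols <- inf$site
  empty_pairs <- tibble::tibble(site1 = integer(), site2 = integer())
  if (length(cols) < 2L) {
    warning("fewer than 2 informative sites; empty compatibility report",
            call. = FALSE)
    return(structure(
      list(sites = sites, informative_sites = cols,
           n_informative = length(cols), n_pairs = 0L,
           incompatible = empty_pairs, excluded_multiallelic = multi$site),
      class = "compat_report"
    ))
  }
  m <- .seq_char_matrix(x$seq)
  prs <- utils::combn(cols, 2L)
  incompat <- list()
  for (k in seq_len(ncol(prs))) {
    a <- prs[1L, k]; b <- prs[2L, k]
    if (!four_gamete_compatible(m[, a], m[, b])) {
      incompat[[length(incompat) + 1L]] <- tibble::tibble(site1 = a, site2 = b)
    }
  }
  structure(
    list(
      sites = sites,
      informative_sites = cols,
      n_informative = length(cols),
      n_pairs = ncol(prs),
      incompatible = if (length(incompat)) dplyr::bind_rows(incompat) else empty_pairs,
      excluded_multiallelic = multi$site
    ),
    class = "compat_report"
  )
}

#' @export
print.compat_report <- function(x, ...) {
  cat(sprintf(
    "<compat_report> %d informative biallelic sites, %d pairs, %d incompatible\n",
    x$n_informative, x$n_pairs, nrow(x$incompatible)))
  if (length(x$excluded_multiallelic)) {
    cat("  multi-allelic informative sites excluded from test:",
        paste(x$excluded_multiallelic, collapse = ", "), "\n")
  }
  invisible(x)
}
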