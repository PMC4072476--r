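#' Potential synonymous and nonsynonymous sites of a codon
#'
#' Counts the fractional numbers of synonymous (S) and nonsynonymous (N)
#' sites of a sense codon under the modified Nei-Gojobori scheme: at each
#' of the three codon positions the three possible single-nucleotide
#' changes are weighted by the transition/transversion bias `kappa`
#' (transitions weighted `kappa`, transversions 1) and the synonymous site
#' fraction of the position is the weighted share of changes that preserve
#' the encoded amino acid. `kappa = 1` recovers the classic unweighted
#' Nei-Gojobori (1986) counts. Changes that would create a stop codon are
#' counted as nonsynonymous. S + N = 3 for every sense codon.
#'
#' @param codon A single sense codon (3-letter string over A/C/G/T).
#' @param kappa Transition/transversion rate-ratio weight (> 0).
#' @return Named numeric vector `c(S = , N = )`.
#' @examples
#' count_sites("TTT", kappa = 1) # S = 1/3
#' count_sites("TTT", kappa = 2) # S = 1/2
#' @export
count_sites <- function(codon, kappa = 1) {
  codon <- .check_codon(codon)
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    stop("`kappa` must be a single positive number", call. = FALSE)
  }
  aa0 <- ml_translate_codon(codon)
  S <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    alts <- setdiff(.NUC, ref)
    w <- ifelse(ml_is_transition(ref, alts), kappa, 1)
    aa1 <- vapply(alts, function(b) ml_translate_codon(.mutate_codon(codon, pos, b)),
                  character(1L))
    syn <- aa1 == aa0 # stop targets translate to "*" and fall out as nonsynonymous
    S <- S + sum(w[syn]) / sum(w)
  }
  c(S = S, N = 3 - S)
}

# per-codon S values for all 64 codons at a given kappa (NA for stops),
# memoised per kappa
.codon_S_vector <- function(kappa) {
  key <- paste0("S_", format(kappa, digits = 15))
  if (is.null(.ml_cache[[key]])) {
    tab <- ml_codon_table()
    S <- rep(NA_real_, 64L)
    for (i in seq_len(64L)) {
      if (!tab$is_stop[i]) S[i] <- count_sites(tab$codons[i], kappa)[["S"]]
    }
    .ml_cache[[key]] <- setNames(S, tab$codons)
  }
  .ml_cache[[key]]
}

#' Synonymous and nonsynonymous differences between two codons
#'
#' Classifies the nucleotide differences between two sense codons into
#' synonymous (`sd`) and nonsynonymous (`nd`) counts. Codons differing at
#' one position are classified directly; for two or three differences all
#' orderings (mutational pathways) of the single changes are enumerated and
#' the classification is averaged over pathways, excluding pathways that
#' pass through a stop codon. If every pathway is blocked by stops, the
#' differing positions are classified independently in the first codon's
#' context as a fallback. Always `sd + nd` equals the nucleotide Hamming
#' distance between the codons.
#'
#' @param c1,c2 Sense codons (3-letter strings over A/C/G/T).
#' @return Named numeric vector `c(sd = , nd = )`.
#' @examples
#' count_pair_differences("TTT", "GTA") # c(sd = 0.5, nd = 1.5)
#' @export
count_pair_differences <- function(c1, c2) {
  c1 <- .check_codon(c1, "c1")
  c2 <- .check_codon(c2, "c2")
  d <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  k <- length(d)
  if (k == 0L) return(c(sd = 0, nd = 0))

  orderings <- switch(as.character(k),
    "1" = list(d),
    "2" = list(d, rev(d)),
    "3" = {
      p <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(seq_len(6L), function(i) d[p[i, ]])
    }
  )
  targets <- strsplit(c2, "")[[1L]]

  walk_path <- function(ord) {
    cur <- c1
    sd <- nd <- 0
    for (pos in ord) {
      nxt <- .mutate_codon(cur, pos, targets[pos])
      if (ml_is_stop(nxt)) return(NULL) # pathway through a stop: excluded
      if (ml_translate_codon(nxt) == ml_translate_codon(cur)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }

  paths <- purrr::compact(lapply(orderings, walk_path))
  if (length(paths) == 0L) {
    # all pathways blocked: classify each differing position independently
    # in the context of the first codon
    sd <- nd <- 0
    for (pos in d) {
      nxt <- .mutate_codon(c1, pos, targets[pos])
      if (!ml_is_stop(nxt) && ml_translate_codon(nxt) == ml_translate_codon(c1)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
    }
    return(c(sd = sd, nd = nd))
  }
  avg <- Reduce(`+`, paths) / length(paths)
  c(sd = avg[[1L]], nd = avg[[2L]])
}

# memoised 64x64 lookup tables of sd and nd for all sense-codon pairs
.codon_pair_tables <- function() {
  if (is.null(.ml_cache$SD)) {
    tab <- ml_codon_table()
    SD <- ND <- matrix(NA_real_, 64L, 64L,
                       dimnames = list(tab$codons, tab$codons))
    sense <- which(!tab$is_stop)
    for (i in sense) {
      for (j in sense) {
        if (j < i) {
          SD[i, j] <- SD[j, i]
          ND[i, j] <- ND[j, i]
        } else {
          v <- count_pair_differences(tab$codons[i], tab$codons[j])
          SD[i, j] <- v[["sd"]]
          ND[i, j] <- v[["nd"]]
        }
      }
    }
    .ml_cache$SD <- SD
    .ml_cache$ND <- ND
  }
  list(SD = .ml_cache$SD, ND = .ml_cache$ND)
}

#' Jukes-Cantor multiple-hit correction
#'
#' Converts an observed proportion of differences per site into an
#' estimated number of substitutions per site, `-(3/4) log(1 - 4p/3)`.
#' Proportions at or beyond the saturation bound 3/4 raise an error rather
#' than being clipped.
#'
#' @param p Proportion(s) of observed differences, `0 <= p < 3/4`.
#' @return Corrected distance(s), same length as `p`.
#' @examples
#' jc_correct(0.05)
#' @export
jc_correct <- function(p) {
  if (any(is.na(p)) || any(p < 0)) {
    stop("`p` must be non-negative", call. = FALSE)
  }
  if (any(p >= 0.75)) {
    stop("saturation error: proportion of differences >= 3/4 cannot be ",
         "Jukes-Cantor corrected", call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Moment estimator of the transition/transversion bias
#'
#' A rough kappa estimate from third codon positions: over all sequence
#' pairs, counts transition and transversion differences at third
#' positions and returns `2 * ts / tv` (the factor 2 accounts for each
#' site offering one transition but two transversion targets). Intended as
#' a convenience default; a maximum-likelihood estimate from a substitution
#' model fit is preferable when available and can be passed directly as
#' `kappa` wherever accepted.
#'
#' @param x An `allele_set`.
#' @return A single numeric kappa estimate (>= 0; `NA` if no third-position
#'   differences are observed).
#' @export
estimate_kappa <- function(x) {
  x <- as_allele_set(x)
  m <- .seq_char_matrix(x$seq)
  third <- m[, seq(3L, ncol(m), by = 3L), drop = FALSE]
  n <- nrow(third)
  ts <- tv <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- third[i, ]; b <- third[j, ]
      ok <- a %in% .NUC & b %in% .NUC & a != b
      if (!any(ok)) next
      is_ts <- .TS_PARTNER[a[ok]] == b[ok]
      ts <- ts + sum(is_ts)
      tv <- tv + sum(!is_ts)
    }
  }
  if (ts + tv == 0L) return(NA_real_)
  if (tv == 0L) return(Inf)
  2 * ts / tv
}

#' Pairwise synonymous and nonsynonymous distance matrices
#'
#' Computes modified Nei-Gojobori pairwise distances for an aligned allele
#' set: per pair, synonymous and nonsynonymous differences are summed over
#' codons (pathway-averaged, see [count_pair_differences()]), potential
#' site totals are averaged between the two sequences, and the resulting
#' proportions `pS`, `pN` are Jukes-Cantor corrected into `dS` and `dN`.
#' Codons containing gaps, `N`, or a stop in either sequence of a pair are
#' deleted pairwise. Pairs whose `pS` or `pN` reaches the Jukes-Cantor
#' saturation bound get `NA` in the corrected matrix and are listed in the
#' `saturated` element.
#'
#' @param x An `allele_set` (typically with the PBR excluded via
#'   [apply_region_mask()] when the goal is neutral-clock dating).
#' @param kappa Transition/transversion bias used in site counting
#'   (default 1 = classic Nei-Gojobori; see [estimate_kappa()]).
#' @return An object of class `pairwise_distances`: list with `names`,
#'   matrices `dS`, `dN`, `pS`, `pN`, per-sequence potential synonymous
#'   site counts `LS_per_seq`, `kappa`, and a tibble `saturated`.
#' @examples
#' a <- allele_set(c(
#'   x = "AAAAAAAAAAAAAAAAAAAAAAAATTT",
#'   y = "AAAAAAAAAAAAAAAAAAAAAAAATTC"
#' ))
#' dnds_distances(a)$dS
#' @export
dnds_distances <- function(x, kappa = 1) {
  x <- as_allele_set(x)
  n <- length(x$seq)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  cm <- .codon_string_matrix(x)
  tab <- ml_codon_table()
  idx <- matrix(match(cm, tab$codons), nrow = n) # NA for gap/N codons
  idx[idx %in% which(tab$is_stop)] <- NA_integer_
  valid <- !is.na(idx)

  Sv <- .codon_S_vector(kappa)
  pt <- .codon_pair_tables()

  dS <- dN <- pS <- pN <- matrix(0, n, n, dimnames = list(names(x$seq), names(x$seq)))
  sat <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      use <- valid[i, ] & valid[j, ]
      if (!any(use)) {
        dS[i, j] <- dS[j, i] <- NA_real_
        dN[i, j] <- dN[j, i] <- NA_real_
        next
      }
      ii <- idx[i, use]; jj <- idx[j, use]
      sd_sum <- sum(pt$SD[cbind(ii, jj)])
      nd_sum <- sum(pt$ND[cbind(ii, jj)])
      Sbar <- (sum(Sv[ii]) + sum(Sv[jj])) / 2
      Nbar <- 3 * sum(use) - Sbar
      ps <- sd_sum / Sbar
      pn <- nd_sum / Nbar
      pS[i, j] <- pS[j, i] <- ps
      pN[i, j] <- pN[j, i] <- pn
      if (ps >= 0.75 || pn >= 0.75) {
        dS[i, j] <- dS[j, i] <- if (ps >= 0.75) NA_real_ else jc_correct(ps)
        dN[i, j] <- dN[j, i] <- if (pn >= 0.75) NA_real_ else jc_correct(pn)
        sat[[length(sat) + 1L]] <- tibble::tibble(
          name1 = names(x$seq)[i], name2 = names(x$seq)[j],
          pS = ps, pN = pn
        )
      } else {
        dS[i, j] <- dS[j, i] <- jc_correct(ps)
        dN[i, j] <- dN[j, i] <- jc_correct(pn)
      }
    }
  }
  LS <- vapply(seq_len(n), function(i) sum(Sv[idx[i, valid[i, ]]]), numeric(1L))
  structure(
    list(
      names = names(x$seq),
      dS = dS, dN = dN, pS = pS, pN = pN,
      LS_per_seq = setNames(LS, names(x$seq)),
      kappa = kappa,
      groups = x$groups,
      saturated = if (length(sat)) dplyr::bind_rows(sat) else
        tibble::tibble(name1 = character(), name2 = character(),
                       pS = numeric(), pN = numeric())
    ),
    class = "pairwise_distances"
  )
}

#' @export
print.pairwise_distances <- function(x, ...) {
  n <- length(x$names)
  off <- x$dS[upper.tri(x$dS)]
  cat(sprintf("<pairwise_distances> %d alleles, kappa = %.3g\n", n, x$kappa))
  cat(sprintf("  dS: mean %.4g, max %.4g; mean LS %.4g\n",
              mean(off, na.rm = TRUE), max(off, na.rm = TRUE),
              mean(x$LS_per_seq)))
  if (nrow(x$saturated)) {
    cat("  saturated pairs:", nrow(x$saturated), "\n")
  }
  invisible(x)
}

#' Within-group summaries of synonymous divergence
#'
#' Averages and maxima of pairwise `dS` (and `dN`) over all unordered
#' within-group allele pairs, plus the mean per-sequence number of
#' potential synonymous sites (LS) — the quantities feeding the
#' divergence-time formulas. Groups with fewer than two members are
#' skipped with a warning.
#'
#' @param d A `pairwise_distances` object.
#' @param groups Named character vector mapping allele names to group
#'   tags, or a data frame with columns `name` and `group`. Defaults to
#'   the group labels stored in the allele set the distances were computed
#'   from.
#' @return A tibble with columns `group`, `n_alleles`, `n_pairs`,
#'   `dS_mean`, `dS_max`, `dN_mean`, `LS_mean`.
#' @export
group_summary <- function(d, groups = NULL) {
  stopifnot(inherits(d, "pairwise_distances"))
  if (is.null(groups)) groups <- d$groups
  if (is.null(groups)) {
    stop("no group labels available; supply `groups`", call. = FALSE)
  }
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$name)
  }
  groups <- groups[intersect(names(groups), d$names)]
  out <- list()
  for (g in unique(groups)) {
    members <- names(groups)[groups == g]
    if (length(members) < 2L) {
      warning("group '", g, "' has fewer than 2 members; skipped",
              call. = FALSE)
      next
    }
    sub_s <- d$dS[members, members]
    sub_n <- d$dN[members, members]
    vs <- sub_s[upper.tri(sub_s)]
    vn <- sub_n[upper.tri(sub_n)]
    out[[g]] <- tibble::tibble(
      group = g,
      n_alleles = length(members),
      n_pairs = length(vs),
      dS_mean = mean(vs, na.rm = TRUE),
      dS_max = max(vs, na.rm = TRUE),
      dN_mean = mean(vn, na.rm = TRUE),
      LS_mean = mean(d$LS_per_seq[members])
    )
  }
  if (length(out) == 0L) {
    stop("no group with >= 2 members", call. = FALSE)
  }
  dplyr::bind_rows(out)
}
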