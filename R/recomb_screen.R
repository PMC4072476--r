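#' Upper-tail binomial probability of regional substitution clustering
#'
#' The elementary statistic of the recombinant screen: if `n` nucleotide
#' differences between two alleles were scattered uniformly over an
#' alignment of `L` sites, the number falling inside a particular region
#' of `l` sites would be binomial with success probability `p = l/L`. The
#' function returns the exact upper-tail probability of observing `m` or
#' more differences in the region,
#' `P = sum_{i=m}^{n} C(n,i) p^i (1-p)^{n-i}`, by direct summation (no
#' normal approximation). A small tail marks a region carrying unexpectedly
#' many of the pair's differences — the signature of a spliced (recombinant
#' or gene-converted) segment.
#'
#' @param m Differences observed inside the region (`0 <= m <= n`).
#' @param n Total differences between the pair.
#' @param l Region length in sites (`0 < l < L`).
#' @param L Total alignment length in sites.
#' @return The tail probability (1 when `m = 0`).
#' @examples
#' binomial_region_tail(5, 10, 10, 100)
#' @export
binomial_region_tail <- function(m, n, l, L) {
  if (any(c(m, n, l, L) < 0) || m > n) {
    stop("argument error: need 0 <= m <= n", call. = FALSE)
  }
  if (l <= 0 || l >= L) {
    stop("argument error: need 0 < l < L", call. = FALSE)
  }
  if (m == 0) return(1)
  p <- l / L
  i <- m:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

#' Screen an allele set for putative recombinants
#'
#' Slides windows along the codon alignment and, for every unordered
#' allele pair, tests whether a window holds more of the pair's
#' nucleotide differences than uniform scatter would allow, using the
#' exact binomial tail of [binomial_region_tail()]. Because a spliced
#' segment can occupy anything from a short conversion tract to half the
#' gene, windows are scanned at geometrically growing sizes (`window`,
#' `2*window`, `4*window`, ... while smaller than the alignment), each
#' size sliding with a proportionally scaled step. Window tails are
#' compared against a Sidak-corrected threshold. Overlapping windows are
#' not independent tests, so the correction counts, at each size, windows
#' at half-overlap spacing (`2C/size` for an alignment of `C` codons,
#' capped at the actual window count) and sums over sizes; windows
#' sharing more than half their span carry largely redundant information,
#' and null simulations show this choice holds the per-pair
#' false-positive rate close to `alpha`. A pair is flagged when
#' any window is significant; an allele is *removed* when it is flagged
#' against at least two distinct partners, the expected signature of a
#' recombinant clustering differences against both parental lineages —
#' this avoids discarding both members of every flagged pair.
#'
#' Differences are counted at the nucleotide level on pairwise-deleted
#' columns (positions where either sequence has `-` or `N` are ignored,
#' and window/alignment lengths count only used positions).
#'
#' @param x An `allele_set`.
#' @param window Base (smallest) window size in codons.
#' @param step Step between window starts at the base size, in codons;
#'   scaled proportionally for the larger sizes.
#' @param alpha Per-pair significance level.
#' @param correction `"sidak"` (default) or `"none"` (each window tested
#'   at `alpha`).
#' @return An object of class `screen_result`: list with `flags` (tibble
#'   of significant allele-pair/window combinations with tail
#'   probabilities), `removed` (character vector of allele names),
#'   `retained` (the filtered `allele_set`) and `config`.
#' @export
screen_recombinants <- function(x, window = 30L, step = 5L, alpha = 0.01,
                                correction = c("sidak", "none")) {
  x <- as_allele_set(x)
  correction <- match.arg(correction)
  window <- as.integer(window); step <- as.integer(step)
  C <- x$n_codons
  if (is.na(window) || window <= 0L || window >= C) {
    stop("config error: `window` must satisfy 0 < window < ", C,
         " codons", call. = FALSE)
  }
  if (is.na(step) || step <= 0L) {
    stop("config error: `step` must be positive", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("config error: `alpha` must be in (0, 1)", call. = FALSE)
  }
  n <- length(x$seq)
  if (n < 2L) stop("need at least 2 sequences to screen", call. = FALSE)

  m <- .seq_char_matrix(x$seq)
  usable <- m == "A" | m == "C" | m == "G" | m == "T"
  # geometrically growing window sizes, each slid at a scaled step
  sizes <- window
  while (2L * sizes[length(sizes)] < C) {
    sizes <- c(sizes, 2L * sizes[length(sizes)])
  }
  windows <- dplyr::bind_rows(lapply(seq_along(sizes), function(s) {
    w <- sizes[[s]]
    st <- max(1L, step * 2L^(s - 1L))
    # always include the final placement so the scan reaches the 3' end
    starts <- unique(c(seq(1L, C - w + 1L, by = st), C - w + 1L))
    tibble::tibble(start = starts, end = starts + w - 1L, size = w)
  }))
  win_nt_start <- 3L * (windows$start - 1L) + 1L
  win_nt_end <- 3L * windows$end
  # effective number of tests for the Sidak correction: per size, windows
  # at half-overlap spacing, never more than the actual window count
  n_eff <- sum(vapply(sizes, function(w) {
    min(sum(windows$size == w), max(1, round(2 * C / w)))
  }, numeric(1L)))
  thr <- if (correction == "sidak") 1 - (1 - alpha)^(1 / n_eff) else alpha

  nt_pos <- seq_len(ncol(m))
  flags <- list()
  pair_flagged <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      use <- usable[i, ] & usable[j, ]
      diffs <- use & (m[i, ] != m[j, ])
      ntot <- sum(diffs)
      Ltot <- sum(use)
      if (ntot == 0L || Ltot == 0L) next
      for (w in seq_len(nrow(windows))) {
        inwin <- nt_pos >= win_nt_start[w] & nt_pos <= win_nt_end[w]
        l_eff <- sum(use & inwin)
        if (l_eff == 0L || l_eff >= Ltot) next
        m_obs <- sum(diffs & inwin)
        if (m_obs == 0L) next
        pv <- binomial_region_tail(m_obs, ntot, l_eff, Ltot)
        if (pv <= thr) {
          pair_flagged[i, j] <- pair_flagged[j, i] <- TRUE
          flags[[length(flags) + 1L]] <- tibble::tibble(
            allele1 = names(x$seq)[i],
            allele2 = names(x$seq)[j],
            window_start = windows$start[w],
            window_end = windows$end[w],
            m = m_obs, n = ntot, l = l_eff, L = Ltot,
            p_tail = pv
          )
        }
      }
    }
  }
  flags <- if (length(flags)) dplyr::bind_rows(flags) else
    tibble::tibble(allele1 = character(), allele2 = character(),
                   window_start = integer(), window_end = integer(),
                   m = integer(), n = integer(), l = integer(),
                   L = integer(), p_tail = numeric())
  n_partners <- rowSums(pair_flagged)
  removed <- names(x$seq)[n_partners >= 2L]
  retained <- if (length(removed) < n) {
    subset_alleles(x, setdiff(names(x$seq), removed))
  } else {
    stop("screening removed every allele; relax `alpha` or inspect input",
         call. = FALSE)
  }
  structure(
    list(
      flags = flags,
      removed = removed,
      retained = retained,
      config = list(window = window, step = step, alpha = alpha,
                    correction = correction, threshold = thr,
                    n_effective_windows = n_eff)
    ),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "<screen_result> %d flagged pair-window(s), %d allele(s) removed, %d retained\n",
    nrow(x$flags), length(x$removed), length(x$retained$seq)))
  if (length(x$removed)) {
    cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  }
  invisible(x)
}
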