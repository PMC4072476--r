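#' Probability of k ancestral lineages for n sampled lineages
#'
#' Computes the coalescent ancestral-process probability g_nk(t): the
#' probability that `n` lineages sampled today descend from exactly `k`
#' ancestral lineages at scaled time `t` in the past. In a neutral
#' coalescent `t` is measured in units of N (haploid) generations; for
#' allelic genealogies shaped by balancing selection the appropriate unit
#' involves an unknown allelic effective size and selection intensity, so
#' a single `scale` factor converts user time units into coalescent units
#' (`t_coal = t / scale`) rather than asserting any effective size.
#'
#' The computation uses the classical alternating series
#' \deqn{g_{nk}(t) = \sum_{j=k}^{n} e^{-j(j-1)t/2} \frac{(2j-1)(-1)^{j-k}
#'   k_{(j-1)} n_{[j]}}{k!\,(j-k)!\,n_{(j)}}}
#' with rising (`a_(b)`) and falling (`a_[b]`) factorials evaluated
#' through log-gamma, summed with Kahan compensation. The alternating
#' terms grow combinatorially with `n`, so `n` is capped at 64; beyond
#' that an error is raised rather than returning an unstable value.
#'
#' @param n Number of sampled lineages (`1 <= n <= 64`).
#' @param k Number of ancestral lineages (`1 <= k <= n`).
#' @param t Time before present in user units (>= 0).
#' @param scale Conversion factor from user time units to coalescent
#'   units (default 1: `t` is already in coalescent units).
#' @return The probability g_nk(t).
#' @examples
#' lineage_probability(2, 1, 1) # 1 - exp(-1)
#' @export
lineage_probability <- function(n, k, t, scale = 1) {
  .check_lineage_args(n, k, t, scale)
  t <- t / scale
  if (t == 0) return(as.numeric(k == n))
  j <- k:n
  log_a <- lgamma(k + j - 1) - lgamma(k) - lgamma(k + 1) - lgamma(j - k + 1)
  log_b <- lgamma(n + 1) - lgamma(n - j + 1) + lgamma(n) - lgamma(n + j)
  log_mag <- -j * (j - 1) * t / 2 + log(2 * j - 1) + log_a + log_b
  if (max(log_mag) > log(1e3)) {
    # the alternating terms are so large that cancellation would swamp
    # the result; evaluate the pure-death process by uniformization
    # instead (all-nonnegative arithmetic, stable at any t)
    return(.gnk_uniformization(n, t)[k])
  }
  terms <- ifelse((j - k) %% 2 == 0, 1, -1) * exp(log_mag)
  s <- .kahan_sum(terms)
  # clamp tiny numerical undershoot/overshoot
  min(1, max(0, s))
}

# distribution of the ancestral-lineage count by uniformization of the
# coalescent death chain (k -> k-1 at rate k(k-1)/2): Poisson mixture of
# powers of the uniformized transition operator, every term nonnegative
.gnk_uniformization <- function(n, t) {
  rates <- (1:n) * (0:(n - 1)) / 2
  lam <- rates[n]
  mu <- lam * t
  v <- c(rep(0, n - 1), 1)
  res <- numeric(n)
  m_max <- ceiling(mu + 12 * sqrt(mu) + 30)
  logw <- -mu
  for (m in 0:m_max) {
    if (logw > -745) res <- res + exp(logw) * v
    out <- v * rates / lam
    v <- v - out + c(out[-1], 0)
    logw <- logw + log(mu) - log(m + 1)
  }
  res
}

#' Distribution of the number of ancestral lineages
#'
#' Full distribution of g_nk(t) over `k = 1..n`, with the upper-tail
#' probabilities `P(K >= k)` so that persistence questions — e.g. "how
#' probable is it that at least 7 of the ancestral lineages of a sample of
#' 31 alleles were already distinct t ago?" — read off a single row.
#'
#' @inheritParams lineage_probability
#' @return A tibble of class `lineage_distribution` with columns `n`,
#'   `t`, `k`, `probability` and `p_at_least` (= P(K >= k)).
#' @examples
#' lineage_distribution(10, 0.5)
#' @export
lineage_distribution <- function(n, t, scale = 1) {
  .check_lineage_args(n, 1L, t, scale)
  p <- vapply(seq_len(n), function(k) lineage_probability(n, k, t, scale),
              numeric(1L))
  out <- tibble::tibble(
    n = as.integer(n),
    t = t / scale,
    k = seq_len(n),
    probability = p,
    p_at_least = rev(cumsum(rev(p)))
  )
  class(out) <- c("lineage_distribution", class(out))
  out
}

.check_lineage_args <- function(n, k, t, scale) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("argument error: `n` must be a positive integer", call. = FALSE)
  }
  if (n > 64) {
    stop("argument error: `n` > 64 is outside the numerically stable range ",
         "of the alternating-series evaluation", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n || k != round(k)) {
    stop("argument error: need 1 <= k <= n", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("argument error: `t` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("argument error: `scale` must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

# compensated (Kahan) summation of an alternating series
.kahan_sum <- function(x) {
  s <- 0; c <- 0
  for (v in x) {
    y <- v - c
    tt <- s + y
    c <- (tt - s) - y
    s <- tt
  }
  s
}
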