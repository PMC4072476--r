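# Independent oracles used to freeze expected values. These deliberately
# use different algorithms (plain recursion / exhaustive enumeration /
# Monte-Carlo) from the implementation they check.

NUCS <- c("A", "C", "G", "T")

oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

oracle_is_stop <- function(codon) oracle_translate(codon) == "*"

# ---- codon pathway oracle -------------------------------------------------
# enumerate every ordering of single-base changes from c1 to c2 by
# recursion, skip orderings passing through a stop, average (sd, nd)
oracle_pair_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diffpos <- which(a != b)
  if (length(diffpos) == 0) return(c(sd = 0, nd = 0))
  paths <- list()
  recurse <- function(cur, remaining, sd, nd) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- c(sd, nd)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- b[p]
      if (oracle_is_stop(nxt)) next
      syn <- oracle_translate(nxt) == oracle_translate(cur)
      recurse(nxt, setdiff(remaining, p), sd + syn, nd + !syn)
    }
  }
  recurse(c1, diffpos, 0, 0)
  if (length(paths) == 0) {
    # all orderings blocked: independent per-position classification in
    # the context of c1
    sd <- nd <- 0
    for (p in diffpos) {
      nxt <- c1
      substr(nxt, p, p) <- b[p]
      if (!oracle_is_stop(nxt) && oracle_translate(nxt) == oracle_translate(c1)) {
        sd <- sd + 1
      } else nd <- nd + 1
    }
    return(c(sd = sd, nd = nd))
  }
  avg <- Reduce(`+`, paths) / length(paths)
  c(sd = avg[1], nd = avg[2])
}

# ---- classic NG86 site counts (kappa = 1), straight fraction count --------
oracle_ng86_S <- function(codon) {
  aa0 <- oracle_translate(codon)
  S <- 0
  for (pos in 1:3) {
    nsyn <- 0
    for (b in setdiff(NUCS, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_translate(mut) == aa0) nsyn <- nsyn + 1
    }
    S <- S + nsyn / 3
  }
  S
}

# ---- exhaustive Fitch minimum --------------------------------------------
# minimum number of edge changes over all internal-node labelings of a
# rooted binary tree with fixed tip states
oracle_parsimony_min <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  grids <- do.call(expand.grid,
                   c(rep(list(NUCS), nnode), stringsAsFactors = FALSE))
  best <- Inf
  st <- character(ntip + nnode)
  st[seq_len(ntip)] <- tip_states[tree$tip.label]
  for (r in seq_len(nrow(grids))) {
    st[ntip + seq_len(nnode)] <- unlist(grids[r, ], use.names = FALSE)
    ch <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    if (ch < best) best <- ch
  }
  best
}

# ---- Monte-Carlo coalescent lineage counts --------------------------------
# distribution of the number of ancestral lineages at time t by direct
# simulation of exponential coalescence waiting times
oracle_lineage_mc <- function(n, t, nrep) {
  rates <- sapply(n:2, function(j) j * (j - 1) / 2)
  waits <- matrix(rexp(nrep * (n - 1), rate = rep(rates, each = nrep)),
                  nrow = nrep)
  cum <- t(apply(waits, 1, cumsum))
  k <- n - rowSums(cum <= t)
  tabulate(k, nbins = n) / nrep
}

# ---- random sequence-pair generators --------------------------------------
random_coding_pair_null <- function(len_codons, ndiff) {
  L <- 3 * len_codons
  s1 <- sample(NUCS, L, replace = TRUE)
  s2 <- s1
  pos <- sample.int(L, ndiff)
  s2[pos] <- vapply(s1[pos], function(b) sample(setdiff(NUCS, b), 1), "")
  allele_set(c(p1 = paste(s1, collapse = ""), p2 = paste(s2, collapse = "")))
}

all_sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}
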