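#' Place substitutions on a tree by Fitch parsimony
#'
#' Maps the variable columns of an aligned allele set onto a phylogeny by
#' Fitch parsimony: for each site a bottom-up pass computes the minimum
#' number of state changes, and a deterministic top-down pass assigns each
#' change to a branch (a child keeps its parent's state whenever that
#' state lies in the child's first-pass state set; otherwise the
#' alphabetically first member of the set is chosen and a change is
#' charged to the branch). Branch-level attribution can differ among
#' equally parsimonious reconstructions, but per-site change totals — and
#' therefore tree-path substitution counts on homoplasy-aware data — are
#' invariant, which is what the pairwise recount ([ks_matrix()]) uses.
#'
#' By default only columns whose segregating states are synonymous in
#' every codon context ([classify_sites()]) are mapped, matching the use
#' of the map to re-count synonymous substitutions between alleles.
#'
#' @param tree A `phylo` tree whose tip labels are allele names of `x`.
#'   Unrooted trees are rooted on `outgroup` when given, otherwise on the
#'   first tip; multifurcations are resolved arbitrarily
#'   (per-site minimum counts are unaffected by root placement).
#' @param x An `allele_set` containing (at least) all tree tips.
#' @param sites Integer vector of 1-based alignment columns to map;
#'   default: all variable columns, restricted by `synonymous_only`.
#' @param synonymous_only Restrict the default site set to synonymous
#'   columns.
#' @param outgroup Optional tip name used to root an unrooted input tree.
#' @return An object of class `branch_change_map`: list with the rooted
#'   binary `tree` actually used, `edge_counts` (numeric vector parallel
#'   to `tree$edge` rows), `per_site` (tibble `site`, `n_changes`),
#'   `sites`, and the internal tip-incidence matrix used for path sums.
#' @export
fitch_map <- function(tree, x, sites = NULL, synonymous_only = TRUE,
                      outgroup = NULL) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object", call. = FALSE)
  x <- as_allele_set(x)
  missing_tips <- setdiff(tree$tip.label, names(x$seq))
  if (length(missing_tips)) {
    stop("tree tips missing from allele set: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) {
      stop("outgroup '", outgroup, "' is not a tree tip", call. = FALSE)
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[[1L]],
                      resolve.root = TRUE)
  }
  tree <- ape::multi2di(tree)
  xs <- subset_alleles(x, tree$tip.label)

  if (is.null(sites)) {
    cls <- classify_sites(xs)
    if (synonymous_only) {
      cls <- dplyr::filter(cls, !is.na(.data$effect),
                           .data$effect == "synonymous")
    }
    sites <- cls$site
  }
  sites <- sort(unique(as.integer(sites)))
  if (any(sites < 1L | sites > xs$alignment_length)) {
    stop("sites outside alignment", call. = FALSE)
  }

  m <- .seq_char_matrix(xs$seq)[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  edge_key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  eo_to_edge <- match(paste(eo[, 1L], eo[, 2L]), edge_key)

  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  # lowest set bit -> nucleotide, in alphabetical preference order A,C,G,T
  first_state <- function(s) {
    for (b in c(1L, 2L, 4L, 8L)) if (bitwAnd(s, b)) return(b)
    stop("empty state set") # unreachable
  }

  nedges <- nrow(tree$edge)
  edge_counts <- numeric(nedges)
  per_site <- integer(length(sites))
  root <- ntip + 1L

  for (si in seq_along(sites)) {
    col <- sites[[si]]
    obs <- m[, col]
    sets <- integer(ntip + nnode)
    sets[seq_len(ntip)] <- ifelse(obs %in% .NUC, bit[obs], 15L)
    # bottom-up: combine the two children of each internal node
    acc <- integer(ntip + nnode)
    cnt <- 0L
    for (e in seq_len(nrow(eo))) {
      p <- eo[e, 1L]
      s_ch <- sets[eo[e, 2L]]
      if (acc[p] == 0L) {
        acc[p] <- s_ch
      } else {
        inter <- bitwAnd(acc[p], s_ch)
        if (inter != 0L) {
          acc[p] <- inter
        } else {
          acc[p] <- bitwOr(acc[p], s_ch)
          cnt <- cnt + 1L
        }
      }
      sets[p] <- acc[p]
    }
    per_site[si] <- cnt
    # top-down: assign states, charging changes to branches
    state <- integer(ntip + nnode)
    state[root] <- first_state(sets[root])
    for (e in rev(seq_len(nrow(eo)))) {
      p <- eo[e, 1L]; ch <- eo[e, 2L]
      if (bitwAnd(state[p], sets[ch])) {
        state[ch] <- state[p]
      } else {
        state[ch] <- first_state(sets[ch])
        edge_counts[eo_to_edge[e]] <- edge_counts[eo_to_edge[e]] + 1
      }
    }
  }

  # tip-incidence of each edge (which tips lie below it), for path sums
  desc <- matrix(FALSE, nrow = nedges, ncol = ntip,
                 dimnames = list(NULL, tree$tip.label))
  below <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (e in seq_len(nrow(eo))) {
    p <- eo[e, 1L]; ch <- eo[e, 2L]
    desc[eo_to_edge[e], below[[ch]]] <- TRUE
    below[[p]] <- c(below[[p]], below[[ch]])
  }

  structure(
    list(
      tree = tree,
      edge_counts = edge_counts,
      per_site = tibble::tibble(site = sites, n_changes = per_site),
      sites = sites,
      tip_incidence = desc
    ),
    class = "branch_change_map"
  )
}

#' @export
print.branch_change_map <- function(x, ...) {
  cat(sprintf(
    "<branch_change_map> %d sites mapped on %d tips; %g changes total (max %g on one branch)\n",
    length(x$sites), length(x$tree$tip.label),
    sum(x$edge_counts), if (length(x$edge_counts)) max(x$edge_counts) else 0))
  invisible(x)
}

#' Substitutions along the tree path between two alleles
#'
#' Sums the parsimony-mapped changes over the branches of the unique path
#' connecting two tips. Because every mapped change on the path is
#' counted — including parallel and back substitutions that cancel in a
#' direct pairwise comparison — the path count can exceed the raw
#' pairwise difference count; that surplus is exactly the multiple-hit
#' signal the recount is designed to expose.
#'
#' @param map A `branch_change_map` from [fitch_map()].
#' @param leaf1,leaf2 Tip names.
#' @return Numeric substitution count along the path (0 for a tip against
#'   itself).
#' @export
path_ks <- function(map, leaf1, leaf2) {
  stopifnot(inherits(map, "branch_change_map"))
  tips <- colnames(map$tip_incidence)
  if (!leaf1 %in% tips) stop("unknown leaf: ", leaf1, call. = FALSE)
  if (!leaf2 %in% tips) stop("unknown leaf: ", leaf2, call. = FALSE)
  if (leaf1 == leaf2) return(0)
  on_path <- xor(map$tip_incidence[, leaf1], map$tip_incidence[, leaf2])
  sum(map$edge_counts[on_path])
}

#' All-pairs tree-path substitution counts (KS matrix)
#'
#' Computes the matrix of path substitution counts between every pair of
#' tips from a branch change map, and its maximum `ks_max` — the input to
#' the recount TMRCA estimator [tmrca_from_ks()].
#'
#' @param map A `branch_change_map` from [fitch_map()].
#' @return A list with `ks` (symmetric named matrix) and `ks_max`.
#' @export
ks_matrix <- function(map) {
  stopifnot(inherits(map, "branch_change_map"))
  D <- map$tip_incidence * 1
  A <- t(D) %*% (map$edge_counts * D)
  s <- diag(A)
  ks <- outer(s, s, "+") - 2 * A
  diag(ks) <- 0
  list(ks = ks, ks_max = max(ks))
}
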