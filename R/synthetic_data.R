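#' Configuration for the allele-set simulator
#'
#' Bundles and validates the parameters of [simulate_alleles()]. The
#' defaults emulate the kind of data the package's analyses are aimed at:
#' a few dozen complete MHC class II CDS of ~257 codons (so that dropping
#' a 27-codon peptide-binding mask leaves a 690-nt background region),
#' synonymous divergence reaching ~0.08 between the deepest allele pairs,
#' a transition bias of 2, weak purifying selection on the background
#' (omega 0.5) and a ~10-fold elevated nonsynonymous rate inside the
#' peptide-binding region, as observed for MHC genes under balancing
#' selection.
#'
#' @param seed Integer RNG seed (reproducibility contract: same config,
#'   same seed, byte-identical output).
#' @param n_alleles Number of alleles (tree tips) when `tree` is random.
#' @param n_codons Alignment length in codons.
#' @param tree Optional `phylo` tree with edge lengths in expected
#'   synonymous substitutions per synonymous site; when `NULL` a random
#'   coalescent-shaped tree over `n_alleles` tips is drawn and rescaled
#'   so its mean root-to-tip depth equals `branch_scale / 2` (making the
#'   deepest pairwise dS about `branch_scale`). Supplied trees are used
#'   with their own lengths.
#' @param branch_scale Target maximum pairwise synonymous divergence for
#'   random trees.
#' @param kappa Transition/transversion proposal bias.
#' @param omega_background,omega_pbr Nonsynonymous/synonymous rate ratios
#'   outside and inside the mask.
#' @param pbr_mask A `region_mask` marking the elevated-omega codons, or
#'   `NULL` for a homogeneous omega. Default: the shipped 27-codon
#'   peptide-binding mask (29-codon leader offset).
#' @param infinite_sites If `TRUE`, no alignment column is substituted
#'   more than once (useful to generate homoplasy-free data).
#' @param recombinants List of `list(parent1 =, parent2 =, breakpoint =)`
#'   entries; each produces one spliced allele (parent1 left of the
#'   breakpoint codon, parent2 from it on) appended to the output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_alleles = 31L,
                       n_codons = 257L,
                       tree = NULL,
                       branch_scale = 0.08,
                       kappa = 2,
                       omega_background = 0.5,
                       omega_pbr = 10,
                       pbr_mask = default_pbr_mask(offset = 29L),
                       infinite_sites = FALSE,
                       recombinants = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  n_alleles <- as.integer(n_alleles)
  n_codons <- as.integer(n_codons)
  if (n_alleles < 2L) stop("`n_alleles` must be >= 2", call. = FALSE)
  if (n_codons < 2L) stop("`n_codons` must be >= 2", call. = FALSE)
  if (!is.null(tree) && !inherits(tree, "phylo")) {
    stop("`tree` must be NULL or a phylo object", call. = FALSE)
  }
  if (branch_scale < 0) stop("`branch_scale` must be >= 0", call. = FALSE)
  if (kappa <= 0) stop("`kappa` must be positive", call. = FALSE)
  if (omega_background < 0 || omega_pbr < 0) {
    stop("omegas must be >= 0", call. = FALSE)
  }
  if (!is.null(pbr_mask)) {
    if (!inherits(pbr_mask, "region_mask")) {
      stop("`pbr_mask` must be a region_mask or NULL", call. = FALSE)
    }
    mask_alignment_codons(pbr_mask, n_codons) # bounds check
  }
  for (r in recombinants) {
    if (!all(c("parent1", "parent2", "breakpoint") %in% names(r))) {
      stop("each recombinant needs parent1, parent2 and breakpoint",
           call. = FALSE)
    }
    bp <- as.integer(r$breakpoint)
    if (is.na(bp) || bp <= 1L || bp > n_codons) {
      stop("recombinant breakpoint must lie strictly inside the alignment ",
           "(1 < breakpoint <= ", n_codons, ")", call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), n_alleles = n_alleles,
         n_codons = n_codons, tree = tree, branch_scale = branch_scale,
         kappa = kappa, omega_background = omega_background,
         omega_pbr = omega_pbr, pbr_mask = pbr_mask,
         infinite_sites = infinite_sites, recombinants = recombinants),
    class = "sim_config"
  )
}

#' Simulate an allele set with recorded ground truth
#'
#' Evolves a random in-frame ancestral sequence down a tree codon by
#' codon. Point mutations are proposed at total rate 3 x (codons) per
#' unit branch length, with targets drawn under the transition bias
#' `kappa`; synonymous proposals are always accepted (so branch lengths
#' are calibrated in expected synonymous substitutions per synonymous
#' site), stop-creating proposals are rejected, and nonsynonymous
#' proposals are accepted with probability `min(1, omega)` of their
#' region. For `omega > 1` a second, nonsynonymous-only proposal stream
#' at rate `(omega - 1)` inside the region supplies the excess — a
#' deliberately simple selection stand-in, not a full codon model, that
#' leaves the synonymous clock untouched. With `infinite_sites = TRUE`
#' each alignment column may change at most once across the whole tree.
#' Requested splice recombinants are constructed from the simulated tips
#' post hoc and appended.
#'
#' @param cfg A [sim_config()].
#' @return A list with `alleles` (an `allele_set`; recombinants carry
#'   `REC` names) and `truth`: the scaled `tree`, per-edge realized
#'   `branch_syn`/`branch_nonsyn` counts (parallel to `tree$edge`),
#'   `column_hits` (substitutions per alignment column), `ks_true`
#'   (tip-pair matrix of synonymous changes summed along tree paths),
#'   `recombinants` registry and the `seed`.
#' @export
simulate_alleles <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  C <- cfg$n_codons
  tab <- ml_codon_table()
  sense <- tab$codons[!tab$is_stop]

  tree <- cfg$tree
  if (is.null(tree)) {
    tree <- ape::rcoal(cfg$n_alleles,
                       tip.label = sprintf("SYN-DRB1*%02d:01",
                                           seq_len(cfg$n_alleles)))
    depth <- ape::node.depth.edgelength(tree)[seq_len(cfg$n_alleles)]
    target <- cfg$branch_scale / 2
    if (mean(depth) > 0) {
      tree$edge.length <- tree$edge.length * target / mean(depth)
    }
  }
  tree <- ape::multi2di(tree)
  ntip <- length(tree$tip.label)
  total_len <- sum(tree$edge.length)
  if (cfg$infinite_sites && 3 * C * total_len > 0.3 * 3 * C) {
    stop("infeasible config: infinite_sites with expected substitution ",
         "load this high would exhaust the alignment columns; increase ",
         "n_codons or shorten the tree", call. = FALSE)
  }

  mask_codons <- if (is.null(cfg$pbr_mask)) integer(0) else
    mask_alignment_codons(cfg$pbr_mask, C)
  in_mask <- seq_len(C) %in% mask_codons
  omega_of <- ifelse(in_mask, cfg$omega_pbr, cfg$omega_background)

  ancestor <- sample(sense, C, replace = TRUE)
  eo_tree <- ape::reorder.phylo(tree, "postorder")
  eo <- eo_tree$edge
  eo_len <- eo_tree$edge.length
  edge_key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  preorder <- rev(seq_len(nrow(eo)))

  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- ancestor
  branch_syn <- branch_nonsyn <- numeric(nrow(tree$edge))
  column_hits <- integer(3L * C)
  p_ts <- cfg$kappa / (cfg$kappa + 2)

  propose_target <- function(ref) {
    if (runif(1) < p_ts) {
      .TS_PARTNER[[ref]]
    } else {
      sample(setdiff(.NUC, c(ref, .TS_PARTNER[[ref]])), 1L)
    }
  }

  apply_event <- function(seqv, nt_pos, require_nonsyn = FALSE) {
    # returns list(seq, kind) with kind in none/syn/nonsyn
    if (cfg$infinite_sites && column_hits[nt_pos] > 0L) {
      return(list(seq = seqv, kind = "none"))
    }
    cod_i <- (nt_pos - 1L) %/% 3L + 1L
    within <- (nt_pos - 1L) %% 3L + 1L
    cod <- seqv[[cod_i]]
    ref <- substr(cod, within, within)
    new_cod <- .mutate_codon(cod, within, propose_target(ref))
    if (ml_is_stop(new_cod)) return(list(seq = seqv, kind = "none"))
    syn <- ml_translate_codon(new_cod) == ml_translate_codon(cod)
    if (require_nonsyn && syn) return(list(seq = seqv, kind = "none"))
    if (!syn) {
      om <- omega_of[[cod_i]]
      accept_p <- if (require_nonsyn) 1 else min(1, om)
      if (runif(1) >= accept_p) return(list(seq = seqv, kind = "none"))
    }
    seqv[[cod_i]] <- new_cod
    column_hits[nt_pos] <<- column_hits[nt_pos] + 1L
    list(seq = seqv, kind = if (syn) "syn" else "nonsyn")
  }

  boost_regions <- list()
  for (om in unique(omega_of[omega_of > 1])) {
    boost_regions[[length(boost_regions) + 1L]] <-
      list(codons = which(omega_of == om), excess = om - 1)
  }

  for (e in preorder) {
    p <- eo[e, 1L]; ch <- eo[e, 2L]
    len <- eo_len[e]
    edge_row <- match(paste(p, ch), edge_key)
    seqv <- seqs[[p]]
    n_events <- rpois(1L, 3 * C * len)
    if (n_events > 0L) {
      for (nt_pos in sample.int(3L * C, n_events, replace = TRUE)) {
        res <- apply_event(seqv, nt_pos)
        seqv <- res$seq
        if (res$kind == "syn") branch_syn[edge_row] <- branch_syn[edge_row] + 1
        if (res$kind == "nonsyn") branch_nonsyn[edge_row] <- branch_nonsyn[edge_row] + 1
      }
    }
    for (br in boost_regions) {
      n_extra <- rpois(1L, 3 * length(br$codons) * len * br$excess)
      if (n_extra > 0L) {
        cod_pick <- sample(br$codons, n_extra, replace = TRUE)
        within_pick <- sample.int(3L, n_extra, replace = TRUE)
        for (idx in seq_len(n_extra)) {
          nt_pos <- 3L * (cod_pick[idx] - 1L) + within_pick[idx]
          res <- apply_event(seqv, nt_pos, require_nonsyn = TRUE)
          seqv <- res$seq
          if (res$kind == "nonsyn") {
            branch_nonsyn[edge_row] <- branch_nonsyn[edge_row] + 1
          }
        }
      }
    }
    seqs[[ch]] <- seqv
  }

  tip_seqs <- vapply(seq_len(ntip),
                     function(i) paste(seqs[[i]], collapse = ""),
                     character(1L))
  names(tip_seqs) <- tree$tip.label

  rec_registry <- list()
  rec_seqs <- character(0)
  for (ri in seq_along(cfg$recombinants)) {
    r <- cfg$recombinants[[ri]]
    p1 <- if (is.numeric(r$parent1)) tree$tip.label[[r$parent1]] else r$parent1
    p2 <- if (is.numeric(r$parent2)) tree$tip.label[[r$parent2]] else r$parent2
    if (!all(c(p1, p2) %in% names(tip_seqs))) {
      stop("recombinant parents must be simulated tips", call. = FALSE)
    }
    child <- make_recombinant(tip_seqs[[p1]], tip_seqs[[p2]],
                              as.integer(r$breakpoint))
    nm <- sprintf("SYN-REC*%02d:01", ri)
    rec_seqs[[nm]] <- child
    rec_registry[[ri]] <- tibble::tibble(
      name = nm, parent1 = p1, parent2 = p2,
      breakpoint = as.integer(r$breakpoint)
    )
  }

  # per-pair synonymous path counts from the realized per-branch counts
  desc <- matrix(FALSE, nrow = nrow(tree$edge), ncol = ntip,
                 dimnames = list(NULL, tree$tip.label))
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (e in seq_len(nrow(eo))) {
    p <- eo[e, 1L]; ch <- eo[e, 2L]
    desc[match(paste(p, ch), edge_key), below[[ch]]] <- TRUE
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  D <- desc * 1
  A <- t(D) %*% (branch_syn * D)
  s <- diag(A)
  ks_true <- outer(s, s, "+") - 2 * A
  diag(ks_true) <- 0

  alleles <- allele_set(c(tip_seqs, rec_seqs))
  truth <- list(
    tree = tree,
    branch_syn = branch_syn,
    branch_nonsyn = branch_nonsyn,
    column_hits = column_hits,
    ks_true = ks_true,
    recombinants = if (length(rec_registry)) dplyr::bind_rows(rec_registry)
      else tibble::tibble(name = character(), parent1 = character(),
                          parent2 = character(), breakpoint = integer()),
    seed = cfg$seed
  )
  list(alleles = alleles, truth = truth)
}

#' Splice two aligned sequences at a codon breakpoint
#'
#' Returns the chimeric sequence taking `s1` for codons before
#' `breakpoint` and `s2` from `breakpoint` on — the construction used to
#' plant known recombinants for testing the screen.
#'
#' @param s1,s2 Equal-length in-frame nucleotide strings.
#' @param breakpoint Codon index of the splice, strictly inside the
#'   alignment (`1 < breakpoint <= n_codons`, with both flanks non-empty).
#' @return The spliced sequence string.
#' @examples
#' make_recombinant("AAAAAATTT", "GGGGGGCCC", 2)
#' @export
make_recombinant <- function(s1, s2, breakpoint) {
  if (nchar(s1) != nchar(s2)) {
    stop("parent sequences must have equal length", call. = FALSE)
  }
  if (nchar(s1) %% 3L != 0L) {
    stop("parent sequences must be in frame", call. = FALSE)
  }
  C <- nchar(s1) %/% 3L
  breakpoint <- as.integer(breakpoint)
  if (is.na(breakpoint) || breakpoint <= 1L || breakpoint > C) {
    stop("degenerate splice: breakpoint must satisfy 1 < breakpoint <= ",
         C, call. = FALSE)
  }
  cut <- 3L * (breakpoint - 1L)
  paste0(substr(s1, 1L, cut), substr(s2, cut + 1L, nchar(s2)))
}
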