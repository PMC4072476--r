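#' Define a codon-region mask
#'
#' A `region_mask` names a set of codon positions — typically the
#' peptide-binding-region (PBR) residues of an MHC molecule, which evolve
#' under balancing selection with a strongly elevated nonsynonymous rate —
#' in mature-protein coordinates, together with a signal-peptide offset
#' that converts them to alignment coordinates. Position `p` of the mature
#' protein corresponds to alignment codon `p + offset`.
#'
#' @param positions Integer vector of 1-based mature-protein codon
#'   positions (duplicates removed, stored sorted).
#' @param offset Signal-peptide length in codons (non-negative integer);
#'   the default 0 means positions are already alignment codon numbers.
#' @return An object of class `region_mask`.
#' @seealso [default_pbr_mask()] for the 27-residue DRB1 peptide-binding
#'   mask shipped with the package.
#' @export
region_mask <- function(positions, offset = 0L) {
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) == 0L) stop("mask has no positions", call. = FALSE)
  if (any(is.na(positions)) || any(positions < 1L)) {
    stop("mask positions must be positive integers", call. = FALSE)
  }
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 0L) {
    stop("`offset` must be a non-negative integer", call. = FALSE)
  }
  structure(list(positions = positions, offset = offset),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d codons, offset %d\n  %s\n",
              length(x$positions), x$offset,
              paste(head(x$positions, 12L), collapse = " ")))
  invisible(x)
}

#' Read a codon mask file
#'
#' The file format is one 1-based codon position per line; blank lines and
#' `#` comments are ignored.
#'
#' @param path Path to the mask file.
#' @param offset Signal-peptide codon offset, see [region_mask()].
#' @return A `region_mask`.
#' @export
read_region_mask <- function(path, offset = 0L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  pos <- suppressWarnings(as.integer(lines))
  if (anyNA(pos)) {
    stop("mask file contains non-integer entries: ",
         paste(lines[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  region_mask(pos, offset = offset)
}

#' Default DRB1 peptide-binding-region mask (27 codons)
#'
#' Returns the mask shipped with the package: a commonly used set of 24
#' DR beta-chain peptide-contact residues plus positions 57, 67 and 90,
#' which also participate in the peptide-binding groove — 27 codons in
#' total, numbered on the mature beta-1 domain. The set is a documented,
#' editable default (`inst/extdata/pbr27_default_mask.txt`): analyses
#' accept any mask, and users with a preferred contact-residue definition
#' should supply their own file via [read_region_mask()].
#'
#' @param offset Signal-peptide codon offset (DRB1 precursors carry a
#'   29-residue leader, hence the default 29 when masking complete CDS).
#' @return A `region_mask` of 27 codons.
#' @export
default_pbr_mask <- function(offset = 29L) {
  path <- system.file("extdata", "pbr27_default_mask.txt",
                      package = "mhclineage", mustWork = TRUE)
  read_region_mask(path, offset = offset)
}

#' Apply a codon-region mask to an allele set
#'
#' In `exclude` mode the masked codons are removed (e.g. dropping the PBR
#' before tree building or synonymous-clock dating, because its ~10-fold
#' elevated nonsynonymous rate under balancing selection distorts
#' distances); in `include` mode only the masked codons are kept. Codon
#' boundaries are always preserved.
#'
#' @param x An `allele_set`.
#' @param mask A `region_mask`.
#' @param mode `"exclude"` (default) or `"include"`.
#' @return An `allele_set` restricted to the selected codons.
#' @examples
#' a <- allele_set(c(x = "ATGAAATTTGGG", y = "ATGAAGTTTGGG"))
#' apply_region_mask(a, region_mask(2), mode = "exclude")
#' @export
apply_region_mask <- function(x, mask, mode = c("exclude", "include")) {
  x <- as_allele_set(x)
  mode <- match.arg(mode)
  if (!inherits(mask, "region_mask")) {
    stop("`mask` must be a region_mask", call. = FALSE)
  }
  codons <- mask_alignment_codons(mask, x$n_codons)
  keep <- if (mode == "exclude") setdiff(seq_len(x$n_codons), codons) else codons
  if (length(keep) == 0L) {
    stop("mask error: no codons left after applying mask in ", mode, " mode",
         call. = FALSE)
  }
  nt <- as.vector(rbind(3L * (keep - 1L) + 1L,
                        3L * (keep - 1L) + 2L,
                        3L * keep))
  newseq <- vapply(x$seq, function(s) {
    paste(strsplit(s, "")[[1L]][nt], collapse = "")
  }, character(1L))
  allele_set(newseq, group_labels = x$groups)
}

# mask positions translated to alignment codon coordinates, with bounds check
mask_alignment_codons <- function(mask, n_codons) {
  codons <- mask$positions + mask$offset
  bad <- codons < 1L | codons > n_codons
  if (any(bad)) {
    stop("mask error: positions ",
         paste(mask$positions[bad], collapse = ", "),
         " fall outside the alignment (", n_codons, " codons, offset ",
         mask$offset, ")", call. = FALSE)
  }
  codons
}
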