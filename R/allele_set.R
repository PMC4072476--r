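#' Construct a set of aligned, in-frame allele coding sequences
#'
#' An `allele_set` is the central container of the package: a named set of
#' equal-length, in-frame nucleotide sequences (the aligned complete CDS of
#' MHC alleles), with an optional mapping of allele names to group labels
#' (e.g. the two major phylogenetic groups of an allelic tree).
#'
#' Sequences must all have the same length, the length must be divisible by
#' three, and the alphabet is restricted to `A`, `C`, `G`, `T`, the
#' alignment gap `-` and the ambiguity code `N`. Codons containing `-` or
#' `N` are tolerated here and deleted pairwise by downstream analyses.
#'
#' @param sequences Named character vector of aligned nucleotide sequences.
#' @param group_labels Optional named character vector mapping allele names
#'   to group tags (e.g. `"A"`/`"B"`). Names must be a subset of the
#'   sequence names.
#' @return An object of class `allele_set` with elements `seq` (named
#'   character vector), `alignment_length`, `n_codons` and `groups`.
#' @examples
#' a <- allele_set(c(x = "ATGAAATTT", y = "ATGAAGTTT"))
#' a
#' @export
allele_set <- function(sequences, group_labels = NULL) {
  if (length(sequences) == 0L) {
    stop("`sequences` must contain at least one sequence", call. = FALSE)
  }
  sequences <- toupper(unlist(sequences))
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("all sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate sequence names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "), call. = FALSE)
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("alignment error: sequences have unequal lengths (",
         paste(range(lens), collapse = "-"), ")", call. = FALSE)
  }
  L <- lens[[1L]]
  if (L %% 3L != 0L) {
    stop("frame error: alignment length ", L, " is not divisible by 3",
         call. = FALSE)
  }
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad)) {
    stop("alphabet error: illegal characters in ",
         paste(names(sequences)[bad], collapse = ", "),
         " (allowed: A C G T N -)", call. = FALSE)
  }
  if (!is.null(group_labels)) {
    group_labels <- setNames(as.character(group_labels), names(group_labels))
    unknown <- setdiff(names(group_labels), names(sequences))
    if (length(unknown)) {
      stop("group labels refer to unknown alleles: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(
      seq = sequences,
      alignment_length = unname(L),
      n_codons = unname(L) %/% 3L,
      groups = group_labels
    ),
    class = "allele_set"
  )
}

#' @export
print.allele_set <- function(x, ...) {
  cat(sprintf("<allele_set> %d sequences x %d nt (%d codons)\n",
              length(x$seq), x$alignment_length, x$n_codons))
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat("  groups: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  }
  cat("  ", paste(head(names(x$seq), 4L), collapse = ", "),
      if (length(x$seq) > 4L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.allele_set <- function(x) length(x$seq)

#' @export
names.allele_set <- function(x) names(x$seq)

#' Coerce to an allele set
#'
#' @param x An `allele_set`, or a named character vector of aligned
#'   sequences.
#' @param ... Unused.
#' @return An `allele_set`.
#' @export
as_allele_set <- function(x, ...) {
  if (inherits(x, "allele_set")) return(x)
  if (is.character(x)) return(allele_set(x))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to an allele_set", call. = FALSE)
}

#' Subset an allele set by name or index
#'
#' @param x An `allele_set`.
#' @param i Character names or integer/logical indices of alleles to keep.
#' @return An `allele_set` with the selected alleles; group labels are
#'   carried along.
#' @export
subset_alleles <- function(x, i) {
  x <- as_allele_set(x)
  keep <- x$seq[i]
  if (anyNA(keep) || length(keep) == 0L) {
    stop("unknown alleles in subset", call. = FALSE)
  }
  g <- x$groups
  if (!is.null(g)) g <- g[intersect(names(g), names(keep))]
  allele_set(keep, group_labels = if (length(g)) g else NULL)
}

#' Read an aligned multi-FASTA of allele coding sequences
#'
#' Reads a multi-record FASTA file (via Biostrings) and validates it as an
#' aligned, in-frame allele set. Record names are kept verbatim; use
#' [parse_allele_names()] to decompose IMGT-style names such as
#' `HLA-DRB1*03:01`.
#'
#' @param path Path to an aligned FASTA file.
#' @return An `allele_set`.
#' @export
read_alleles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  allele_set(setNames(as.character(ss), names(ss)))
}

#' Write an allele set to FASTA
#'
#' @param x An `allele_set`.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_alleles <- function(x, path, width = 70L) {
  x <- as_allele_set(x)
  ss <- Biostrings::BStringSet(x$seq)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Parse IMGT-style allele names
#'
#' Decomposes names of the form `<prefix>-<locus>*<f1>:<f2>...` (e.g.
#' `HLA-DRB1*11:01`, `Patr-DRB1*03:01`) into the species prefix, locus, the
#' ordered numeric name fields, and the allelic-lineage field (the first
#' name field, so `HLA-DRB1*03:01` belongs to lineage `03`). Names that do
#' not follow the nomenclature are returned with `NA` components rather
#' than dropped.
#'
#' @param x Character vector of allele names, or an `allele_set`.
#' @return A tibble with columns `name`, `prefix`, `locus`, `fields`
#'   (list column of character vectors) and `lineage`.
#' @examples
#' parse_allele_names(c("HLA-DRB1*11:01", "Mamu-DRB1*03:05:01"))
#' @export
parse_allele_names <- function(x) {
  if (inherits(x, "allele_set")) x <- names(x$seq)
  rx <- "^([A-Za-z]+)-([A-Za-z0-9]+)\\*([0-9]+(?::[0-9]+)*)$"
  m <- regmatches(x, regexec(rx, x))
  parsed <- purrr::map(m, function(g) {
    if (length(g) == 0L) {
      list(prefix = NA_character_, locus = NA_character_,
           fields = character(0), lineage = NA_character_)
    } else {
      f <- strsplit(g[[4L]], ":", fixed = TRUE)[[1L]]
      list(prefix = g[[2L]], locus = g[[3L]], fields = f, lineage = f[[1L]])
    }
  })
  tibble::tibble(
    name = x,
    prefix = purrr::map_chr(parsed, "prefix"),
    locus = purrr::map_chr(parsed, "locus"),
    fields = purrr::map(parsed, "fields"),
    lineage = purrr::map_chr(parsed, "lineage")
  )
}

#' Format parsed allele names back into nomenclature strings
#'
#' Inverse of [parse_allele_names()] for rows that parsed successfully.
#'
#' @param parsed A tibble as returned by [parse_allele_names()].
#' @return Character vector of formatted names (`NA` where unparsed).
#' @export
format_allele_names <- function(parsed) {
  purrr::pmap_chr(
    parsed[c("prefix", "locus", "fields")],
    function(prefix, locus, fields) {
      if (is.na(prefix) || length(fields) == 0L) return(NA_character_)
      paste0(prefix, "-", locus, "*", paste(fields, collapse = ":"))
    }
  )
}

#' Drop sequences that are not full-length functional CDS
#'
#' Removes sequences containing internal stop codons or made entirely of
#' gaps; intended as the ingestion filter of the full pipeline, mirroring
#' restriction of phylogenetic analysis to complete, functional coding
#' sequences. A terminal stop codon (final codon of the alignment) is
#' tolerated.
#'
#' @param x An `allele_set`.
#' @return An `allele_set` with offending sequences removed (with a
#'   warning naming them).
#' @export
drop_nonfunctional <- function(x) {
  x <- as_allele_set(x)
  cm <- .codon_string_matrix(x)
  internal <- cm[, -ncol(cm), drop = FALSE]
  has_stop <- apply(internal, 1L, function(cods) any(ml_is_stop(cods)))
  all_gap <- !nzchar(gsub("-", "", x$seq))
  bad <- has_stop | all_gap
  if (any(bad)) {
    warning("dropping non-functional sequences: ",
            paste(names(x$seq)[bad], collapse = ", "), call. = FALSE)
    if (all(bad)) stop("no functional sequences remain", call. = FALSE)
    x <- subset_alleles(x, which(!bad))
  }
  x
}
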