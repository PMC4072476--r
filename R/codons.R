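# Internal codon machinery shared by the distance, site-classification and
# simulation code. All tables derive from the standard genetic code as
# shipped with Biostrings; stop codons are never treated as valid states of
# a functional MHC coding sequence.

.NUC <- c("A", "C", "G", "T")

# transition partner of each nucleotide (A<->G, C<->T)
.TS_PARTNER <- c(A = "G", C = "T", G = "A", T = "C")

ml_codon_table <- function() {
  if (is.null(.ml_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .ml_cache$codons <- names(gc)
    .ml_cache$aa <- unname(gc)
    .ml_cache$is_stop <- unname(gc) == "*"
  }
  list(
    codons = .ml_cache$codons,
    aa = .ml_cache$aa,
    is_stop = .ml_cache$is_stop
  )
}

ml_translate_codon <- function(codon) {
  tab <- ml_codon_table()
  aa <- tab$aa[match(codon, tab$codons)]
  ifelse(is.na(aa), "X", aa)
}

ml_is_stop <- function(codon) {
  tab <- ml_codon_table()
  codon %in% tab$codons[tab$is_stop]
}

ml_is_transition <- function(from, to) {
  .TS_PARTNER[from] == to
}

.check_codon <- function(codon, arg = "codon") {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L) {
    stop(sprintf("`%s` must be a single 3-letter string", arg), call. = FALSE)
  }
  codon <- toupper(codon)
  if (!all(strsplit(codon, "")[[1]] %in% .NUC)) {
    stop(sprintf("`%s` must be over the alphabet A/C/G/T, got '%s'", arg, codon),
         call. = FALSE)
  }
  if (ml_is_stop(codon)) {
    stop(sprintf("`%s` is a stop codon ('%s'); stop codons carry no potential sites",
                 arg, codon), call. = FALSE)
  }
  codon
}

# substitute one position of a codon
.mutate_codon <- function(codon, pos, base) {
  substr(codon, pos, pos) <- base
  codon
}

# split an alignment of equal-length sequences into an n x L character matrix
.seq_char_matrix <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[[1L]])
  matrix(unlist(strsplit(toupper(unlist(seqs)), ""), use.names = FALSE),
         nrow = n, ncol = L, byrow = TRUE,
         dimnames = list(names(seqs), NULL))
}

# n x C matrix of codon strings for an allele_set
.codon_string_matrix <- function(x) {
  seqs <- toupper(x$seq)
  C <- x$n_codons
  starts <- 3L * (seq_len(C) - 1L) + 1L
  out <- vapply(seqs, function(s) substring(s, starts, starts + 2L),
                character(C))
  # vapply drops to a plain vector for single-codon alignments
  if (C == 1L) {
    matrix(out, ncol = 1L, dimnames = list(names(seqs), NULL))
  } else {
    t(out)
  }
}
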