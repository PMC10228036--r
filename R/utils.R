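#' Reverse-complement a DNA string
#'
#' Complements A/C/G/T (N stays N) and reverses the sequence. Input must be
#' uppercase DNA over the alphabet `{A,C,G,T,N}`.
#'
#' @param seq A single character string of uppercase DNA.
#' @return The reverse-complemented string.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(seq)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}

# vectorised single-string splitter: "ACGT" -> c("A","C","G","T")
seq_chars <- function(seq) {
  if (nchar(seq) == 0L) return(character(0L))
  strsplit(seq, "", fixed = TRUE)[[1L]]
}

is_dna <- function(seq, allow_n = TRUE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  !grepl(sprintf("[^%s]", alphabet), seq)
}

#' Construct a sequencing read
#'
#' A read couples an identifier, an uppercase DNA sequence and per-base Phred
#' quality scores (offset-free integers). Sequence and qualities must have
#' equal length; qualities must lie in `[0, 60]`.
#'
#' @param id Read identifier (without the leading `@`).
#' @param sequence Uppercase DNA over `{A,C,G,T,N}`. `N` is legal in reads.
#' @param qualities Integer vector of Phred scores, one per base.
#' @return An object of class `aq_read`: a list with elements `id`,
#'   `sequence`, `qualities`.
#' @export
#' @examples
#' aq_read("r1", "ACGT", c(40L, 40L, 40L, 40L))
aq_read <- function(id, sequence, qualities) {
  qualities <- as.integer(qualities)
  if (nchar(sequence) != length(qualities)) {
    stop(sprintf("read '%s': sequence length (%d) != quality length (%d)",
                 id, nchar(sequence), length(qualities)))
  }
  if (!is_dna(sequence)) {
    stop(sprintf("read '%s': sequence contains characters outside {A,C,G,T,N}", id))
  }
  if (length(qualities) && (min(qualities) < 0L || max(qualities) > 60L)) {
    stop(sprintf("read '%s': Phred qualities must lie in [0, 60]", id))
  }
  structure(list(id = id, sequence = sequence, qualities = qualities),
            class = "aq_read")
}

#' @export
print.aq_read <- function(x, ...) {
  cat(sprintf("<read %s: %d bp, mean Q%.1f>\n", x$id, nchar(x$sequence),
              if (length(x$qualities)) mean(x$qualities) else NA_real_))
  invisible(x)
}

#' Construct a reference sequence
#'
#' A named amplicon, allele or genomic-region sequence that reads are aligned
#' to, with an optional expected cut site. The cut site is the 0-based count
#' of reference bases to the left of the nuclease cleavage point, so
#' `cut_site = 0` means cleavage before the first base.
#'
#' @param name Reference name; non-empty, no whitespace.
#' @param sequence Uppercase DNA over `{A,C,G,T}`. `N` is not allowed in
#'   references: they are user-curated sequences.
#' @param cut_site Optional integer in `[0, nchar(sequence)]`.
#' @return An object of class `aq_reference`.
#' @export
aq_reference <- function(name, sequence, cut_site = NULL) {
  if (!nzchar(name)) stop("reference name must be non-empty")
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop(sprintf("reference '%s': empty sequence", name))
  if (!is_dna(sequence, allow_n = FALSE)) {
    stop(sprintf("reference '%s': sequence contains characters outside {A,C,G,T}", name))
  }
  if (!is.null(cut_site)) {
    cut_site <- as.integer(cut_site)
    if (cut_site < 0L || cut_site > nchar(sequence)) {
      stop(sprintf("reference '%s': cut_site %d outside [0, %d]",
                   name, cut_site, nchar(sequence)))
    }
  }
  structure(list(name = name, sequence = sequence, cut_site = cut_site),
            class = "aq_reference")
}

#' @export
print.aq_reference <- function(x, ...) {
  cat(sprintf("<reference %s: %d bp%s>\n", x$name, nchar(x$sequence),
              if (is.null(x$cut_site)) "" else sprintf(", cut site %d", x$cut_site)))
  invisible(x)
}

# validate a list of aq_reference: unique non-empty names
validate_reference_set <- function(references) {
  if (length(references) == 0L) stop("reference set is empty")
  nms <- vapply(references, function(r) r$name, character(1L))
  dup <- nms[duplicated(nms)]
  if (length(dup)) {
    stop(sprintf("duplicate reference name(s): %s", paste(unique(dup), collapse = ", ")))
  }
  invisible(references)
}

reference_names <- function(references) {
  vapply(references, function(r) r$name, character(1L))
}

reference_by_name <- function(references, name) {
  idx <- match(name, reference_names(references))
  if (is.na(idx)) stop(sprintf("unknown reference '%s'", name))
  references[[idx]]
}
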