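# Minimal single-end SAM emission: the pipeline's optional alignment export.
# Mapped records carry FLAG 0, 1-based POS and the alignment's CIGAR;
# unmapped records carry FLAG 4, POS 0, CIGAR "*".

#' CIGAR string of an alignment
#'
#' @param alignment An [aq_alignment()] object.
#' @return Run-length CIGAR string, e.g. `"8M3D9M"`.
#' @export
cigar_string <- function(alignment) {
  if (length(alignment$op) == 0L) return("*")
  paste0(alignment$len, alignment$op, collapse = "")
}

#' Write assignments to a SAM file
#'
#' @param records List of records, each a list with elements `read`
#'   (an [aq_read()]), `reference` (reference name, or `NA` if unmapped) and
#'   `alignment` (an [aq_alignment()], or `NULL` if unmapped).
#' @param references List of [aq_reference()]; every mapped record's
#'   reference name must appear here.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(records, references, path) {
  validate_reference_set(references)
  nms <- reference_names(references)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (r in references) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", r$name, nchar(r$sequence)), con)
  }
  for (rec in records) {
    read <- rec$read
    qual <- phred_encode(read$qualities)
    if (!nzchar(qual)) qual <- "*"
    if (is.null(rec$alignment) || is.na(rec$reference)) {
      writeLines(paste(read$id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                       read$sequence, qual, sep = "\t"), con)
    } else {
      if (!rec$reference %in% nms) {
        stop(sprintf("alignment references unknown sequence '%s'", rec$reference))
      }
      writeLines(paste(read$id, 0L, rec$reference, rec$alignment$ref_start + 1L,
                       60L, cigar_string(rec$alignment), "*", 0L, 0L,
                       read$sequence, qual, sep = "\t"), con)
    }
  }
  invisible(path)
}
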