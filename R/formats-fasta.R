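# FASTA and BED input. FASTA parsing is delegated to Biostrings; this layer
# enforces the reference-set contract (unique names, non-empty sequences,
# no N bases) that a general-purpose reader does not.

#' Read reference sequences from FASTA
#'
#' Reads one or more amplicon/allele/region references. Multi-line sequences
#' are concatenated, lowercase folds to uppercase, and record order is
#' preserved. The reference name is the first whitespace-delimited token of
#' the header. Cut sites are not encoded in FASTA; supply them separately
#' (see [run_amplicon()]).
#'
#' @param path Path to a FASTA file with at least one record.
#' @return List of [aq_reference()] objects in file order (cut sites unset).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop(sprintf("%s: no FASTA records", path))
  nms <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nms))) stop(sprintf("%s: FASTA record with empty name", path))
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) {
    stop(sprintf("%s: duplicate reference name(s): %s", path,
                 paste(dup, collapse = ", ")))
  }
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    stop(sprintf("%s: empty sequence under header '%s'", path,
                 nms[which(widths == 0L)[1L]]))
  }
  refs <- vector("list", length(set))
  for (i in seq_along(set)) {
    refs[[i]] <- aq_reference(nms[i], toupper(as.character(set[[i]])))
  }
  refs
}

#' Write references (or any named sequences) to FASTA
#'
#' @param sequences Named character vector, or list of [aq_reference()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  if (is.list(sequences) && length(sequences) &&
      inherits(sequences[[1L]], "aq_reference")) {
    seqs <- vapply(sequences, function(r) r$sequence, character(1L))
    names(seqs) <- reference_names(sequences)
    sequences <- seqs
  }
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, max(1L, nchar(s)), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read genomic regions of interest from BED
#'
#' Tab-separated BED with required columns chrom, start, end (0-based,
#' half-open). Column 4, if present, names the region (default
#' `"chrom:start-end"`); column 5, if present, is an integer cut site in
#' genomic coordinates. Lines starting with `#`, `track` or `browser` are
#' skipped.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `cut_site` (NA when absent), one row per region, in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  regions <- data.frame(chrom = character(0L), start = integer(0L),
                        end = integer(0L), name = character(0L),
                        cut_site = integer(0L), stringsAsFactors = FALSE)
  rows <- list()
  for (ln in which(keep)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop(sprintf("%s line %d: fewer than 3 BED columns", path, ln))
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("%s line %d: non-integer coordinates", path, ln))
    }
    if (start < 0L || start >= end) {
      stop(sprintf("%s line %d: invalid interval [%s, %s)", path, ln, f[2L], f[3L]))
    }
    name <- if (length(f) >= 4L && nzchar(f[4L])) f[4L] else
      sprintf("%s:%d-%d", f[1L], start, end)
    cut <- NA_integer_
    if (length(f) >= 5L && nzchar(f[5L])) {
      cut <- suppressWarnings(as.integer(f[5L]))
      if (is.na(cut)) stop(sprintf("%s line %d: non-integer cut site", path, ln))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = f[1L], start = start, end = end, name = name, cut_site = cut,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) regions <- do.call(rbind, rows)
  dup <- unique(regions$name[duplicated(regions$name)])
  if (length(dup)) {
    stop(sprintf("%s: duplicate region name(s): %s", path, paste(dup, collapse = ", ")))
  }
  regions
}
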