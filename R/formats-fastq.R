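# FASTQ I/O. Phred offset is fixed at 33 (modern Illumina); gzip input is
# detected by the two magic bytes 0x1f 0x8b, never by file extension.

is_gzip_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

open_text_input <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is_gzip_file(path)) gzfile(path, "rt") else file(path, "rt")
}

phred_decode <- function(qual_string) {
  if (nchar(qual_string) == 0L) return(integer(0L))
  as.integer(utf8ToInt(qual_string)) - 33L
}

phred_encode <- function(qualities) {
  if (length(qualities) == 0L) return("")
  intToUtf8(as.integer(qualities) + 33L)
}

parse_fastq_lines <- function(lines, path) {
  n <- length(lines)
  # trailing blank line(s) from editors are tolerated
  while (n > 0L && !nzchar(lines[n])) n <- n - 1L
  if (n == 0L) return(list())
  if (n %% 4L != 0L) {
    stop(sprintf("%s: truncated FASTQ record at record %d", path, n %/% 4L + 1L))
  }
  idx <- seq(1L, n, by = 4L)
  headers <- lines[idx]
  if (any(substr(headers, 1L, 1L) != "@")) {
    bad <- which(substr(headers, 1L, 1L) != "@")[1L]
    stop(sprintf("%s: record %d does not start with '@'", path, bad))
  }
  ids <- sub("\\s.*$", "", substring(headers, 2L))
  seqs <- toupper(lines[idx + 1L])
  quals <- lines[idx + 3L]
  reads <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    if (nchar(seqs[i]) != nchar(quals[i])) {
      stop(sprintf("%s: sequence/quality length mismatch for read '%s'",
                   path, ids[i]))
    }
    reads[[i]] <- aq_read(ids[i], seqs[i], phred_decode(quals[i]))
  }
  reads
}

#' Read FASTQ files
#'
#' Reads 4-line FASTQ records (Phred+33) from a plain or gzip-compressed file.
#' Compression is detected from the gzip magic bytes, not the file extension.
#' In paired mode the two files are read in parallel and records are paired by
#' index; the files must contain the same number of records.
#'
#' @param path Path to a FASTQ file.
#' @param paired_with Optional path to the mate FASTQ file.
#' @return Single mode: a list of [aq_read()] objects in file order. Paired
#'   mode: a list with elements `first` and `second`, equal-length lists of
#'   reads paired by record index.
#' @export
read_fastq <- function(path, paired_with = NULL) {
  con <- open_text_input(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  reads1 <- parse_fastq_lines(lines, path)
  if (is.null(paired_with)) return(reads1)
  con2 <- open_text_input(paired_with)
  lines2 <- readLines(con2, warn = FALSE)
  close(con2)
  reads2 <- parse_fastq_lines(lines2, paired_with)
  if (length(reads1) != length(reads2)) {
    stop(sprintf(
      "paired FASTQ files hold unequal record counts (%d vs %d); %s ends early",
      length(reads1), length(reads2),
      if (length(reads1) < length(reads2)) path else paired_with))
  }
  list(first = reads1, second = reads2)
}

#' Write reads to a FASTQ file
#'
#' @param reads List of [aq_read()] objects.
#' @param path Output path.
#' @param gzip Write gzip-compressed output.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, gzip = FALSE) {
  con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (length(reads)) {
    lines <- vapply(reads, function(r) {
      paste0("@", r$id, "\n", r$sequence, "\n+\n", phred_encode(r$qualities))
    }, character(1L))
    writeLines(lines, con)
  }
  invisible(path)
}
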