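# Read placement on reference sequences: exact semi-global affine-gap
# dynamic programming (Gotoh, in C++), indel left-alignment, and
# best-reference assignment for pooled-amplicon / allele-specific runs.

#' Alignment scoring parameters
#'
#' Defaults (match 1, mismatch 4, gap open 6, gap extend 1) mirror the
#' published defaults of the mapping stage commonly used on amplicon data, so
#' mapped/unmapped behaviour is comparable. A read counts as mapped when its
#' best score reaches `min_mapped_score_fraction` of the maximum attainable
#' score (`match` times read length).
#'
#' @param match Match reward (positive integer).
#' @param mismatch Mismatch penalty (positive integer, subtracted).
#' @param gap_open Gap-opening penalty; a gap of length L costs
#'   `gap_open + gap_extend * L`.
#' @param gap_extend Per-base gap-extension penalty.
#' @param min_mapped_score_fraction Mapped-call threshold as a fraction of the
#'   maximum attainable score.
#' @return A list of class `aq_scoring`.
#' @export
scoring <- function(match = 1L, mismatch = 4L, gap_open = 6L, gap_extend = 1L,
                    min_mapped_score_fraction = 0.30) {
  stopifnot(match >= 0L, mismatch >= 0L, gap_open >= 0L, gap_extend >= 0L,
            min_mapped_score_fraction >= 0, min_mapped_score_fraction <= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_mapped_score_fraction = min_mapped_score_fraction),
            class = "aq_scoring")
}

#' Construct an alignment
#'
#' An alignment places a read on a reference: `ref_start` is the 0-based
#' offset of the first aligned reference base, `op`/`len` encode the CIGAR
#' operations (`M` aligned pair, `I` insertion in the read, `D` deletion from
#' the reference). Invariants: M+I lengths sum to the read length; adjacent
#' operations differ; no leading or trailing D; the reference footprint fits.
#'
#' @param ref_start 0-based reference offset.
#' @param score Integer alignment score.
#' @param op Character vector of operation codes in `{M, I, D}`.
#' @param len Integer vector of run lengths, parallel to `op`.
#' @return A list of class `aq_alignment`.
#' @export
aq_alignment <- function(ref_start, score, op, len) {
  structure(list(ref_start = as.integer(ref_start), score = as.integer(score),
                 op = as.character(op), len = as.integer(len)),
            class = "aq_alignment")
}

#' Check alignment structural invariants
#'
#' @param alignment An [aq_alignment()].
#' @param read_length Length of the aligned read.
#' @param ref_length Length of the reference.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_alignment <- function(alignment, read_length, ref_length) {
  op <- alignment$op; len <- alignment$len
  stopifnot(length(op) == length(len), all(len >= 1L), all(op %in% c("M", "I", "D")))
  if (length(op) > 1L && any(op[-1L] == op[-length(op)])) {
    stop("adjacent alignment operations share an op code")
  }
  if (length(op) && (op[1L] == "D" || op[length(op)] == "D")) {
    stop("alignment has a leading or trailing deletion")
  }
  if (sum(len[op != "D"]) != read_length) {
    stop("M+I operation lengths do not sum to the read length")
  }
  if (alignment$ref_start < 0L ||
      alignment$ref_start + sum(len[op != "I"]) > ref_length) {
    stop("alignment reference footprint exceeds the reference")
  }
  invisible(TRUE)
}

#' @export
print.aq_alignment <- function(x, ...) {
  cat(sprintf("<alignment: ref_start %d, score %d, CIGAR %s>\n",
              x$ref_start, x$score, cigar_string(x)))
  invisible(x)
}

#' Semi-global affine-gap alignment of a read to a reference
#'
#' Dynamic programming that is global in the read and free at both reference
#' ends: the whole read must be explained, unaligned reference flanks are not
#' penalized. A gap of length L costs `gap_open + gap_extend * L`. An N in
#' the read matches any reference base with score 0. Among co-optimal
#' alignments the traceback prefers M, then D, then I at every cell, so the
#' output is deterministic.
#'
#' @param read_seq Read sequence (uppercase, `{A,C,G,T,N}`), non-empty.
#' @param ref_seq Reference sequence (uppercase, `{A,C,G,T}`), non-empty.
#' @param params [scoring()].
#' @return A maximal-score [aq_alignment()].
#' @export
#' @examples
#' semiglobal_align("ACGGTCATAAGGCTTAA", "ACGGTCATTGCAAGGCTTAA")
semiglobal_align <- function(read_seq, ref_seq, params = scoring()) {
  res <- .semiglobal_align_cpp(read_seq, ref_seq, params$match, params$mismatch,
                               params$gap_open, params$gap_extend)
  aln <- aq_alignment(res$ref_start, res$score, res$op, res$len)
  validate_alignment(aln, nchar(read_seq), nchar(ref_seq))
  aln
}

# read sequence implied by an alignment over the reference (sanity check)
implied_read <- function(alignment, read_seq, ref_seq) {
  i <- 0L; out <- character(0L)
  for (k in seq_along(alignment$op)) {
    if (alignment$op[k] != "D") {
      out <- c(out, substr(read_seq, i + 1L, i + alignment$len[k]))
      i <- i + alignment$len[k]
    }
  }
  paste(out, collapse = "")
}

#' Left-align insertions and deletions
#'
#' Shifts every I/D run to the smallest reference coordinate that still
#' explains the read (the variant-normalization convention): a gap run moves
#' left past an aligned column as long as the read base that hops over the
#' gap matches the reference base it lands on, so a deletion settles on the
#' leftmost deletable copy of a repeat and an insertion on the leftmost
#' anchor. The implied read is unchanged and the operation is idempotent;
#' on maximal-score alignments the score is unchanged too. Canonical
#' placement makes equivalent alignments of the same edit — common on
#' repetitive references — compare equal, so signature counting groups them.
#'
#' @param alignment An [aq_alignment()] valid for the pair.
#' @param read_seq,ref_seq The aligned sequences.
#' @return The left-aligned [aq_alignment()].
#' @export
left_align_indels <- function(alignment, read_seq, ref_seq) {
  if (implied_read(alignment, read_seq, ref_seq) != read_seq) {
    stop("inconsistent alignment: operations do not reproduce the read")
  }
  op <- alignment$op
  len <- alignment$len
  ref_start <- alignment$ref_start
  rd <- seq_chars(read_seq)
  rf <- seq_chars(ref_seq)

  repeat {
    changed <- FALSE
    # read index / ref index (0-based, consumed so far) at the start of run k
    i <- 0L; r <- ref_start
    k <- 1L
    while (k <= length(op)) {
      L <- len[k]
      if (op[k] %in% c("I", "D") && k > 1L && op[k - 1L] == "M") {
        avail <- len[k - 1L]
        s <- 0L
        if (op[k] == "D") {
          # deletion at 0-based ref position r-s; the aligned column left of
          # the run hops to its right, onto ref base rf[r+L-s]: allowed while
          # the hopping read base still matches there
          while (s < avail && (i - s) >= 1L && rd[i - s] == rf[r + L - s]) s <- s + 1L
        } else {
          # insertion anchored at r-s; after a shift the run's last read base
          # becomes an aligned column on ref base rf[r-s]: allowed while they
          # match
          while (s < avail && (r - s) >= 1L && (i - s) >= 1L &&
                 rd[i + L - s] == rf[r - s]) s <- s + 1L
        }
        if (s > 0L) {
          # move s M columns from before the run to after it
          len[k - 1L] <- len[k - 1L] - s
          if (k < length(op) && op[k + 1L] == "M") {
            len[k + 1L] <- len[k + 1L] + s
          } else {
            op <- append(op, "M", after = k)
            len <- append(len, s, after = k)
          }
          if (len[k - 1L] == 0L) {
            op <- op[-(k - 1L)]
            len <- len[-(k - 1L)]
          }
          # merge any adjacent runs of the same op created by the removal
          if (length(op) > 1L) {
            merged_op <- op[1L]; merged_len <- len[1L]
            for (t in 2L:length(op)) {
              if (op[t] == merged_op[length(merged_op)]) {
                merged_len[length(merged_len)] <- merged_len[length(merged_len)] + len[t]
              } else {
                merged_op <- c(merged_op, op[t])
                merged_len <- c(merged_len, len[t])
              }
            }
            op <- merged_op; len <- merged_len
          }
          changed <- TRUE
          break
        }
      }
      if (op[k] != "D") i <- i + L
      if (op[k] != "I") r <- r + L
      k <- k + 1L
    }
    if (!changed) break
  }
  out <- aq_alignment(ref_start, alignment$score, op, len)
  validate_alignment(out, nchar(read_seq), nchar(ref_seq))
  stopifnot(implied_read(out, read_seq, ref_seq) == read_seq)
  out
}

#' Assign a read to the best-matching reference
#'
#' Aligns the read against every reference. If the best forward score falls
#' below the mapped threshold, the reverse complement is also tried and the
#' better orientation kept. The read is `unmapped` when the best score is
#' below `min_mapped_score_fraction * match * read length`, `ambiguous` when
#' two or more references tie at the best score, and otherwise `mapped` to
#' the winning reference with a left-aligned alignment.
#'
#' @param read An [aq_read()].
#' @param references List of [aq_reference()] (at least one).
#' @param params [scoring()].
#' @return A list of class `aq_assignment` with `status` in
#'   `{"mapped", "unmapped", "ambiguous"}`; when mapped, also
#'   `reference_name`, `alignment`, `strand` (`"+"` or `"-"`) and
#'   `aligned_sequence` (the read as aligned, reverse-complemented for
#'   `strand == "-"`).
#' @export
assign_to_reference <- function(read, references, params = scoring()) {
  validate_reference_set(references)
  threshold <- params$min_mapped_score_fraction * params$match * nchar(read$sequence)

  align_all <- function(seq) {
    lapply(references, function(ref) semiglobal_align(seq, ref$sequence, params))
  }
  fwd <- align_all(read$sequence)
  fwd_scores <- vapply(fwd, function(a) a$score, integer(1L))
  best_seq <- read$sequence
  best <- fwd
  best_scores <- fwd_scores
  strand <- "+"
  if (max(fwd_scores) < threshold) {
    rc <- revcomp(read$sequence)
    rev <- align_all(rc)
    rev_scores <- vapply(rev, function(a) a$score, integer(1L))
    if (max(rev_scores) > max(fwd_scores)) {
      best_seq <- rc
      best <- rev
      best_scores <- rev_scores
      strand <- "-"
    }
  }
  top <- max(best_scores)
  if (top < threshold) {
    return(structure(list(status = "unmapped"), class = "aq_assignment"))
  }
  winners <- which(best_scores == top)
  if (length(winners) >= 2L) {
    return(structure(list(status = "ambiguous"), class = "aq_assignment"))
  }
  w <- winners[1L]
  aln <- left_align_indels(best[[w]], best_seq, references[[w]]$sequence)
  structure(list(status = "mapped", reference_name = references[[w]]$name,
                 alignment = aln, strand = strand, aligned_sequence = best_seq),
            class = "aq_assignment")
}
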