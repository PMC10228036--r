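# Read quality control (sliding-window 3' trimming plus ordered filters) and
# paired-end overlap merging. Defaults mirror the widely used fastp and FLASH
# tools so behaviour on typical amplicon data is familiar.

#' Quality-control parameters
#'
#' @param window_size Sliding-window width in bases for 3' quality trimming.
#' @param window_quality Mean Phred score a trailing window must reach; the
#'   longest 3' suffix whose every trailing window falls below this is cut.
#' @param qualified_quality Per-base Phred threshold; bases below it count as
#'   unqualified for the quality filter.
#' @param max_unqualified_fraction Maximum tolerated fraction of unqualified
#'   bases before a read is dropped.
#' @param max_n_bases Maximum number of N bases tolerated per read.
#' @param min_length Minimum read length after trimming.
#' @return A list of class `aq_qc_params`.
#' @export
qc_params <- function(window_size = 4L, window_quality = 20,
                      qualified_quality = 15, max_unqualified_fraction = 0.40,
                      max_n_bases = 5L, min_length = 15L) {
  stopifnot(window_size >= 1L, window_quality >= 0, qualified_quality >= 0,
            max_unqualified_fraction >= 0, max_unqualified_fraction <= 1,
            max_n_bases >= 0L, min_length >= 0L)
  structure(list(window_size = as.integer(window_size),
                 window_quality = window_quality,
                 qualified_quality = qualified_quality,
                 max_unqualified_fraction = max_unqualified_fraction,
                 max_n_bases = as.integer(max_n_bases),
                 min_length = as.integer(min_length)),
            class = "aq_qc_params")
}

#' Trim the low-quality 3' tail of a read
#'
#' Drops the longest 3' suffix in which every trailing window — the up-to-
#' `window_size` bases ending at each suffix position, clipped at the suffix
#' start — has mean quality below `window_quality`, repeated until no such
#' suffix remains. A window reaching back into the kept prefix would dilute
#' the tail with good bases, so windows are evaluated within the candidate
#' suffix; removing one bad suffix can expose another (good bases just past
#' the cut no longer prop up its windows), hence the fixpoint iteration,
#' which also makes trimming idempotent. May return a zero-length read.
#'
#' @param read An [aq_read()].
#' @param params [qc_params()].
#' @return The trimmed read.
#' @export
trim_read <- function(read, params = qc_params()) {
  repeat {
    trimmed <- trim_tail_once(read, params)
    if (nchar(trimmed$sequence) == nchar(read$sequence)) return(trimmed)
    read <- trimmed
  }
}

trim_tail_once <- function(read, params) {
  q <- read$qualities
  n <- length(q)
  if (n == 0L) return(read)
  w <- params$window_size
  thr <- params$window_quality
  # plain_bad[j]: mean of the window ending at j (clipped at the read start)
  # is below the threshold
  cs <- cumsum(as.numeric(q))
  j <- seq_len(n)
  lo <- pmax(1L, j - w + 1L)
  win_mean <- (cs[j] - c(0, cs)[lo]) / (j - lo + 1L)
  plain_bad <- win_mean < thr
  all_bad_from <- rev(cumprod(rev(plain_bad))) > 0
  # candidate suffix starts: the clipped head window of length 1 is q[s]
  for (s in which(q < thr)) {
    head_end <- min(s + w - 2L, n)
    ok <- TRUE
    if (head_end >= s) {
      head_means <- cumsum(as.numeric(q[s:head_end])) / seq_len(head_end - s + 1L)
      ok <- all(head_means < thr)
    }
    if (ok && s + w - 1L <= n) ok <- all_bad_from[s + w - 1L]
    if (ok) {
      if (s == 1L) return(aq_read(read$id, "", integer(0L)))
      return(aq_read(read$id, substr(read$sequence, 1L, s - 1L),
                     q[seq_len(s - 1L)]))
    }
  }
  read
}

#' Filter a trimmed read
#'
#' Checks, in order: length below `min_length`; N count above `max_n_bases`;
#' fraction of bases below `qualified_quality` above
#' `max_unqualified_fraction`. The first failing check is reported.
#'
#' @param read A trimmed [aq_read()].
#' @param params [qc_params()].
#' @return `"pass"`, or the failure reason: `"length"`, `"n_bases"` or
#'   `"quality"`.
#' @export
filter_read <- function(read, params = qc_params()) {
  n <- nchar(read$sequence)
  if (n < params$min_length) return("length")
  n_count <- nchar(read$sequence) - nchar(gsub("N", "", read$sequence, fixed = TRUE))
  if (n_count > params$max_n_bases) return("n_bases")
  if (n > 0L) {
    frac <- sum(read$qualities < params$qualified_quality) / n
    if (frac > params$max_unqualified_fraction) return("quality")
  }
  "pass"
}

#' Trim and filter a batch of reads
#'
#' Applies [trim_read()] then [filter_read()] to each read and accounts for
#' every input read exactly once, so
#' `reads_in == reads_out + reads_dropped_quality + reads_dropped_n +
#' reads_dropped_length` always holds.
#'
#' @param reads List of [aq_read()].
#' @param params [qc_params()].
#' @return A list with `reads` (the surviving, trimmed reads), `report`
#'   (class `aq_qc_report`: counts `reads_in`, `reads_out`,
#'   `reads_dropped_quality`, `reads_dropped_n`, `reads_dropped_length`,
#'   `bases_trimmed`) and `kept` (logical vector over the input reads).
#' @export
qc_reads <- function(reads, params = qc_params()) {
  out <- vector("list", length(reads))
  kept <- logical(length(reads))
  dropped <- c(quality = 0L, n_bases = 0L, length = 0L)
  bases_trimmed <- 0L
  j <- 0L
  for (i in seq_along(reads)) {
    trimmed <- trim_read(reads[[i]], params)
    bases_trimmed <- bases_trimmed +
      (nchar(reads[[i]]$sequence) - nchar(trimmed$sequence))
    verdict <- filter_read(trimmed, params)
    if (verdict == "pass") {
      j <- j + 1L
      out[[j]] <- trimmed
      kept[i] <- TRUE
    } else {
      dropped[[verdict]] <- dropped[[verdict]] + 1L
    }
  }
  report <- structure(list(
    reads_in = length(reads), reads_out = j,
    reads_dropped_quality = dropped[["quality"]],
    reads_dropped_n = dropped[["n_bases"]],
    reads_dropped_length = dropped[["length"]],
    bases_trimmed = bases_trimmed), class = "aq_qc_report")
  stopifnot(report$reads_in == report$reads_out + report$reads_dropped_quality +
              report$reads_dropped_n + report$reads_dropped_length)
  list(reads = out[seq_len(j)], report = report, kept = kept)
}

#' Overlap-merging parameters
#'
#' @param min_overlap Minimum overlap length in bases considered.
#' @param max_overlap_mismatch_fraction Maximum mismatch density tolerated in
#'   a candidate overlap.
#' @return A list of class `aq_merge_params`.
#' @export
merge_params <- function(min_overlap = 10L, max_overlap_mismatch_fraction = 0.25) {
  stopifnot(min_overlap >= 1L, max_overlap_mismatch_fraction >= 0,
            max_overlap_mismatch_fraction <= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_overlap_mismatch_fraction = max_overlap_mismatch_fraction),
            class = "aq_merge_params")
}

#' Merge a read pair by 3' overlap
#'
#' Reverse-complements the second read (reversing its qualities) and scores
#' every "innie" overlap length from `min_overlap` up to the shorter read
#' length. Positions where either base is N count as matches. Candidates with
#' mismatch fraction at most `max_overlap_mismatch_fraction` compete; the
#' lowest fraction wins, ties going to the larger overlap. The merged
#' sequence is the first read's unique prefix, the overlap consensus, and the
#' second read's unique suffix. Consensus columns keep the agreeing base at
#' quality `min(60, max(q1, q2))`, or on disagreement the higher-quality base
#' at quality `|q1 - q2|` (a quality tie keeps the first read's base).
#' Read-through ("outie") layouts are not merged.
#'
#' @param r1,r2 The forward and reverse reads of a pair ([aq_read()]).
#' @param params [merge_params()].
#' @return The merged [aq_read()] (id taken from `r1`), or `NULL` when no
#'   overlap qualifies.
#' @export
merge_pair <- function(r1, r2, params = merge_params()) {
  s1 <- seq_chars(r1$sequence)
  q1 <- r1$qualities
  s2 <- seq_chars(revcomp(r2$sequence))
  q2 <- rev(r2$qualities)
  n1 <- length(s1); n2 <- length(s2)
  max_o <- min(n1, n2)
  if (max_o < params$min_overlap) return(NULL)
  best_o <- 0L
  best_frac <- Inf
  for (o in params$min_overlap:max_o) {
    a <- s1[(n1 - o + 1L):n1]
    b <- s2[1L:o]
    mism <- sum(a != b & a != "N" & b != "N")
    frac <- mism / o
    if (frac <= params$max_overlap_mismatch_fraction &&
        (frac < best_frac || (frac == best_frac && o > best_o))) {
      best_frac <- frac
      best_o <- o
    }
  }
  if (best_o == 0L) return(NULL)
  o <- best_o
  ia <- (n1 - o + 1L):n1
  ib <- 1L:o
  a <- s1[ia]; qa <- q1[ia]
  b <- s2[ib]; qb <- q2[ib]
  cons <- character(o)
  consq <- integer(o)
  agree <- a == b | a == "N" | b == "N"
  # on an N column the non-N base (if any) wins
  base_a <- ifelse(a == "N" & b != "N", b, a)
  cons[agree] <- base_a[agree]
  consq[agree] <- pmin(60L, pmax(qa, qb))[agree]
  take_a <- qa >= qb
  cons[!agree] <- ifelse(take_a[!agree], a[!agree], b[!agree])
  consq[!agree] <- abs(qa - qb)[!agree]
  tail_seq <- if (o < n2) s2[(o + 1L):n2] else character(0L)
  tail_q <- if (o < n2) q2[(o + 1L):n2] else integer(0L)
  merged_seq <- paste(c(s1[seq_len(n1 - o)], cons, tail_seq), collapse = "")
  merged_q <- c(q1[seq_len(n1 - o)], consq, tail_q)
  aq_read(r1$id, merged_seq, merged_q)
}
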