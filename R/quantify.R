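# Editing-outcome quantification: alignments -> edit events -> signatures ->
# modified/unmodified classification, signature tables and per-position
# indel/substitution profiles.

#' Edit events of an alignment
#'
#' Transcribes a left-aligned alignment into edit events in reference order:
#' one deletion per D run (position = first deleted base, 0-based), one
#' insertion per I run (position = anchor, the count of reference bases to
#' its left; sequence = the inserted read bases), and one single-base
#' substitution per mismatched M column (adjacent mismatches are not merged,
#' preserving single-base resolution for base-editor reporting). An N in the
#' read is never called a substitution.
#'
#' @param alignment A left-aligned [aq_alignment()].
#' @param read_seq,ref_seq The aligned sequences.
#' @return A data.frame with columns `kind` (`"deletion"`, `"insertion"`,
#'   `"substitution"`), `position`, `length`, `sequence`.
#' @export
extract_edits <- function(alignment, read_seq, ref_seq) {
  kind <- character(0L); position <- integer(0L)
  length_ <- integer(0L); sequence <- character(0L)
  i <- 0L
  r <- alignment$ref_start
  for (k in seq_along(alignment$op)) {
    L <- alignment$len[k]
    o <- alignment$op[k]
    if (o == "M") {
      a <- seq_chars(substr(read_seq, i + 1L, i + L))
      b <- seq_chars(substr(ref_seq, r + 1L, r + L))
      mism <- which(a != b & a != "N")
      if (length(mism)) {
        kind <- c(kind, rep("substitution", length(mism)))
        position <- c(position, r + mism - 1L)
        length_ <- c(length_, rep(1L, length(mism)))
        sequence <- c(sequence, a[mism])
      }
      i <- i + L; r <- r + L
    } else if (o == "D") {
      kind <- c(kind, "deletion")
      position <- c(position, r)
      length_ <- c(length_, L)
      sequence <- c(sequence, "")
      r <- r + L
    } else {
      kind <- c(kind, "insertion")
      position <- c(position, r)
      length_ <- c(length_, L)
      sequence <- c(sequence, substr(read_seq, i + 1L, i + L))
      i <- i + L
    }
  }
  ev <- data.frame(kind = kind, position = position, length = length_,
                   sequence = sequence, stringsAsFactors = FALSE)
  ev[order(ev$position, ev$kind, ev$length, ev$sequence), , drop = FALSE]
}

#' Quantification window around a cut site
#'
#' With no cut site the window spans the whole reference; with a cut site
#' `c` it is `[max(0, c - half_width), min(L, c + half_width))`.
#'
#' @param reference An [aq_reference()].
#' @param half_width Bases on each side of the cut site (default 10).
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
quant_window <- function(reference, half_width = 10L) {
  L <- nchar(reference$sequence)
  if (is.null(reference$cut_site)) return(c(0L, L))
  c(max(0L, reference$cut_site - as.integer(half_width)),
    min(L, reference$cut_site + as.integer(half_width)))
}

#' Classify a read as modified or unmodified
#'
#' In `indel` mode a read is modified iff it carries a deletion whose
#' footprint intersects the window, or an insertion whose anchor `p`
#' satisfies `start <= p <= end`; substitutions never count (sequencing
#' errors must not inflate editing estimates). In `base_editor` mode a
#' substitution inside the window also counts.
#'
#' @param events Edit events from [extract_edits()].
#' @param window Integer `c(start, end)`, 0-based half-open.
#' @param mode `"indel"` or `"base_editor"`.
#' @return `"modified"` or `"unmodified"`.
#' @export
classify_read <- function(events, window, mode = c("indel", "base_editor")) {
  mode <- match.arg(mode)
  if (nrow(events) == 0L) return("unmodified")
  ws <- window[1L]; we <- window[2L]
  del <- events$kind == "deletion" &
    events$position < we & (events$position + events$length) > ws
  ins <- events$kind == "insertion" &
    events$position >= ws & events$position <= we
  hit <- any(del) || any(ins)
  if (mode == "base_editor") {
    sub <- events$kind == "substitution" &
      events$position >= ws & events$position < we
    hit <- hit || any(sub)
  }
  if (hit) "modified" else "unmodified"
}

#' Signature of a read
#'
#' The canonical set of edit events a read is grouped and counted by. In
#' `indel` mode all insertions and deletions are kept wherever they fall (the
#' window governs classification, not identity) and substitutions are
#' dropped. In `base_editor` mode substitutions inside the window are also
#' kept. Events are sorted by (position, kind, length, sequence); the empty
#' signature denotes an unmodified read.
#'
#' @inheritParams classify_read
#' @return A data.frame of events in canonical order.
#' @export
signature_of <- function(events, window, mode = c("indel", "base_editor")) {
  mode <- match.arg(mode)
  keep <- events$kind %in% c("insertion", "deletion")
  if (mode == "base_editor") {
    keep <- keep | (events$kind == "substitution" &
                      events$position >= window[1L] & events$position < window[2L])
  }
  ev <- events[keep, , drop = FALSE]
  ev <- ev[order(ev$position, ev$kind, ev$length, ev$sequence), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# single-letter codes used in signature keys
kind_code <- c(deletion = "D", insertion = "I", substitution = "S")

#' Compact text key of a signature
#'
#' One token per event, `position:code:length` with the inserted or
#' substituted bases appended (`"8:D:3"`, `"6:I:2:GG"`, `"10:S:1:A"`), joined
#' by `;`. The empty signature is keyed `"WT"`.
#'
#' @param signature Event data.frame from [signature_of()].
#' @return A single string.
#' @export
signature_key <- function(signature) {
  if (nrow(signature) == 0L) return("WT")
  tok <- sprintf("%d:%s:%d", signature$position, kind_code[signature$kind],
                 signature$length)
  has_seq <- nzchar(signature$sequence)
  tok[has_seq] <- paste0(tok[has_seq], ":", signature$sequence[has_seq])
  paste(tok, collapse = ";")
}

# sort key with zero-padded coordinates so lexicographic order matches the
# canonical (position, kind, length, sequence) event order
signature_sort_key <- function(key) {
  if (key == "WT") return("")
  toks <- strsplit(key, ";", fixed = TRUE)[[1L]]
  padded <- vapply(toks, function(t) {
    f <- strsplit(t, ":", fixed = TRUE)[[1L]]
    sprintf("%08d:%s:%08d:%s", as.integer(f[1L]), f[2L], as.integer(f[3L]),
            if (length(f) >= 4L) f[4L] else "")
  }, character(1L))
  paste(padded, collapse = ";")
}

#' Parse a signature key back into events
#'
#' Inverse of [signature_key()].
#'
#' @param key Signature key string (`"WT"` for the empty signature).
#' @return Event data.frame in canonical order.
#' @export
parse_signature_key <- function(key) {
  empty <- data.frame(kind = character(0L), position = integer(0L),
                      length = integer(0L), sequence = character(0L),
                      stringsAsFactors = FALSE)
  if (is.na(key) || key == "WT" || !nzchar(key)) return(empty)
  code_kind <- c(D = "deletion", I = "insertion", S = "substitution")
  toks <- strsplit(key, ";", fixed = TRUE)[[1L]]
  rows <- lapply(toks, function(t) {
    f <- strsplit(t, ":", fixed = TRUE)[[1L]]
    if (length(f) < 3L || !f[2L] %in% names(code_kind)) {
      stop(sprintf("malformed signature token '%s'", t))
    }
    data.frame(kind = code_kind[[f[2L]]], position = as.integer(f[1L]),
               length = as.integer(f[3L]),
               sequence = if (length(f) >= 4L) f[4L] else "",
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev[order(ev$position, ev$kind, ev$length, ev$sequence), , drop = FALSE]
}

#' Tally assignments into a sample summary
#'
#' Single pass over read/assignment pairs producing conserved read
#' accounting (`total == mapped + unmapped + ambiguous`), per-reference
#' modified/unmodified counts, signature counts and per-position profiles.
#' Depth at a reference position counts every read whose alignment covers it
#' with an M or D column; deletion counts cover the deleted footprint,
#' insertion counts attach to the anchor coordinate, substitution counts to
#' the substituted base.
#'
#' @param assignments List of lists, each with elements `read` ([aq_read()])
#'   and `assignment` ([assign_to_reference()] result).
#' @param references List of [aq_reference()].
#' @param windows Named list of `c(start, end)` windows, one per reference
#'   (defaults to [quant_window()] of each reference).
#' @param mode `"indel"` or `"base_editor"`.
#' @return A list of class `aq_sample_summary`: counts `total_reads`,
#'   `mapped_reads`, `unmapped_reads`, `ambiguous_reads`, and `per_reference`
#'   — for each reference a list with `assigned`, `modified`, `unmodified`,
#'   `signatures` (named count vector, key -> reads), `representatives`
#'   (key -> list(read, alignment) of the highest-mean-quality carrier) and
#'   `profile` (per-position depth/deletion/insertion/substitution counts).
#' @export
tally <- function(assignments, references, windows = NULL,
                  mode = c("indel", "base_editor")) {
  mode <- match.arg(mode)
  validate_reference_set(references)
  nms <- reference_names(references)
  if (is.null(windows)) {
    windows <- lapply(references, quant_window)
    names(windows) <- nms
  }
  for (nm in nms) {
    w <- windows[[nm]]
    L <- nchar(reference_by_name(references, nm)$sequence)
    if (is.null(w) || w[1L] < 0L || w[1L] >= w[2L] || w[2L] > L) {
      stop(sprintf("invalid window for reference '%s'", nm))
    }
  }

  per <- stats::setNames(lapply(references, function(ref) {
    L <- nchar(ref$sequence)
    list(assigned = 0L, modified = 0L, unmodified = 0L,
         signatures = stats::setNames(integer(0L), character(0L)),
         representatives = list(),
         rep_quality = numeric(0L),
         depth = integer(L), del = integer(L), ins = integer(L), sub = integer(L))
  }), nms)

  total <- mapped <- unmapped <- ambiguous <- 0L
  for (item in assignments) {
    total <- total + 1L
    asn <- item$assignment
    if (asn$status == "unmapped") { unmapped <- unmapped + 1L; next }
    if (asn$status == "ambiguous") { ambiguous <- ambiguous + 1L; next }
    mapped <- mapped + 1L
    nm <- asn$reference_name
    ref <- reference_by_name(references, nm)
    events <- extract_edits(asn$alignment, asn$aligned_sequence, ref$sequence)
    sig <- signature_of(events, windows[[nm]], mode)
    key <- signature_key(sig)
    cls <- classify_read(events, windows[[nm]], mode)

    acc <- per[[nm]]
    acc$assigned <- acc$assigned + 1L
    if (cls == "modified") acc$modified <- acc$modified + 1L
    else acc$unmodified <- acc$unmodified + 1L
    acc$signatures[key] <- (if (key %in% names(acc$signatures))
      acc$signatures[[key]] else 0L) + 1L
    mq <- if (length(item$read$qualities)) mean(item$read$qualities) else 0
    if (!key %in% names(acc$representatives) || mq > acc$rep_quality[[key]]) {
      acc$representatives[[key]] <- list(read = item$read,
                                         alignment = asn$alignment,
                                         sequence = asn$aligned_sequence)
      acc$rep_quality[key] <- mq
    }
    # per-position profile
    span <- sum(asn$alignment$len[asn$alignment$op != "I"])
    cover <- asn$alignment$ref_start + seq_len(span)  # 1-based positions
    acc$depth[cover] <- acc$depth[cover] + 1L
    if (nrow(events)) {
      for (e in seq_len(nrow(events))) {
        p <- events$position[e]
        if (events$kind[e] == "deletion") {
          idx <- (p + 1L):(p + events$length[e])
          acc$del[idx] <- acc$del[idx] + 1L
        } else if (events$kind[e] == "insertion") {
          if (p < length(acc$ins)) acc$ins[p + 1L] <- acc$ins[p + 1L] + 1L
        } else {
          acc$sub[p + 1L] <- acc$sub[p + 1L] + 1L
        }
      }
    }
    per[[nm]] <- acc
  }

  stopifnot(total == mapped + unmapped + ambiguous)
  for (nm in nms) {
    acc <- per[[nm]]
    stopifnot(acc$assigned == acc$modified + acc$unmodified,
              sum(acc$signatures) == acc$assigned)
  }
  structure(list(total_reads = total, mapped_reads = mapped,
                 unmapped_reads = unmapped, ambiguous_reads = ambiguous,
                 mode = mode, windows = windows, per_reference = per),
            class = "aq_sample_summary")
}

#' @export
print.aq_sample_summary <- function(x, ...) {
  cat(sprintf("<sample summary: %d reads (%d mapped, %d unmapped, %d ambiguous)>\n",
              x$total_reads, x$mapped_reads, x$unmapped_reads, x$ambiguous_reads))
  for (nm in names(x$per_reference)) {
    acc <- x$per_reference[[nm]]
    cat(sprintf("  %s: %d assigned (%d modified, %d unmodified), %d signatures\n",
                nm, acc$assigned, acc$modified, acc$unmodified,
                length(acc$signatures)))
  }
  invisible(x)
}

#' Per-position indel and substitution frequencies
#'
#' @param summary An [tally()] result.
#' @param reference_name Reference to report on.
#' @return A data.frame with one row per reference position: `position`
#'   (0-based), `depth`, `deletion_count`, `insertion_count`,
#'   `substitution_count` and the corresponding fractions (0 when depth is 0).
#' @export
position_frequencies <- function(summary, reference_name) {
  if (!reference_name %in% names(summary$per_reference)) {
    stop(sprintf("unknown reference '%s'", reference_name))
  }
  acc <- summary$per_reference[[reference_name]]
  L <- length(acc$depth)
  frac <- function(count) ifelse(acc$depth > 0L, count / acc$depth, 0)
  data.frame(position = seq_len(L) - 1L, depth = acc$depth,
             deletion_count = acc$del, insertion_count = acc$ins,
             substitution_count = acc$sub,
             deletion_fraction = frac(acc$del),
             insertion_fraction = frac(acc$ins),
             substitution_fraction = frac(acc$sub))
}

#' Most frequent signatures of a reference
#'
#' @param summary A [tally()] result.
#' @param reference_name Reference to report on.
#' @param n Maximum number of rows.
#' @return A data.frame sorted by read count (descending; ties broken by
#'   canonical signature order) with columns `signature`, `reads`,
#'   `percentage` (of reads assigned to the reference). The empty signature
#'   (`"WT"`) participates like any other.
#' @export
top_signatures <- function(summary, reference_name, n = 10L) {
  stopifnot(n >= 1L)
  if (!reference_name %in% names(summary$per_reference)) {
    stop(sprintf("unknown reference '%s'", reference_name))
  }
  acc <- summary$per_reference[[reference_name]]
  if (length(acc$signatures) == 0L) {
    return(data.frame(signature = character(0L), reads = integer(0L),
                      percentage = numeric(0L), stringsAsFactors = FALSE))
  }
  keys <- names(acc$signatures)
  counts <- as.integer(acc$signatures)
  ord <- order(-counts, vapply(keys, signature_sort_key, character(1L)))
  keys <- keys[ord]; counts <- counts[ord]
  take <- seq_len(min(n, length(keys)))
  data.frame(signature = keys[take], reads = counts[take],
             percentage = 100 * counts[take] / acc$assigned,
             stringsAsFactors = FALSE)
}
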