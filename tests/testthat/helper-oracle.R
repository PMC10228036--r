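# Brute-force three-matrix affine-gap DP in plain R: the score oracle the
# compiled aligner is checked against. Global in the read, free end gaps in
# the reference; gap of length L costs open + ext * L; N in the read scores 0.
oracle_semiglobal_score <- function(read, ref, match = 1L, mismatch = 4L,
                                    open = 6L, ext = 1L) {
  rd <- strsplit(read, "")[[1L]]
  rf <- strsplit(ref, "")[[1L]]
  m <- length(rd); n <- length(rf)
  NEG <- -1e9
  M <- matrix(NEG, m + 1L, n + 1L)
  D <- matrix(NEG, m + 1L, n + 1L)
  I <- matrix(NEG, m + 1L, n + 1L)
  M[1L, ] <- 0
  for (i in 2L:(m + 1L)) {
    for (j in 1L:(n + 1L)) {
      I[i, j] <- max(M[i - 1L, j] - open - ext, D[i - 1L, j] - open - ext,
                     I[i - 1L, j] - ext)
      if (j > 1L) {
        s <- if (rd[i - 1L] == "N") 0L
             else if (rd[i - 1L] == rf[j - 1L]) match else -mismatch
        M[i, j] <- max(M[i - 1L, j - 1L], D[i - 1L, j - 1L],
                       I[i - 1L, j - 1L]) + s
        D[i, j] <- max(M[i, j - 1L] - open - ext, I[i, j - 1L] - open - ext,
                       D[i, j - 1L] - ext)
      }
    }
  }
  max(M[m + 1L, ], D[m + 1L, ], I[m + 1L, ])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# read = reference mutated by up to n_edits random substitutions/insertions/
# deletions (indels 1-3 bp)
mutate_seq <- function(seq, n_edits) {
  chars <- strsplit(seq, "")[[1L]]
  for (e in seq_len(n_edits)) {
    if (length(chars) < 5L) break
    kind <- sample(c("sub", "ins", "del"), 1L)
    if (kind == "sub") {
      p <- sample(length(chars), 1L)
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    } else if (kind == "ins") {
      p <- sample(length(chars) + 1L, 1L)
      ins <- sample(c("A", "C", "G", "T"), sample(3L, 1L), replace = TRUE)
      chars <- append(chars, ins, after = p - 1L)
    } else {
      len <- sample(3L, 1L)
      if (length(chars) > len + 2L) {
        p <- sample(length(chars) - len, 1L)
        chars <- chars[-(p:(p + len - 1L))]
      }
    }
  }
  paste(chars, collapse = "")
}

# rebuild the read from the reference and the alignment's edit events: the
# round-trip that proves the reported operations explain every read base
reconstruct_read <- function(alignment, read_seq, ref_seq) {
  events <- extract_edits(alignment, read_seq, ref_seq)
  span <- sum(alignment$len[alignment$op != "I"])
  window_seq <- substr(ref_seq, alignment$ref_start + 1L,
                       alignment$ref_start + span)
  events$position <- events$position - alignment$ref_start
  apply_signature(window_seq, events)
}
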