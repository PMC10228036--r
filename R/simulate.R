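# Seeded amplicon-read simulator with truth labels: generates reads from a
# reference carrying a known spectrum of editing outcomes under a simple
# substitution-error and truncated-normal quality model. Every other module
# is validated against its truth table.

#' Simulation specification
#'
#' Defines the editing-outcome spectrum and sequencing model for a simulated
#' sample. Fractions in `spectrum` may sum to less than 1; the remainder is
#' unedited (empty-signature) reads.
#'
#' @param reference An [aq_reference()].
#' @param spectrum List of `list(signature = <event data.frame>, fraction =
#'   <numeric>)`; signatures as produced by [signature_of()] or
#'   [parse_signature_key()].
#' @param n_reads Number of reads (pairs, for paired layout) to generate.
#' @param substitution_error_rate Per-base probability of a uniform
#'   substitution error.
#' @param quality_mean,quality_sd Per-base Phred quality model: normal with
#'   this mean and standard deviation, rounded and truncated to `[2, 41]`.
#' @param layout `"single"` or `"paired"`.
#' @param read_length Read length in bases. Single-end reads are truncated to
#'   this length (or kept whole if the edited template is shorter).
#' @param fragment_mean,fragment_sd Fragment-length model (paired layout
#'   only); fragments are clipped to the template and must fit the read
#'   length.
#' @param seed Integer RNG seed; identical specs give identical output.
#' @return A list of class `aq_sim_spec`.
#' @export
sim_spec <- function(reference, spectrum = list(), n_reads = 1000L,
                     substitution_error_rate = 0.001,
                     quality_mean = 35, quality_sd = 3,
                     layout = c("single", "paired"), read_length = 150L,
                     fragment_mean = NULL, fragment_sd = NULL, seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(inherits(reference, "aq_reference"), n_reads >= 0L,
            read_length >= 1L, substitution_error_rate >= 0,
            substitution_error_rate <= 1)
  fracs <- vapply(spectrum, function(s) s$fraction, numeric(1L))
  if (length(fracs) && (any(fracs < 0) || sum(fracs) > 1 + 1e-9)) {
    stop("spectrum fractions must be >= 0 and sum to <= 1")
  }
  if (layout == "paired" && (is.null(fragment_mean) || is.null(fragment_sd))) {
    stop("paired layout requires fragment_mean and fragment_sd")
  }
  structure(list(reference = reference, spectrum = spectrum,
                 n_reads = as.integer(n_reads),
                 substitution_error_rate = substitution_error_rate,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 layout = layout, read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 seed = as.integer(seed)),
            class = "aq_sim_spec")
}

#' Apply a signature to a reference sequence
#'
#' Builds the edited template a signature describes. Events are applied
#' right-to-left so earlier coordinates stay valid while the sequence length
#' changes; when an insertion shares its position with a deletion or
#' substitution, the insertion is applied last, placing the inserted bases
#' left of the edited reference base (the anchor convention).
#'
#' @param ref_seq Reference sequence.
#' @param signature Event data.frame (canonical order).
#' @return The edited DNA string.
#' @export
#' @examples
#' apply_signature("ACGGTCATTGCAAGGCTTAA", parse_signature_key("8:D:3"))
apply_signature <- function(ref_seq, signature) {
  if (nrow(signature) == 0L) return(ref_seq)
  L <- nchar(ref_seq)
  bad <- (signature$kind == "insertion" &
            (signature$position < 0L | signature$position > L)) |
    (signature$kind != "insertion" &
       (signature$position < 0L | signature$position + signature$length > L))
  if (any(bad)) stop("signature event outside the reference")
  ord <- order(signature$position, signature$kind != "insertion",
               decreasing = TRUE)
  out <- ref_seq
  for (e in ord) {
    p <- signature$position[e]
    if (signature$kind[e] == "deletion") {
      out <- paste0(substr(out, 1L, p),
                    substr(out, p + signature$length[e] + 1L, nchar(out)))
    } else if (signature$kind[e] == "insertion") {
      out <- paste0(substr(out, 1L, p), signature$sequence[e],
                    substr(out, p + 1L, nchar(out)))
    } else {
      out <- paste0(substr(out, 1L, p), signature$sequence[e],
                    substr(out, p + signature$length[e] + 1L, nchar(out)))
    }
  }
  out
}

# one vector of truncated-normal Phred qualities
sim_qualities <- function(n, mean, sd) {
  pmin(41L, pmax(2L, as.integer(round(stats::rnorm(n, mean, sd)))))
}

# uniform substitution errors at the given per-base rate
sim_errors <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  chars <- seq_chars(seq)
  hit <- which(stats::runif(length(chars)) < rate)
  for (h in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[h])
    chars[h] <- alt[[ceiling(stats::runif(1L) * length(alt))]]
  }
  paste(chars, collapse = "")
}

#' Simulate amplicon reads with truth labels
#'
#' Draws each read independently: outcome signature (by spectrum fraction),
#' fragment coordinates (paired layout), per-base qualities, then
#' substitution errors — one RNG stream consumed in that fixed order, so a
#' given spec (including seed) always reproduces the same sample.
#'
#' @param spec An [sim_spec()].
#' @return A list: `reads` (single layout: list of [aq_read()]; paired:
#'   list with `first` and `second` read lists) and `truth`, a data.frame
#'   with one row per read/pair: `id`, `signature` (key of the source
#'   signature, `"WT"` for unedited).
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "aq_sim_spec"))
  set.seed(spec$seed)
  ref_seq <- spec$reference$sequence
  sigs <- lapply(spec$spectrum, function(s) s$signature)
  keys <- vapply(sigs, signature_key, character(1L))
  fracs <- vapply(spec$spectrum, function(s) s$fraction, numeric(1L))
  templates <- c(lapply(sigs, function(s) apply_signature(ref_seq, s)),
                 list(ref_seq))
  keys <- c(keys, "WT")
  probs <- c(fracs, 1 - sum(fracs))
  paired <- spec$layout == "paired"
  if (paired && any(nchar(unlist(templates)) < spec$read_length)) {
    stop("paired layout: read_length exceeds an edited template length")
  }

  n <- spec$n_reads
  ids <- sprintf("sim_%06d", seq_len(n))
  truth_sig <- character(n)
  r1 <- vector("list", n)
  r2 <- if (paired) vector("list", n) else NULL
  for (i in seq_len(n)) {
    k <- if (length(probs) == 1L) 1L else
      sample.int(length(probs), 1L, prob = probs)
    truth_sig[i] <- keys[k]
    tmpl <- templates[[k]]
    if (paired) {
      flen <- NA_integer_
      for (try in seq_len(100L)) {
        cand <- as.integer(round(stats::rnorm(1L, spec$fragment_mean,
                                              spec$fragment_sd)))
        if (cand >= spec$read_length && cand <= nchar(tmpl)) { flen <- cand; break }
      }
      if (is.na(flen)) stop("could not draw a feasible fragment length in 100 tries")
      fstart <- if (nchar(tmpl) == flen) 1L else
        sample.int(nchar(tmpl) - flen + 1L, 1L)
      frag <- substr(tmpl, fstart, fstart + flen - 1L)
      s1 <- substr(frag, 1L, spec$read_length)
      s2 <- revcomp(substr(frag, flen - spec$read_length + 1L, flen))
      q1 <- sim_qualities(nchar(s1), spec$quality_mean, spec$quality_sd)
      q2 <- sim_qualities(nchar(s2), spec$quality_mean, spec$quality_sd)
      s1 <- sim_errors(s1, spec$substitution_error_rate)
      s2 <- sim_errors(s2, spec$substitution_error_rate)
      r1[[i]] <- aq_read(paste0(ids[i], "/1"), s1, q1)
      r2[[i]] <- aq_read(paste0(ids[i], "/2"), s2, q2)
    } else {
      s <- if (nchar(tmpl) > spec$read_length)
        substr(tmpl, 1L, spec$read_length) else tmpl
      q <- sim_qualities(nchar(s), spec$quality_mean, spec$quality_sd)
      s <- sim_errors(s, spec$substitution_error_rate)
      r1[[i]] <- aq_read(ids[i], s, q)
    }
  }
  truth <- data.frame(id = ids, signature = truth_sig, stringsAsFactors = FALSE)
  reads <- if (paired) list(first = r1, second = r2) else r1
  list(reads = reads, truth = truth)
}

#' Write a simulator truth table as TSV
#'
#' @param truth Truth data.frame from [simulate_reads()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SimSpec from JSON
#'
#' JSON form: fields of [sim_spec()] with `reference` an object
#' `{name, sequence, cut_site?}` and `spectrum` a list of
#' `{signature: <key>, fraction}` entries using [signature_key()] notation.
#'
#' @param path Path to the JSON file.
#' @return An [sim_spec()].
#' @export
read_sim_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  ref <- aq_reference(cfg$reference$name, cfg$reference$sequence,
                      cfg$reference$cut_site)
  spectrum <- lapply(cfg$spectrum, function(s) {
    list(signature = parse_signature_key(s$signature), fraction = s$fraction)
  })
  args <- cfg[setdiff(names(cfg), c("reference", "spectrum"))]
  do.call(sim_spec, c(list(reference = ref, spectrum = spectrum), args))
}
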