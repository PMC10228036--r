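ref20 <- "ACGGTCATTGCAAGGCTTAA"

test_that("edit events transcribe CIGAR runs and mismatched columns", {
  ident <- extract_edits(aq_alignment(0L, 20L, "M", 20L), ref20, ref20)
  expect_equal(nrow(ident), 0L)

  del <- extract_edits(aq_alignment(0L, 8L, c("M", "D", "M"), c(8L, 3L, 9L)),
                       "ACGGTCATAAGGCTTAA", ref20)
  expect_equal(del$kind, "deletion")
  expect_equal(del$position, 8L)
  expect_equal(del$length, 3L)

  ins <- extract_edits(aq_alignment(0L, 12L, c("M", "I", "M"), c(6L, 2L, 14L)),
                       "ACGGTCGGATTGCAAGGCTTAA", ref20)
  expect_equal(ins$kind, "insertion")
  expect_equal(ins$position, 6L)
  expect_equal(ins$sequence, "GG")

  # adjacent mismatches stay single-base; N columns are not substitutions
  rd <- paste0("AGTG", substr(ref20, 5L, 19L), "N")
  subs <- extract_edits(aq_alignment(0L, 0L, "M", 20L), rd, ref20)
  expect_equal(subs$kind, rep("substitution", 2L))
  expect_equal(subs$position, c(1L, 2L))
  expect_equal(subs$length, rep(1L, 2L))
  expect_equal(subs$sequence, c("G", "T"))
})

test_that("modified classification respects window intersection and mode", {
  no_events <- extract_edits(aq_alignment(0L, 20L, "M", 20L), ref20, ref20)
  expect_equal(classify_read(no_events, c(0L, 20L), "indel"), "unmodified")

  del <- parse_signature_key("8:D:3")
  expect_equal(classify_read(del, c(0L, 20L), "indel"), "modified")
  expect_equal(classify_read(del, c(12L, 20L), "indel"), "unmodified")
  expect_equal(classify_read(del, c(10L, 20L), "indel"), "modified")  # touches

  ins <- parse_signature_key("6:I:2:GG")
  expect_equal(classify_read(ins, c(6L, 10L), "indel"), "modified")
  expect_equal(classify_read(ins, c(0L, 6L), "indel"), "modified")  # anchor == end
  expect_equal(classify_read(ins, c(0L, 5L), "indel"), "unmodified")

  sub <- parse_signature_key("10:S:1:A")
  expect_equal(classify_read(sub, c(0L, 20L), "indel"), "unmodified")
  expect_equal(classify_read(sub, c(0L, 20L), "base_editor"), "modified")
  expect_equal(classify_read(sub, c(0L, 10L), "base_editor"), "unmodified")
})

test_that("signatures are canonical, mode-aware and key round-trips", {
  mixed <- rbind(parse_signature_key("8:D:3"), parse_signature_key("3:S:1:T"))
  sig_indel <- signature_of(mixed, c(0L, 20L), "indel")
  expect_equal(signature_key(sig_indel), "8:D:3")
  sig_be <- signature_of(mixed, c(0L, 20L), "base_editor")
  expect_equal(signature_key(sig_be), "3:S:1:T;8:D:3")
  # substitutions outside the window are excluded even in base-editor mode
  sig_be2 <- signature_of(mixed, c(5L, 20L), "base_editor")
  expect_equal(signature_key(sig_be2), "8:D:3")

  empty <- signature_of(mixed[0L, ], c(0L, 20L), "indel")
  expect_equal(signature_key(empty), "WT")
  expect_equal(nrow(parse_signature_key("WT")), 0L)

  key <- "6:I:2:GG;8:D:3"
  expect_equal(signature_key(parse_signature_key(key)), key)
})

make_assignment <- function(id, read_seq, ref, status = "mapped") {
  rd <- aq_read(id, read_seq, rep(35L, nchar(read_seq)))
  asn <- if (status == "mapped") {
    aln <- semiglobal_align(read_seq, ref$sequence)
    structure(list(status = "mapped", reference_name = ref$name,
                   alignment = left_align_indels(aln, read_seq, ref$sequence),
                   strand = "+", aligned_sequence = read_seq),
              class = "aq_assignment")
  } else {
    structure(list(status = status), class = "aq_assignment")
  }
  list(read = rd, assignment = asn)
}

test_that("tally conserves read accounting and groups signatures", {
  ref <- aq_reference("amp1", ref20)
  del_read <- apply_signature(ref20, parse_signature_key("8:D:3"))
  items <- c(
    lapply(1:5, function(i) make_assignment(sprintf("d%d", i), del_read, ref)),
    lapply(1:3, function(i) make_assignment(sprintf("w%d", i), ref20, ref)),
    lapply(1:2, function(i) make_assignment(sprintf("u%d", i), "TTTT",
                                            ref, status = "unmapped")))
  s <- tally(items, list(ref))
  expect_equal(s$total_reads, 10L)
  expect_equal(s$mapped_reads, 8L)
  expect_equal(s$unmapped_reads, 2L)
  acc <- s$per_reference$amp1
  expect_equal(acc$modified, 5L)
  expect_equal(acc$unmodified, 3L)
  expect_equal(acc$signatures[["8:D:3"]], 5L)
  expect_equal(acc$signatures[["WT"]], 3L)
  expect_equal(sum(acc$signatures), acc$assigned)

  empty <- tally(list(), list(ref))
  expect_equal(empty$total_reads, 0L)
  expect_equal(empty$per_reference$amp1$assigned, 0L)
})

test_that("per-position frequencies reflect deletion footprints and depth", {
  ref <- aq_reference("amp1", ref20)
  del_read <- apply_signature(ref20, parse_signature_key("8:D:3"))
  items <- c(
    lapply(1:4, function(i) make_assignment(sprintf("d%d", i), del_read, ref)),
    lapply(1:6, function(i) make_assignment(sprintf("w%d", i), ref20, ref)))
  s <- tally(items, list(ref))
  freqs <- position_frequencies(s, "amp1")
  expect_equal(nrow(freqs), 20L)
  expect_equal(freqs$depth, rep(10L, 20L))
  expect_equal(freqs$deletion_fraction[9:11], rep(0.4, 3L))  # positions 8..10
  expect_equal(freqs$deletion_fraction[-(9:11)], rep(0, 17L))
  expect_true(all(freqs$insertion_fraction == 0))
  expect_true(all(freqs$deletion_count <= freqs$depth))
  expect_error(position_frequencies(s, "nope"), "unknown")
})

test_that("top signatures rank by count with deterministic tie-breaks", {
  ref <- aq_reference("amp1", ref20)
  del_read <- apply_signature(ref20, parse_signature_key("8:D:3"))
  ins_read <- apply_signature(ref20, parse_signature_key("6:I:2:GG"))
  items <- c(
    lapply(1:6, function(i) make_assignment(sprintf("d%d", i), del_read, ref)),
    lapply(1:3, function(i) make_assignment(sprintf("i%d", i), ins_read, ref)),
    lapply(1:1, function(i) make_assignment(sprintf("w%d", i), ref20, ref)))
  s <- tally(items, list(ref))
  top <- top_signatures(s, "amp1", 2L)
  expect_equal(nrow(top), 2L)
  expect_equal(top$signature, c("8:D:3", "6:I:2:GG"))
  expect_equal(top$reads, c(6L, 3L))
  expect_equal(top$percentage, c(60, 30))

  all_rows <- top_signatures(s, "amp1", 50L)
  expect_equal(nrow(all_rows), 3L)

  # tie at equal counts: canonical order by position
  items_tie <- c(
    lapply(1:3, function(i) make_assignment(sprintf("d%d", i), del_read, ref)),
    lapply(1:3, function(i) make_assignment(sprintf("i%d", i), ins_read, ref)))
  st <- tally(items_tie, list(ref))
  tt <- top_signatures(st, "amp1", 2L)
  expect_equal(tt$signature, c("6:I:2:GG", "8:D:3"))
})

test_that("simulated spectra are recovered through align + tally", {
  ref <- fixture_reference()
  spec <- sim_spec(ref, del8_spectrum(0.30), n_reads = 400L,
                   substitution_error_rate = 0, read_length = 200L, seed = 9L)
  sim <- simulate_reads(spec)
  items <- lapply(sim$reads, function(rd) {
    list(read = rd, assignment = assign_to_reference(rd, list(ref)))
  })
  s <- tally(items, list(ref))
  realized <- sum(sim$truth$signature == "8:D:3")
  expect_equal(s$mapped_reads, 400L)
  expect_equal(s$per_reference$amp1$modified, realized)
  expect_equal(s$per_reference$amp1$signatures[["8:D:3"]], realized)
  expect_equal(s$per_reference$amp1$signatures[["WT"]], 400L - realized)
})
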