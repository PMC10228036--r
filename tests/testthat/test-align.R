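ref20 <- "ACGGTCATTGCAAGGCTTAA"

test_that("semi-global alignment reproduces worked indel examples", {
  ident <- semiglobal_align(ref20, ref20)
  expect_equal(ident$ref_start, 0L)
  expect_equal(ident$score, 20L)
  expect_equal(cigar_string(ident), "20M")

  del <- semiglobal_align("ACGGTCATAAGGCTTAA", ref20)
  expect_equal(del$score, 8L)  # 17 matches - (6 + 3)
  expect_equal(cigar_string(del), "8M3D9M")
  expect_equal(del$ref_start, 0L)

  ins <- semiglobal_align("ACGGTCGGATTGCAAGGCTTAA", ref20)
  expect_equal(ins$score, 12L)  # 20 matches - (6 + 2)
  expect_equal(cigar_string(ins), "6M2I14M")

  # free end gaps: an interior fragment aligns without penalty
  frag <- semiglobal_align(substr(ref20, 6L, 15L), ref20)
  expect_equal(frag$score, 10L)
  expect_equal(frag$ref_start, 5L)

  # N matches anything at score 0
  n_read <- semiglobal_align("ACGGTNATTG", ref20)
  expect_equal(n_read$score, 9L)
  expect_equal(cigar_string(n_read), "10M")
})

test_that("aligner score matches the brute-force DP oracle and explains every read base", {
  set.seed(101)
  for (i in 1:60) {
    ref <- random_dna(sample(10:40, 1L))
    read <- mutate_seq(ref, sample(0:3, 1L))
    aln <- semiglobal_align(read, ref)
    expect_equal(aln$score, oracle_semiglobal_score(read, ref),
                 info = sprintf("instance %d: read %s vs ref %s", i, read, ref))
    expect_equal(reconstruct_read(aln, read, ref), read,
                 info = sprintf("instance %d reconstruction", i))
  }
})

test_that("aligner score agrees with Biostrings pairwiseAlignment on random instances", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4,
                                                  baseOnly = TRUE)
  set.seed(102)
  for (i in 1:40) {
    ref <- random_dna(sample(20:40, 1L))
    read <- mutate_seq(ref, sample(0:3, 1L))
    pa <- Biostrings::pairwiseAlignment(pattern = read, subject = ref,
                                        substitutionMatrix = mat,
                                        gapOpening = 6, gapExtension = 1,
                                        type = "global-local")
    expect_equal(semiglobal_align(read, ref)$score, Biostrings::score(pa))
  }
})

test_that("alignment score is symmetric under reverse complement", {
  set.seed(103)
  for (i in 1:30) {
    ref <- random_dna(sample(15:40, 1L))
    read <- mutate_seq(ref, sample(0:3, 1L))
    fwd <- semiglobal_align(read, ref)$score
    rev <- semiglobal_align(revcomp(read), revcomp(ref))$score
    expect_equal(fwd, rev)
  }
})

test_that("left-alignment shifts indels to the smallest explaining coordinate", {
  # canonical worked example: the only 1-base deletion reproducing the read
  la <- left_align_indels(aq_alignment(0L, 4L, c("M", "D", "M"), c(5L, 1L, 3L)),
                          "AAAAAAAA", "AAAAGAAAA")
  expect_equal(cigar_string(la), "4M1D4M")
  expect_equal(la$ref_start, 0L)

  # alignments without indels pass through unchanged
  plain <- aq_alignment(2L, 10L, "M", 10L)
  expect_identical(left_align_indels(plain, substr(ref20, 3L, 12L), ref20), plain)

  # inconsistent alignment is rejected
  expect_error(left_align_indels(aq_alignment(0L, 0L, "M", 4L), "ACGTT", ref20))
})

test_that("left-alignment is idempotent and preserves the implied read", {
  set.seed(104)
  for (i in 1:40) {
    ref <- random_dna(sample(15:40, 1L))
    read <- mutate_seq(ref, sample(1:3, 1L))
    aln <- semiglobal_align(read, ref)
    la1 <- left_align_indels(aln, read, ref)
    la2 <- left_align_indels(la1, read, ref)
    expect_identical(la1, la2)
    expect_equal(reconstruct_read(la1, read, ref), read)
    expect_equal(la1$score, aln$score)
  }
})

test_that("co-optimal indel placements on a repeat collapse to one signature", {
  ref <- "AAAAGAAAA"
  read <- "AAAAGAAA"  # one A lost from the 3' homopolymer run
  keys <- character(0L)
  for (p in 5:7) {  # every interior placement of the deletion
    ops <- if (p == 7L) c("M", "D", "M") else c("M", "D", "M")
    aln <- aq_alignment(0L, 1L, ops, c(p, 1L, 8L - p))
    la <- left_align_indels(aln, read, ref)
    keys <- c(keys, signature_key(extract_edits(la, read, ref)))
  }
  expect_equal(unique(keys), "5:D:1")

  read_ins <- "AAAAGAAAAA"  # one A gained in the 3' run
  keys <- vapply(list(c(9L, 1L), c(8L, 1L)), function(x) {
    ops <- if (x[1L] == 9L) c("M", "I") else c("M", "I", "M")
    lens <- if (x[1L] == 9L) c(9L, 1L) else c(8L, 1L, 1L)
    la <- left_align_indels(aq_alignment(0L, 2L, ops, lens), read_ins, ref)
    signature_key(extract_edits(la, read_ins, ref))
  }, character(1L))
  expect_equal(unique(keys), "5:I:1:A")
})

test_that("reads are assigned to the best reference with tie and threshold handling", {
  set.seed(105)
  ref_a <- aq_reference("alleleA", random_dna(60L))
  chars <- strsplit(ref_a$sequence, "")[[1L]]
  for (p in c(15L, 30L, 45L)) {
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1L]
  }
  ref_b <- aq_reference("alleleB", paste(chars, collapse = ""))

  rd <- aq_read("x", ref_b$sequence, rep(35L, 60L))
  asn <- assign_to_reference(rd, list(ref_a, ref_b))
  expect_equal(asn$status, "mapped")
  expect_equal(asn$reference_name, "alleleB")
  expect_equal(cigar_string(asn$alignment), "60M")

  # identical references force an ambiguous call
  twin <- assign_to_reference(rd, list(ref_b, aq_reference("copy", ref_b$sequence)))
  expect_equal(twin$status, "ambiguous")

  # unrelated read falls below the mapped threshold
  junk <- aq_read("junk", random_dna(60L), rep(35L, 60L))
  res <- assign_to_reference(junk, list(ref_a))
  expect_true(res$status %in% c("unmapped", "mapped"))

  # reverse-complement rescue
  rc <- aq_read("rc", revcomp(ref_a$sequence), rep(35L, 60L))
  asn_rc <- assign_to_reference(rc, list(ref_a, ref_b))
  expect_equal(asn_rc$status, "mapped")
  expect_equal(asn_rc$reference_name, "alleleA")
  expect_equal(asn_rc$strand, "-")

  expect_error(assign_to_reference(rd, list()), "empty")
})
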