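ref20 <- "ACGGTCATTGCAAGGCTTAA"

test_that("anchored alignment projects reads onto reference coordinates", {
  ref <- aq_reference("amp1", ref20)

  # identity read: two ungapped rows of the reference width
  msa <- anchored_msa(ref, list(list(label = "WT", sequence = ref20,
                                     alignment = aq_alignment(0L, 20L, "M", 20L))))
  expect_equal(msa$labels[1L], "amp1")
  expect_equal(msa$rows, c(ref20, ref20))

  # deletion renders as gap columns over its footprint
  del_read <- apply_signature(ref20, parse_signature_key("8:D:3"))
  msa_d <- anchored_msa(ref, list(list(
    label = "del", sequence = del_read,
    alignment = aq_alignment(0L, 8L, c("M", "D", "M"), c(8L, 3L, 9L)))))
  expect_equal(nchar(msa_d$rows[2L]), 20L)
  expect_equal(substr(msa_d$rows[2L], 9L, 11L), "---")
  expect_equal(gsub("-", "", msa_d$rows[2L]), del_read)
  expect_equal(msa_d$rows[1L], ref20)

  # insertion widens the anchor column; the reference row gains a gap block
  ins_read <- apply_signature(ref20, parse_signature_key("6:I:2:GG"))
  msa_i <- anchored_msa(ref, list(list(
    label = "ins", sequence = ins_read,
    alignment = aq_alignment(0L, 12L, c("M", "I", "M"), c(6L, 2L, 14L)))))
  expect_equal(unique(nchar(msa_i$rows)), 22L)
  expect_equal(substr(msa_i$rows[1L], 7L, 8L), "--")
  expect_equal(substr(msa_i$rows[2L], 7L, 8L), "GG")
  expect_equal(gsub("-", "", msa_i$rows[1L]), ref20)
  expect_equal(gsub("-", "", msa_i$rows[2L]), ins_read)

  # mixed rows with different insertions still share one width and de-gap
  short <- substr(ref20, 6L, 15L)
  msa_m <- anchored_msa(ref, list(
    list(label = "ins", sequence = ins_read,
         alignment = aq_alignment(0L, 12L, c("M", "I", "M"), c(6L, 2L, 14L))),
    list(label = "frag", sequence = short,
         alignment = aq_alignment(5L, 10L, "M", 10L))))
  expect_equal(length(unique(nchar(msa_m$rows))), 1L)
  expect_equal(gsub("-", "", msa_m$rows[3L]), short)
})

test_that("anchored alignment FASTA round-trips rows and labels", {
  ref <- aq_reference("amp1", ref20)
  del_read <- apply_signature(ref20, parse_signature_key("8:D:3"))
  msa <- anchored_msa(ref, list(list(
    label = "8:D:3 (40.0%)", sequence = del_read,
    alignment = aq_alignment(0L, 8L, c("M", "D", "M"), c(8L, 3L, 9L)))))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "msa.fasta")
  write_msa_fasta(msa, path)
  lines <- readLines(path)
  expect_equal(lines[1L], ">amp1")
  expect_equal(lines[2L], ref20)
  expect_equal(lines[3L], ">8:D:3_(40.0%)")
  expect_equal(gsub("-", "", lines[4L]), del_read)
})

report_fixture_summary <- function(ref) {
  del_read <- apply_signature(ref$sequence, parse_signature_key("8:D:3"))
  items <- c(
    lapply(1:4, function(i) {
      rd <- aq_read(sprintf("d%d", i), del_read, rep(35L, nchar(del_read)))
      list(read = rd, assignment = assign_to_reference(rd, list(ref)))
    }),
    lapply(1:6, function(i) {
      rd <- aq_read(sprintf("w%d", i), ref$sequence, rep(35L, nchar(ref$sequence)))
      list(read = rd, assignment = assign_to_reference(rd, list(ref)))
    }))
  tally(items, list(ref))
}

test_that("report rendering writes paired figures, CSV twins and the alignment FASTA", {
  ref <- aq_reference("amp1", ref20)
  s <- report_fixture_summary(ref)
  dir <- withr::local_tempdir()
  files <- render_report(s, list(ref), dir)
  expect_true(all(file.exists(files)))
  base <- function(x) file.path(dir, x)
  needed <- c("amp1_alignment.svg", "amp1_alignment.png", "amp1_alignment.fasta",
              "amp1_alignment.csv", "amp1_reads.svg", "amp1_reads.png",
              "amp1_read_summary.csv", "amp1_frequencies.svg",
              "amp1_frequencies.png", "amp1_position_frequencies.csv")
  expect_true(all(needed %in% basename(files)))
  expect_true(all(file.info(base(needed))$size > 0L))

  # every plotted number equals a cell of its CSV twin
  rs <- utils::read.csv(base("amp1_read_summary.csv"))
  expect_equal(rs$reads[rs$category == "total"], 10L)
  expect_equal(rs$reads[rs$category == "mapped"], 10L)
  expect_equal(rs$reads[rs$category == "modified"], 4L)
  expect_equal(rs$reads[rs$category == "unmodified"], 6L)

  pf <- utils::read.csv(base("amp1_position_frequencies.csv"))
  expect_equal(nrow(pf), 20L)
  expect_equal(pf$deletion_fraction[pf$position %in% 8:10], rep(0.4, 3L))

  # alignment CSV mirrors the FASTA rows
  al <- utils::read.csv(base("amp1_alignment.csv"), colClasses = "character")
  fa <- readLines(base("amp1_alignment.fasta"))
  expect_equal(al$row, fa[seq(2L, length(fa), by = 2L)])
  expect_equal(al$label[1L], "amp1")
})

test_that("multi-reference reports add a comparison panel with matching CSV", {
  set.seed(301)
  ref_a <- aq_reference("alleleA", random_dna(60L))
  chars <- strsplit(ref_a$sequence, "")[[1L]]
  chars[c(15L, 30L, 45L)] <- vapply(c(15L, 30L, 45L), function(p) {
    setdiff(c("A", "C", "G", "T"), chars[p])[1L]
  }, character(1L))
  ref_b <- aq_reference("alleleB", paste(chars, collapse = ""))
  del_b <- apply_signature(ref_b$sequence, parse_signature_key("20:D:2"))
  items <- c(
    lapply(1:3, function(i) {
      rd <- aq_read(sprintf("a%d", i), ref_a$sequence, rep(35L, 60L))
      list(read = rd, assignment = assign_to_reference(rd, list(ref_a, ref_b)))
    }),
    lapply(1:2, function(i) {
      rd <- aq_read(sprintf("b%d", i), del_b, rep(35L, nchar(del_b)))
      list(read = rd, assignment = assign_to_reference(rd, list(ref_a, ref_b)))
    }))
  s <- tally(items, list(ref_a, ref_b))
  dir <- withr::local_tempdir()
  files <- render_report(s, list(ref_a, ref_b), dir)
  expect_true("reference_comparison.csv" %in% basename(files))
  expect_true("reference_comparison.svg" %in% basename(files))
  comp <- utils::read.csv(file.path(dir, "reference_comparison.csv"))
  expect_equal(comp$assigned[comp$reference == "alleleA"], 3L)
  expect_equal(comp$assigned[comp$reference == "alleleB"], 2L)
  expect_equal(comp$modified[comp$reference == "alleleB"], 2L)
  expect_equal(comp$modified_percent[comp$reference == "alleleB"], 100)
})

test_that("an empty run still renders the full file inventory", {
  ref <- aq_reference("amp1", ref20)
  s <- tally(list(), list(ref))
  dir <- withr::local_tempdir()
  files <- render_report(s, list(ref), dir)
  expect_true(all(file.exists(files)))
  expect_true("amp1_read_summary.csv" %in% basename(files))
  rs <- utils::read.csv(file.path(dir, "amp1_read_summary.csv"))
  expect_equal(rs$reads, rep(0L, 4L))
  pf <- utils::read.csv(file.path(dir, "amp1_position_frequencies.csv"))
  expect_equal(pf$depth, rep(0L, 20L))
  expect_equal(pf$deletion_fraction, rep(0, 20L))
})
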