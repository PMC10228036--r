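# End-to-end orchestration: QC -> (merge) -> assignment -> tally -> report,
# for amplicon / pooled / allele-specific runs and the regions-of-interest
# mode for whole-genome input. The pipeline is deterministic: identical
# inputs and parameters give identical tables and summaries.

aq_version <- function() {
  as.character(utils::packageVersion("ampliquant"))
}

log_stage <- function(fmt, ...) {
  message(sprintf(paste0("[ampliquant] ", fmt), ...))
}

qc_report_list <- function(report) {
  list(reads_in = report$reads_in, reads_out = report$reads_out,
       reads_dropped_quality = report$reads_dropped_quality,
       reads_dropped_n = report$reads_dropped_n,
       reads_dropped_length = report$reads_dropped_length,
       bases_trimmed = report$bases_trimmed)
}

summary_list <- function(summary) {
  per <- lapply(summary$per_reference, function(acc) {
    list(assigned = acc$assigned, modified = acc$modified,
         unmodified = acc$unmodified,
         signatures = as.list(acc$signatures))
  })
  list(total_reads = summary$total_reads, mapped_reads = summary$mapped_reads,
       unmapped_reads = summary$unmapped_reads,
       ambiguous_reads = summary$ambiguous_reads, per_reference = per)
}

apply_cut_sites <- function(references, cut_sites) {
  if (is.null(cut_sites) || length(cut_sites) == 0L) return(references)
  nms <- reference_names(references)
  unknown <- setdiff(names(cut_sites), nms)
  if (length(unknown)) {
    stop(sprintf("cut site given for unknown reference(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  lapply(references, function(ref) {
    if (ref$name %in% names(cut_sites)) {
      aq_reference(ref$name, ref$sequence, cut_sites[[ref$name]])
    } else ref
  })
}

# shared tail of both run modes: assignment onward
quantify_and_report <- function(reads, references, out_dir, mode, window_size,
                                top_n, score_params, write_sam_file,
                                prefilter = NULL) {
  windows <- lapply(references, quant_window, half_width = window_size)
  names(windows) <- reference_names(references)

  log_stage("aligning %d reads against %d reference(s)", length(reads),
            length(references))
  prefilter_skipped <- 0L
  assignments <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    read <- reads[[i]]
    if (!is.null(prefilter) && !prefilter_test(prefilter, read$sequence)) {
      prefilter_skipped <- prefilter_skipped + 1L
      assignments[[i]] <- list(
        read = read,
        assignment = structure(list(status = "unmapped"), class = "aq_assignment"))
      next
    }
    assignments[[i]] <- list(
      read = read,
      assignment = assign_to_reference(read, references, score_params))
  }
  summary <- tally(assignments, references, windows, mode)
  log_stage("tally: %d mapped, %d unmapped, %d ambiguous",
            summary$mapped_reads, summary$unmapped_reads,
            summary$ambiguous_reads)

  files <- render_report(summary, references, out_dir, top_n)
  for (ref in references) {
    path <- file.path(out_dir, paste0(ref$name, "_indel_types.csv"))
    utils::write.csv(top_signatures2(summary, ref$name, .Machine$integer.max),
                     path, row.names = FALSE, quote = FALSE)
    files <- c(files, path)
  }
  if (!is.null(write_sam_file)) {
    records <- lapply(assignments, function(item) {
      if (item$assignment$status == "mapped") {
        list(read = item$read, reference = item$assignment$reference_name,
             alignment = item$assignment$alignment)
      } else {
        list(read = item$read, reference = NA_character_, alignment = NULL)
      }
    })
    write_sam(records, references, write_sam_file)
    files <- c(files, write_sam_file)
  }
  list(summary = summary, files = files, prefilter_skipped = prefilter_skipped)
}

preprocess_stage <- function(fastq1, fastq2, out_dir, qc, merge,
                             gzip_merged) {
  if (!is.null(fastq2)) {
    pairs <- read_fastq(fastq1, paired_with = fastq2)
    log_stage("read %d read pairs", length(pairs$first))
    qc1 <- qc_reads(pairs$first, qc)
    qc2 <- qc_reads(pairs$second, qc)
    both <- qc1$kept & qc2$kept
    # pairs where only one mate survives QC are dropped with their mate
    k1 <- pairs$first[both]
    k2 <- pairs$second[both]
    k1 <- lapply(k1, function(r) trim_read(r, qc))
    k2 <- lapply(k2, function(r) trim_read(r, qc))
    merged <- list()
    unmerged <- 0L
    for (i in seq_along(k1)) {
      m <- merge_pair(k1[[i]], k2[[i]], merge)
      if (is.null(m)) unmerged <- unmerged + 1L
      else merged[[length(merged) + 1L]] <- m
    }
    log_stage("merged %d pairs, %d unmerged (dropped)", length(merged), unmerged)
    merged_path <- file.path(out_dir,
                             if (gzip_merged) "merged.fastq.gz" else "merged.fastq")
    write_fastq(merged, merged_path, gzip = gzip_merged)
    report <- structure(list(
      reads_in = qc1$report$reads_in + qc2$report$reads_in,
      reads_out = qc1$report$reads_out + qc2$report$reads_out,
      reads_dropped_quality = qc1$report$reads_dropped_quality +
        qc2$report$reads_dropped_quality,
      reads_dropped_n = qc1$report$reads_dropped_n + qc2$report$reads_dropped_n,
      reads_dropped_length = qc1$report$reads_dropped_length +
        qc2$report$reads_dropped_length,
      bases_trimmed = qc1$report$bases_trimmed + qc2$report$bases_trimmed),
      class = "aq_qc_report")
    list(reads = merged, qc_report = report,
         pairs_merged = length(merged), pairs_unmerged = unmerged,
         extra_files = merged_path)
  } else {
    reads <- read_fastq(fastq1)
    log_stage("read %d single-end reads", length(reads))
    qc_res <- qc_reads(reads, qc)
    log_stage("QC kept %d of %d reads", qc_res$report$reads_out,
              qc_res$report$reads_in)
    list(reads = qc_res$reads, qc_report = qc_res$report,
         pairs_merged = NULL, pairs_unmerged = NULL, extra_files = character(0L))
  }
}

#' Run the amplicon pipeline
#'
#' Quality control, optional paired-end merging (unmerged pairs are dropped
#' and counted), best-reference assignment, tallying and report rendering.
#' The same procedure serves single-amplicon, pooled-amplicon and
#' allele-specific analyses: the reference FASTA simply holds one, several,
#' or the allele sequences.
#'
#' @param fastq1 Path to the (first) FASTQ file.
#' @param reference Path to the reference FASTA, or a list of
#'   [aq_reference()].
#' @param out_dir Output directory.
#' @param fastq2 Optional mate FASTQ path (paired-end input).
#' @param cut_sites Optional named list/vector of cut sites
#'   (reference name -> 0-based position).
#' @param window_size Half-width of the quantification window around each
#'   cut site (ignored for references without one, which use the full
#'   sequence).
#' @param mode `"indel"` or `"base_editor"`.
#' @param top_n Signatures shown in the alignment view.
#' @param qc,merge,score_params Stage parameters ([qc_params()],
#'   [merge_params()], [scoring()]).
#' @param sam Also write `alignments.sam`.
#' @param gzip_merged Compress the merged-reads FASTQ.
#' @return A run summary (class `aq_run_summary`): `qc_report`,
#'   `pairs_merged`/`pairs_unmerged` (paired input only), `sample_summary`,
#'   `files` (inventory of written paths), `version`, `config`.
#' @export
run_amplicon <- function(fastq1, reference, out_dir, fastq2 = NULL,
                         cut_sites = NULL, window_size = 10L,
                         mode = c("indel", "base_editor"), top_n = 10L,
                         qc = qc_params(), merge = merge_params(),
                         score_params = scoring(), sam = FALSE,
                         gzip_merged = FALSE) {
  mode <- match.arg(mode)
  references <- if (is.character(reference)) read_fasta(reference) else reference
  validate_reference_set(references)
  references <- apply_cut_sites(references, cut_sites)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  pre <- preprocess_stage(fastq1, fastq2, out_dir, qc, merge, gzip_merged)
  res <- quantify_and_report(pre$reads, references, out_dir, mode, window_size,
                             top_n, score_params,
                             if (sam) file.path(out_dir, "alignments.sam") else NULL)

  config <- list(fastq1 = fastq1, fastq2 = fastq2,
                 reference = if (is.character(reference)) reference else "<in-memory>",
                 out_dir = out_dir, cut_sites = as.list(cut_sites),
                 window_size = window_size, mode = mode, top_n = top_n,
                 qc = unclass(qc), merge = unclass(merge),
                 scoring = unclass(score_params))
  finish_run(pre, res, out_dir, config)
}

finish_run <- function(pre, res, out_dir, config) {
  qc_json <- file.path(out_dir, "qc_report.json")
  jsonlite::write_json(qc_report_list(pre$qc_report), qc_json,
                       auto_unbox = TRUE, pretty = TRUE)
  run <- structure(list(qc_report = pre$qc_report,
                        pairs_merged = pre$pairs_merged,
                        pairs_unmerged = pre$pairs_unmerged,
                        sample_summary = res$summary,
                        prefilter_skipped = res$prefilter_skipped,
                        files = c(res$files, pre$extra_files, qc_json),
                        version = aq_version(), config = config),
                   class = "aq_run_summary")
  summary_json <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(
    list(version = run$version, qc_report = qc_report_list(pre$qc_report),
         pairs_merged = pre$pairs_merged, pairs_unmerged = pre$pairs_unmerged,
         prefilter_skipped = res$prefilter_skipped,
         sample_summary = summary_list(res$summary),
         files = run$files, config = config),
    summary_json, auto_unbox = TRUE, pretty = TRUE, null = "null")
  run$files <- c(run$files, summary_json)
  run
}

#' @export
print.aq_run_summary <- function(x, ...) {
  s <- x$sample_summary
  cat(sprintf("<run: %d reads in, %d analyzed; %d mapped, %d unmapped, %d ambiguous>\n",
              x$qc_report$reads_in, s$total_reads, s$mapped_reads,
              s$unmapped_reads, s$ambiguous_reads))
  invisible(x)
}

#' Build a k-mer prefilter over region sequences
#'
#' Indexes every k-mer of every region and of their reverse complements.
#' A read sharing no indexed k-mer cannot align well to any region and is
#' skipped without dynamic programming, which keeps the regions-of-interest
#' mode tractable on whole-genome input.
#'
#' @param regions List of [aq_reference()] (extracted regions).
#' @param k K-mer length (at least 8).
#' @return An object of class `aq_prefilter`.
#' @export
build_kmer_prefilter <- function(regions, k = 15L) {
  k <- as.integer(k)
  stopifnot(k >= 8L)
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (region in regions) {
    if (nchar(region$sequence) < k) {
      warning(sprintf("region '%s' is shorter than k = %d; it contributes no k-mers",
                      region$name, k))
      next
    }
    for (seq in c(region$sequence, revcomp(region$sequence))) {
      n <- nchar(seq)
      starts <- 1L:(n - k + 1L)
      kmers <- substring(seq, starts, starts + k - 1L)
      for (km in unique(kmers)) assign(km, TRUE, envir = index)
    }
  }
  structure(list(index = index, k = k), class = "aq_prefilter")
}

#' Test a read against a k-mer prefilter
#'
#' @param prefilter An [build_kmer_prefilter()] index.
#' @param read_seq Read sequence.
#' @return `TRUE` if the read shares at least one indexed k-mer (align it),
#'   `FALSE` if it can be skipped.
#' @export
prefilter_test <- function(prefilter, read_seq) {
  n <- nchar(read_seq)
  k <- prefilter$k
  if (n < k) return(FALSE)
  starts <- 1L:(n - k + 1L)
  kmers <- substring(read_seq, starts, starts + k - 1L)
  for (km in kmers) {
    if (exists(km, envir = prefilter$index, inherits = FALSE)) return(TRUE)
  }
  FALSE
}

#' Run the regions-of-interest pipeline on whole-genome input
#'
#' Extracts each BED region (plus `flank` bases of genomic context, clipped
#' at chromosome ends with a warning) from the genome FASTA as a reference —
#' BED column 5, when present, supplies the cut site, shifted into region
#' coordinates — then builds the k-mer prefilter and runs QC, merging,
#' assignment and per-region quantification exactly as in
#' [run_amplicon()]. Reads skipped by the prefilter count as unmapped.
#'
#' @param fastq1 Path to the (first) FASTQ file.
#' @param genome Path to the genome FASTA.
#' @param regions_bed Path to the BED file of regions of interest.
#' @param out_dir Output directory.
#' @param fastq2 Optional mate FASTQ path.
#' @param flank Bases of genomic context added on each side of a region.
#' @param kmer Prefilter k-mer length.
#' @inheritParams run_amplicon
#' @return An `aq_run_summary`, as for [run_amplicon()], with
#'   `prefilter_skipped` counting reads the prefilter excluded.
#' @export
run_wgs <- function(fastq1, genome, regions_bed, out_dir, fastq2 = NULL,
                    flank = 100L, kmer = 15L, window_size = 10L,
                    mode = c("indel", "base_editor"), top_n = 10L,
                    qc = qc_params(), merge = merge_params(),
                    score_params = scoring(), sam = FALSE,
                    gzip_merged = FALSE) {
  mode <- match.arg(mode)
  chroms <- read_fasta(genome)
  chrom_names <- reference_names(chroms)
  bed <- read_bed(regions_bed)
  missing <- setdiff(unique(bed$chrom), chrom_names)
  if (length(missing)) {
    stop(sprintf("BED chromosome(s) absent from genome: %s",
                 paste(missing, collapse = ", ")))
  }
  flank <- as.integer(flank)
  references <- vector("list", nrow(bed))
  for (i in seq_len(nrow(bed))) {
    chrom <- reference_by_name(chroms, bed$chrom[i])
    L <- nchar(chrom$sequence)
    start <- bed$start[i] - flank
    end <- bed$end[i] + flank
    if (start < 0L || end > L) {
      warning(sprintf("region '%s' plus flank exceeds chromosome '%s'; clipped",
                      bed$name[i], bed$chrom[i]))
      start <- max(0L, start)
      end <- min(L, end)
    }
    cut <- NULL
    if (!is.na(bed$cut_site[i])) {
      cut <- bed$cut_site[i] - start  # genomic -> region coordinates
      if (cut < 0L || cut > end - start) {
        stop(sprintf("region '%s': cut site %d outside the extracted region",
                     bed$name[i], bed$cut_site[i]))
      }
    }
    references[[i]] <- aq_reference(
      bed$name[i], substr(chrom$sequence, start + 1L, end), cut)
  }
  validate_reference_set(references)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  prefilter <- build_kmer_prefilter(references, kmer)
  pre <- preprocess_stage(fastq1, fastq2, out_dir, qc, merge, gzip_merged)
  res <- quantify_and_report(pre$reads, references, out_dir, mode, window_size,
                             top_n, score_params,
                             if (sam) file.path(out_dir, "alignments.sam") else NULL,
                             prefilter = prefilter)
  log_stage("prefilter skipped %d reads", res$prefilter_skipped)
  config <- list(fastq1 = fastq1, fastq2 = fastq2, genome = genome,
                 regions_bed = regions_bed, out_dir = out_dir, flank = flank,
                 kmer = kmer, window_size = window_size, mode = mode,
                 top_n = top_n, qc = unclass(qc), merge = unclass(merge),
                 scoring = unclass(score_params))
  finish_run(pre, res, out_dir, config)
}
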