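# Result rendering: reference-anchored alignment of the most frequent
# editing outcomes, read-accounting bar chart, per-position frequency plot,
# and a per-reference comparison panel for allele-specific / pooled runs.
# Figures are views; every plotted number also lands in a CSV twin.

#' Reference-anchored alignment of representative reads
#'
#' Projects per-read pairwise alignments onto reference coordinates instead
#' of re-running a multiple-sequence aligner: all rows share the same
#' reference, so the projection is exact and deterministic. The union of
#' insertion anchors across rows defines extra columns sized to the longest
#' insertion at each anchor; deletions and absent insertions render as `-`.
#'
#' @param reference An [aq_reference()].
#' @param representatives List of lists with elements `label`, `sequence`
#'   (the read as aligned) and `alignment` (left-aligned [aq_alignment()]
#'   against `reference`).
#' @return A list of class `aq_anchored_msa` with `labels` (reference first)
#'   and `rows` (equal-length gapped strings; de-gapping row 1 yields the
#'   reference, de-gapping any other row yields that representative read).
#' @export
anchored_msa <- function(reference, representatives) {
  L <- nchar(reference$sequence)
  for (rep in representatives) {
    validate_alignment(rep$alignment, nchar(rep$sequence), L)
  }
  # union of insertion anchors -> block widths
  widths <- integer(L + 1L)  # widths[a + 1] = widest insertion at anchor a
  for (rep in representatives) {
    r <- rep$alignment$ref_start
    for (k in seq_along(rep$alignment$op)) {
      o <- rep$alignment$op[k]; len <- rep$alignment$len[k]
      if (o == "I") widths[r + 1L] <- max(widths[r + 1L], len)
      if (o != "I") r <- r + len
    }
  }

  render_row <- function(seq, alignment) {
    # cells: for each anchor a in 0..L an optional insertion block, then
    # (for a < L) the base column a
    ins_cells <- rep(strrep("-", widths), 1L)[widths > 0L]
    names(ins_cells) <- which(widths > 0L) - 1L
    base_cells <- rep("-", L)
    if (!is.null(alignment)) {
      i <- 0L; r <- alignment$ref_start
      for (k in seq_along(alignment$op)) {
        o <- alignment$op[k]; len <- alignment$len[k]
        if (o == "M") {
          base_cells[(r + 1L):(r + len)] <- seq_chars(substr(seq, i + 1L, i + len))
          i <- i + len; r <- r + len
        } else if (o == "D") {
          base_cells[(r + 1L):(r + len)] <- "-"
          r <- r + len
        } else {
          frag <- substr(seq, i + 1L, i + len)
          ins_cells[[as.character(r)]] <-
            paste0(frag, strrep("-", widths[r + 1L] - len))
          i <- i + len
        }
      }
    } else {
      base_cells <- seq_chars(seq)  # reference row
    }
    out <- character(0L)
    for (a in 0L:L) {
      if (widths[a + 1L] > 0L) out <- c(out, ins_cells[[as.character(a)]])
      if (a < L) out <- c(out, base_cells[a + 1L])
    }
    paste(out, collapse = "")
  }

  rows <- c(render_row(reference$sequence, NULL),
            vapply(representatives, function(rep) {
              render_row(rep$sequence, rep$alignment)
            }, character(1L)))
  labels <- c(reference$name,
              vapply(representatives, function(rep) rep$label, character(1L)))
  stopifnot(length(unique(nchar(rows))) == 1L)
  structure(list(labels = labels, rows = rows), class = "aq_anchored_msa")
}

#' Write an anchored alignment as FASTA
#'
#' @param msa An [anchored_msa()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msa_fasta <- function(msa, path) {
  seqs <- msa$rows
  names(seqs) <- gsub("\\s+", "_", msa$labels)
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}

save_figure <- function(plot, base_path, width = 9, height = 5) {
  paths <- character(0L)
  svg_path <- paste0(base_path, ".svg")
  grDevices::svg(svg_path, width = width, height = height)
  print(plot)
  grDevices::dev.off()
  paths <- c(paths, svg_path)
  png_path <- paste0(base_path, ".png")
  grDevices::png(png_path, width = width * 100, height = height * 100,
                 res = 100, type = "cairo")
  print(plot)
  grDevices::dev.off()
  c(paths, png_path)
}

msa_plot <- function(msa, title) {
  cells <- do.call(rbind, lapply(seq_along(msa$rows), function(i) {
    chars <- seq_chars(msa$rows[i])
    data.frame(row = i, column = seq_along(chars), base = chars,
               stringsAsFactors = FALSE)
  }))
  cells$row_label <- factor(msa$labels[cells$row],
                            levels = rev(unique(msa$labels)))
  palette <- c(A = "#4daf4a", C = "#377eb8", G = "#ff7f00", T = "#e41a1c",
               N = "#999999", `-` = "#f0f0f0")
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$column, y = .data$row_label,
                                           fill = .data$base)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = palette, drop = FALSE) +
    ggplot2::labs(title = title, x = "alignment column", y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(legend.position = "bottom")
  if (nchar(msa$rows[1L]) <= 120L) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$base), size = 2)
  }
  p
}

reads_barchart <- function(counts, title) {
  df <- data.frame(category = factor(names(counts), levels = names(counts)),
                   reads = as.integer(counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$reads)) +
    ggplot2::geom_col(fill = "#377eb8") +
    ggplot2::geom_text(ggplot2::aes(label = .data$reads), vjust = -0.4, size = 3) +
    ggplot2::labs(title = title, x = NULL, y = "reads") +
    ggplot2::theme_minimal(base_size = 10)
}

frequency_plot <- function(freqs, title) {
  long <- rbind(
    data.frame(position = freqs$position, fraction = freqs$deletion_fraction,
               type = "deletion"),
    data.frame(position = freqs$position, fraction = freqs$insertion_fraction,
               type = "insertion"),
    data.frame(position = freqs$position, fraction = freqs$substitution_fraction,
               type = "substitution"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$fraction,
                                     color = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(deletion = "#e41a1c",
                                           insertion = "#377eb8",
                                           substitution = "#4daf4a")) +
    ggplot2::labs(title = title, x = "reference position (0-based)",
                  y = "fraction of covering reads") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Render per-reference figures, tables and alignment exports
#'
#' Writes, per reference: the anchored-alignment figure with its FASTA and
#' CSV, the read-accounting bar chart (total / mapped / modified /
#' unmodified) with its CSV, and the per-position frequency figure with its
#' CSV. Multi-reference runs additionally get a per-reference comparison
#' panel. All figures are written as SVG and PNG; every plotted number
#' equals a cell of the corresponding CSV.
#'
#' @param summary A [tally()] result.
#' @param references List of [aq_reference()].
#' @param out_dir Output directory (created if needed).
#' @param top_n Signatures shown in the alignment view.
#' @return Character vector of written file paths.
#' @export
render_report <- function(summary, references, out_dir, top_n = 10L) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop(sprintf("cannot create '%s'", out_dir))
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop(sprintf("output directory '%s' is not writable", out_dir))
  }
  written <- character(0L)
  emit_csv <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  for (ref in references) {
    nm <- ref$name
    acc <- summary$per_reference[[nm]]
    tops <- top_signatures2(summary, nm, top_n)
    reps <- list()
    for (i in seq_len(nrow(tops))) {
      key <- tops$signature[i]
      rep <- acc$representatives[[key]]
      if (is.null(rep)) next
      reps[[length(reps) + 1L]] <- list(
        label = sprintf("%s (%.1f%%)", key, tops$percentage[i]),
        sequence = rep$sequence, alignment = rep$alignment)
    }
    msa <- anchored_msa(ref, reps)
    base <- file.path(out_dir, nm)
    written <- c(written,
                 save_figure(msa_plot(msa, sprintf("%s: top editing outcomes", nm)),
                             paste0(base, "_alignment")),
                 write_msa_fasta(msa, paste0(base, "_alignment.fasta")),
                 emit_csv(data.frame(label = msa$labels, row = msa$rows),
                          paste0(base, "_alignment.csv")))
    counts <- c(total = summary$total_reads, mapped = summary$mapped_reads,
                modified = acc$modified, unmodified = acc$unmodified)
    written <- c(written,
                 save_figure(reads_barchart(counts, sprintf("%s: read accounting", nm)),
                             paste0(base, "_reads"), width = 5),
                 emit_csv(data.frame(category = names(counts),
                                     reads = as.integer(counts)),
                          paste0(base, "_read_summary.csv")))
    freqs <- position_frequencies(summary, nm)
    written <- c(written,
                 save_figure(frequency_plot(freqs, sprintf("%s: per-position edits", nm)),
                             paste0(base, "_frequencies")),
                 emit_csv(freqs, paste0(base, "_position_frequencies.csv")))
  }
  if (length(references) > 1L) {
    comp <- do.call(rbind, lapply(references, function(ref) {
      acc <- summary$per_reference[[ref$name]]
      data.frame(reference = ref$name, assigned = acc$assigned,
                 modified = acc$modified, unmodified = acc$unmodified,
                 modified_percent = if (acc$assigned > 0L)
                   100 * acc$modified / acc$assigned else 0)
    }))
    long <- rbind(data.frame(reference = comp$reference, reads = comp$modified,
                             class = "modified"),
                  data.frame(reference = comp$reference, reads = comp$unmodified,
                             class = "unmodified"))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$reference, y = .data$reads,
                                            fill = .data$class)) +
      ggplot2::geom_col() +
      ggplot2::scale_fill_manual(values = c(modified = "#e41a1c",
                                            unmodified = "#377eb8")) +
      ggplot2::labs(title = "Per-reference editing outcomes", x = NULL,
                    y = "assigned reads") +
      ggplot2::theme_minimal(base_size = 10)
    written <- c(written,
                 save_figure(p, file.path(out_dir, "reference_comparison"),
                             width = 5),
                 emit_csv(comp, file.path(out_dir, "reference_comparison.csv")))
  }
  written
}

# top_signatures tolerant of empty summaries (render path)
top_signatures2 <- function(summary, reference_name, n) {
  acc <- summary$per_reference[[reference_name]]
  if (is.null(acc) || length(acc$signatures) == 0L) {
    return(data.frame(signature = character(0L), reads = integer(0L),
                      percentage = numeric(0L), stringsAsFactors = FALSE))
  }
  top_signatures(summary, reference_name, n)
}
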