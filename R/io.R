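#' Read a split-signal genotyping-array export
#'
#' Reads the de-facto standard tab-delimited per-probe signal table with
#' header columns `Name`, `Chr`, `Position` and, per sample,
#' `"<sample>.Log R Ratio"` and `"<sample>.B Allele Freq"`. Positions are
#' 1-based.
#'
#' @param path file path.
#' @param max_bad_frac tolerated fraction of malformed rows (non-numeric
#'   position) before reading fails; offending rows are dropped with a
#'   warning.
#' @return Long tibble: `probe`, `chrom`, `position`, `sample`, `lrr`, `baf`,
#'   sorted by chromosome and position.
#' @export
read_signal_table <- function(path, max_bad_frac = 0.05) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("Name", "Chr", "Position")
  if (!all(need %in% names(raw))) {
    stop("signal file must have columns Name, Chr, Position", call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(raw$Position))
  bad <- !is.finite(pos)
  if (any(bad)) {
    if (mean(bad) > max_bad_frac) {
      stop(sum(bad), " malformed rows exceed the tolerated fraction", call. = FALSE)
    }
    warning("dropping ", sum(bad), " malformed row(s)", call. = FALSE)
    raw <- raw[!bad, , drop = FALSE]
    pos <- pos[!bad]
  }
  lrr_cols <- grep("\\.Log R Ratio$", names(raw), value = TRUE)
  samples <- sub("\\.Log R Ratio$", "", lrr_cols)
  if (length(samples) == 0L) stop("no '<sample>.Log R Ratio' columns found", call. = FALSE)
  out <- purrr::map_dfr(samples, function(s) {
    baf_col <- paste0(s, ".B Allele Freq")
    tibble::tibble(
      probe = as.character(raw$Name),
      chrom = as.character(raw$Chr),
      position = pos,
      sample = s,
      lrr = suppressWarnings(as.numeric(raw[[paste0(s, ".Log R Ratio")]])),
      baf = if (baf_col %in% names(raw)) {
        suppressWarnings(as.numeric(raw[[baf_col]]))
      } else NA_real_
    )
  })
  dplyr::arrange(out, .data$sample, .data$chrom, .data$position)
}

#' Write signals in the split-signal export format
#'
#' Inverse of [read_signal_table()]: writes one row per probe with per-sample
#' `"<sample>.Log R Ratio"` / `"<sample>.B Allele Freq"` column pairs. Numeric
#' round trip is exact to double-precision printing.
#'
#' @param signals long tibble with columns `probe`, `chrom`, `position`,
#'   `sample`, `lrr`, `baf`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(signals, path) {
  wide <- tidyr::pivot_wider(
    signals,
    id_cols = c("probe", "chrom", "position"),
    names_from = "sample",
    values_from = c("lrr", "baf"),
    names_glue = "{sample}.{ifelse(.value == 'lrr', 'Log R Ratio', 'B Allele Freq')}"
  )
  wide <- dplyr::arrange(wide, .data$chrom, .data$position)
  names(wide)[1:3] <- c("Name", "Chr", "Position")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Convert long signals to per-chromosome signal matrices
#'
#' @param signals long tibble as returned by [read_signal_table()].
#' @param signal which value column to spread: `"lrr"` or `"baf"`.
#' @return Named list (by chromosome) of [signal_matrix()] objects with one
#'   row per sample; probes missing for a sample are masked.
#' @export
signals_to_matrices <- function(signals, signal = c("lrr", "baf")) {
  signal <- match.arg(signal)
  chroms <- unique(signals$chrom)
  out <- lapply(chroms, function(ch) {
    sub <- signals[signals$chrom == ch, , drop = FALSE]
    tracks <- lapply(split(sub, sub$sample), function(df) {
      df <- df[order(df$position), , drop = FALSE]
      list(chrom = ch, positions = df$position, values = df[[signal]])
    })
    sm <- stack_sequences(tracks)
    sm
  })
  names(out) <- chroms
  out
}

# BED-style export: 0-based half-open intervals covering the boundary probes.
bed_intervals <- function(df) {
  dplyr::mutate(df, start_bed = .data$start_bp - 1, end_bed = .data$end_bp)
}

#' Write a segment table
#'
#' Exports segments as tab-delimited text with BED-style 0-based half-open
#' genomic intervals (`start = start_bp - 1`, `end = end_bp`); internal probe
#' indices remain 1-based inclusive.
#'
#' @param segments segment tibble (from [segment_gfl()] or with calls
#'   appended); columns beyond the standard set are carried along.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- bed_intervals(segments)
  keep <- intersect(c("sequence", "chrom", "start_bed", "end_bed", "n_probes",
                      "mean", "state", "lr", "accepted", "reason"), names(out))
  out <- out[, keep]
  names(out)[names(out) == "start_bed"] <- "start"
  names(out)[names(out) == "end_bed"] <- "end"
  names(out)[names(out) == "sequence"] <- "sample"
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write the retained-jump audit table
#'
#' @param jumps retained jump tibble (with `cutoff` where available).
#' @param data the [signal_matrix()] the jumps refer to (for positions).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jumps <- function(jumps, data, path) {
  out <- tibble::tibble(
    sample = jumps$sequence,
    chrom = data$chrom,
    position = data$positions[jumps$j],
    size = jumps$size,
    cutoff = if ("cutoff" %in% names(jumps)) jumps$cutoff else NA_real_
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a simulation truth table
#'
#' @param truth a `truth_table`.
#' @param path output path (tab-delimited: sample, chrom, BED-style start/end,
#'   CN state, LOH flag).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- bed_intervals(truth$segments)
  out <- tibble::tibble(sample = out$sequence, chrom = out$chrom,
                        start = out$start_bed, end = out$end_bed,
                        n_probes = out$n_probes, cn = out$cn, loh = out$loh)
  readr::write_tsv(out, path)
  invisible(path)
}
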