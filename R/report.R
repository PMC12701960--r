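## Tab-delimited result files.
##
## Each processed input yields three files: a peak-depth table and a
## signal table (rows = scans, columns = ions; blank cell = ion absent)
## plus a per-scan summary. Formatting is fixed (fractions 4 decimals,
## m/z 5 decimals, intensities 4-significant-digit scientific) so output
## is byte-stable for identical inputs and settings.

.fmt_intensity <- function(x) ifelse(is.na(x), "",
                                     formatC(x, format = "e", digits = 3))
.fmt_fraction <- function(x) formatC(x, format = "f", digits = 4)

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

#' Write the three-file result bundle for one input
#'
#' Emits `<stem>_<prefix>PeakDepth.txt`, `<stem>_<prefix>Signal.txt` and
#' `<stem>_<prefix>Summary.txt` (prefix `"Oxo"` for oxonium runs, `"Y"`
#' for Y-ion runs). Ion columns follow the selection order; the three
#' tables share an identical scan row set and ordering. If a target file
#' already exists it is suffixed with a timestamp and a message logged.
#'
#' @param summaries List of classified `spectrum_summary` objects.
#' @param ions The `ion_selection` that was searched.
#' @param out_dir Output directory (created if needed).
#' @param file_stem Stem naming the three files.
#' @param prefix File-name prefix, `"Oxo"` (default) or `"Y"`.
#' @return Character vector of the three paths written.
#' @export
write_bundle <- function(summaries, ions, out_dir, file_stem,
                         prefix = "Oxo") {
  if (length(summaries) == 0L) stop("no scan summaries to write",
                                    call. = FALSE)
  if (nrow(ions) == 0L) stop("empty ion selection", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  scan <- vapply(summaries, `[[`, integer(1), "scan_number")
  n <- length(scan)
  depth <- matrix("", n, nrow(ions))
  signal <- matrix("", n, nrow(ions))
  for (i in seq_len(n)) {
    m <- summaries[[i]]$matches
    j <- match(m$ion_name, ions$name)
    depth[i, j] <- as.character(m$peak_depth)
    signal[i, j] <- .fmt_intensity(m$intensity)
  }
  ion_cols <- sprintf("%s_%s", ions$name, formatC(ions$mz, format = "f",
                                                  digits = 5))
  depth_df <- data.frame(Scan = scan, depth, check.names = FALSE,
                         stringsAsFactors = FALSE)
  signal_df <- data.frame(Scan = scan, signal, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(depth_df)[-1] <- ion_cols
  names(signal_df)[-1] <- ion_cols

  summary_df <- data.frame(
    Scan = scan,
    MSLevel = vapply(summaries, `[[`, integer(1), "ms_level"),
    Activation = vapply(summaries, `[[`, character(1), "activation"),
    RetentionTimeMin = vapply(summaries, function(s)
      if (is.na(s$retention_time)) "" else .fmt_fraction(s$retention_time),
      character(1)),
    TIC = .fmt_intensity(vapply(summaries, `[[`, numeric(1), "tic")),
    IonsMatched = vapply(summaries, `[[`, integer(1), "n_matched"),
    IonsInDepthWindow = vapply(summaries, `[[`, integer(1),
                               "n_matched_in_window"),
    OxoniumTICFraction = .fmt_fraction(
      vapply(summaries, `[[`, numeric(1), "oxonium_tic_fraction")),
    LikelyGlycoSpectrum = vapply(summaries, function(s)
      isTRUE(s$likely_glyco), logical(1)),
    stringsAsFactors = FALSE
  )

  paths <- file.path(out_dir, sprintf("%s_%s%s.txt", file_stem, prefix,
                                      c("PeakDepth", "Signal", "Summary")))
  for (p in paths) if (file.exists(p)) {
    stamped <- sub("\\.txt$",
                   format(Sys.time(), "_%Y%m%d%H%M%S.txt"), p)
    message("output exists, writing ", stamped, " instead of ", p)
    paths[paths == p] <- stamped
  }
  .write_tsv(depth_df, paths[1])
  .write_tsv(signal_df, paths[2])
  .write_tsv(summary_df, paths[3])
  paths
}

#' Write the Y-ion result bundle for one input
#'
#' Same three-file layout as [write_bundle()] with Y-ion targets as
#' columns (one per label x charge x isotope) and one row per PSM scan.
#'
#' @param tables Named list (names = scan numbers) of
#'   [extract_y_ions()] result data frames.
#' @param out_dir Output directory.
#' @param file_stem Stem naming the files.
#' @return Character vector of the three paths written.
#' @export
write_y_bundle <- function(tables, out_dir, file_stem) {
  if (length(tables) == 0L) stop("no Y-ion tables to write", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  key <- function(t) sprintf("%s_z%d_M+%d", t$label, t$charge, t$isotope)
  all_cols <- unique(unlist(lapply(tables, function(t) key(t))))
  scan <- as.integer(names(tables))
  n <- length(scan)
  depth <- matrix("", n, length(all_cols))
  signal <- matrix("", n, length(all_cols))
  n_matched <- integer(n)
  for (i in seq_len(n)) {
    t <- tables[[i]]
    j <- match(key(t), all_cols)
    hit <- t$matched
    depth[i, j[hit]] <- as.character(t$peak_depth[hit])
    signal[i, j[hit]] <- .fmt_intensity(t$intensity[hit])
    n_matched[i] <- sum(hit)
  }
  depth_df <- data.frame(Scan = scan, depth, check.names = FALSE)
  signal_df <- data.frame(Scan = scan, signal, check.names = FALSE)
  names(depth_df)[-1] <- all_cols
  names(signal_df)[-1] <- all_cols
  summary_df <- data.frame(
    Scan = scan,
    YIonsSearched = vapply(tables, nrow, integer(1)),
    YIonsMatched = n_matched,
    stringsAsFactors = FALSE
  )
  paths <- file.path(out_dir, sprintf("%s_Y%s.txt", file_stem,
                                      c("PeakDepth", "Signal", "Summary")))
  .write_tsv(depth_df, paths[1])
  .write_tsv(signal_df, paths[2])
  .write_tsv(summary_df, paths[3])
  paths
}
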