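# Readers/writers for per-nucleotide probing tracks and PARIS-style
# duplex-group tables. Both are plain tab-separated text; "NA" marks
# missing counts. The package consumes already-summarized mean read
# counts per position -- producing those summaries from raw sequencing
# data is out of scope.

#' Read a per-nucleotide probing track
#'
#' Expected columns (tab-separated, with header):
#' `position` (1-based, strictly increasing), `base` (A/C/G/U),
#' `s1` (mean RNase S1 count), `v1` (mean RNase V1 count),
#' `dms` (mean DMS stop count; defined only for A/C). Positions without
#' coverage may be absent or carry `NA` counts.
#'
#' @param path file path.
#' @return A `probing_track` data.frame.
#' @export
read_track <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character",
                                         "numeric", "numeric", "numeric"),
                          na.strings = "NA", stringsAsFactors = FALSE)
  need <- c("position", "base", "s1", "v1", "dms")
  if (!identical(names(df), need))
    stop("read_track: header must be: ", paste(need, collapse = "/"))
  validate_track(df)
}

#' Validate a probing-track data.frame
#' @param df data.frame with columns position/base/s1/v1/dms.
#' @return the validated data.frame with class `probing_track`.
#' @export
validate_track <- function(df) {
  if (nrow(df) > 1L && any(diff(df$position) <= 0L)) {
    bad <- which(diff(df$position) <= 0L)[1L] + 1L
    stop(sprintf("track line %d: positions must be strictly increasing", bad))
  }
  for (col in c("s1", "v1", "dms")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0L)
      stop(sprintf("track line %d: negative %s count", bad[1L], col))
  }
  bad <- which(df$base %in% c("G", "U") & !is.na(df$dms))
  if (length(bad) > 0L)
    stop(sprintf("track line %d: DMS value on %s (DMS reads only A/C)",
                 bad[1L], df$base[bad[1L]]))
  badb <- which(!(df$base %in% c("A", "C", "G", "U", "N")))
  if (length(badb) > 0L)
    stop(sprintf("track line %d: invalid base '%s'", badb[1L], df$base[badb[1L]]))
  class(df) <- c("probing_track", "data.frame")
  df
}

#' @rdname read_track
#' @param track a `probing_track` data.frame.
#' @export
write_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a duplex-group table
#'
#' Tab-separated columns: `dataset_id`, `left_start`, `left_end`,
#' `right_start`, `right_end`, `reads`. The left span must lie strictly
#' 5' of the right span.
#'
#' @param path file path.
#' @return A `duplex_table` data.frame grouped (sorted) by `dataset_id`.
#' @export
read_duplexes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("dataset_id", "left_start", "left_end", "right_start",
            "right_end", "reads")
  if (!identical(names(df), need))
    stop("read_duplexes: header must be: ", paste(need, collapse = "/"))
  validate_duplexes(df)
}

#' Validate a duplex-group data.frame
#' @param df duplex data.frame (see [read_duplexes()]).
#' @return validated `duplex_table` sorted by dataset then position.
#' @export
validate_duplexes <- function(df) {
  for (r in seq_len(nrow(df))) {
    if (df$left_start[r] > df$left_end[r] || df$right_start[r] > df$right_end[r])
      stop(sprintf("duplex line %d: span start exceeds end", r))
    if (df$left_end[r] >= df$right_start[r])
      stop(sprintf("duplex line %d: left/right spans overlap or touch", r))
    if (df$reads[r] < 1L)
      stop(sprintf("duplex line %d: reads must be >= 1", r))
  }
  df <- df[order(df$dataset_id, df$left_start, df$right_start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("duplex_table", "data.frame")
  df
}

#' @rdname read_duplexes
#' @param duplexes a `duplex_table` data.frame.
#' @export
write_duplexes <- function(duplexes, path) {
  utils::write.table(duplexes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export one count channel as bedGraph
#'
#' Coordinates become 0-based half-open on write.
#'
#' @param track a `probing_track`.
#' @param channel one of `s1`, `v1`, `dms`.
#' @param path output path.
#' @param chrom name for column 1.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, channel = c("s1", "v1", "dms"), path,
                           chrom = "transcript") {
  channel <- match.arg(channel)
  keep <- !is.na(track[[channel]])
  lines <- sprintf("%s\t%d\t%d\t%g", chrom,
                   track$position[keep] - 1L, track$position[keep],
                   track[[channel]][keep])
  writeLines(c(sprintf("track type=bedGraph name=%s", channel), lines), path)
  invisible(path)
}

#' Read / write FASTA (single record)
#' @param path file path.
#' @return a [transcript_seq()].
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) stop("read_fasta: no FASTA header")
  id <- sub("^>\\s*", "", lines[hdr[1L]])
  id <- strsplit(id, "\\s+")[[1]][1L]
  to <- if (length(hdr) > 1L) hdr[2L] - 1L else length(lines)
  transcript_seq(id, paste(lines[(hdr[1L] + 1L):to], collapse = ""))
}

#' @rdname read_fasta
#' @param seq a [transcript_seq()].
#' @param width line width.
#' @export
write_fasta <- function(seq, path, width = 70L) {
  n <- length(seq)
  starts <- seq(1L, n, by = width)
  chunks <- substring(seq$residues, starts, pmin(starts + width - 1L, n))
  writeLines(c(sprintf(">%s", seq$id), chunks), path)
  invisible(path)
}
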