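#' Per-base numeric signal aligned to a sequence
#'
#' A `score_track` holds one numeric value per scored position of a named
#' sequence: dinucleotide-usage ratios, curvature, W/S anisotropy, SymCurv,
#' windowed edit distances.  Coordinates are 0-based: the first value refers
#' to position `start`, subsequent values to `start + step`, `start + 2*step`,
#' and so on.  Missing values (masked windows) are `NA`.
#'
#' @param seq_id Sequence identifier (bedGraph chrom field).
#' @param start 0-based offset of the first scored position.
#' @param step Spacing between scored positions in bp (>= 1).
#' @param values Numeric vector of scores; `NA` marks masked positions.
#' @param label Free-text name of the signal.
#' @return An object of class `score_track`.
#' @export
score_track <- function(seq_id, start, step, values, label = "score") {
  stopifnot(is.character(seq_id), length(seq_id) == 1L)
  start <- as.integer(start)
  step <- as.integer(step)
  if (is.na(step) || step < 1L) stop("step must be >= 1")
  if (is.na(start) || start < 0L) stop("start must be >= 0")
  structure(
    list(seq_id = seq_id, start = start, step = step,
         values = as.numeric(values), label = label),
    class = "score_track"
  )
}

#' @export
print.score_track <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<score_track> %s on %s: %d values (start=%d, step=%d)\n",
              x$label, x$seq_id, length(x$values), x$start, x$step))
  if (length(v)) {
    cat(sprintf("  range [%.4g, %.4g], mean %.4g, %d masked\n",
                min(v), max(v), mean(v), sum(is.na(x$values))))
  }
  invisible(x)
}

#' @export
length.score_track <- function(x) length(x$values)

#' @export
as.data.frame.score_track <- function(x, ...) {
  data.frame(
    seq_id = x$seq_id,
    pos = x$start + (seq_along(x$values) - 1L) * x$step,
    value = x$values,
    label = x$label,
    stringsAsFactors = FALSE
  )
}

#' 0-based positions covered by a track
#' @param track A `score_track`.
#' @return Integer vector of scored positions.
#' @export
track_positions <- function(track) {
  track$start + (seq_along(track$values) - 1L) * track$step
}

#' Write score tracks as bedGraph
#'
#' One interval per scored value, `[pos, pos + step)`, 0-based half-open as
#' the bedGraph standard requires.  Masked (`NA`) values are skipped.
#'
#' @param track A `score_track`.
#' @param path Output file.
#' @param track_line Emit a `track type=bedGraph` header line?
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, track_line = TRUE) {
  stopifnot(inherits(track, "score_track"))
  pos <- track_positions(track)
  keep <- !is.na(track$values)
  con <- file(path, "w")
  on.exit(close(con))
  if (track_line) {
    writeLines(sprintf("track type=bedGraph name=\"%s\"", track$label), con)
  }
  if (any(keep)) {
    writeLines(sprintf("%s\t%d\t%d\t%.6g", track$seq_id, pos[keep],
                       pos[keep] + track$step, track$values[keep]), con)
  }
  invisible(path)
}

#' Write feature hits as BED6
#'
#' @param hits Data frame with columns `seq_id`, `start`, `end`, `name`,
#'   `score`, `strand` (0-based half-open coordinates).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(hits, path) {
  need <- c("seq_id", "start", "end", "name", "score", "strand")
  stopifnot(all(need %in% names(hits)))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   hits$seq_id, as.integer(hits$start), as.integer(hits$end),
                   hits$name, as.integer(round(hits$score)), hits$strand)
  writeLines(lines, path)
  invisible(path)
}
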