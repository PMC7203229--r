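#' Levenshtein edit distance between two strings
#'
#' Unit-cost substitutions, insertions and deletions; symmetric in its
#' arguments.  Used as a windowed divergence measure between orthologous
#' intronic sequences.
#'
#' @param a,b Character scalars (empty strings allowed).
#' @return Integer edit distance.
#' @export
levenshtein <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  as.integer(utils::adist(a, b)[1L, 1L])
}

#' Windowed Levenshtein divergence track
#'
#' Slides a window over two equal-coordinate sequences and records the edit
#' distance between the window contents at the same offset — the linear
#' version of a divergence heat map.  Trailing partial windows are dropped.
#'
#' @param a,b Character scalars (sequences on a shared coordinate system);
#'   `a` provides the track's sequence id when named.
#' @param window Window size in bp.
#' @param step Step between window starts in bp.
#' @param seq_id Identifier for the output track.
#' @return A [score_track] with one value per window start.
#' @export
levenshtein_track <- function(a, b, window = 100L, step = 20L,
                              seq_id = "seq") {
  window <- as.integer(window)
  step <- as.integer(step)
  la <- nchar(a); lb <- nchar(b)
  if (window > la || window > lb) {
    stop("window (", window, ") exceeds a sequence length")
  }
  n <- min(la, lb)
  starts <- seq.int(1L, n - window + 1L, by = step)
  vals <- vapply(starts, function(s) {
    as.numeric(levenshtein(substr(a, s, s + window - 1L),
                           substr(b, s, s + window - 1L)))
  }, numeric(1))
  score_track(seq_id, start = 0L, step = step, values = vals,
              label = sprintf("levenshtein_w%d", window))
}
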