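#' Segment a sequence into GC-homogeneous isochores
#'
#' Recursive binary segmentation on base composition.  At each step the
#' split point maximizing the Jensen-Shannon-divergence segmentation
#' statistic `2 * N * JSD(left, right)` (natural log; `N` = informative
#' bases in the segment) between the GC compositions of the two parts is
#' taken; recursion continues while the statistic is at least `t0` and both
#' parts respect `min_length`.  The returned segments tile `[0, len)`
#' completely without overlap.  `N` bases carry no compositional
#' information and are excluded from GC counts.
#'
#' @param seq Character scalar DNA sequence.
#' @param t0 Halting parameter: minimum statistic required to accept a split.
#' @param min_length Minimum segment length in bp.
#' @param seq_id Sequence identifier for the output.
#' @return Data frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `gc_fraction`, `family` (see [classify_isochore()]).
#' @export
segment_gc <- function(seq, t0 = 100, min_length = 3000L, seq_id = "seq") {
  min_length <- as.integer(min_length)
  codes <- .seq_codes(seq)
  n <- length(codes)
  if (n < min_length) {
    warning("sequence shorter than min_length; returning a single segment")
    return(.isochore_df(seq_id, 0L, n, .gc_fraction(seq)))
  }
  is_gc <- !is.na(codes) & (codes == 2L | codes == 3L)
  informative <- !is.na(codes)
  cgc <- c(0, cumsum(is_gc))       # gc count in [0, i)
  cinf <- c(0, cumsum(informative)) # informative count in [0, i)

  h <- function(p) {  # binary entropy, nats; 0*log(0) := 0
    q <- 1 - p
    out <- numeric(length(p))
    ok <- p > 0 & p < 1
    out[ok] <- -(p[ok] * log(p[ok]) + q[ok] * log(q[ok]))
    out
  }

  segments <- list()
  recurse <- function(s, e) {  # 0-based half-open [s, e)
    len <- e - s
    lo <- s + min_length
    hi <- e - min_length
    if (hi >= lo) {
      ks <- lo:hi  # candidate boundaries (left = [s,k), right = [k,e))
      n1 <- cinf[ks + 1L] - cinf[s + 1L]
      n2 <- cinf[e + 1L] - cinf[ks + 1L]
      g1 <- cgc[ks + 1L] - cgc[s + 1L]
      g2 <- cgc[e + 1L] - cgc[ks + 1L]
      ok <- n1 > 0 & n2 > 0
      if (any(ok)) {
        ntot <- cinf[e + 1L] - cinf[s + 1L]
        ptot <- (cgc[e + 1L] - cgc[s + 1L]) / ntot
        stat <- rep(-Inf, length(ks))
        stat[ok] <- 2 * (ntot * h(ptot) -
                           n1[ok] * h(g1[ok] / n1[ok]) -
                           n2[ok] * h(g2[ok] / n2[ok]))
        best <- which.max(stat)
        if (stat[best] >= t0) {
          k <- ks[best]
          recurse(s, k)
          recurse(k, e)
          return(invisible(NULL))
        }
      }
    }
    gc <- if (cinf[e + 1L] - cinf[s + 1L] > 0) {
      (cgc[e + 1L] - cgc[s + 1L]) / (cinf[e + 1L] - cinf[s + 1L])
    } else NA_real_
    segments[[length(segments) + 1L]] <<- c(s, e, gc)
    invisible(NULL)
  }
  recurse(0L, n)
  segs <- do.call(rbind, segments)
  segs <- segs[order(segs[, 1L]), , drop = FALSE]
  .isochore_df(seq_id, segs[, 1L], segs[, 2L], segs[, 3L])
}

.isochore_df <- function(seq_id, start, end, gc) {
  data.frame(
    seq_id = seq_id,
    start = as.integer(start),
    end = as.integer(end),
    gc_fraction = gc,
    family = vapply(gc, classify_isochore, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Classify a GC fraction into an isochore family
#'
#' The GC-richest family H3 is assigned strictly above 52% GC; the lower
#' families follow configurable upper cutoffs (defaults 37/41/46/52%).
#'
#' @param gc_fraction GC fraction in \[0, 1\] (`NA` allowed, returns `NA`).
#' @param cutoffs Named upper bounds for families L1, L2, H1, H2 (ascending).
#' @return One of `"L1"`, `"L2"`, `"H1"`, `"H2"`, `"H3"`.
#' @export
classify_isochore <- function(gc_fraction,
                              cutoffs = c(L1 = 0.37, L2 = 0.41,
                                          H1 = 0.46, H2 = 0.52)) {
  if (is.na(gc_fraction)) return(NA_character_)
  if (gc_fraction < 0 || gc_fraction > 1) {
    stop("gc_fraction must lie in [0, 1]")
  }
  stopifnot(length(cutoffs) == 4L, !is.unsorted(cutoffs))
  idx <- findInterval(gc_fraction, cutoffs, left.open = TRUE) + 1L
  c(names(cutoffs), "H3")[idx]
}
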