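#' Normalized cross-correlation of two vectors
#'
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))` — cosine similarity, computed
#' without mean-centering.  Pass `center = TRUE` for the mean-centered
#' (Pearson) variant as a sensitivity check.
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @param center Subtract means first?
#' @return Value in \[-1, 1\]; `NA` with a warning when either vector has
#'   zero norm.
#' @export
norm_corr <- function(x, y, center = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (center) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0) {
    warning("zero-norm vector; normalized cross-correlation undefined")
    return(NA_real_)
  }
  sum(x * y) / sqrt(nx * ny)
}

## overlap correlation of `track` against `ref` at candidate shift s:
## track(n) is compared with ref(n - s)
.shift_corr <- function(track, ref, s, min_overlap = 0.5, center = FALSE) {
  L <- length(track)
  n0 <- max(1L, 1L + s)
  n1 <- min(L, L + s)
  if (n1 - n0 + 1L < ceiling(min_overlap * L)) return(NA_real_)
  suppressWarnings(norm_corr(track[n0:n1], ref[(n0 - s):(n1 - s)],
                             center = center))
}

#' Estimate per-track phase offsets against a reference oscillation
#'
#' For each track, searches integer shifts in `[-max_shift, +max_shift]`
#' exhaustively and reports the shift maximizing the normalized
#' cross-correlation with the reference over the overlapping span — a
#' deterministic replacement for manual curation of phase offsets.  A
#' recovered offset `s` means the track reproduces the reference delayed
#' by `s` bp.  Ties resolve to the smallest absolute shift, negative
#' first.  Tracks that are constant (zero variance) or that retain less
#' than `min_overlap` of their span at every shift are excluded with a
#' warning.
#'
#' @param tracks List of [score_track] objects (or numeric vectors) cropped
#'   to a common span.
#' @param reference The reference [score_track] (or numeric vector).
#' @param max_shift Maximum absolute shift in bp.
#' @param min_overlap Minimum retained overlap fraction.
#' @param center Use mean-centered correlation?
#' @return Data frame with `track` (index or id), `offset`, `corr`;
#'   excluded tracks carry `NA` offsets.
#' @export
estimate_phase_offsets <- function(tracks, reference, max_shift = 10L,
                                   min_overlap = 0.5, center = FALSE) {
  stopifnot(length(tracks) >= 1L)
  ref <- .track_values(reference)
  shifts <- -max_shift:max_shift
  ord <- order(abs(shifts), shifts)  # smallest |s| first, negative first
  shifts <- shifts[ord]
  res <- lapply(seq_along(tracks), function(i) {
    tv <- .track_values(tracks[[i]])
    if (length(tv) != length(ref)) {
      stop("track ", i, " length differs from the reference")
    }
    if (stats::var(tv) == 0) {
      warning("track ", i, " is constant; offset undefined")
      return(c(NA_real_, NA_real_))
    }
    cors <- vapply(shifts, function(s) {
      .shift_corr(tv, ref, s, min_overlap = min_overlap, center = center)
    }, numeric(1))
    if (all(is.na(cors))) {
      warning("track ", i, " has insufficient overlap at every shift")
      return(c(NA_real_, NA_real_))
    }
    best <- which.max(cors)            # first max in tie-break order
    c(shifts[best], cors[best])
  })
  m <- do.call(rbind, res)
  ids <- vapply(seq_along(tracks), function(i) {
    t <- tracks[[i]]
    if (inherits(t, "score_track")) t$seq_id else as.character(i)
  }, character(1))
  data.frame(track = ids, offset = as.integer(m[, 1L]), corr = m[, 2L],
             stringsAsFactors = FALSE)
}

.track_values <- function(x) {
  if (inherits(x, "score_track")) x$values else as.numeric(x)
}

## apply offsets: aligned(n) = track(n + s); positions shifted out are NA
.apply_offsets <- function(tracks, offsets) {
  lapply(seq_along(tracks), function(i) {
    tv <- .track_values(tracks[[i]])
    s <- offsets[i]
    L <- length(tv)
    out <- rep(NA_real_, L)
    n <- seq_len(L)
    src <- n + s
    ok <- src >= 1L & src <= L
    out[n[ok]] <- tv[src[ok]]
    out
  })
}

#' Consensus oscillation of aligned tracks with bootstrap CI
#'
#' Shifts each track by its estimated offset, averages per position, and
#' attaches a percentile bootstrap confidence interval obtained by
#' resampling the track set with replacement.
#'
#' @param tracks List of [score_track] objects or numeric vectors of equal
#'   length.
#' @param offsets Integer offsets as returned by
#'   [estimate_phase_offsets()] (`NA` offsets are dropped).
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param seed Integer RNG seed; the result is reproducible per seed.
#' @param conf Confidence level.
#' @return List with `mean`, `ci_low`, `ci_high` (numeric vectors; `NA`
#'   where fewer than two tracks overlap) and `n_tracks`.
#' @export
aligned_consensus <- function(tracks, offsets, n_boot = 1000L, seed = 1L,
                              conf = 0.95) {
  if (n_boot < 2L) stop("n_boot must be >= 2")
  keep <- !is.na(offsets)
  tracks <- tracks[keep]; offsets <- offsets[keep]
  if (length(tracks) < 2L) stop("need >= 2 aligned tracks")
  aligned <- do.call(rbind, .apply_offsets(tracks, offsets))
  mean_track <- colMeans(aligned, na.rm = TRUE)
  mean_track[colSums(!is.na(aligned)) < 2L] <- NA_real_
  set.seed(seed)
  k <- nrow(aligned)
  boots <- matrix(NA_real_, nrow = n_boot, ncol = ncol(aligned))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(k, k, replace = TRUE)
    boots[b, ] <- colMeans(aligned[idx, , drop = FALSE], na.rm = TRUE)
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boots, 2L, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  ci_low <- pmin(ci[1L, ], mean_track)
  ci_high <- pmax(ci[2L, ], mean_track)
  ci_low[is.na(mean_track)] <- NA_real_
  ci_high[is.na(mean_track)] <- NA_real_
  list(mean = mean_track, ci_low = ci_low, ci_high = ci_high,
       n_tracks = k)
}

#' Segment-wise mean pairwise cross-correlation of aligned tracks
#'
#' Cuts the aligned span into consecutive `segment`-bp pieces (default
#' 20-mers) and, for each piece, averages [norm_corr()] over all unordered
#' track pairs — the linear heat-map vector summarizing local phase
#' coherence.
#'
#' @param tracks List of aligned [score_track] objects or numeric vectors
#'   of equal length.
#' @param segment Segment length in positions.
#' @return Data frame with `segment_start` (0-based position offset) and
#'   `mean_corr`.
#' @export
crosscorr_heatmap <- function(tracks, segment = 20L) {
  vals <- lapply(tracks, .track_values)
  L <- unique(vapply(vals, length, integer(1)))
  if (length(L) != 1L) stop("tracks must have equal length")
  if (segment > L) stop("segment longer than the aligned span")
  n_seg <- L %/% segment
  k <- length(vals)
  pairs <- utils::combn(k, 2L)
  out <- vapply(seq_len(n_seg), function(j) {
    idx <- ((j - 1L) * segment + 1L):(j * segment)
    cs <- apply(pairs, 2L, function(p) {
      suppressWarnings(norm_corr(vals[[p[1L]]][idx], vals[[p[2L]]][idx]))
    })
    mean(cs, na.rm = TRUE)
  }, numeric(1))
  data.frame(segment_start = (seq_len(n_seg) - 1L) * segment,
             mean_corr = out)
}
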