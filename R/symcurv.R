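#' Default dinucleotide wedge table for curvature calculation
#'
#' Roll/tilt deflection angles (degrees) per dinucleotide step used by
#' [curvature_track()].  The default is a consensus-style roll-wedge set in
#' which A-tract steps (AA/TT, AT) are nearly straight and flexible
#' pyrimidine-purine steps (TA, CA/TG, CG) carry the largest roll, the
#' behaviour that reproduces classic phased-A-tract macroscopic bending
#' under vector summation.  Tilt is zero throughout and roll is symmetric
#' under reverse complement (`roll(XY) = roll(revcomp(XY))`), so a
#' curvature profile read on the reverse complement is the mirror image of
#' the forward profile.  Absolute units cancel in SymCurv ratios; the table
#' is fully configurable.
#'
#' @return Data frame with columns `dinuc`, `roll`, `tilt` (16 rows).
#' @export
wedge_table <- function() {
  roll <- c(
    AA = 0.5, AC = 3.0, AG = 2.0, AT = 1.0,
    CA = 6.0, CC = 4.5, CG = 5.5, CT = 2.0,
    GA = 4.0, GC = 5.0, GG = 4.5, GT = 3.0,
    TA = 7.0, TC = 4.0, TG = 6.0, TT = 0.5
  )
  data.frame(dinuc = names(roll), roll = unname(roll), tilt = 0,
             stringsAsFactors = FALSE)
}

#' DNA curvature track
#'
#' Computes per-base curvature as the magnitude of the vector sum of
#' per-step deflection vectors over a sliding window (default 30 bp)
#' centred on each base, divided by the window length.  Each dinucleotide
#' step contributes a roll/tilt deflection rotated by the cumulative
#' helical twist, so deflections recurring in phase with the helical repeat
#' reinforce (macroscopic bends) while isotropically distributed ones
#' cancel.  Values are non-negative, in degrees per bp.
#'
#' @param seq Character scalar DNA sequence.
#' @param model List with `wedge` (data frame as [wedge_table()]), `twist`
#'   (degrees per step) and `window` (bp).
#' @param seq_id Sequence id for the output track.
#' @return A [score_track]; positions without a full window are not scored,
#'   windows containing non-ACGT bases score `NA`.
#' @export
curvature_track <- function(seq,
                            model = list(wedge = wedge_table(),
                                         twist = 34.3, window = 30L),
                            seq_id = "seq") {
  win <- as.integer(model$window)
  len <- nchar(seq)
  if (len < win + 2L) stop("sequence shorter than the curvature window")
  codes <- .seq_codes(seq)
  n_steps <- len - 1L
  a <- codes[-len]; b <- codes[-1L]
  dinuc_idx <- 4L * (a - 1L) + b            # NA-safe: NA propagates
  wedge <- model$wedge
  key <- match(wedge$dinuc,
               paste0(rep(c("A", "C", "G", "T"), each = 4L),
                      rep(c("A", "C", "G", "T"), 4L)))
  roll <- numeric(16L); tilt <- numeric(16L)
  roll[key] <- wedge$roll; tilt[key] <- wedge$tilt
  phi <- (seq_len(n_steps) - 1L) * model$twist * pi / 180
  r <- roll[dinuc_idx]; t <- tilt[dinuc_idx]
  vx <- r * cos(phi) - t * sin(phi)
  vy <- r * sin(phi) + t * cos(phi)
  cx <- c(0, cumsum(ifelse(is.na(vx), 0, vx)))
  cy <- c(0, cumsum(ifelse(is.na(vy), 0, vy)))
  cna <- c(0L, cumsum(is.na(vx)))
  # even-extent handling: the `win`-bp window centred at base n covers the
  # `win` dinucleotide steps between bases n - win/2 .. n + win/2, so the
  # window is exactly symmetric about n
  half <- win %/% 2L
  centers <- half:(len - 1L - half)         # 0-based scored positions
  s0 <- centers - half + 1L                 # first step index (1-based)
  s1 <- centers + half                      # last step index
  sx <- cx[s1 + 1L] - cx[s0]
  sy <- cy[s1 + 1L] - cy[s0]
  bad <- (cna[s1 + 1L] - cna[s0]) > 0L
  vals <- sqrt(sx^2 + sy^2) / win
  vals[bad] <- NA_real_
  score_track(seq_id, start = centers[1L], step = 1L, values = vals,
              label = "curvature")
}

#' Mirror-symmetry component of SymCurv
#'
#' Sums the reciprocal absolute differences between curvature values at
#' mirrored flank positions `n - i` and `n + i` for `i = 1..m`; each
#' difference is floored at `epsilon` so a perfectly symmetric profile
#' scores `m / epsilon`.
#'
#' @param curv A [score_track] of curvature values (step 1).
#' @param n 0-based sequence position at which to evaluate.
#' @param m Flank half-width in bp (default 25).
#' @param epsilon Floor for absolute differences.
#' @return Numeric symmetry score.
#' @export
s_sym <- function(curv, n, m = 25L, epsilon = 1e-6) {
  idx <- .track_index(curv, n)
  v <- curv$values
  if (idx - m < 1L || idx + m > length(v)) {
    stop("position ", n, " lacks full +/-", m, " support in the track")
  }
  d <- abs(v[idx - seq_len(m)] - v[idx + seq_len(m)])
  sum(1 / pmax(d, epsilon))
}

#' Local-minimum convexity component of SymCurv
#'
#' Reciprocal of the discrete second difference
#' `Curv[n-1] + Curv[n+1] - 2 Curv[n]`, positive exactly at strict local
#' curvature minima.  A zero second difference (flat profile) is replaced
#' by `1/epsilon` with positive sign and flagged.  The alternative reading
#' of the denominator as the first-difference asymmetry
#' `Curv[n-1] - Curv[n+1]` is available via `mode = "first_difference"`.
#'
#' @param curv A [score_track] of curvature values (step 1).
#' @param n 0-based sequence position.
#' @param epsilon Replacement scale for a degenerate denominator.
#' @param mode `"second_difference"` (default) or `"first_difference"`.
#' @return Numeric convexity score (signed).
#' @export
s_min <- function(curv, n, epsilon = 1e-6,
                  mode = c("second_difference", "first_difference")) {
  mode <- match.arg(mode)
  idx <- .track_index(curv, n)
  v <- curv$values
  if (idx < 2L || idx > length(v) - 1L) {
    stop("position ", n, " lacks +/-1 neighbours in the track")
  }
  den <- if (mode == "second_difference") {
    v[idx - 1L] + v[idx + 1L] - 2 * v[idx]
  } else {
    v[idx - 1L] - v[idx + 1L]
  }
  if (is.na(den)) return(NA_real_)
  if (den == 0) {
    message("note: degenerate (flat) curvature at position ", n,
            "; s_min capped at 1/epsilon")
    return(1 / epsilon)
  }
  out <- 1 / den
  if (abs(out) > 1 / epsilon) out <- sign(out) / epsilon
  out
}

.track_index <- function(track, n) {
  idx <- (as.integer(n) - track$start) %/% track$step + 1L
  if ((as.integer(n) - track$start) %% track$step != 0L ||
      idx < 1L || idx > length(track$values)) {
    stop("position ", n, " is not scored by the track")
  }
  idx
}

#' Predict the nucleosome dyad of a sequence by SymCurv
#'
#' Candidate dyads are strict local curvature minima
#' (`Curv[n] < Curv[n-1]` and `Curv[n] <= Curv[n+1]`; the leftmost wins a
#' flat tie) with full `+/-m` flank support; the candidate maximizing
#' `SymCurv = s_sym * s_min` is returned.  Deterministic: exact SymCurv
#' ties resolve to the leftmost position.
#'
#' @param curv A [score_track] of curvature values (step 1).
#' @param m Flank half-width for [s_sym()].
#' @param epsilon Floor/replacement scale for both components.
#' @param smin_mode Passed to [s_min()].
#' @return List with `position` (0-based bp, `NA` if no admissible
#'   minimum), `symcurv_score`, `s_sym`, `s_min`, and a `candidates` data
#'   frame of all scored local minima.
#' @export
predict_dyad <- function(curv, m = 25L, epsilon = 1e-6,
                         smin_mode = "second_difference") {
  v <- curv$values
  if (length(v) < 2L * m + 3L) stop("track too short for +/-", m, " flanks")
  interior <- 2L:(length(v) - 1L)
  is_min <- !is.na(v[interior]) & !is.na(v[interior - 1L]) &
    !is.na(v[interior + 1L]) &
    v[interior] < v[interior - 1L] & v[interior] <= v[interior + 1L]
  cand_idx <- interior[is_min]
  cand_idx <- cand_idx[cand_idx - m >= 1L & cand_idx + m <= length(v)]
  no_dyad <- list(position = NA_integer_, symcurv_score = NA_real_,
                  s_sym = NA_real_, s_min = NA_real_,
                  candidates = data.frame(position = integer(),
                                          symcurv_score = numeric()))
  if (!length(cand_idx)) return(no_dyad)
  pos <- curv$start + (cand_idx - 1L) * curv$step
  ssym <- vapply(pos, function(p) s_sym(curv, p, m = m, epsilon = epsilon),
                 numeric(1))
  smin <- vapply(pos, function(p) {
    suppressMessages(s_min(curv, p, epsilon = epsilon, mode = smin_mode))
  }, numeric(1))
  sc <- ssym * smin
  ok <- !is.na(sc)
  if (!any(ok)) return(no_dyad)
  pos <- pos[ok]; ssym <- ssym[ok]; smin <- smin[ok]; sc <- sc[ok]
  best <- which(sc == max(sc))[1L]           # leftmost on ties
  list(position = pos[best], symcurv_score = sc[best],
       s_sym = ssym[best], s_min = smin[best],
       candidates = data.frame(position = pos, symcurv_score = sc))
}

#' Superhelical location of a position relative to a dyad
#'
#' Expresses `position - dyad` in helical turns and rounds to the nearest
#' half turn, the conventional SHL coordinate (SHL 0 at the dyad).
#'
#' @param position 0-based bp position.
#' @param dyad 0-based dyad position.
#' @param helical_repeat Helical repeat in bp.
#' @return Half-integer SHL value.
#' @export
shl_of <- function(position, dyad, helical_repeat = 10.3) {
  delta <- position - dyad
  if (abs(delta) > 7.5 * helical_repeat) {
    stop("position lies outside the nucleosomal span of the dyad")
  }
  round(2 * delta / helical_repeat) / 2
}

#' SHL occupancy profile of a feature across sequences
#'
#' For each sequence, the two half-integer SHL bins bracketing the midpoint
#' of its feature interval receive one count each (a feature midpoint
#' falling exactly on a bin contributes to the bins half a turn either
#' side); counts are summed over sequences.  The result is the radial
#' occupancy profile of the feature on the nucleosome.
#'
#' @param dyads Named list (by `seq_id`) of dyad positions (0-based bp).
#' @param features Data frame with columns `seq_id`, `start`, `end`
#'   (0-based half-open feature intervals).
#' @param helical_repeat Helical repeat in bp.
#' @return Data frame with `shl` (-7 to +7 by 0.5) and integer `count`;
#'   counts sum to twice the number of scored sequences.
#' @export
shl_occupancy_profile <- function(dyads, features, helical_repeat = 10.3) {
  bins <- seq(-7, 7, by = 0.5)
  counts <- setNames(integer(length(bins)), as.character(bins))
  for (i in seq_len(nrow(features))) {
    sid <- features$seq_id[i]
    dyad <- dyads[[sid]]
    if (is.null(dyad) || is.na(dyad)) {
      warning("no dyad call for ", sid, "; skipped")
      next
    }
    mid <- (features$start[i] + features$end[i]) / 2
    x <- (mid - dyad) / helical_repeat
    lo <- floor(2 * x) / 2
    hi <- lo + 0.5
    if (lo == x) {                  # midpoint exactly on a bin: take the
      lo <- x - 0.5                 # bins half a turn either side
      hi <- x + 0.5
    }
    if (lo < bins[1L] || hi > bins[length(bins)]) {
      warning("feature midpoint outside the nucleosomal span for ", sid,
              "; skipped")
      next
    }
    counts[as.character(lo)] <- counts[as.character(lo)] + 1L
    counts[as.character(hi)] <- counts[as.character(hi)] + 1L
  }
  data.frame(shl = bins, count = unname(counts))
}
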