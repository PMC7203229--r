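#' Dinucleotide class ratios of a 40-mer
#'
#' A 40-bp window is read as 20 non-overlapping dinucleotide frames.  For
#' each dinucleotide type the observed frame frequency (count / 20) is
#' divided by the expected frequency 1/16 = 0.0625 of any given type under
#' equiprobable bases.  The S class sums these observed/expected ratios over
#' the flexible, nucleosome-core-favouring types {GG, CC, CG}; the W class
#' over the rigid boundary types {AA, TT}.  Both classes are bounded by 16
#' (20/20 / 0.0625) and their sum never exceeds 16.
#'
#' @param window40 Character scalar of length exactly 40.
#' @param expected Expected per-type frame frequency (default `0.0625`).
#' @param mask_n_fraction Windows with more than this fraction of `N` bases
#'   score `NA` for both classes.
#' @return Named numeric vector `c(s_class=, w_class=)`; `NA`s when masked.
#' @export
dinuc_class_ratio <- function(window40, expected = 0.0625,
                              mask_n_fraction = 0.10) {
  if (nchar(window40) != 40L) stop("window must be exactly 40 bp")
  codes <- .seq_codes(window40)
  if (mean(is.na(codes)) > mask_n_fraction) {
    return(c(s_class = NA_real_, w_class = NA_real_))
  }
  .dinuc_class_from_codes(codes, expected)
}

## codes: integer codes of a 40-mer; returns the two class scores
.dinuc_class_from_codes <- function(codes, expected = 0.0625) {
  first <- codes[seq(1L, 39L, by = 2L)]
  second <- codes[seq(2L, 40L, by = 2L)]
  ok <- !is.na(first) & !is.na(second)
  # dinucleotide index 1..16 = 4*(first-1) + second
  dinuc <- 4L * (first[ok] - 1L) + second[ok]
  # A=1 C=2 G=3 T=4: GG=11, CC=6, CG=7, AA=1, TT=16
  s_cnt <- sum(dinuc == 11L | dinuc == 6L | dinuc == 7L)
  w_cnt <- sum(dinuc == 1L | dinuc == 16L)
  c(s_class = (s_cnt / 20) / expected, w_class = (w_cnt / 20) / expected)
}

#' Nucleosome-favouring dinucleotide usage tracks
#'
#' Evaluates [dinuc_class_ratio()] on 40-bp windows starting every `step`
#' bp over a sequence, yielding the paired S-class (GG/CC/CG) and W-class
#' (AA/TT) usage maps.  `step = 1` gives the smooth sliding map; `step = 40`
#' gives the strict consecutive-40-mer reading.
#'
#' @param seq Character scalar DNA sequence (length >= 40).
#' @param step Window start spacing in bp.
#' @param seq_id Sequence id for the output tracks.
#' @param mask_n_fraction Passed to [dinuc_class_ratio()].
#' @return List with [score_track] elements `s_class` and `w_class`.
#' @export
dinuc_usage_tracks <- function(seq, step = 1L, seq_id = "seq",
                               mask_n_fraction = 0.10) {
  n <- nchar(seq)
  if (n < 40L) stop("sequence shorter than the 40-bp window")
  step <- as.integer(step)
  codes <- .seq_codes(seq)
  starts <- seq.int(1L, n - 39L, by = step)
  m <- vapply(starts, function(s) {
    w <- codes[s:(s + 39L)]
    if (mean(is.na(w)) > mask_n_fraction) {
      c(NA_real_, NA_real_)
    } else {
      .dinuc_class_from_codes(w)
    }
  }, numeric(2))
  list(
    s_class = score_track(seq_id, start = starts[1L] - 1L, step = step,
                          values = m[1L, ], label = "dinuc_s_class"),
    w_class = score_track(seq_id, start = starts[1L] - 1L, step = step,
                          values = m[2L, ], label = "dinuc_w_class")
  )
}

#' Default groove-site offset table for W/S scoring
#'
#' Signed offsets (bp from the dyad) of the 14 minor-groove and 12
#' major-groove contact sites of the 147-bp nucleosomal frame under a
#' 10.3-bp helical repeat: minor sites at `±round(10.3 i + 5.15)` for
#' `i = 0..6`, major sites at `±round(10.3 i)` for `i = 1..6`.
#'
#' @param helical_repeat Helical repeat in bp.
#' @param frame Nucleosomal frame extent in bp.
#' @return List with integer vectors `minor_offsets` (14), `major_offsets`
#'   (12) and the `frame` width.
#' @export
groove_site_table <- function(helical_repeat = 10.3, frame = 147L) {
  minor <- round(helical_repeat * (0:6) + helical_repeat / 2)
  major <- round(helical_repeat * (1:6))
  tbl <- list(
    minor_offsets = as.integer(sort(c(-minor, minor))),
    major_offsets = as.integer(sort(c(-major, major))),
    frame = as.integer(frame)
  )
  validate_groove_sites(tbl)
  tbl
}

#' Validate a groove-site table
#'
#' Checks the 14-minor/12-major cardinality, the frame bound, and that the
#' two site sets are disjoint.
#'
#' @param sites List as returned by [groove_site_table()].
#' @return `sites`, invisibly; errors when invalid.
#' @export
validate_groove_sites <- function(sites) {
  if (length(sites$minor_offsets) != 14L) stop("need exactly 14 minor sites")
  if (length(sites$major_offsets) != 12L) stop("need exactly 12 major sites")
  half <- sites$frame / 2
  offs <- c(sites$minor_offsets, sites$major_offsets)
  if (any(abs(offs) > half)) stop("site offset outside the nucleosomal frame")
  if (length(intersect(sites$minor_offsets, sites$major_offsets))) {
    stop("minor and major site sets overlap")
  }
  invisible(sites)
}

## start position (relative to the dyad) of the dinucleotide scored at a
## signed site offset: outward-pointing on both sides of the dyad
.outward <- function(offsets) ifelse(offsets < 0L, offsets - 1L, offsets)

## WW = {AA,AT,TA,TT} -> both codes in {1,4}; SS -> both in {2,3}
.ws_class_vector <- function(codes) {
  n <- length(codes)
  a <- codes[-n]
  b <- codes[-1L]
  w <- (a == 1L | a == 4L) & (b == 1L | b == 4L)
  s <- (a == 2L | a == 3L) & (b == 2L | b == 3L)
  cls <- integer(n - 1L)           # 0 = neither / masked
  cls[which(w)] <- 1L
  cls[which(s)] <- -1L
  cls
}

#' W/S rotational anisotropy score at one dyad position
#'
#' Counts WW dinucleotides (AA/AT/TA/TT) at minor-groove sites and SS
#' dinucleotides (GG/GC/CG/CC) at major-groove sites of the 147-bp frame
#' centred at `n`, minus the out-of-phase combinations:
#' `S = sum_minor C_WW + sum_major C_SS - sum_minor C_SS - sum_major C_WW`.
#' Each site contributes via a single dinucleotide pointing outward from
#' the dyad (starting at `dyad + offset` for positive offsets, ending
#' there for negative ones), so the covered base set is mirror-symmetric
#' and the track of a reverse complement is the reversed track.  The
#' score is bounded by \[-26, +26\].
#'
#' @param seq Character scalar DNA sequence.
#' @param n 0-based dyad position.
#' @param sites Groove-site table ([groove_site_table()]).
#' @return Numeric score, or `NA` when the frame leaves the sequence.
#' @export
ws_score_at <- function(seq, n, sites = groove_site_table()) {
  codes <- .seq_codes(seq)
  cls <- .ws_class_vector(codes)
  .ws_score_codes(cls, length(codes), as.integer(n), sites)
}

.ws_score_codes <- function(cls, len, n, sites) {
  half <- floor(sites$frame / 2)
  if (n - half < 0L || n + half > len - 1L) return(NA_real_)
  # site dinucleotides point outward from the dyad: a site at offset o > 0
  # starts at dyad + o, a site at o < 0 ends at dyad + o, so the covered
  # base set is mirror-symmetric about the dyad
  mi <- n + .outward(sites$minor_offsets) + 1L
  ma <- n + .outward(sites$major_offsets) + 1L
  if (any(mi < 1L) || any(mi > length(cls)) ||
      any(ma < 1L) || any(ma > length(cls))) {
    return(NA_real_)
  }
  sum(cls[mi] == 1L) + sum(cls[ma] == -1L) -
    sum(cls[mi] == -1L) - sum(cls[ma] == 1L)
}

#' W/S anisotropy track over a sequence
#'
#' [ws_score_at()] evaluated at every position admitting the full 147-bp
#' frame, sliding by 1 bp.
#'
#' @param seq Character scalar DNA sequence (length >= frame).
#' @param sites Groove-site table.
#' @param seq_id Sequence id for the output track.
#' @return A [score_track].
#' @export
ws_track <- function(seq, sites = groove_site_table(), seq_id = "seq") {
  len <- nchar(seq)
  if (len < sites$frame) stop("sequence shorter than the nucleosomal frame")
  codes <- .seq_codes(seq)
  cls <- .ws_class_vector(codes)
  half <- floor(sites$frame / 2)
  centers <- half:(len - 1L - half)
  # vectorized: for each site offset add the in/out-of-phase indicator
  vals <- numeric(length(centers))
  for (off in .outward(sites$minor_offsets)) {
    idx <- centers + off + 1L
    vals <- vals + (cls[idx] == 1L) - (cls[idx] == -1L)
  }
  for (off in .outward(sites$major_offsets)) {
    idx <- centers + off + 1L
    vals <- vals + (cls[idx] == -1L) - (cls[idx] == 1L)
  }
  score_track(seq_id, start = centers[1L], step = 1L, values = vals,
              label = "ws_anisotropy")
}

#' Expected genomic spacing of a k-mer
#'
#' Under an equiprobable i.i.d. background a given k-mer recurs on average
#' every `4^k` bp — e.g. 4096 bp for the 6-mer seed of a miRNA.
#'
#' @param k k-mer length.
#' @return Expected spacing in bp.
#' @export
expected_kmer_spacing <- function(k) 4^as.integer(k)
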