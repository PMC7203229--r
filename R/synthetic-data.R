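#' Generate an i.i.d. background sequence at a chosen GC fraction
#'
#' Bases are drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`; fully reproducible per seed.
#'
#' @param length Sequence length in bp (>= 1).
#' @param gc GC fraction in (0, 1\].
#' @param seed Integer RNG seed.
#' @return Character scalar DNA sequence.
#' @export
gen_background <- function(length, gc = 0.5, seed = 1L) {
  if (!(gc > 0 && gc <= 1)) stop("gc must lie in (0, 1]")
  if (length < 1L) stop("length must be >= 1")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Plant a sequence signal into a background
#'
#' Overwrites part of a background sequence with one of the signal classes
#' the detectors in this package look for, and returns the modified
#' sequence together with a ground-truth record:
#'
#' * `"nps"` — a G/C-rich core (default 80 bp) flanked by rigid poly-A /
#'   poly-T boundary tracts.
#' * `"ws_oscillation"` — WW dinucleotides forced at the minor-groove
#'   offsets and SS dinucleotides at the major-groove offsets of the
#'   default groove-site table, around `position + phase`.
#' * `"curvature_symmetry"` — the downstream flank is overwritten with the
#'   reverse complement of the upstream flank (mirror superhelical
#'   symmetry about the dyad), with a straight A/T tract and a fixed
#'   high-roll boundary step that carve a curvature minimum at the dyad.
#' * `"motif_cluster"` — `n_sites` sequences sampled from a PWM placed at
#'   regular `spacing`.
#' * `"mirhr"` — a copy of `query` with exactly `k` substitutions placed
#'   outside the consensus substring; `strand = "-"` plants the reverse
#'   complement.
#'
#' @param seq Background character sequence.
#' @param spec List with `kind`, `position` (0-based anchor) and
#'   kind-specific parameters (`core`, `boundary`; `phase`; `flank`;
#'   `pwm`, `n_sites`, `spacing`; `query`, `k`, `strand`, `consensus`).
#' @param seed Integer RNG seed.
#' @return List with `seq` (modified sequence) and `ground_truth` (one-row
#'   data frame: `kind`, `start`, `end`, `position`, `params`).
#' @export
plant_signal <- function(seq, spec, seed = 1L) {
  set.seed(seed)
  kind <- match.arg(spec$kind, c("nps", "ws_oscillation",
                                 "curvature_symmetry", "motif_cluster",
                                 "mirhr"))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- as.integer(spec$position)
  put <- function(at0, piece) {  # at0: 0-based start
    idx <- at0 + seq_len(nchar(piece))
    if (min(idx) < 1L || max(idx) > length(chars)) {
      stop("planted interval outside sequence bounds")
    }
    chars[idx] <<- strsplit(piece, "", fixed = TRUE)[[1]]
  }
  gt_start <- NA_integer_; gt_end <- NA_integer_; params <- ""

  if (kind == "nps") {
    core <- if (is.null(spec$core)) 80L else as.integer(spec$core)
    boundary <- if (is.null(spec$boundary)) 20L else as.integer(spec$boundary)
    piece <- paste0(strrep("A", boundary),
                    paste(sample(c("G", "C"), core, replace = TRUE),
                          collapse = ""),
                    strrep("T", boundary))
    put(pos, piece)
    gt_start <- pos; gt_end <- pos + nchar(piece)
    params <- sprintf("core=%d;boundary=%d", core, boundary)
  } else if (kind == "ws_oscillation") {
    phase <- if (is.null(spec$phase)) 0L else as.integer(spec$phase)
    sites <- if (is.null(spec$sites)) groove_site_table() else spec$sites
    ww <- c("AA", "AT", "TA", "TT"); ss <- c("GG", "GC", "CG", "CC")
    out <- function(off) if (off < 0L) off - 1L else off  # outward site
    for (off in sites$minor_offsets) {
      put(pos + phase + out(off), sample(ww, 1L))
    }
    for (off in sites$major_offsets) {
      put(pos + phase + out(off), sample(ss, 1L))
    }
    gt_start <- pos + phase + min(sites$minor_offsets)
    gt_end <- pos + phase + max(sites$minor_offsets) + 2L
    params <- sprintf("phase=%d", phase)
  } else if (kind == "curvature_symmetry") {
    flank <- if (is.null(spec$flank)) 60L else as.integer(spec$flank)
    stopifnot(flank > 16L)
    # straight A/T valley: A^14 [A] T^14, with a high-roll CA step at the
    # upstream valley boundary (mirrored to TG downstream)
    put(pos - 16L, paste0("CA", strrep("A", 14L)))
    chars[pos + 1L] <- "A"
    # mirror: s[pos + i] = complement(s[pos - i]) for i = 1..flank
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    up <- chars[pos + 1L - seq_len(flank)]
    chars[(pos + 1L) + seq_len(flank)] <- unname(comp[up])
    gt_start <- pos - flank; gt_end <- pos + flank + 1L
    params <- sprintf("flank=%d", flank)
  } else if (kind == "motif_cluster") {
    stopifnot(!is.null(spec$pwm))
    n_sites <- if (is.null(spec$n_sites)) 5L else as.integer(spec$n_sites)
    spacing <- if (is.null(spec$spacing)) 30L else as.integer(spec$spacing)
    L <- ncol(spec$pwm$probs)
    for (s in seq_len(n_sites)) {
      site <- paste(apply(spec$pwm$probs, 2L, function(p) {
        sample(c("A", "C", "G", "T"), 1L, prob = p)
      }), collapse = "")
      put(pos + (s - 1L) * spacing, site)
    }
    gt_start <- pos; gt_end <- pos + (n_sites - 1L) * spacing + L
    params <- sprintf("pwm=%s;n_sites=%d;spacing=%d",
                      spec$pwm$motif_id, n_sites, spacing)
  } else if (kind == "mirhr") {
    stopifnot(!is.null(spec$query))
    k <- if (is.null(spec$k)) 0L else as.integer(spec$k)
    strand <- if (is.null(spec$strand)) "+" else spec$strand
    consensus <- if (is.null(spec$consensus)) "GGCTCCTGCC"
                 else spec$consensus
    q <- gsub("U", "T", toupper(spec$query), fixed = TRUE)
    cons <- gsub("U", "T", toupper(consensus), fixed = TRUE)
    qc <- strsplit(q, "", fixed = TRUE)[[1]]
    protected <- integer(0)
    at <- regexpr(cons, q, fixed = TRUE)
    if (at > 0L) protected <- at:(at + nchar(cons) - 1L)
    free <- setdiff(seq_along(qc), protected)
    if (k > length(free)) stop("k exceeds the mutable positions")
    if (k > 0L) {
      for (i in sample(free, k)) {
        qc[i] <- sample(setdiff(c("A", "C", "G", "T"), qc[i]), 1L)
      }
    }
    piece <- paste(qc, collapse = "")
    if (strand == "-") piece <- revcomp(piece)
    put(pos, piece)
    gt_start <- pos; gt_end <- pos + nchar(piece)
    params <- sprintf("k=%d;strand=%s", k, strand)
  }

  list(
    seq = paste(chars, collapse = ""),
    ground_truth = data.frame(
      kind = kind, start = gt_start, end = gt_end, position = pos,
      params = params, stringsAsFactors = FALSE
    )
  )
}

#' Plant several signals into one background
#'
#' Applies [plant_signal()] for each spec in turn (seeding each plant from
#' `seed + index`), collecting all ground-truth records.  Planted
#' intervals must not overlap unless `allow_overlap = TRUE`.
#'
#' @param seq Background character sequence.
#' @param specs List of plant specs (see [plant_signal()]).
#' @param seed Integer base RNG seed.
#' @param allow_overlap Permit overlapping planted intervals?
#' @return List with `seq` and the combined `ground_truth` data frame.
#' @export
plant_signals <- function(seq, specs, seed = 1L, allow_overlap = FALSE) {
  gt <- list()
  for (i in seq_along(specs)) {
    res <- plant_signal(seq, specs[[i]], seed = seed + i)
    seq <- res$seq
    gt[[i]] <- res$ground_truth
  }
  gt <- do.call(rbind, gt)
  if (!allow_overlap && nrow(gt) > 1L) {
    ord <- order(gt$start)
    if (any(gt$start[ord][-1L] < gt$end[ord][-nrow(gt)])) {
      stop("planted intervals overlap; pass allow_overlap = TRUE to permit")
    }
  }
  list(seq = seq, ground_truth = gt)
}

#' Write plant ground truth as TSV
#' @param ground_truth Data frame of ground-truth records (rbind of
#'   [plant_signal()] outputs).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  utils::write.table(ground_truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default bursty-expression model parameters
#'
#' Telegraph-style transcription for one gene, measured as a population
#' average over `n_cells` effective cells (what a qPCR panel reports).
#' Per cell, bursts arrive as a Poisson process (`burst_frequency` per
#' minute), each adding a geometric number of transcripts
#' (`burst_size_mean`), on top of a small constitutive `basal_rate`;
#' transcripts decay at `decay_rate` per minute (half-life about 4.6 min,
#' the short-lived-transcript regime in which 20-min sampling shows
#' visible dynamics).  In the `miR_high` condition burst sizes are
#' multiplied by `suppression_factor` while the time lies inside
#' `suppression_window` (the M-phase-rich interval, minutes) and by
#' `amplification_factor` after the window closes.
#'
#' @param burst_frequency Bursts per minute per cell.
#' @param burst_size_mean Mean transcripts per burst.
#' @param decay_rate First-order decay per minute.
#' @param basal_rate Constitutive synthesis per minute per cell.
#' @param n_cells Effective number of cells averaged per measurement.
#' @param suppression_window `(t_start, t_end]` in minutes.
#' @param suppression_factor Burst-size multiplier in (0, 1] inside the
#'   window.
#' @param amplification_factor Burst-size multiplier >= 1 after the
#'   window.
#' @return A `burst_model` list.
#' @export
burst_model <- function(burst_frequency = 0.15, burst_size_mean = 20,
                        decay_rate = 0.15, basal_rate = 0.1,
                        n_cells = 100L,
                        suppression_window = c(80, 100),
                        suppression_factor = 0.35,
                        amplification_factor = 1.0) {
  stopifnot(burst_frequency > 0, burst_size_mean > 0, decay_rate > 0,
            basal_rate >= 0, n_cells >= 1L,
            suppression_factor > 0, suppression_factor <= 1,
            amplification_factor >= 1)
  structure(
    list(burst_frequency = burst_frequency,
         burst_size_mean = burst_size_mean, decay_rate = decay_rate,
         basal_rate = basal_rate, n_cells = as.integer(n_cells),
         suppression_window = suppression_window,
         suppression_factor = suppression_factor,
         amplification_factor = amplification_factor),
    class = "burst_model"
  )
}

#' Simulate a bursty expression panel
#'
#' Integrates the telegraph-style model of [burst_model()] per gene in
#' 1-minute steps (with a 100-min burn-in so time zero sits near the
#' stationary regime) and records transcript abundance at the requested
#' timepoints.  Under `condition = "miR_high"` burst sizes are scaled by
#' the model's suppression factor inside the suppression window and by
#' the amplification factor afterwards; `condition = "control"` leaves
#' bursts untouched.  Fully reproducible per seed.
#'
#' @param n_genes Number of genes.
#' @param timepoints Numeric sampling times in minutes (labelled
#'   `t<minutes>`), default `0, 20, ..., 180`.
#' @param model A [burst_model()].
#' @param condition `"control"` or `"miR_high"`.
#' @param seed Integer RNG seed.
#' @return An [expression_panel()] of raw (unnormalized) abundances.
#' @export
simulate_expression_panel <- function(n_genes = 43L,
                                      timepoints = seq(0, 180, by = 20),
                                      model = burst_model(),
                                      condition = c("control", "miR_high"),
                                      seed = 1L) {
  condition <- match.arg(condition)
  set.seed(seed)
  burn_in <- 100
  dt <- 1
  times <- seq(-burn_in, max(timepoints), by = dt)
  p_geom <- 1 / (1 + model$burst_size_mean)
  win <- model$suppression_window
  nc <- model$n_cells
  vals <- matrix(0, nrow = n_genes, ncol = length(timepoints))
  for (g in seq_len(n_genes)) {
    # per-cell abundance averaged over nc cells; total burst input per
    # step is a Poisson number of geometric bursts (negative binomial)
    x <- nc * model$basal_rate / model$decay_rate
    out <- numeric(length(timepoints))
    for (ti in seq_along(times)) {
      t <- times[ti]
      x <- x * exp(-model$decay_rate * dt) + nc * model$basal_rate * dt
      n_bursts <- stats::rpois(1L, nc * model$burst_frequency * dt)
      if (n_bursts > 0L) {
        size <- stats::rnbinom(1L, size = n_bursts, prob = p_geom)
        if (condition == "miR_high") {
          if (t > win[1L] && t <= win[2L]) {
            size <- size * model$suppression_factor
          } else if (t > win[2L]) {
            size <- size * model$amplification_factor
          }
        }
        x <- x + size
      }
      hit <- which(timepoints == t)
      if (length(hit)) out[hit] <- x / nc
    }
    vals[g, ] <- out
  }
  expression_panel(vals,
                   genes = sprintf("gene%02d", seq_len(n_genes)),
                   timepoints = paste0("t", timepoints),
                   condition = condition,
                   reference_timepoint = paste0("t", timepoints[1L]))
}
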