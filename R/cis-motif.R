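#' Read position frequency matrices in JASPAR PFM text format
#'
#' Parses the JASPAR flat format: a `>ID NAME` header followed by four
#' rows (A, C, G, T) of counts, with or without the `A [ ... ]` row
#' decorations.  Each matrix is converted to a probability PWM with a
#' pseudocount split by the background, and to the log2-odds form used for
#' scanning.
#'
#' @param path PFM text file (one or more motifs).
#' @param pseudocount Total pseudocount added per column, split by the
#'   background frequencies.
#' @param background Named background probabilities for A, C, G, T.
#' @return List of `pwm` objects (fields `motif_id`, `name`, `counts`,
#'   `probs`, `log_odds`, `background`, `pseudocount`).
#' @export
read_jaspar <- function(path, pseudocount = 0.8,
                        background = c(A = 0.25, C = 0.25,
                                       G = 0.25, T = 0.25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR headers found in ", path)
  out <- lapply(seq_along(heads), function(i) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    body <- lines[from:to]
    if (length(body) != 4L) {
      stop("motif ", sub("^>\\s*", "", lines[heads[i]]),
           ": expected 4 base rows, found ", length(body))
    }
    rows <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]\\s*\\[", "", l)
      l <- sub("\\]\\s*$", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    lens <- vapply(rows, length, integer(1))
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(hdr, "\\s+")[[1]][1L]
    if (length(unique(lens)) != 1L) {
      stop("motif ", id, ": base rows have unequal lengths")
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    make_pwm(counts, motif_id = id,
             name = sub("^\\S+\\s*", "", hdr),
             pseudocount = pseudocount, background = background)
  })
  out
}

#' Build a PWM object from a count (or probability) matrix
#'
#' @param counts 4 x L numeric matrix with rows A, C, G, T.
#' @param motif_id Motif identifier.
#' @param name Motif name.
#' @param pseudocount Total pseudocount per column, split by background.
#' @param background Named background probabilities (sum to 1).
#' @return A `pwm` object.
#' @export
make_pwm <- function(counts, motif_id = "motif", name = motif_id,
                     pseudocount = 0.8,
                     background = c(A = 0.25, C = 0.25,
                                    G = 0.25, T = 0.25)) {
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 1L)
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  bg <- background[c("A", "C", "G", "T")]
  probs <- apply(counts, 2L, function(col) {
    (col + pseudocount * bg) / (sum(col) + pseudocount)
  })
  log_odds <- log2(probs / bg)
  structure(
    list(motif_id = motif_id, name = name, counts = counts, probs = probs,
         log_odds = log_odds, background = bg, pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s), length %d\n", x$motif_id, x$name,
              ncol(x$counts)))
  invisible(x)
}

#' Write PWMs back to JASPAR PFM text
#'
#' @param pwms List of `pwm` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$motif_id, p$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, " [ ",
                        paste(format(p$counts[b, ], trim = TRUE),
                              collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Reverse-complement a PWM
#' @param pwm A `pwm` object.
#' @return The reverse-complemented `pwm`.
#' @export
revcomp_pwm <- function(pwm) {
  rc <- pwm$counts[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$counts))),
                   drop = FALSE]
  rownames(rc) <- c("A", "C", "G", "T")
  make_pwm(rc, motif_id = pwm$motif_id, name = pwm$name,
           pseudocount = pwm$pseudocount, background = pwm$background)
}

## raw log-odds scores of a PWM at every admissible start (1-based) on the
## + strand of `codes`; NA where the window overlaps a non-ACGT base
.pwm_scores <- function(codes, log_odds) {
  L <- ncol(log_odds)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    contrib <- log_odds[codes[j:(j + n - 1L)], j]
    contrib[is.na(codes[j:(j + n - 1L)])] <- NA_real_
    sc <- sc + contrib
  }
  sc
}

#' Scan a sequence with a PWM at a relative-score threshold
#'
#' Both strands are scanned with the log2-odds matrix; the relative score
#' min-max normalizes the raw score by the matrix's own score range,
#' `rel = (raw - min_possible) / (max_possible - min_possible)`, and hits
#' with `rel >= rel_threshold` are reported, sorted by start (`+` strand
#' first on ties).  All overlapping hits are kept.
#'
#' @param seq Character scalar DNA sequence.
#' @param pwm A `pwm` object.
#' @param rel_threshold Relative-score threshold in (0, 1].
#' @param seq_id Sequence id for the hits.
#' @return Data frame with `motif_id`, `seq_id`, `start` (0-based),
#'   `end`, `strand`, `rel_score`, `raw_score`.
#' @export
scan_pwm <- function(seq, pwm, rel_threshold = 0.80, seq_id = "seq") {
  if (!(rel_threshold > 0 && rel_threshold <= 1)) {
    stop("rel_threshold must lie in (0, 1]")
  }
  codes <- .seq_codes(seq)
  L <- ncol(pwm$log_odds)
  if (length(codes) < L) stop("sequence shorter than the motif")
  lo_min <- sum(apply(pwm$log_odds, 2L, min))
  lo_max <- sum(apply(pwm$log_odds, 2L, max))
  hits <- list()
  for (strand in c("+", "-")) {
    lo <- if (strand == "+") pwm$log_odds else revcomp_pwm(pwm)$log_odds
    raw <- .pwm_scores(codes, lo)
    rel <- (raw - lo_min) / (lo_max - lo_min)
    keep <- which(!is.na(rel) & rel >= rel_threshold)
    if (length(keep)) {
      hits[[strand]] <- data.frame(
        motif_id = pwm$motif_id, seq_id = seq_id,
        start = keep - 1L, end = keep - 1L + L, strand = strand,
        rel_score = rel[keep], raw_score = raw[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(motif_id = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), rel_score = numeric(),
                      raw_score = numeric(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$strand != "+"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Optimal histogram bin width (Shimazaki-Shinomoto)
#'
#' Selects, from a candidate list, the bin width minimizing the cost
#' `C(width) = (2*kbar - v) / width^2` where `kbar` and `v` are the mean
#' and biased variance of the bin counts at that width.  Ties resolve to
#' the smaller width; degenerate data (all positions equal) also return
#' the smallest candidate.
#'
#' @param positions Numeric positions (>= 2 values).
#' @param candidates Candidate bin widths (> 0).
#' @return The selected width.
#' @export
optimal_bin_width <- function(positions, candidates) {
  if (length(positions) < 2L) stop("need at least 2 positions")
  if (!length(candidates)) stop("need at least one candidate width")
  stopifnot(all(candidates > 0))
  candidates <- sort(unique(candidates))
  if (diff(range(positions)) == 0) return(candidates[1L])
  costs <- vapply(candidates, function(w) {
    cnt <- .bin_counts(positions, w)
    kbar <- mean(cnt)
    v <- mean((cnt - kbar)^2)
    (2 * kbar - v) / w^2
  }, numeric(1))
  candidates[which.min(costs)]  # first min = smallest width on ties
}

## bin counts over [min, min + n_bins*w) with right-open bins; the final
## bin absorbs the maximum
.bin_counts <- function(positions, w) {
  lo <- min(positions)
  n_bins <- max(1L, ceiling((max(positions) - lo) / w))
  idx <- pmin(floor((positions - lo) / w) + 1L, n_bins)
  tabulate(idx, nbins = n_bins)
}

#' Histogram of motif hit positions at a chosen bin width
#'
#' @param hits Data frame of hits ([scan_pwm()] output, possibly from
#'   several motifs) with a `start` column and a class label column.
#' @param bin_width Bin width in bp (e.g. from [optimal_bin_width()]).
#' @param classes Named character vector mapping `motif_id` to class.
#' @return List with `bin_width`, `breaks` and a counts matrix
#'   (bins x classes); total counts equal `nrow(hits)`.
#' @export
motif_histogram <- function(hits, bin_width, classes) {
  if (!nrow(hits)) stop("no hits to bin")
  cls <- .map_classes(hits$motif_id, classes)
  lo <- min(hits$start)
  n_bins <- max(1L, ceiling((max(hits$start) - lo + 1) / bin_width))
  breaks <- lo + (0:n_bins) * bin_width
  idx <- pmin(floor((hits$start - lo) / bin_width) + 1L, n_bins)
  levels_cls <- sort(unique(cls))
  counts <- sapply(levels_cls, function(cl) {
    tabulate(idx[cls == cl], nbins = n_bins)
  })
  counts <- matrix(counts, nrow = n_bins,
                   dimnames = list(NULL, levels_cls))
  list(bin_width = bin_width, breaks = breaks, counts = counts)
}

.map_classes <- function(motif_ids, classes) {
  unknown <- setdiff(unique(motif_ids), names(classes))
  if (length(unknown)) {
    stop("unknown motif id(s): ", paste(unknown, collapse = ", "))
  }
  unname(classes[motif_ids])
}

#' Per-class motif counts and the TFAP2:TCF ratio
#'
#' Tallies hits per motif class and reports the ratio of TFAP2A/B/C-class
#' to TCF3/4-class counts, the summary used to compare cis-cluster
#' composition across sequences; the ratio is `NA` (flagged by a warning)
#' when the TCF class is empty.
#'
#' @param hits Data frame of hits with a `motif_id` column.
#' @param classes Named character vector mapping `motif_id` to class
#'   (classes `"TFAP2"` and `"TCF"` feed the ratio).
#' @return List with `counts` (named integer vector per class) and
#'   `tfap2_tcf_ratio`.
#' @export
motif_class_stats <- function(hits, classes) {
  cls <- .map_classes(hits$motif_id, classes)
  counts <- table(factor(cls, levels = sort(unique(unname(classes)))))
  counts <- setNames(as.integer(counts), names(counts))
  tcf <- if ("TCF" %in% names(counts)) counts[["TCF"]] else 0L
  tfap2 <- if ("TFAP2" %in% names(counts)) counts[["TFAP2"]] else 0L
  ratio <- if (tcf == 0L) {
    warning("no TCF-class hits; TFAP2:TCF ratio undefined")
    NA_real_
  } else {
    tfap2 / tcf
  }
  list(counts = counts, tfap2_tcf_ratio = ratio)
}
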