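#' Nearest-neighbor RNA/RNA duplex energy model
#'
#' Helix-stacking free energies (kcal/mol, 37 C) for antiparallel RNA/RNA
#' duplexes, indexed by the two consecutive base pairs of a stack written
#' 5'->3' on the query strand.  Watson-Crick stacks carry the standard
#' nearest-neighbor values; stacks involving G:U wobble pairs use
#' simplified negative values.  Duplex initiation is penalized positively
#' and every maximal run of unpaired positions enclosed by helix costs
#' `mismatch_penalty`.  The model is a transparent threshold-filter
#' approximation of full hybridization folding: no bulges, asymmetric
#' loops or suboptimal structures.
#'
#' @param initiation Duplex initiation penalty (kcal/mol).
#' @param mismatch_penalty Penalty per maximal mismatch run (kcal/mol).
#' @param wobble_stack Stacking value for any stack containing one G:U
#'   pair.
#' @param wobble_wobble_stack Stacking value for a stack of two G:U pairs.
#' @return An `energy_model` list with `stack` (6 x 6 matrix over pairs
#'   AU, UA, CG, GC, GU, UG), `initiation`, `mismatch_penalty`.
#' @export
energy_model <- function(initiation = 4.09, mismatch_penalty = 3.0,
                         wobble_stack = -1.0, wobble_wobble_stack = -0.5) {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  stack <- matrix(NA_real_, 6L, 6L, dimnames = list(pairs, pairs))
  # Watson-Crick nearest-neighbor stacks, 5'p1 p2 3' on the query strand
  wc <- c(
    "AU.AU" = -0.93,  # 5'AA3'/3'UU5'
    "AU.UA" = -1.10,  # 5'AU3'/3'UA5'
    "UA.AU" = -1.33,  # 5'UA3'/3'AU5'
    "CG.UA" = -2.08,  # 5'CU3'/3'GA5'
    "CG.AU" = -2.11,  # 5'CA3'/3'GU5'
    "GC.UA" = -2.24,  # 5'GU3'/3'CA5'
    "GC.AU" = -2.35,  # 5'GA3'/3'CU5'
    "CG.GC" = -2.36,  # 5'CG3'/3'GC5'
    "GC.GC" = -3.26,  # 5'GG3'/3'CC5' == GG/CC
    "GC.CG" = -3.42   # 5'GC3'/3'CG5'
  )
  rev_pair <- c(AU = "UA", UA = "AU", CG = "GC", GC = "CG",
                GU = "UG", UG = "GU")
  for (key in names(wc)) {
    p <- strsplit(key, ".", fixed = TRUE)[[1]]
    stack[p[1L], p[2L]] <- wc[[key]]
    # reading the stack from the opposite strand swaps and flips the pairs
    stack[rev_pair[p[2L]], rev_pair[p[1L]]] <- wc[[key]]
  }
  # remaining WC x WC entries are symmetry images already filled; wobble:
  for (p1 in pairs) {
    for (p2 in pairs) {
      if (is.na(stack[p1, p2])) {
        n_wobble <- (p1 %in% c("GU", "UG")) + (p2 %in% c("GU", "UG"))
        stack[p1, p2] <- if (n_wobble == 2L) wobble_wobble_stack
                         else wobble_stack
      }
    }
  }
  stopifnot(all(stack < 0), initiation > 0)
  structure(list(stack = stack, initiation = initiation,
                 mismatch_penalty = mismatch_penalty),
            class = "energy_model")
}

.as_rna <- function(seq) {
  chartr("Tt", "Uu", toupper(seq))
}

#' Ungapped homology scan of a query against a subject sequence
#'
#' Slides the full-length query (no gaps) over both strands of the
#' subject; every window is scored as the fraction of identical positions
#' (T and U are equivalent) and windows exceeding `min_identity` are
#' returned.  Minus-strand hits are reported in forward coordinates with
#' the strand-oriented window sequence.
#'
#' @param query Query sequence (RNA or DNA; a miRNA, typically).
#' @param subject Subject DNA sequence.
#' @param min_identity Identity threshold (strict `>`).
#' @param seq_id Subject id for the hits.
#' @param query_id Query id recorded per hit.
#' @return Data frame with `query_id`, `seq_id`, `start`, `end` (0-based
#'   half-open, forward coordinates), `strand`, `identity`, `window`
#'   (strand-oriented matched sequence), sorted by (`seq_id`, `start`,
#'   `strand`).
#' @export
scan_homology <- function(query, subject, min_identity = 0.68,
                          seq_id = "seq", query_id = "query") {
  qd <- gsub("U", "T", toupper(query), fixed = TRUE)
  L <- nchar(qd)
  if (L > nchar(subject)) {
    warning("query longer than subject; no scan performed")
    return(.empty_homology())
  }
  qcodes <- .seq_codes(qd)
  res <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") toupper(subject) else revcomp(subject)
    scodes <- .seq_codes(subj)
    n <- length(scodes) - L + 1L
    ident <- numeric(n)
    for (j in seq_len(L)) {
      eq <- scodes[j:(j + n - 1L)] == qcodes[j]
      eq[is.na(eq)] <- FALSE
      ident <- ident + eq
    }
    ident <- ident / L
    keep <- which(ident > min_identity)
    if (length(keep)) {
      start_fwd <- if (strand == "+") keep - 1L
                   else nchar(subject) - (keep - 1L) - L
      res[[strand]] <- data.frame(
        query_id = query_id, seq_id = seq_id,
        start = start_fwd, end = start_fwd + L, strand = strand,
        identity = ident[keep],
        window = substring(subj, keep, keep + L - 1L),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(.empty_homology())
  out <- out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_homology <- function() {
  data.frame(query_id = character(), seq_id = character(),
             start = integer(), end = integer(), strand = character(),
             identity = numeric(), window = character(),
             stringsAsFactors = FALSE)
}

#' Filter homology hits for an exact consensus substring
#'
#' Keeps hits whose strand-oriented window contains the consensus
#' sequence, or its reverse complement, as an exact substring.
#'
#' @param hits Data frame from [scan_homology()] (needs a `window`
#'   column).
#' @param consensus Consensus sequence (default the high-affinity
#'   GGCTCCTGCC decamer; the shorter GGCTCCTG octamer form is accepted
#'   too).
#' @return The filtered hits, with a `has_consensus` column set.
#' @export
consensus_filter <- function(hits, consensus = "GGCTCCTGCC") {
  stopifnot(nzchar(consensus))
  cons <- gsub("U", "T", toupper(consensus), fixed = TRUE)
  rc <- revcomp(cons)
  has <- grepl(cons, hits$window, fixed = TRUE) |
    grepl(rc, hits$window, fixed = TRUE)
  out <- hits[has, , drop = FALSE]
  if (nrow(out)) out$has_consensus <- TRUE
  rownames(out) <- NULL
  out
}

#' Nearest-neighbor duplex free energy of a miRNA against a site
#'
#' Pairs the miRNA antiparallel against the complement of the
#' strand-oriented site (so a site identical to the miRNA forms a perfect
#' duplex).  Positions pair as Watson-Crick or G:U wobble; the free energy
#' is the initiation penalty, plus the stacking term for every two
#' consecutive paired positions, plus `mismatch_penalty` for every
#' helix-interrupting maximal
#' run of unpaired positions.  More negative is more stable; a site with
#' no complementary positions returns the bare (positive) initiation.
#'
#' @param mirna miRNA sequence (RNA or DNA letters), 5'->3'.
#' @param site Site sequence of equal length (strand-oriented hit window).
#' @param model An [energy_model()].
#' @return Free energy in kcal/mol.
#' @export
duplex_delta_g <- function(mirna, site, model = energy_model()) {
  m <- strsplit(.as_rna(mirna), "", fixed = TRUE)[[1]]
  s <- strsplit(.as_rna(site), "", fixed = TRUE)[[1]]
  if (length(m) != length(s)) stop("mirna and site must have equal length")
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  partner <- unname(comp[s])          # opposing base for each position
  pair <- paste0(m, partner)          # e.g. "AU", "GU", ...
  valid <- pair %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  dg <- model$initiation
  if (!any(valid)) return(dg)          # no duplex: bare initiation
  for (i in seq_len(length(m) - 1L)) {
    if (valid[i] && valid[i + 1L]) {
      dg <- dg + model$stack[pair[i], pair[i + 1L]]
    }
  }
  # each maximal unpaired run flanked by helix on both sides interrupts
  # the duplex once; dangling unpaired ends carry no penalty
  runs <- rle(valid)
  interior <- which(!runs$values)
  interior <- interior[interior > 1L & interior < length(runs$values)]
  dg + model$mismatch_penalty * length(interior)
}

#' Full miRNA homology-region identification pipeline
#'
#' Chains the ungapped homology scan, the exact-consensus filter and the
#' duplex free-energy filter over a set of subject sequences, with
#' stage-by-stage candidate counts reported via messages.
#'
#' @param query miRNA query sequence.
#' @param subjects Named character vector (or list) of subject sequences.
#' @param min_identity Identity threshold (strict `>`).
#' @param consensus Consensus sequence for [consensus_filter()].
#' @param dg_max Maximum (least negative) admissible duplex energy,
#'   kcal/mol.
#' @param model An [energy_model()].
#' @param query_id Query id recorded per hit.
#' @return Data frame of surviving hits with `identity`, `has_consensus`
#'   and `delta_g` columns.
#' @export
mirhr_pipeline <- function(query, subjects, min_identity = 0.68,
                           consensus = "GGCTCCTGCC", dg_max = -36.0,
                           model = energy_model(), query_id = "query") {
  subjects <- as.list(subjects)
  if (!length(subjects)) return(.empty_mirhr())
  ids <- names(subjects)
  if (is.null(ids)) ids <- paste0("seq", seq_along(subjects))
  cand <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    scan_homology(query, subjects[[i]], min_identity = min_identity,
                  seq_id = ids[i], query_id = query_id)
  }))
  if (is.null(cand) || !nrow(cand)) return(.empty_mirhr())
  message("homology scan: ", nrow(cand), " candidate(s)")
  kept <- consensus_filter(cand, consensus = consensus)
  message("consensus filter: ", nrow(kept), " of ", nrow(cand), " kept")
  if (!nrow(kept)) return(.empty_mirhr())
  kept$delta_g <- vapply(kept$window, function(w) {
    duplex_delta_g(query, w, model = model)
  }, numeric(1), USE.NAMES = FALSE)
  out <- kept[kept$delta_g <= dg_max, , drop = FALSE]
  message("duplex energy filter: ", nrow(out), " of ", nrow(kept), " kept")
  rownames(out) <- NULL
  out
}

.empty_mirhr <- function() {
  cbind(.empty_homology(),
        data.frame(has_consensus = logical(), delta_g = numeric()))
}

#' Longest inverted-repeat stem around a center
#'
#' Finds the longest inverted repeat (reverse-complement symmetric arms
#' separated by a loop of at least `min_loop` bases) whose loop midpoint
#' lies within `+/-slack` of `center`, allowing up to `max_mismatch`
#' mismatched arm positions; mismatches may not cap the outer end of the
#' stem.  Returns the arm length in bp (0 when no stem exists) — the
#' sequence-level proxy for the hairpin size the region could form as RNA.
#'
#' @param seq Character scalar DNA sequence.
#' @param center 0-based position around which to search.
#' @param max_mismatch Maximum mismatches tolerated in the stem.
#' @param min_loop Minimum loop length in bases.
#' @param slack Search half-width around `center` in bp.
#' @return Integer stem arm length.
#' @export
palindrome_stem <- function(seq, center, max_mismatch = 0L, min_loop = 3L,
                            slack = 5L) {
  codes <- .seq_codes(seq)
  n <- length(codes)
  if (center < 0L || center > n - 1L) stop("center outside the sequence")
  best <- 0L
  # enumerate candidate loops [l, r] (0-based, inclusive) of length
  # >= min_loop whose midpoint is within +/-slack of center
  for (mid2 in (2L * (center - slack)):(2L * (center + slack))) {
    # mid2 = l + r; arms are s[l-1-k] vs s[r+1+k]
    for (loop_len in min_loop:n) {
      if ((mid2 - loop_len + 1L) %% 2L != 0L) next
      l <- (mid2 - loop_len + 1L) %/% 2L
      r <- l + loop_len - 1L
      if (l < 0L || r > n - 1L) break
      arm <- 0L; mm <- 0L; best_here <- 0L
      while (TRUE) {
        i <- l - 1L - arm
        j <- r + 1L + arm
        if (i < 0L || j > n - 1L) break
        ci <- codes[i + 1L]; cj <- codes[j + 1L]
        pairs <- !is.na(ci) && !is.na(cj) && (ci + cj == 5L)  # A/T=1/4 C/G=2/3
        if (!pairs) {
          mm <- mm + 1L
          if (mm > max_mismatch) break
        } else {
          best_here <- arm + 1L
        }
        arm <- arm + 1L
      }
      if (best_here > best) best <- best_here
    }
  }
  best
}
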