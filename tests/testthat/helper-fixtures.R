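# Shared fixtures and independent oracles, built in code at test time.

# GC-rich 30-nt miRNA-like query containing the GGCTCCTGCC consensus
mir_query <- function() "GCGGCTCCTGCCGCGGCAGCGGCAGCGCGG"

# two small demo PFMs: a TCF3/4-like E-box motif and a TFAP2-like
# GC-palindromic motif; counts are multinomial draws around a consensus
demo_pwms <- function() {
  tcf_counts <- rbind(
    A = c(20,  1,  1,  1,  1,  1,  1, 20),
    C = c( 2, 30,  2, 30,  1,  2,  1,  2),
    G = c( 2,  1, 30,  1, 30,  2,  2,  2),
    T = c( 1,  1,  1,  1,  1, 28, 29,  9)
  )
  tfap_counts <- rbind(
    A = c( 1,  2, 28,  9,  9, 28,  2,  1),
    C = c(30,  30, 2,  9,  9,  2,  1,  2),
    G = c( 2,  1,  2,  9,  9,  2, 30, 30),
    T = c( 1,  1,  2,  7,  7,  2,  1,  1)
  )
  list(make_pwm(tcf_counts, motif_id = "TCF_demo", name = "tcf"),
       make_pwm(tfap_counts, motif_id = "TFAP2_demo", name = "tfap2"))
}

write_demo_pfm <- function(path = tempfile(fileext = ".pfm")) {
  write_jaspar(demo_pwms(), path)
  path
}

# independent full dynamic-programming edit-distance oracle
lev_dp <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  if (n && m) {
    for (i in 1:n) {
      for (j in 1:m) {
        d[i + 1L, j + 1L] <- min(
          d[i, j + 1L] + 1L,
          d[i + 1L, j] + 1L,
          d[i, j] + (av[i] != bv[j])
        )
      }
    }
  }
  d[n + 1L, m + 1L]
}

random_dna <- function(n, seed) gen_background(n, gc = 0.5, seed = seed)

# brute-force SymCurv winner: enumerate every admissible strict local
# minimum and recompute s_sym and the second difference from the raw
# values, independently of predict_dyad()
brute_force_dyad <- function(curv, m = 25L, epsilon = 1e-6) {
  v <- curv$values
  best_pos <- NA_integer_
  best_score <- -Inf
  for (idx in (m + 1L):(length(v) - m)) {
    if (idx < 2L || idx > length(v) - 1L) next
    if (any(is.na(v[(idx - m):(idx + m)]))) next
    if (!(v[idx] < v[idx - 1L] && v[idx] <= v[idx + 1L])) next
    ssym <- 0
    for (i in 1:m) {
      ssym <- ssym + 1 / max(abs(v[idx - i] - v[idx + i]), epsilon)
    }
    den <- v[idx - 1L] + v[idx + 1L] - 2 * v[idx]
    smin <- if (den == 0) 1 / epsilon else 1 / den
    if (abs(smin) > 1 / epsilon) smin <- sign(smin) / epsilon
    sc <- ssym * smin
    if (sc > best_score) {
      best_score <- sc
      best_pos <- curv$start + (idx - 1L) * curv$step
    }
  }
  list(position = best_pos, symcurv_score = best_score)
}

# per-position PWM rescoring oracle (both strands, min-max relative score)
brute_force_pwm_hits <- function(seq, pwm, rel_threshold) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- ncol(pwm$log_odds)
  lo_min <- sum(apply(pwm$log_odds, 2L, min))
  lo_max <- sum(apply(pwm$log_odds, 2L, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  for (start in seq_len(length(chars) - L + 1L)) {
    win <- chars[start:(start + L - 1L)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    for (strand in c("+", "-")) {
      site <- if (strand == "+") win else rev(unname(comp[win]))
      raw <- sum(vapply(seq_len(L), function(j) {
        pwm$log_odds[site[j], j]
      }, numeric(1)))
      rel <- (raw - lo_min) / (lo_max - lo_min)
      if (rel >= rel_threshold) {
        out[[length(out) + 1L]] <- data.frame(
          start = start - 1L, strand = strand, rel_score = rel)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character(),
                      rel_score = numeric()))
  }
  do.call(rbind, out)
}

# naive O(n * m) ungapped homology scan oracle (both strands)
brute_force_homology <- function(query, subject, min_identity) {
  q <- strsplit(gsub("U", "T", toupper(query)), "", fixed = TRUE)[[1]]
  L <- length(q)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(subject) else revcomp(subject)
    sv <- strsplit(s, "", fixed = TRUE)[[1]]
    for (start in seq_len(length(sv) - L + 1L)) {
      ident <- mean(sv[start:(start + L - 1L)] == q)
      if (ident > min_identity) {
        fwd <- if (strand == "+") start - 1L
               else nchar(subject) - (start - 1L) - L
        out[[length(out) + 1L]] <- data.frame(
          start = fwd, strand = strand, identity = ident)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character(),
                      identity = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

# exhaustive inverted-repeat oracle around a center
brute_force_stem <- function(seq, center, max_mismatch = 0L, min_loop = 3L,
                             slack = 5L) {
  codes <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T"))
  n <- length(codes)
  best <- 0L
  for (l in 0:(n - 1L)) {
    for (r in (l - 1L):(n - 1L)) {
      loop_len <- r - l + 1L
      if (loop_len < min_loop) next
      mid <- (l + r) / 2
      if (abs(mid - center) > slack) next
      arm <- 0L; mm <- 0L; best_here <- 0L
      repeat {
        i <- l - 1L - arm; j <- r + 1L + arm
        if (i < 0L || j > n - 1L) break
        good <- !is.na(codes[i + 1L]) && !is.na(codes[j + 1L]) &&
          codes[i + 1L] + codes[j + 1L] == 5L
        if (!good) {
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

# W/S-type two-phase pulse oscillation used for phase-recovery
# experiments: +1 pulses every 10.3 bp, -1 pulses half a period later
ws_waveform <- function(n) {
  t <- 0:(n - 1)
  ifelse((t %% 10.3) < 1, 1, ifelse(((t + 5.15) %% 10.3) < 1, -1, 0))
}
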