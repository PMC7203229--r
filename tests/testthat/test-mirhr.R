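test_that("homology scan finds exact, mutated and reverse-strand copies", {
  q <- mir_query()
  L <- nchar(q)
  bg <- random_dna(3000, seed = 301)

  exact <- plant_signal(bg, list(kind = "mirhr", position = 500, k = 0,
                                 query = q), seed = 1)
  h <- scan_homology(q, exact$seq)
  self <- h[h$start == 500, ]
  expect_identical(nrow(self), 1L)
  expect_equal(self$identity, 1.0)
  expect_identical(self$strand, "+")

  for (k in c(3L, 6L)) {
    mut <- plant_signal(bg, list(kind = "mirhr", position = 1500, k = k,
                                 query = q), seed = k)
    hm <- scan_homology(q, mut$seq, min_identity = 0.5)
    got <- hm[hm$start == 1500 & hm$strand == "+", ]
    expect_equal(got$identity, (L - k) / L)
  }

  minus <- plant_signal(bg, list(kind = "mirhr", position = 2500, k = 0,
                                 strand = "-", query = q), seed = 9)
  hmn <- scan_homology(q, minus$seq)
  got <- hmn[hmn$start == 2500, ]
  expect_identical(got$strand, "-")
  expect_equal(got$identity, 1.0)

  expect_warning(empty <- scan_homology(strrep("A", 100), "ACGT"),
                 "longer")
  expect_identical(nrow(empty), 0L)
})

test_that("homology scan matches the naive oracle and is strand equivariant", {
  q <- substr(mir_query(), 1, 20)
  for (i in 1:5) {
    subj <- random_dna(400, seed = 310 + i)
    got <- scan_homology(q, subj, min_identity = 0.45)
    oracle <- brute_force_homology(q, subj, 0.45)
    expect_identical(got$start, oracle$start)
    expect_identical(got$strand, oracle$strand)
    expect_equal(got$identity, oracle$identity)

    # reverse-complementing the subject mirrors hits and flips strands
    rc <- scan_homology(q, revcomp(subj), min_identity = 0.45)
    n <- nchar(subj); L <- nchar(q)
    mirrored <- data.frame(start = n - got$end,
                           strand = ifelse(got$strand == "+", "-", "+"),
                           identity = got$identity)
    mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
    expect_equal(rc$start, mirrored$start)
    expect_equal(rc$strand, mirrored$strand)
    expect_equal(rc$identity, mirrored$identity)
  }
})

test_that("consensus filter requires an exact substring on either strand", {
  win_ok <- paste0("AAAA", "GGCTCCTGCC", "TTTT")
  win_rc <- paste0("AAAA", revcomp("GGCTCCTGCC"), "TTTT")
  win_broken <- paste0("AAAA", "GGCTACTGCC", "TTTT")
  hits <- data.frame(window = c(win_ok, win_rc, win_broken),
                     start = 1:3, stringsAsFactors = FALSE)
  kept <- consensus_filter(hits)
  expect_identical(kept$start, 1:2)
  expect_true(all(kept$has_consensus))
  # the shorter Methods-style octamer form is accepted as an option
  kept8 <- consensus_filter(hits, consensus = "GGCTCCTG")
  expect_identical(kept8$start, 1:2)
})

test_that("duplex energies match an independent table-summing oracle", {
  model <- energy_model()
  oracle_dg <- function(mirna, site) {
    m <- strsplit(chartr("Tt", "Uu", toupper(mirna)), "")[[1]]
    s <- strsplit(chartr("Tt", "Uu", toupper(site)), "")[[1]]
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    pr <- paste0(m, comp[s])
    ok <- pr %in% rownames(model$stack)
    if (!any(ok)) return(model$initiation)
    dg <- model$initiation
    for (i in seq_len(length(m) - 1L)) {
      if (ok[i] && ok[i + 1L]) dg <- dg + model$stack[pr[i], pr[i + 1L]]
    }
    runs <- rle(ok)
    inner <- which(!runs$values)
    inner <- inner[inner > 1L & inner < length(runs$values)]
    dg + model$mismatch_penalty * length(inner)
  }
  set.seed(21)
  for (i in 1:20) {
    mir <- random_dna(22, seed = 500 + i)
    site <- strsplit(mir, "")[[1]]
    nmut <- sample(0:5, 1)
    if (nmut > 0) {
      at <- sample(22, nmut)
      site[at] <- vapply(site[at], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    site <- paste(site, collapse = "")
    expect_equal(duplex_delta_g(mir, site, model), oracle_dg(mir, site))
  }
})

test_that("duplex energy responds correctly to pairs and mismatches", {
  model <- energy_model()
  # appending a complementary GC pair strictly stabilizes
  base <- "GCGCAUGC"
  longer <- paste0(base, "G")
  expect_lt(duplex_delta_g(longer, longer, model),
            duplex_delta_g(base, base, model))
  # one central mismatch destabilizes: site base replaced by the
  # complement of the query base, which can never pair
  site <- strsplit(base, "")[[1]]
  site[4] <- "G"   # query C faces complement(G) = C: no pair
  mm <- paste(site, collapse = "")
  expect_gt(duplex_delta_g(base, mm, model),
            duplex_delta_g(base, base, model))
  # no complementary positions at all: bare positive initiation
  expect_equal(duplex_delta_g("AAAA", "GGGG", model), model$initiation)
  # all stacking entries are negative, initiation positive
  expect_true(all(model$stack < 0))
  expect_gt(model$initiation, 0)
})

test_that("orientation is consistent between strands", {
  # the strand-oriented window of a minus-strand hit forms the same
  # duplex as the plus-strand site it mirrors
  q <- mir_query()
  bg <- random_dna(500, seed = 321)
  pl <- plant_signal(bg, list(kind = "mirhr", position = 200, k = 2,
                              query = q), seed = 3)
  fwd_hits <- scan_homology(q, pl$seq)
  rc_hits <- scan_homology(q, revcomp(pl$seq))
  expect_equal(sort(fwd_hits$window), sort(rc_hits$window))
  dg <- function(w) duplex_delta_g(q, w)
  expect_equal(sort(vapply(fwd_hits$window, dg, numeric(1))),
               sort(vapply(rc_hits$window, dg, numeric(1))))
})

test_that("the pipeline keeps planted sites and rejects decoys exactly", {
  q <- mir_query()
  L <- nchar(q)
  for (s in 1:5) {
    bg <- gen_background(6000, gc = 0.5, seed = 700 + s)
    # five conforming plants
    plants <- lapply(0:4, function(i) {
      list(kind = "mirhr", position = 300 + i * 500, k = min(i, 3),
           query = q)
    })
    res <- plant_signals(bg, plants, seed = 10 * s)
    seq <- res$seq
    # decoys: low identity (x2), broken consensus (x2), poor duplex (x1)
    chars <- strsplit(seq, "")[[1]]
    decoy <- function(pos, window) {
      chars[pos + seq_len(L)] <<- strsplit(window, "")[[1]]
    }
    set.seed(900 + s)
    mutate <- function(x, at) {
      v <- strsplit(x, "")[[1]]
      v[at] <- vapply(v[at], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      paste(v, collapse = "")
    }
    cons_at <- as.integer(regexpr("GGCTCCTGCC", q, fixed = TRUE))
    outside <- setdiff(seq_len(L), cons_at:(cons_at + 9L))
    decoy(3000, mutate(q, sample(outside, 12)))          # identity 0.6
    decoy(3500, mutate(q, sample(outside, 11)))          # identity < 0.68
    decoy(4000, mutate(q, cons_at + 3L))                 # consensus broken
    decoy(4500, mutate(q, cons_at + 7L))                 # consensus broken
    # duplex decoy: barely above the identity cutoff, with spread
    # substitutions to the complement of the query base (never pairs,
    # not even as a wobble) shattering the helix into penalized
    # fragments
    spread <- round(outside[seq(1, length(outside), length.out = 9)])
    qv <- strsplit(q, "")[[1]]
    comp_dna <- c(A = "T", C = "G", G = "C", T = "A")
    anti <- qv
    anti[spread] <- comp_dna[qv[spread]]
    decoy(5200, paste(anti, collapse = ""))
    seq <- paste(chars, collapse = "")

    hits <- suppressMessages(mirhr_pipeline(q, c(genome = seq)))
    truth <- res$ground_truth$start
    # a hit counts for the planted site it overlaps (repetitive queries
    # can fire a few bases off the planted start)
    expect_true(all(vapply(truth, function(p) {
      any(abs(hits$start - p) <= 5L)
    }, logical(1))))                                  # recall = 1
    expect_true(all(vapply(hits$start, function(p) {
      any(abs(truth - p) <= 5L)
    }, logical(1))))                                  # precision = 1
  }
})

test_that("pipeline filters are monotone in their thresholds", {
  q <- mir_query()
  bg <- gen_background(4000, gc = 0.5, seed = 41)
  res <- plant_signals(bg, lapply(c(500, 1500, 2500), function(p) {
    list(kind = "mirhr", position = p, k = 4, query = q)
  }), seed = 5)
  run <- function(mi, dg) {
    suppressMessages(
      nrow(mirhr_pipeline(q, c(g = res$seq), min_identity = mi,
                          dg_max = dg)))
  }
  expect_gte(run(0.68, -36), run(0.80, -36))
  expect_gte(run(0.68, -36), run(0.68, -50))
})

test_that("self-scan of the query's host survives all filters", {
  q <- mir_query()
  host <- paste0(random_dna(100, 51), gsub("U", "T", q),
                 random_dna(100, 52))
  hits <- suppressMessages(mirhr_pipeline(q, c(host = host)))
  expect_identical(hits$start, 100L)
  expect_equal(hits$identity, 1.0)
  expect_identical(
    nrow(suppressMessages(mirhr_pipeline(q, character(0)))), 0L)
})

test_that("palindrome stems match constructions and the quadratic oracle", {
  # inverted repeat with a proper loop: GGCGC / TTTA / GCGCC
  hp <- paste0(strrep("A", 10), "GGCGC", "TTTA", "GCGCC", strrep("A", 10))
  expect_identical(palindrome_stem(hp, 16L), 5L)
  # adjacent arms only qualify when the loop floor is relaxed
  expect_identical(palindrome_stem("AAAGGGCCCAAA", 5L, min_loop = 0L), 3L)
  expect_identical(palindrome_stem(strrep("A", 30), 15L), 0L)

  for (s in 1:50) {
    seq <- random_dna(200, seed = 800 + s)
    center <- 100L
    expect_identical(palindrome_stem(seq, center),
                     brute_force_stem(seq, center))
  }
})
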