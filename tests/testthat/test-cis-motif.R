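test_that("JASPAR PFM files parse and round-trip", {
  path <- write_demo_pfm()
  pwms <- read_jaspar(path)
  expect_length(pwms, 2L)
  expect_identical(pwms[[1L]]$motif_id, "TCF_demo")
  # column sums of the probability form are 1
  for (p in pwms) {
    expect_true(all(abs(colSums(p$probs) - 1) < 1e-9))
  }
  # round trip preserves counts
  path2 <- tempfile(fileext = ".pfm")
  write_jaspar(pwms, path2)
  back <- read_jaspar(path2)
  expect_equal(back[[1L]]$counts, pwms[[1L]]$counts)
  expect_equal(back[[2L]]$counts, pwms[[2L]]$counts)

  bad <- tempfile()
  writeLines(c(">broken m", "A [ 1 2 ]", "C [ 1 2 3 ]", "G [ 1 2 ]",
               "T [ 1 2 ]"), bad)
  expect_error(read_jaspar(bad), "broken")
})

test_that("scan_pwm scores consensus at 1 and worst sequence at 0", {
  pwm <- demo_pwms()[[1L]]
  cons <- paste(c("A", "C", "G", "T")[apply(pwm$log_odds, 2L, which.max)],
                collapse = "")
  worst <- paste(c("A", "C", "G", "T")[apply(pwm$log_odds, 2L, which.min)],
                 collapse = "")
  hc <- scan_pwm(cons, pwm, rel_threshold = 0.99)
  expect_equal(hc$rel_score[hc$strand == "+"], 1)
  hw <- scan_pwm(worst, pwm, rel_threshold = 0.05)
  expect_false("+" %in% hw$strand)
  expect_error(scan_pwm(cons, pwm, rel_threshold = 1.5), "threshold")
})

test_that("scan_pwm equals per-position rescoring for random PWMs", {
  set.seed(31)
  seq <- random_dna(500, seed = 31)
  for (i in 1:10) {
    cnt <- sapply(1:7, function(j) rmultinom(1, 40, runif(4, 0.05, 1)))
    rownames(cnt) <- c("A", "C", "G", "T")
    pwm <- make_pwm(cnt, motif_id = paste0("R", i))
    got <- scan_pwm(seq, pwm, rel_threshold = 0.75)
    oracle <- brute_force_pwm_hits(seq, pwm, 0.75)
    key <- function(d) sort(paste(d$start, d$strand))
    expect_identical(key(got), key(oracle))
    expect_equal(sort(got$rel_score), sort(oracle$rel_score))
  }
})

test_that("scan_pwm agrees with Biostrings matchPWM on the plus strand", {
  set.seed(77)
  cnt <- sapply(1:8, function(j) rmultinom(1, 40, runif(4)))
  rownames(cnt) <- c("A", "C", "G", "T")
  storage.mode(cnt) <- "integer"
  seq <- random_dna(600, seed = 78)
  mine <- scan_pwm(seq, make_pwm(cnt), rel_threshold = 0.75)
  # same pseudocount scheme: total 0.8 split over a uniform background
  pwmB <- Biostrings::PWM(cnt, type = "log2probratio",
                          prior.params = c(A = 0.2, C = 0.2,
                                           G = 0.2, T = 0.2))
  mB <- Biostrings::matchPWM(pwmB, Biostrings::DNAString(seq),
                             min.score = "75%")
  expect_identical(sort(mine$start[mine$strand == "+"]),
                   sort(BiocGenerics::start(mB) - 1L))
})

test_that("hit sets shrink monotonically with the threshold", {
  pwm <- demo_pwms()[[2L]]
  seq <- random_dna(2000, seed = 81)
  h60 <- scan_pwm(seq, pwm, 0.60)
  h75 <- scan_pwm(seq, pwm, 0.75)
  h90 <- scan_pwm(seq, pwm, 0.90)
  key <- function(d) paste(d$start, d$strand)
  expect_true(all(key(h90) %in% key(h75)))
  expect_true(all(key(h75) %in% key(h60)))
})

test_that("relative scores are strand symmetric", {
  pwm <- demo_pwms()[[1L]]
  set.seed(5)
  for (i in 1:20) {
    site <- random_dna(ncol(pwm$counts), seed = 400 + i)
    fwd <- scan_pwm(site, pwm, rel_threshold = 1e-9)
    rc <- scan_pwm(revcomp(site), revcomp_pwm(pwm), rel_threshold = 1e-9)
    expect_equal(fwd$rel_score[fwd$strand == "+"],
                 rc$rel_score[rc$strand == "+"])
  }
})

test_that("optimal_bin_width matches grid evaluation and handles ties", {
  ss_cost <- function(positions, w) {
    lo <- min(positions)
    nb <- max(1L, ceiling((max(positions) - lo) / w))
    idx <- pmin(floor((positions - lo) / w) + 1L, nb)
    cnt <- tabulate(idx, nbins = nb)
    (2 * mean(cnt) - mean((cnt - mean(cnt))^2)) / w^2
  }
  for (i in 1:20) {
    set.seed(1000 + i)
    pos <- c(rnorm(150, 30, 4), rnorm(100, 70, 9))
    cands <- 1:40
    got <- optimal_bin_width(pos, cands)
    costs <- vapply(cands, function(w) ss_cost(pos, w), numeric(1))
    expect_identical(got, cands[which.min(costs)])
  }
  # degenerate data: smallest candidate
  expect_identical(optimal_bin_width(rep(5, 10), c(2, 7, 13)), 2)
  expect_error(optimal_bin_width(numeric(0), 1:3), "positions")
})

test_that("selected width is stable on a finer candidate grid", {
  set.seed(2)
  pos <- runif(1000, 0, 100)
  coarse <- seq(2, 60, by = 2)
  fine <- seq(2, 60, by = 0.2)
  w_coarse <- optimal_bin_width(pos, coarse)
  w_fine <- optimal_bin_width(pos, fine)
  expect_lte(abs(w_coarse - w_fine), 2)
})

test_that("histograms conserve hit counts at every width", {
  pwm <- demo_pwms()[[1L]]
  seq <- random_dna(3000, seed = 83)
  hits <- rbind(scan_pwm(seq, demo_pwms()[[1L]], 0.7),
                scan_pwm(seq, demo_pwms()[[2L]], 0.7))
  classes <- c(TCF_demo = "TCF", TFAP2_demo = "TFAP2")
  for (w in c(10, 55, 200)) {
    h <- motif_histogram(hits, w, classes)
    expect_identical(sum(h$counts), nrow(hits))
  }
})

test_that("class statistics report counts and the TFAP2:TCF ratio", {
  hits <- data.frame(motif_id = c(rep("TCF_demo", 10),
                                  rep("TFAP2_demo", 10)))
  classes <- c(TCF_demo = "TCF", TFAP2_demo = "TFAP2")
  st <- motif_class_stats(hits, classes)
  expect_equal(st$tfap2_tcf_ratio, 1.0)
  expect_identical(st$counts, c(TCF = 10L, TFAP2 = 10L))

  only_tfap <- data.frame(motif_id = rep("TFAP2_demo", 4))
  expect_warning(st2 <- motif_class_stats(only_tfap, classes), "TCF")
  expect_true(is.na(st2$tfap2_tcf_ratio))
  expect_error(motif_class_stats(data.frame(motif_id = "junk"), classes),
               "unknown motif")
})

test_that("planted clusters partition around a reference point", {
  # 5 TCF-like sites upstream and 4 TFAP2-like sites downstream of the
  # midpoint, mirroring the polarity of cis-clusters around a homology
  # region
  pwms <- demo_pwms()
  bg <- random_dna(1200, seed = 85)
  up <- plant_signal(bg, list(kind = "motif_cluster", position = 100,
                              pwm = pwms[[1L]], n_sites = 5,
                              spacing = 40), seed = 1)
  both <- plant_signal(up$seq, list(kind = "motif_cluster",
                                    position = 800, pwm = pwms[[2L]],
                                    n_sites = 4, spacing = 40), seed = 2)
  hits <- rbind(scan_pwm(both$seq, pwms[[1L]], 0.80, seq_id = "x"),
                scan_pwm(both$seq, pwms[[2L]], 0.80, seq_id = "x"))
  mid <- 600
  up_hits <- hits[hits$start < mid, ]
  down_hits <- hits[hits$start >= mid, ]
  expect_gte(sum(up_hits$motif_id == "TCF_demo"), 5L)
  expect_gte(sum(down_hits$motif_id == "TFAP2_demo"), 4L)
  expect_identical(sum(down_hits$motif_id == "TCF_demo" &
                         down_hits$rel_score > 0.95), 0L)
})
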