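test_that("JASPAR parsing handles bracketed, bare and malformed input", {
  # 15-column bracketed matrix with header
  txt <- c(">MX0001 TESTMOTIF",
           paste("A [", paste(rep(1, 15), collapse = " "), "]"),
           paste("C [", paste(rep(2, 15), collapse = " "), "]"),
           paste("G [", paste(rep(3, 15), collapse = " "), "]"),
           paste("T [", paste(rep(4, 15), collapse = " "), "]"))
  cm <- read_jaspar(txt)
  expect_equal(ncol(cm$counts), 15L)
  expect_equal(cm$motif_id, "MX0001 TESTMOTIF")
  expect_equal(unname(cm$counts["G", 1L]), 3)

  # row order on disk is normalized to A,C,G,T
  shuffled <- read_jaspar(c(">X", "T [ 4 ]", "A [ 1 ]", "G [ 3 ]", "C [ 2 ]"))
  expect_equal(unname(shuffled$counts[, 1L]), c(1, 2, 3, 4))

  # single-column G-only matrix
  cm1 <- read_jaspar(c("A [0]", "C [0]", "G [1]", "T [0]"))
  expect_equal(ncol(cm1$counts), 1L)
  expect_equal(unname(cm1$counts[, 1L]), c(0, 0, 1, 0))

  # error contracts
  expect_error(read_jaspar(c(">X", "A [1]", "C [1]", "G [1]")), "4 base rows")
  expect_error(read_jaspar(c("A [1 2]", "C [1]", "G [1 2]", "T [1 2]")), "ragged")
  expect_error(read_jaspar(c("A [1]", "C [1]", "G [-1]", "T [1]")), "negative")
  expect_error(read_jaspar(c(">X", "A [1]", "C [1]", "G [1]", "G [1]")),
               "missing base row")
})

test_that("log-odds construction matches direct arithmetic", {
  # uniform column is uninformative: all weights zero
  cm <- count_matrix(matrix(c(25, 25, 25, 25), nrow = 4))
  pwm <- build_pwm(cm)
  expect_equal(unname(pwm$weights[, 1L]), rep(0, 4))

  # direct arithmetic oracle for a pure-A column
  cm <- count_matrix(matrix(c(100, 0, 0, 0), nrow = 4))
  pwm <- build_pwm(cm, pseudocount = 0.8)
  expect_equal(unname(pwm$weights["A", 1L]),
               log2((100 + 0.8 * 0.25) / ((100 + 0.8) * 0.25)))
  expect_equal(unname(pwm$weights["C", 1L]),
               log2((0.8 * 0.25) / ((100 + 0.8) * 0.25)))

  # max/min scores are the column-wise extrema sums
  pwm <- test_pwm()
  expect_equal(pwm$max_score, sum(apply(pwm$weights, 2, max)))
  expect_equal(pwm$min_score, sum(apply(pwm$weights, 2, min)))

  # degenerate: zero-total column with zero pseudocount
  cm0 <- count_matrix(matrix(c(1, 0, 0, 0, 0, 0, 0, 0), nrow = 4))
  expect_error(build_pwm(cm0, pseudocount = 0), "degenerate")
})

test_that("window scoring and consensus are mutually consistent", {
  pwm <- test_pwm()
  expect_equal(score_window(pwm, consensus(pwm)), pwm$max_score)
  expect_equal(score_window(pwm, anti_consensus(pwm)), pwm$min_score)
  expect_error(score_window(pwm, "ACGT"), "length")
  expect_error(score_window(pwm, paste(rep("N", 15), collapse = "")), "non-ACGT")

  # 2-column toy: hand-summed lookup
  cm <- count_matrix(matrix(c(8, 0, 0, 2,  1, 1, 7, 1), nrow = 4))
  toy <- build_pwm(cm)
  expect_equal(score_window(toy, "TG"),
               unname(toy$weights["T", 1L] + toy$weights["G", 2L]))

  # tie-break: all-uniform matrix has consensus A...A
  unif <- build_pwm(count_matrix(matrix(5, nrow = 4, ncol = 3)))
  expect_equal(consensus(unif), "AAA")
})

test_that("relative score is the min-max percent scale", {
  pwm <- test_pwm()
  expect_equal(relative_score(pwm, pwm$max_score), 100)
  expect_equal(relative_score(pwm, pwm$min_score), 0)
  expect_equal(relative_score(pwm, (pwm$max_score + pwm$min_score) / 2), 50)
  # strictly increasing in the raw score
  raws <- seq(pwm$min_score, pwm$max_score, length.out = 25)
  expect_true(all(diff(relative_score(pwm, raws)) > 0))
})

test_that("scanning recovers a planted consensus and equals brute force", {
  pwm <- test_pwm()
  set.seed(11)
  bg <- random_dna(400)
  planted <- paste0(substr(bg, 1, 150), consensus(pwm), substr(bg, 166, 400))
  hits <- scan_sequence(pwm, planted, threshold = 99)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 150L)
  expect_equal(hits$strand, 1L)
  expect_gte(hits$relative_score, 99)

  # sequence shorter than the motif: empty result with a message, no error
  expect_message(short <- scan_sequence(pwm, "ACGT", 50), "shorter")
  expect_equal(nrow(short), 0L)

  # equality with the naive per-window oracle over random sequences
  set.seed(21)
  for (i in 1:12) {
    cm <- random_count_matrix()
    p <- build_pwm(cm)
    seq <- random_dna(sample(60:400, 1))
    thr <- sample(c(0, 40, 70, 85), 1)
    fast <- scan_sequence(p, seq, threshold = thr)
    slow <- brute_force_scan(p, seq, threshold = thr)
    expect_equal(nrow(fast), nrow(slow))
    expect_equal(fast$start, slow$start)
    expect_equal(fast$strand, slow$strand)
    expect_equal(fast$raw_score, slow$raw_score)
    expect_equal(fast$site, slow$site)
  }
})

test_that("threshold only filters and never reorders or adds hits", {
  pwm <- test_pwm()
  set.seed(31)
  seq <- random_dna(800)
  lo <- scan_sequence(pwm, seq, threshold = 20)
  hi <- scan_sequence(pwm, seq, threshold = 55)
  key <- function(h) paste(h$start, h$strand)
  expect_true(all(key(hi) %in% key(lo)))
  expect_equal(hi, lo[lo$relative_score >= 55, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("reverse-complementing the sequence mirrors the hits", {
  set.seed(41)
  for (i in 1:8) {
    p <- build_pwm(random_count_matrix())
    L <- motif_length(p)
    seq <- random_dna(sample(80:300, 1))
    n <- nchar(seq)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    fwd <- scan_sequence(p, seq, threshold = 60)
    rev <- scan_sequence(p, rc, threshold = 60)
    expect_equal(nrow(fwd), nrow(rev))
    expect_equal(sort(fwd$raw_score), sort(rev$raw_score))
    # starts mirror and strands flip
    mirrored <- sort((n - L) - rev$start)
    expect_equal(sort(fwd$start), mirrored)
    expect_equal(sum(fwd$strand > 0), sum(rev$strand < 0))
  }
})

test_that("palindromic matrices score both strands identically", {
  # counts chosen reverse-complement-symmetric: column j of base b equals
  # column L+1-j of comp(b)
  counts <- cbind(c(10, 2, 3, 5), c(4, 6, 6, 4), c(5, 3, 2, 10))
  pwm <- build_pwm(count_matrix(counts))
  set.seed(51)
  seq <- random_dna(300)
  hits <- scan_sequence(pwm, seq, threshold = 0)
  fwd <- hits[hits$strand > 0, ]
  rev <- hits[hits$strand < 0, ]
  m <- match(fwd$start, rev$start)
  expect_true(all(abs(fwd$raw_score - rev$raw_score[m]) < 1e-9))
})

test_that("hit TSV output uses 1-based inclusive coordinates", {
  pwm <- test_pwm()
  seq <- paste0(strrep("A", 20), consensus(pwm), strrep("A", 20))
  hits <- scan_sequence(pwm, seq, threshold = 99)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_hits_tsv(hits, tmp, motif_length(pwm))
  back <- read.delim(tmp, stringsAsFactors = FALSE)
  expect_equal(back$start, 21L)
  expect_equal(back$end, 35L)
  expect_equal(back$strand, "+")
})
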