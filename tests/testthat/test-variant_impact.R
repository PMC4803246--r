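# independent two-allele oracle: rescan both full alleles unthresholded and
# pick the best-overlapping window by direct comparison
oracle_pct_change <- function(pwm, reference, model, v, threshold = 70) {
  L <- motif_length(pwm)
  mut <- apply_variant(reference, model, v)
  iv <- mut$interval
  wt_hits <- brute_force_scan(pwm, reference, threshold = 0)
  mut_hits <- brute_force_scan(pwm, mut$seq, threshold = 0)
  over <- function(h, lo, hi) h[h$start < hi & (h$start + L) > lo, , drop = FALSE]
  wt_o <- over(wt_hits, iv[["start"]], iv[["end"]])
  mut_hi <- iv[["end"]] + max(0L, mut$length_change)
  mut_o <- over(mut_hits, iv[["start"]], mut_hi)
  if (!any(wt_o$relative_score >= threshold) &&
      !any(mut_o$relative_score >= threshold)) return(0)
  wt_best <- max(wt_o$raw_score)
  mut_best <- if (nrow(mut_o)) max(mut_o$raw_score) else NA
  if (wt_best <= 0) return(NA_real_)
  if (is.na(mut_best)) return(100)
  100 * (wt_best - mut_best) / wt_best
}

test_that("best hit over a locus follows the score/start/strand tie-breaks", {
  hits <- data.frame(sequence_id = "s", start = c(10L, 20L, 50L),
                     strand = c(-1L, 1L, 1L),
                     raw_score = c(12.5, 11.2, 20),
                     relative_score = c(90, 80, 99),
                     site = c("X", "Y", "Z"), stringsAsFactors = FALSE)
  # hit at 50 does not overlap [5, 30)
  best <- best_hit_over_locus(hits, c(5, 30), motif_length = 15L)
  expect_equal(best$raw_score, 12.5)
  # absence of overlap is NULL, not an error
  expect_null(best_hit_over_locus(hits, c(200, 210), 15L))
  # equal scores: smaller start wins, then forward strand
  tie <- data.frame(sequence_id = "s", start = c(20L, 10L, 10L),
                    strand = c(1L, -1L, 1L), raw_score = c(5, 5, 5),
                    relative_score = c(50, 50, 50),
                    site = c("a", "b", "c"), stringsAsFactors = FALSE)
  best <- best_hit_over_locus(tie, c(0, 40), 15L)
  expect_equal(best$start, 10L)
  expect_equal(best$strand, 1L)
  expect_error(best_hit_over_locus(hits, c(10, 10), 15L), "non-empty")
})

test_that("identity substitution has exactly zero impact", {
  fx <- simulate_gene_fixture(seed = 3)
  top <- fx$truth$planted[which.max(fx$truth$planted$raw_score), ]
  pos_off <- 3541L - (top$start + 5L)   # a base inside the strongest element
  rb <- substr(fx$reference, top$start + 6L, top$start + 6L)
  v <- parse_cvariant(sprintf("c.42-%d%s>%s", pos_off, rb, rb))
  res <- assess_variant(fx$pwm, fx$reference, fx$model, v)
  expect_identical(res$pct_change, 0)
  expect_equal(res$wt_raw, res$mut_raw)
})

test_that("a variant far from every element has no impact", {
  fx <- simulate_gene_fixture(seed = 3)
  # c.1-900 is >= 15 bases from both promoter plants (at 320 and 1310)
  pos <- 1500L - 900L
  rb <- substr(fx$reference, pos + 1L, pos + 1L)
  ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
  v <- parse_cvariant(sprintf("c.1-900%s>%s", rb, ab))
  res <- assess_variant(fx$pwm, fx$reference, fx$model, v)
  expect_equal(res$category, "none")
  expect_identical(res$pct_change, 0)
})

test_that("an SNV inside a hit changes the raw score within the column spread", {
  fx <- simulate_gene_fixture(seed = 5)
  pwm <- fx$pwm
  top <- fx$truth$planted[which.max(fx$truth$planted$raw_score), ]
  # substitute the 3rd motif position; site is on strand -1, so motif
  # column 3 sits at contig offset start + L - 3 (0-based)
  L <- motif_length(pwm)
  contig_pos <- top$start + (L - 3L)
  rb <- substr(fx$reference, contig_pos + 1L, contig_pos + 1L)
  ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
  off <- 3541L - contig_pos
  v <- parse_cvariant(sprintf("c.42-%d%s>%s", off, rb, ab))
  res <- assess_variant(pwm, fx$reference, fx$model, v)
  spread <- max(pwm$weights[, 3L]) - min(pwm$weights[, 3L])
  expect_lte(abs(res$wt_raw - res$mut_raw), spread + 1e-9)
})

test_that("impact equals the two-allele brute-force oracle", {
  fx <- simulate_gene_fixture(seed = 9)
  for (v in fx$variants) {
    res <- suppressMessages(
      assess_variant(fx$pwm, fx$reference, fx$model, v))
    expect_equal(res$pct_change,
                 oracle_pct_change(fx$pwm, fx$reference, fx$model, v),
                 tolerance = 1e-9, info = v$raw_text)
  }
})

test_that("enlarging the scan window never changes the assessment", {
  fx <- simulate_gene_fixture(seed = 13)
  v <- fx$variants[[2]]  # 20 bp duplication
  base <- assess_variant(fx$pwm, fx$reference, fx$model, v, window_pad = 40L)
  for (pad in c(60L, 100L, 250L)) {
    res <- assess_variant(fx$pwm, fx$reference, fx$model, v, window_pad = pad)
    expect_equal(res$pct_change, base$pct_change)
    expect_equal(res$category, base$category)
    expect_equal(res$wt_raw, base$wt_raw)
  }
  expect_error(assess_variant(fx$pwm, fx$reference, fx$model, v, window_pad = 3L),
               "window_pad")
})

test_that("the study report inventories planted elements and flags impacts", {
  fx <- simulate_gene_fixture(seed = 1)
  rep <- suppressMessages(
    study_report(fx$pwm, fx$reference, fx$model, fx$variants))
  expect_equal(nrow(rep$inventory), 5L)
  # inventory matches the planted truth record site by site
  tr <- fx$truth$planted[order(fx$truth$planted$start), ]
  inv <- rep$inventory[order(rep$inventory$start), ]
  expect_equal(inv$start, tr$start)
  expect_equal(inv$site, tr$site)
  expect_equal(inv$raw_score, tr$raw_score, tolerance = 1e-9)
  # the two duplications are non-"none"; the far SNV is "none"
  got <- rep$impacts$category[match(fx$truth$variants$variant,
                                    rep$impacts$variant)]
  expect_equal(got, fx$truth$variants$expected_category)
  # zero variants: inventory only
  rep0 <- suppressMessages(study_report(fx$pwm, fx$reference, fx$model, list()))
  expect_equal(nrow(rep0$impacts), 0L)
  expect_equal(nrow(rep0$inventory), 5L)

  # an SNV dropping the strongest intron-1 element disturbs it
  top <- fx$truth$planted[which.max(fx$truth$planted$raw_score), ]
  L <- motif_length(fx$pwm)
  contig_pos <- top$start + (L - 2L)   # motif column 2 on the minus strand
  rb <- substr(fx$reference, contig_pos + 1L, contig_pos + 1L)
  weights <- fx$pwm$weights
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # pick the alternative whose motif-strand base has the lowest weight
  alts <- setdiff(c("A", "C", "G", "T"), rb)
  walt <- weights[comp[alts], 2L]
  ab <- alts[which.min(walt)]
  v <- parse_cvariant(sprintf("c.42-%d%s>%s", 3541L - contig_pos, rb, ab))
  res <- assess_variant(fx$pwm, fx$reference, fx$model, v)
  expect_equal(res$category, "disrupts")
  expect_gt(res$pct_change, 0)
})
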