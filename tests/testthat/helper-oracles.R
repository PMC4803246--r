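# Shared fixtures and independent oracles for the test suite.

# deliberately naive scanner: scores every window on both strands one at a
# time through score_window(); the reference the fast scanner is checked
# against
brute_force_scan <- function(pwm, sequence, threshold) {
  L <- motif_length(pwm)
  n <- nchar(sequence)
  rows <- list()
  if (n >= L) {
    for (s in 0:(n - L)) {
      w <- substr(sequence, s + 1L, s + L)
      for (strand in c(1L, -1L)) {
        site <- if (strand > 0) w else {
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
        }
        raw <- score_window(pwm, site)
        rel <- relative_score(pwm, raw)
        if (rel >= threshold) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = s, strand = strand, raw_score = raw, relative_score = rel,
            site = site, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), strand = integer(),
                      raw_score = numeric(), relative_score = numeric(),
                      site = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, -out$strand), , drop = FALSE]
}

random_count_matrix <- function(L = NULL) {
  if (is.null(L)) L <- sample(4:12, 1L)
  counts <- matrix(rpois(4L * L, lambda = 8), nrow = 4L)
  # guarantee at least one informative, non-degenerate column
  counts[, 1L] <- c(30L, 1L, 1L, 1L)
  count_matrix(counts)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# toy two-exon gene used throughout the coordinate tests:
# exon1 = [1500, 1541), exon2 = [3541, 3691), ATG at 1500
toy_model <- function() {
  gene_model(rbind(c(1500L, 1541L), c(3541L, 3691L)),
             translation_start = 1500L, contig_id = "toy")
}

test_pwm <- function() build_pwm(dr3_matrix())
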