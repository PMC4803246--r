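DNA_BASES <- c("A", "C", "G", "T")

#' Build a log-odds position weight matrix
#'
#' Converts a base-count matrix into log2-odds weights against a background
#' base composition, with a pseudocount distributed proportionally to the
#' background:
#' \deqn{w_{b,i} = \log_2 \frac{c_{b,i} + p \cdot q_b}{(N_i + p)\, q_b}}
#' where \eqn{c_{b,i}} is the count of base b at position i, \eqn{N_i} the
#' column total, \eqn{q_b} the background probability and p the pseudocount.
#'
#' @param cm a `count_matrix`.
#' @param background named numeric of base probabilities (A,C,G,T), summing
#'   to 1. Default uniform.
#' @param pseudocount positive smoothing mass; default 0.8.
#' @return A `pwm` object with `weights` (4 x L, log2), `background`,
#'   `pseudocount`, and the best/worst achievable window scores
#'   `max_score` / `min_score`.
#' @examples
#' pwm <- build_pwm(count_matrix(matrix(c(100, 0, 0, 0), nrow = 4)))
#' pwm$max_score
#' @export
build_pwm <- function(cm, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      pseudocount = 0.8) {
  stopifnot(inherits(cm, "count_matrix"))
  background <- background[DNA_BASES]
  if (anyNA(background) || any(background <= 0)) {
    stop("background must give a positive probability to each of A,C,G,T", call. = FALSE)
  }
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  totals <- colSums(cm$counts)
  if (pseudocount == 0 && any(totals == 0)) {
    stop("degenerate matrix: zero-total column with zero pseudocount", call. = FALSE)
  }
  probs <- (cm$counts + pseudocount * background) /
    rep(totals + pseudocount, each = 4L)
  weights <- log2(probs / background)
  rownames(weights) <- DNA_BASES
  structure(list(
    motif_id = cm$motif_id,
    weights = weights,
    background = background,
    pseudocount = pseudocount,
    max_score = sum(apply(weights, 2L, max)),
    min_score = sum(apply(weights, 2L, min))
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM '", x$motif_id, "': ", ncol(x$weights), " positions, score range [",
      round(x$min_score, 3), ", ", round(x$max_score, 3), "] bits\n", sep = "")
  invisible(x)
}

#' Score a single window against a PWM
#'
#' @param pwm a `pwm`.
#' @param window DNA string of exactly the motif length (A/C/G/T only).
#' @return raw log2-odds score (sum of per-position weights).
#' @export
score_window <- function(pwm, window) {
  stopifnot(inherits(pwm, "pwm"))
  L <- ncol(pwm$weights)
  bases <- strsplit(toupper(window), "", fixed = TRUE)[[1L]]
  if (length(bases) != L) {
    stop("window length ", length(bases), " != motif length ", L, call. = FALSE)
  }
  idx <- match(bases, DNA_BASES)
  if (anyNA(idx)) stop("window contains non-ACGT base", call. = FALSE)
  sum(pwm$weights[cbind(idx, seq_len(L))])
}

#' Min-max relative score of a raw PWM score
#'
#' Maps a raw log-odds score onto the 0-100 scale used for scan thresholds:
#' `100 * (raw - min_score) / (max_score - min_score)`.
#'
#' @param pwm a `pwm`.
#' @param raw raw score(s).
#' @return percent score(s) in \[0, 100\] for achievable raw scores.
#' @export
relative_score <- function(pwm, raw) {
  stopifnot(inherits(pwm, "pwm"))
  rng <- pwm$max_score - pwm$min_score
  if (rng <= 0) stop("degenerate matrix: max_score equals min_score", call. = FALSE)
  # clamp: achievable scores live in [min, max] but vectorized sums can land
  # a rounding error outside
  pmin(100, pmax(0, 100 * (raw - pwm$min_score) / rng))
}

#' Consensus sequence of a PWM
#'
#' Per-position argmax base, ties broken alphabetically (A < C < G < T).
#'
#' @param pwm a `pwm`.
#' @return DNA string of the motif length.
#' @export
consensus <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  paste(DNA_BASES[apply(pwm$weights, 2L, which.max)], collapse = "")
}

#' Anti-consensus (worst-scoring) sequence of a PWM
#' @param pwm a `pwm`.
#' @return DNA string scoring `min_score`.
#' @export
anti_consensus <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  paste(DNA_BASES[apply(pwm$weights, 2L, which.min)], collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Vectorized per-window raw scores along one strand. Windows containing a
# non-ACGT base score NA and are reported via attribute "n_skipped".
window_scores <- function(pwm, sequence) {
  L <- ncol(pwm$weights)
  bases <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(bases)
  if (n < L) return(numeric(0))
  idx <- match(bases, DNA_BASES)
  nw <- n - L + 1L
  scores <- numeric(nw)
  for (j in seq_len(L)) {
    pos <- seq.int(j, j + nw - 1L)
    scores <- scores + pwm$weights[cbind(idx[pos], j)]  # NA where base is not ACGT
  }
  scores
}

#' Scan a sequence for PWM hits on both strands
#'
#' Every window whose min-max relative score reaches `threshold` is
#' returned, on both the forward and reverse strand. Reverse-strand hits
#' report the reverse-complemented site (motif orientation) and strand -1;
#' `start` is always the 0-based offset of the window on the forward
#' strand. Windows containing non-ACGT bases are skipped (a message reports
#' how many).
#'
#' @param pwm a `pwm`.
#' @param sequence DNA string (or `DNAString`).
#' @param threshold relative-score cutoff in \[0, 100\]; default 70, with 80
#'   the conventional stricter setting.
#' @param sequence_id label carried into the hit table.
#' @return data.frame of class `motif_hits` with columns `sequence_id`,
#'   `start` (0-based), `strand` (+1/-1), `raw_score`, `relative_score`,
#'   `site`; sorted by start, forward strand first at equal start.
#' @examples
#' cm <- count_matrix(matrix(c(9, 0, 0, 1, 0, 0, 10, 0), nrow = 4))
#' pwm <- build_pwm(cm)
#' scan_sequence(pwm, "TTAGTT", threshold = 90)
#' @export
scan_sequence <- function(pwm, sequence, threshold = 70, sequence_id = "seq") {
  stopifnot(inherits(pwm, "pwm"))
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  if (threshold < 0 || threshold > 100) stop("threshold must be in [0,100]", call. = FALSE)
  L <- ncol(pwm$weights)
  n <- nchar(sequence)
  empty <- data.frame(sequence_id = character(), start = integer(),
                      strand = integer(), raw_score = numeric(),
                      relative_score = numeric(), site = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("motif_hits", "data.frame")
  if (n < L) {
    message("sequence '", sequence_id, "' shorter than motif (", n, " < ", L,
            "); no windows scanned")
    return(empty)
  }
  fwd <- window_scores(pwm, sequence)
  rc <- revcomp(sequence)
  rev_rc <- window_scores(pwm, rc)
  # window starting at i (0-based) on the forward strand corresponds, on the
  # reverse strand, to the rc window starting at n - L - i
  rev <- rev_rc[(n - L + 1L):1L]

  n_skipped <- sum(is.na(fwd))
  if (n_skipped > 0) {
    message(n_skipped, " window(s) with non-ACGT bases skipped on '",
            sequence_id, "'")
  }

  collect <- function(scores, strand) {
    rel <- relative_score(pwm, scores)
    keep <- which(!is.na(rel) & rel >= threshold)
    if (!length(keep)) return(NULL)
    starts <- keep - 1L
    sites <- vapply(starts, function(s) {
      w <- substr(sequence, s + 1L, s + L)
      if (strand > 0) w else revcomp(w)
    }, character(1))
    data.frame(sequence_id = sequence_id, start = starts,
               strand = strand, raw_score = scores[keep],
               relative_score = rel[keep], site = toupper(sites),
               stringsAsFactors = FALSE)
  }
  hits <- rbind(collect(fwd, 1L), collect(rev, -1L))
  if (is.null(hits)) return(empty)
  hits <- hits[order(hits$start, -hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("motif_hits", "data.frame")
  hits
}

#' Write a motif hit table as TSV
#'
#' Reports 1-based inclusive coordinates, +/- strand symbols, raw scores to
#' 3 decimals and relative scores to 1 decimal.
#'
#' @param hits a `motif_hits` data.frame from [scan_sequence()].
#' @param path output file path.
#' @param motif_length motif length used to derive the end coordinate.
#' @return the reformatted data.frame, invisibly.
#' @export
write_hits_tsv <- function(hits, path, motif_length) {
  out <- data.frame(
    sequence_id = hits$sequence_id,
    start = hits$start + 1L,
    end = hits$start + motif_length,
    strand = ifelse(hits$strand > 0, "+", "-"),
    site = hits$site,
    raw_score = sprintf("%.3f", hits$raw_score),
    relative_score = sprintf("%.1f", hits$relative_score),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
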