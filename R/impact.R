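#' Best-scoring motif hit overlapping a locus
#'
#' Among hits whose window `[start, start + L)` overlaps the 0-based
#' half-open `locus` interval, returns the one with maximal raw score; ties
#' go to the smaller start, then to the forward strand.
#'
#' @param hits a `motif_hits` data.frame.
#' @param locus numeric length-2: 0-based half-open interval.
#' @param motif_length motif length L.
#' @return single-row `motif_hits` data.frame, or `NULL` when no hit
#'   overlaps.
#' @export
best_hit_over_locus <- function(hits, locus, motif_length) {
  if (locus[2L] <= locus[1L]) stop("locus must be non-empty", call. = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  ov <- hits$start < locus[2L] & (hits$start + motif_length) > locus[1L]
  cand <- hits[ov, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  ord <- order(-cand$raw_score, cand$start, -cand$strand)
  out <- cand[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score the impact of a variant on the best local motif hit
#'
#' Scans a padded window around the variant locus in both the wild-type and
#' the mutant allele (unthresholded), picks the best hit overlapping the
#' locus in each, and reports the percent score reduction
#' `100 * (wt - mut) / wt` (positive = the variant weakens the site).
#' For insertions and duplications the mutant locus is widened by the
#' inserted length so shifted copies still count as overlapping, and the
#' category is `creates/duplicates` when the mutant allele carries strictly
#' more above-threshold hits over the locus than the wild type.
#'
#' @param pwm a `pwm`.
#' @param reference contig DNA string.
#' @param model a `gene_model`.
#' @param v a `cvariant`.
#' @param window_pad bases of context scanned either side of the variant
#'   locus; must be at least L - 1. Default 30.
#' @param threshold relative-score cutoff used only for hit counting /
#'   categorisation (best-hit selection is unthresholded). Default 70.
#' @param score_scale `"raw"` (log2-odds; default) or `"relative"`
#'   (min-max percent) as the scale for `pct_change`.
#' @return An `impact_result` list: `variant`, `locus` (wild-type contig
#'   interval), `wt_best`, `mut_best` (hit rows or NULL), `wt_raw`,
#'   `mut_raw`, `pct_change` (NA when undefined), `category` one of
#'   `"disrupts"`, `"creates/duplicates"`, `"none"`.
#' @export
assess_variant <- function(pwm, reference, model, v, window_pad = 30L,
                           threshold = 70, score_scale = c("raw", "relative")) {
  stopifnot(inherits(pwm, "pwm"), inherits(v, "cvariant"))
  score_scale <- match.arg(score_scale)
  if (inherits(reference, "DNAString")) reference <- as.character(reference)
  L <- motif_length(pwm)
  if (window_pad < L - 1L) stop("window_pad must be >= motif length - 1", call. = FALSE)

  mut <- apply_variant(reference, model, v)
  iv <- mut$interval
  n <- nchar(reference)

  win_lo <- max(0L, iv[["start"]] - window_pad)
  win_hi <- min(n, iv[["end"]] + window_pad)
  wt_win <- substr(reference, win_lo + 1L, win_hi)
  # mutant window: same left edge; right edge shifts with the length change
  mut_hi <- min(nchar(mut$seq), win_hi + max(0L, mut$length_change))
  mut_win <- substr(mut$seq, win_lo + 1L, mut_hi)

  wt_hits <- scan_sequence(pwm, wt_win, threshold = 0, sequence_id = "wt")
  mut_hits <- scan_sequence(pwm, mut_win, threshold = 0, sequence_id = "mut")
  wt_hits$start <- wt_hits$start + win_lo
  mut_hits$start <- mut_hits$start + win_lo

  wt_locus <- c(iv[["start"]], iv[["end"]])
  mut_locus <- c(iv[["start"]], iv[["end"]] + max(0L, mut$length_change))

  count_over <- function(hits, locus) {
    if (nrow(hits) == 0L) return(0L)
    ov <- hits$start < locus[2L] & (hits$start + L) > locus[1L]
    sum(ov & hits$relative_score >= threshold)
  }
  n_wt <- count_over(wt_hits, wt_locus)
  n_mut <- count_over(mut_hits, mut_locus)

  if (n_wt == 0L && n_mut == 0L) {
    # no element at the working threshold overlaps the variant in either
    # allele: nothing to disturb
    wt_best <- mut_best <- NULL
    wt_raw <- mut_raw <- NA_real_
    pct_change <- 0
    category <- "none"
  } else {
    wt_best <- best_hit_over_locus(wt_hits, wt_locus, L)
    mut_best <- best_hit_over_locus(mut_hits, mut_locus, L)
    wt_raw <- if (is.null(wt_best)) NA_real_ else wt_best$raw_score
    mut_raw <- if (is.null(mut_best)) NA_real_ else mut_best$raw_score
    scale_of <- function(x) {
      if (is.na(x)) return(NA_real_)
      if (score_scale == "raw") x else relative_score(pwm, x)
    }
    wt_s <- scale_of(wt_raw); mut_s <- scale_of(mut_raw)
    pct_change <- if (is.na(wt_s) || wt_s <= 0) {
      message("wild-type best score <= 0 for '", v$raw_text,
              "'; pct_change undefined")
      NA_real_
    } else if (is.na(mut_s)) 100                         # site lost entirely
      else 100 * (wt_s - mut_s) / wt_s
    category <- if (n_mut > n_wt) "creates/duplicates"
      else if (!is.na(pct_change) && pct_change > 1e-9) "disrupts"
      else "none"
  }

  structure(list(variant = v, locus = wt_locus, wt_best = wt_best,
                 mut_best = mut_best, wt_raw = wt_raw, mut_raw = mut_raw,
                 pct_change = pct_change, category = category,
                 n_wt_hits = n_wt, n_mut_hits = n_mut,
                 score_scale = score_scale),
            class = "impact_result")
}

#' @export
print.impact_result <- function(x, ...) {
  cat("Variant ", x$variant$raw_text, ": ", x$category, sep = "")
  if (!is.na(x$pct_change)) {
    cat(sprintf(" (best local score %s by %.1f%%)",
                if (x$pct_change >= 0) "reduced" else "increased",
                abs(x$pct_change)))
  }
  cat("\n")
  invisible(x)
}

#' Region hit inventory and per-variant impact table
#'
#' Scans each named region for above-threshold motif hits (the element
#' inventory) and assesses every variant, mirroring a regulatory-element
#' survey figure: which elements exist, and which variants disturb or
#' duplicate them.
#'
#' @param pwm a `pwm`.
#' @param reference contig DNA string.
#' @param model a `gene_model`.
#' @param variants list of `cvariant` objects (may be empty).
#' @param regions list of region specs, each a list with `region`
#'   (`"promoter"`/`"intron"`/`"exon"`), optional `index` and
#'   `promoter_length`; default promoter(1500), intron 1, intron 2.
#' @param threshold relative-score cutoff for the inventory; default 70.
#' @param window_pad passed to [assess_variant()].
#' @return list with `inventory` (data.frame: region, start, end, strand,
#'   site, raw_score, relative_score, ordered by region then start) and
#'   `impacts` (data.frame: variant, kind, start, end, wt_raw, mut_raw,
#'   pct_change, category).
#' @export
study_report <- function(pwm, reference, model, variants = list(),
                         regions = NULL, threshold = 70, window_pad = 30L) {
  if (inherits(reference, "DNAString")) reference <- as.character(reference)
  if (is.null(regions)) {
    regions <- list(list(region = "promoter", promoter_length = 1500L),
                    list(region = "intron", index = 1L),
                    list(region = "intron", index = 2L))
  }
  L <- motif_length(pwm)
  inv <- do.call(rbind, lapply(regions, function(rs) {
    reg <- extract_region(model, reference, rs$region,
                          index = if (is.null(rs$index)) 1L else rs$index,
                          promoter_length = if (is.null(rs$promoter_length)) 1500L
                                            else rs$promoter_length)
    hits <- scan_sequence(pwm, reg$seq, threshold = threshold,
                          sequence_id = reg$name)
    if (nrow(hits) == 0L) return(NULL)
    data.frame(region = reg$name, start = hits$start + reg$start,
               end = hits$start + reg$start + L, strand = hits$strand,
               site = hits$site, raw_score = hits$raw_score,
               relative_score = hits$relative_score, stringsAsFactors = FALSE)
  }))
  if (is.null(inv)) {
    inv <- data.frame(region = character(), start = integer(), end = integer(),
                      strand = integer(), site = character(),
                      raw_score = numeric(), relative_score = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    inv <- inv[order(inv$region, inv$start), , drop = FALSE]
    rownames(inv) <- NULL
  }

  impacts <- do.call(rbind, lapply(variants, function(v) {
    res <- assess_variant(pwm, reference, model, v, window_pad = window_pad,
                          threshold = threshold)
    data.frame(variant = v$raw_text, kind = v$kind,
               start = res$locus[1L], end = res$locus[2L],
               wt_raw = res$wt_raw, mut_raw = res$mut_raw,
               pct_change = res$pct_change, category = res$category,
               stringsAsFactors = FALSE)
  }))
  if (is.null(impacts)) {
    impacts <- data.frame(variant = character(), kind = character(),
                          start = integer(), end = integer(),
                          wt_raw = numeric(), mut_raw = numeric(),
                          pct_change = numeric(), category = character(),
                          stringsAsFactors = FALSE)
  } else {
    impacts <- impacts[order(impacts$start), , drop = FALSE]
    rownames(impacts) <- NULL
  }
  list(inventory = inv, impacts = impacts)
}
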