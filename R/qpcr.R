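#' Relative expression from target and reference CT values
#'
#' Comparative CT quantification: `2^-(target_ct - reference_ct)`, the
#' expression of the target gene relative to the internal control gene
#' (e.g. beta-actin) in the same sample.
#'
#' @param target_ct target-gene cycle threshold(s).
#' @param reference_ct reference-gene cycle threshold(s).
#' @return relative expression value(s), > 0.
#' @examples
#' delta_ct(23, 24)  # one cycle earlier than the control gene: 2-fold
#' @export
delta_ct <- function(target_ct, reference_ct) {
  if (any(target_ct <= 0) || any(reference_ct <= 0)) {
    stop("CT values must be positive", call. = FALSE)
  }
  2^-(target_ct - reference_ct)
}

#' Read a qPCR plate table from TSV
#'
#' Expects columns `sample_id`, `gene`, `dose`, `replicate`, `ct`.
#'
#' @param path TSV file path.
#' @return data.frame of class `qpcr_plate`.
#' @export
read_qpcr <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_qpcr(tab)
}

#' Validate a data.frame as a qPCR plate
#' @param tab data.frame with columns `sample_id`, `gene`, `dose`,
#'   `replicate`, `ct`.
#' @return the validated table, classed `qpcr_plate`.
#' @export
as_qpcr <- function(tab) {
  need <- c("sample_id", "gene", "dose", "replicate", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("qPCR table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(tab$ct <= 0)) stop("CT values must be positive", call. = FALSE)
  class(tab) <- c("qpcr_plate", "data.frame")
  tab
}

# per-replicate relative expression of one target gene vs the reference gene,
# matched on (sample_id, dose, replicate)
replicate_rel_expr <- function(plate, gene, reference) {
  tg <- plate[plate$gene == gene, , drop = FALSE]
  rf <- plate[plate$gene == reference, , drop = FALSE]
  if (nrow(tg) == 0L) stop("no records for target gene '", gene, "'", call. = FALSE)
  if (nrow(rf) == 0L) stop("no records for reference gene '", reference, "'",
                           call. = FALSE)
  key <- function(d) paste(d$sample_id, d$dose, d$replicate, sep = "\r")
  idx <- match(key(tg), key(rf))
  if (anyNA(idx)) {
    stop("target records without a matching reference-gene record", call. = FALSE)
  }
  data.frame(dose = tg$dose, replicate = tg$replicate,
             rel_expr = delta_ct(tg$ct, rf$ct[idx]),
             stringsAsFactors = FALSE)
}

geomean <- function(x) exp(mean(log(x)))

#' Per-dose relative expression of a target gene
#'
#' Aggregates replicate `2^-dCT` values per dose. Replicates are combined
#' by their geometric mean (equivalently, the arithmetic mean of dCT), the
#' standard choice for exponential quantities; `type = "arithmetic"` uses
#' the plain mean instead.
#'
#' @param plate a `qpcr_plate`.
#' @param gene target gene name.
#' @param reference reference gene name (default `"ACTB"`).
#' @param type replicate aggregation, `"geometric"` (default) or
#'   `"arithmetic"`.
#' @return data.frame with `gene`, `dose`, `n`, `rel_expr` (aggregated),
#'   `sd_log2` (sd of the replicate log2 relative expressions).
#' @export
relative_expression <- function(plate, gene, reference = "ACTB",
                                type = c("geometric", "arithmetic")) {
  type <- match.arg(type)
  rr <- replicate_rel_expr(plate, gene, reference)
  doses <- sort(unique(rr$dose))
  out <- do.call(rbind, lapply(doses, function(d) {
    x <- rr$rel_expr[rr$dose == d]
    data.frame(gene = gene, dose = d, n = length(x),
               rel_expr = if (type == "geometric") geomean(x) else mean(x),
               sd_log2 = stats::sd(log2(x)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fold change of a treated replicate set versus control
#'
#' Ratio of aggregated relative expressions (geometric by default, so the
#' fold equals `2^-ddCT`); the standard deviation is propagated to first
#' order from the replicate spreads.
#'
#' @param treated numeric vector of replicate relative expressions at the
#'   treated dose.
#' @param control replicate relative expressions at the control dose.
#' @param type aggregation as in [relative_expression()].
#' @return list with `fold` and `sd` (first-order propagated).
#' @export
fold_change <- function(treated, control, type = c("geometric", "arithmetic")) {
  type <- match.arg(type)
  if (length(treated) == 0L || length(control) == 0L) {
    stop("both replicate sets must be non-empty", call. = FALSE)
  }
  if (any(treated <= 0) || any(control <= 0)) {
    stop("relative expressions must be positive", call. = FALSE)
  }
  agg <- if (type == "geometric") geomean else mean
  f <- agg(treated) / agg(control)
  # first-order: var(f)/f^2 = rel-var(treated mean) + rel-var(control mean)
  relvar <- function(x) {
    if (length(x) < 2L) return(0)
    if (type == "geometric") (log(2)^2) * stats::var(log2(x)) / length(x)
    else stats::var(x) / (length(x) * mean(x)^2)
  }
  list(fold = f, sd = f * sqrt(relvar(treated) + relvar(control)))
}

#' Dose-response fold changes for a target gene
#'
#' @param plate a `qpcr_plate`.
#' @param gene target gene.
#' @param reference reference gene (default `"ACTB"`).
#' @param control_dose dose of the untreated control (default 0).
#' @param type aggregation as in [relative_expression()].
#' @return data.frame with `gene`, `dose`, `n`, `rel_expr`, `fold_change`,
#'   `fold_sd`; the control dose has fold 1 by construction.
#' @export
dose_response <- function(plate, gene, reference = "ACTB", control_dose = 0,
                          type = c("geometric", "arithmetic")) {
  type <- match.arg(type)
  rr <- replicate_rel_expr(plate, gene, reference)
  if (!control_dose %in% rr$dose) {
    stop("control dose ", control_dose, " absent from plate", call. = FALSE)
  }
  ctrl <- rr$rel_expr[rr$dose == control_dose]
  re <- relative_expression(plate, gene, reference, type = type)
  fc <- lapply(re$dose, function(d) {
    fold_change(rr$rel_expr[rr$dose == d], ctrl, type = type)
  })
  re$fold_change <- vapply(fc, `[[`, numeric(1), "fold")
  re$fold_sd <- vapply(fc, `[[`, numeric(1), "sd")
  re
}

#' Test for a dose-dependent expression trend
#'
#' Least-squares regression of per-replicate log2 relative expression on
#' the numeric dose; the slope's two-sided p-value tests dose dependence.
#'
#' @param plate a `qpcr_plate`.
#' @param gene target gene.
#' @param reference reference gene (default `"ACTB"`).
#' @return list with `slope` (log2 fold per dose unit), `se`, `p`,
#'   `n_doses`, and the fitted `model`.
#' @export
dose_trend <- function(plate, gene, reference = "ACTB") {
  rr <- replicate_rel_expr(plate, gene, reference)
  nd <- length(unique(rr$dose))
  if (nd < 3L) stop("dose trend needs >= 3 distinct doses (got ", nd, ")",
                    call. = FALSE)
  fit <- stats::lm(log2(rel_expr) ~ dose, data = rr)
  cf <- summary(fit)$coefficients["dose", ]
  list(slope = unname(cf[1L]), se = unname(cf[2L]), p = unname(cf[4L]),
       n_doses = nd, model = fit)
}
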