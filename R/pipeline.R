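#' Read a FASTA reference
#'
#' @param path FASTA file path.
#' @return named character vector of sequences; names are the first word of
#'   each header.
#' @export
read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  out <- as.character(dna)
  names(out) <- vapply(strsplit(names(dna), "\\s+"), `[[`, character(1), 1L)
  out
}

#' Study inclusion bookkeeping
#'
#' @param recruited number of subjects recruited.
#' @param exclusions named integer vector of exclusion counts by reason.
#' @return list with `recruited`, `excluded` (named), `analyzed`
#'   (= recruited - sum of exclusions), and a `ledger` data.frame with the
#'   running remainder after each exclusion.
#' @examples
#' apply_inclusion(158, c(`coding defect` = 127, hypoglycosylation = 8))$analyzed
#' @export
apply_inclusion <- function(recruited, exclusions = integer()) {
  if (recruited < 0) stop("recruited must be >= 0", call. = FALSE)
  if (any(exclusions < 0)) stop("exclusion counts must be >= 0", call. = FALSE)
  remaining <- recruited - cumsum(as.numeric(exclusions))
  if (any(remaining < 0)) {
    stop("exclusions exceed recruited subjects (remainder ",
         min(remaining), ")", call. = FALSE)
  }
  analyzed <- recruited - sum(exclusions)
  ledger <- data.frame(
    reason = if (length(exclusions)) names(exclusions) else character(),
    excluded = as.integer(exclusions),
    remaining = as.integer(remaining),
    stringsAsFactors = FALSE)
  list(recruited = as.integer(recruited),
       excluded = exclusions, analyzed = as.integer(analyzed), ledger = ledger)
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full study pipeline
#'
#' Orchestrates inclusion bookkeeping, the regulatory-element scan and
#' variant impact report, cohort statistics, and qPCR expression analysis,
#' and returns one structured report. Each stage is driven by its entry in
#' `config` and marked `"skipped"` when absent. A stage failure aborts with
#' an error naming the stage.
#'
#' @param config a list with optional entries:
#'   \describe{
#'     \item{inclusion}{list(recruited, exclusions = named vector)}
#'     \item{gene}{either `list(simulate = TRUE, seed, threshold)` to run on
#'       the synthetic fixture, or `list(matrix =, fasta =, gene_model =,
#'       variants =, threshold =)` file paths}
#'     \item{cohort}{either `list(simulate = TRUE, seed, ...)` (arguments to
#'       [simulate_cohort()]) or `list(path =)` a cohort TSV; plus optional
#'       `covariates`}
#'     \item{expression}{either `list(simulate = TRUE, seed, ...)` or
#'       `list(path =)` a plate TSV; plus `genes`, `reference`,
#'       `control_dose`}
#'   }
#' @param out_dir optional directory; when given, the report is written to
#'   `report.json` (sorted keys, 6 significant digits).
#' @return a `study_run` list with one element per stage plus `provenance`.
#' @export
run_study <- function(config, out_dir = NULL) {
  report <- list()
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    stage_log(stage, sprintf("done in %.2fs", proc.time()[["elapsed"]] - t0))
    out
  }

  report$inclusion <- if (is.null(config$inclusion)) "skipped" else {
    run_stage("inclusion", function() {
      inc <- apply_inclusion(config$inclusion$recruited,
                             unlist(config$inclusion$exclusions))
      inc[c("recruited", "excluded", "analyzed")]
    })
  }

  report$vdre <- if (is.null(config$gene)) "skipped" else {
    run_stage("vdre_scan", function() {
      gc <- config$gene
      thr <- if (is.null(gc$threshold)) 70 else gc$threshold
      if (isTRUE(gc$simulate)) {
        fx <- simulate_gene_fixture(seed = if (is.null(gc$seed)) 1L else gc$seed,
                                    threshold = thr)
        rep_ <- suppressMessages(
          study_report(fx$pwm, fx$reference, fx$model, fx$variants,
                       threshold = thr))
      } else {
        pwm <- build_pwm(read_jaspar(gc$matrix))
        ref <- read_fasta(gc$fasta)[[1L]]
        model <- read_gene_model(gc$gene_model)
        variants <- lapply(readLines(gc$variants, warn = FALSE), parse_cvariant)
        rep_ <- suppressMessages(
          study_report(pwm, ref, model, variants, threshold = thr))
      }
      list(inventory = rep_$inventory, impacts = rep_$impacts)
    })
  }

  report$association <- if (is.null(config$cohort)) "skipped" else {
    run_stage("cohort_stats", function() {
      cc <- config$cohort
      cohort <- if (isTRUE(cc$simulate)) {
        args <- cc[setdiff(names(cc), c("simulate", "covariates"))]
        do.call(simulate_cohort, args)$cohort
      } else read_cohort(cc$path)
      covs <- if (is.null(cc$covariates)) c("age", "sex", "rs2227589")
              else cc$covariates
      m <- maf(cohort)
      tt <- dominant_ttest(cohort)
      adj <- adjusted_association(cohort, covs)
      list(maf = m,
           hwe_p = hwe_exact(m$n_het, m$n_hom, m$n_genotyped - m$n_carriers),
           dominant = tt[c("pooled", "welch", "carriers", "noncarriers")],
           adjusted = adj[c("estimate", "se", "t", "df", "p", "n")])
    })
  }

  report$expression <- if (is.null(config$expression)) "skipped" else {
    run_stage("expression", function() {
      ec <- config$expression
      plate <- if (isTRUE(ec$simulate)) {
        args <- ec[setdiff(names(ec), c("simulate", "genes", "reference",
                                        "control_dose"))]
        do.call(simulate_qpcr, args)$plate
      } else read_qpcr(ec$path)
      refg <- if (is.null(ec$reference)) "ACTB" else ec$reference
      ctrl <- if (is.null(ec$control_dose)) 0 else ec$control_dose
      genes <- if (is.null(ec$genes)) setdiff(unique(plate$gene), refg)
               else ec$genes
      lapply(stats::setNames(genes, genes), function(g) {
        dr <- dose_response(plate, g, reference = refg, control_dose = ctrl)
        tr <- dose_trend(plate, g, reference = refg)
        list(dose_response = dr, trend = tr[c("slope", "se", "p", "n_doses")])
      })
    })
  }

  report$provenance <- list(
    config = config[order(names(config))],
    timestamp = NULL,  # deliberately omitted: reports are byte-reproducible
    package_version = as.character(utils::packageVersion("vdrescan")))

  class(report) <- "study_run"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(out_dir, "report.json")
    jsonlite::write_json(sort_keys(unclass(report)), path, auto_unbox = TRUE,
                         digits = 6, dataframe = "rows", force = TRUE,
                         null = "null")
    stage_log("report", paste("written to", path))
  }
  report
}

# recursively sort list keys for byte-stable JSON
sort_keys <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    lapply(x, sort_keys)
  } else x
}

#' @export
print.study_run <- function(x, ...) {
  cat("Study run:\n")
  for (nm in setdiff(names(x), "provenance")) {
    if (identical(x[[nm]], "skipped")) {
      cat("  ", nm, ": skipped\n", sep = "")
    } else {
      cat("  ", nm, ": computed\n", sep = "")
    }
  }
  invisible(x)
}
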