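#' Read a cohort table from TSV
#'
#' Expects a header with columns `id`, `genotype` (0/1/2 copies of the
#' minor allele; NA allowed), `antifxa` (anti-FXa activity as percent of
#' the reference pool), `age`, `sex`, `rs2227589` (0/1/2).
#'
#' @param path TSV file path.
#' @return data.frame of class `cohort_table`.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_cohort(tab)
}

#' Validate a data.frame as a cohort table
#' @param tab data.frame with the columns described in [read_cohort()].
#' @return the validated data.frame, classed `cohort_table`.
#' @export
as_cohort <- function(tab) {
  need <- c("id", "genotype", "antifxa", "age", "sex", "rs2227589")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("cohort table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- !(tab$genotype %in% c(0L, 1L, 2L) | is.na(tab$genotype))
  if (any(bad)) stop("genotype must be 0, 1, 2 or NA", call. = FALSE)
  if (any(tab$antifxa <= 0, na.rm = TRUE)) stop("antifxa must be positive", call. = FALSE)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Minor allele frequency and carrier counts
#'
#' MAF = (het + 2 * hom) / (2 * n genotyped). Missing genotypes are
#' excluded. The unrounded frequency is returned.
#'
#' @param cohort a `cohort_table`, or an integer genotype vector (0/1/2/NA).
#' @return list with `maf`, `n_het`, `n_hom`, `n_genotyped`, `n_carriers`.
#' @examples
#' maf(c(rep(0, 302), rep(1, 5)))$maf  # 5 heterozygotes among 307
#' @export
maf <- function(cohort) {
  g <- if (inherits(cohort, "cohort_table")) cohort$genotype else cohort
  g <- g[!is.na(g)]
  if (length(g) == 0L) stop("no non-missing genotypes", call. = FALSE)
  n_het <- sum(g == 1L); n_hom <- sum(g == 2L)
  list(maf = (n_het + 2 * n_hom) / (2 * length(g)),
       n_het = n_het, n_hom = n_hom, n_genotyped = length(g),
       n_carriers = n_het + n_hom)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed minor-allele count, the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed table.
#'
#' @param het observed heterozygote count.
#' @param hom_minor observed minor-allele homozygote count.
#' @param hom_major observed major-allele homozygote count.
#' @return p-value in (0, 1].
#' @export
hwe_exact <- function(het, hom_minor, hom_major) {
  if (any(c(het, hom_minor, hom_major) < 0)) stop("counts must be >= 0", call. = FALSE)
  n <- het + hom_minor + hom_major
  if (n < 1L) stop("total count must be >= 1", call. = FALSE)
  n_a <- het + 2L * hom_minor          # minor allele count
  if (n_a == 0L || n_a == 2L * n) return(1)
  # heterozygote count has the parity of the allele count
  hets <- seq.int(n_a %% 2L, min(n_a, 2L * n - n_a), by = 2L)
  # log conditional probability of each possible het count (normalized below)
  logp <- vapply(hets, function(h) {
    a <- (n_a - h) / 2          # minor homs
    b <- n - h - a              # major homs
    lgamma(n + 1) - lgamma(h + 1) - lgamma(a + 1) - lgamma(b + 1) + h * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(het, hets)]
  if (is.na(obs)) stop("het count ", het, " impossible for allele count ", n_a,
                       call. = FALSE)
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Dominant-model two-sample t-test on a quantitative trait
#'
#' Compares anti-FXa activity between carriers (genotype > 0) and
#' non-carriers; both the pooled-variance (Student) and Welch variants are
#' returned. Missing genotypes are dropped.
#'
#' @param cohort a `cohort_table`.
#' @return list with elements `pooled` and `welch`, each `(t, df, p)`, plus
#'   per-group summaries `carriers` and `noncarriers` `(n, mean, sd)`.
#' @export
dominant_ttest <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  keep <- !is.na(cohort$genotype) & !is.na(cohort$antifxa)
  x <- cohort$antifxa[keep & cohort$genotype > 0]
  y <- cohort$antifxa[keep & cohort$genotype == 0]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each genotype group needs n >= 2 (carriers: ", length(x),
         ", non-carriers: ", length(y), ")", call. = FALSE)
  }
  pl <- stats::t.test(x, y, var.equal = TRUE)
  we <- stats::t.test(x, y, var.equal = FALSE)
  list(pooled = list(t = unname(pl$statistic), df = unname(pl$parameter),
                     p = pl$p.value),
       welch = list(t = unname(we$statistic), df = unname(we$parameter),
                    p = we$p.value),
       carriers = list(n = length(x), mean = mean(x), sd = stats::sd(x)),
       noncarriers = list(n = length(y), mean = mean(y), sd = stats::sd(y)))
}

#' Two-sample t-test from group summary statistics
#'
#' @param n1,mean1,sd1 first group (e.g. carriers).
#' @param n2,mean2,sd2 second group.
#' @return list with `pooled` and `welch` results, each `(t, df, p)`.
#' @examples
#' ttest_from_summary(8, 90.7, 6.5, 299, 96.4, 7.5)$pooled$p
#' @export
ttest_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2L || n2 < 2L) stop("both groups need n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("sd must be >= 0", call. = FALSE)
  d <- mean1 - mean2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t_p <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  df_p <- n1 + n2 - 2
  se1 <- sd1^2 / n1; se2 <- sd2^2 / n2
  t_w <- d / sqrt(se1 + se2)
  df_w <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  list(pooled = list(t = t_p, df = df_p, p = 2 * stats::pt(-abs(t_p), df_p)),
       welch = list(t = t_w, df = df_w, p = 2 * stats::pt(-abs(t_w), df_w)))
}

#' Covariate-adjusted association of carrier status with the trait
#'
#' Ordinary least-squares model `antifxa ~ carrier + covariates`, the
#' standard way to adjust a two-group mean comparison for age, sex and a
#' background genotype. `rs2227589` enters as a carrier (dominant)
#' indicator, mirroring the coding of the tested variant. Rows with missing
#' values in any used column are dropped listwise.
#'
#' @param cohort a `cohort_table`.
#' @param covariates character vector drawn from `age`, `sex`, `rs2227589`
#'   (or any numeric column of the table); may be empty.
#' @return list with `estimate` (carrier effect on anti-FXa, percentage
#'   points), `se`, `t`, `df`, `p`, `n`, and the fitted `model`.
#' @export
adjusted_association <- function(cohort, covariates = c("age", "sex", "rs2227589")) {
  stopifnot(inherits(cohort, "cohort_table"))
  dat <- as.data.frame(cohort)
  dat$carrier <- as.integer(dat$genotype > 0)
  if ("rs2227589" %in% covariates) {
    dat$rs2227589 <- as.integer(dat$rs2227589 > 0)
  }
  if (anyDuplicated(covariates)) stop("duplicate covariate: ",
    paste(covariates[duplicated(covariates)], collapse = ", "), call. = FALSE)
  used <- c("antifxa", "carrier", covariates)
  dat <- dat[stats::complete.cases(dat[, used, drop = FALSE]), used, drop = FALSE]
  form <- stats::as.formula(paste("antifxa ~ carrier",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- stats::lm(form, data = dat)
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    alias <- colnames(X)[is.na(stats::coef(fit))]
    stop("collinear design: ", paste(alias, collapse = ", "), call. = FALSE)
  }
  cf <- summary(fit)$coefficients["carrier", ]
  list(estimate = unname(cf[1L]), se = unname(cf[2L]), t = unname(cf[3L]),
       df = fit$df.residual, p = unname(cf[4L]), n = nrow(dat), model = fit)
}

#' Normal-approximation confidence interval for a mean
#'
#' `mean +/- z * sd / sqrt(n)`; with `level = 0.95`, z = 1.959964. Set
#' `use_t = TRUE` for the t-quantile instead.
#'
#' @param n sample size (>= 2).
#' @param mean sample mean.
#' @param sd sample standard deviation.
#' @param level confidence level in (0, 1); default 0.95.
#' @param use_t use the t-distribution quantile with n - 1 df.
#' @return numeric `c(low, high)`.
#' @examples
#' round(mean_ci(100, 97.1, 6.6), 1)  # reference-pool interval
#' @export
mean_ci <- function(n, mean, sd, level = 0.95, use_t = FALSE) {
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  q <- if (use_t) stats::qt(1 - (1 - level) / 2, df = n - 1)
       else stats::qnorm(1 - (1 - level) / 2)
  half <- q * sd / sqrt(n)
  c(low = mean - half, high = mean + half)
}
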