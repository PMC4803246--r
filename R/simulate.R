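# All generators are pure functions of (arguments, seed): they run under a
# local RNG state and restore the caller's state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

#' Simulate background DNA
#'
#' i.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`.
#'
#' @param length sequence length (>= 1).
#' @param gc GC fraction in \[0, 1\]; default 0.4.
#' @param seed RNG seed (integer); identical seeds give identical sequences.
#' @return DNA string.
#' @export
simulate_background <- function(length, gc = 0.4, seed = NULL) {
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (gc < 0 || gc > 1) stop("gc must be in [0,1]", call. = FALSE)
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Plant a motif instance at a controlled relative score
#'
#' Starts from the PWM consensus and greedily applies, one at a time, the
#' single-base substitution whose relative score lands closest to
#' `target_relative` without dropping below `target_relative - tolerance`,
#' stopping once the site scores within `target_relative +/- tolerance`.
#' The site (reverse-complemented for strand -1) overwrites the sequence at
#' `position`.
#'
#' @param sequence DNA string to plant into.
#' @param pwm a `pwm`.
#' @param position 0-based offset of the site on the forward strand.
#' @param strand +1 or -1.
#' @param target_relative target relative score in (0, 100\].
#' @param tolerance acceptable deviation in percent points; default 1.
#' @param seed seed for tie-breaking among equally good substitutions.
#' @return list with `seq` (modified sequence), `site` (motif-orientation
#'   site), `start` (= position), `strand`, `raw_score`, `relative_score`.
#' @export
plant_motif <- function(sequence, pwm, position, strand = 1L,
                        target_relative = 100, tolerance = 1, seed = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  L <- motif_length(pwm)
  n <- nchar(sequence)
  if (position < 0L || position + L > n) stop("window does not fit", call. = FALSE)
  if (target_relative <= 0 || target_relative > 100) {
    stop("target_relative must be in (0,100]", call. = FALSE)
  }
  with_seed(seed, {
    site <- consensus(pwm)
    rel <- relative_score(pwm, score_window(pwm, site))
    lo <- target_relative - tolerance
    hi <- target_relative + tolerance
    while (rel > hi) {
      bases <- strsplit(site, "", fixed = TRUE)[[1L]]
      cand <- expand.grid(pos = seq_len(L), base = DNA_BASES,
                          stringsAsFactors = FALSE)
      cand <- cand[bases[cand$pos] != cand$base, , drop = FALSE]
      cand$rel <- vapply(seq_len(nrow(cand)), function(i) {
        b2 <- bases; b2[cand$pos[i]] <- cand$base[i]
        relative_score(pwm, score_window(pwm, paste(b2, collapse = "")))
      }, numeric(1))
      ok <- cand$rel >= lo & cand$rel < rel
      if (!any(ok)) {
        stop(sprintf(
          "cannot reach relative score %.2f +/- %.2f; closest achievable from %.2f is %.2f",
          target_relative, tolerance, rel, max(cand$rel[cand$rel < rel])),
          call. = FALSE)
      }
      cand <- cand[ok, , drop = FALSE]
      best <- which(abs(cand$rel - target_relative) ==
                      min(abs(cand$rel - target_relative)))
      pick <- if (length(best) > 1L) sample(best, 1L) else best
      bases[cand$pos[pick]] <- cand$base[pick]
      site <- paste(bases, collapse = "")
      rel <- cand$rel[pick]
    }
    written <- if (strand > 0) site else revcomp(site)
    out <- paste0(substr(sequence, 1L, position),
                  written,
                  substr(sequence, position + L + 1L, n))
    list(seq = out, site = site, start = position, strand = as.integer(strand),
         raw_score = score_window(pwm, site),
         relative_score = rel)
  })
}

#' Packaged DR3-type position frequency matrix
#'
#' Loads the synthetic RXR/VDR-style direct-repeat matrix shipped with the
#' package (two hexamer half-sites spaced by 3 bp; 15 columns). It is a
#' constructed stand-in with the canonical DR3 structure, not a database
#' matrix.
#'
#' @return a `count_matrix`.
#' @export
dr3_matrix <- function() {
  read_jaspar(system.file("extdata", "synthetic_dr3.jaspar",
                          package = "vdrescan", mustWork = TRUE))
}

default_gene_geometry <- function() {
  list(promoter = 1500L, exon1 = 41L, intron1 = 2000L, exon2 = 150L,
       intron2 = 1000L, exon3 = 150L, tail = 100L)
}

# default plant list: two promoter elements, two in intron 1 (one strongest),
# one in intron 2 -- positions are contig offsets under the default geometry
default_plants <- function() {
  data.frame(
    name = c("promoter_a", "promoter_b", "intron1_top", "intron1_b", "intron2_a"),
    position = c(320L, 1310L, 2459L, 3100L, 4100L),
    strand = c(1L, -1L, -1L, 1L, -1L),
    target_relative = c(78, 85, 92, 75, 80),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete gene fixture with planted regulatory elements
#'
#' Builds a forward-strand toy gene shaped like the regions of interest of
#' an antithrombin-gene survey — a 1,500 bp promoter, a 41 bp first exon
#' (so intronic offsets anchor at coding position 42), a 2 kb intron 1, a
#' 1 kb intron 2 — plants five DR3 elements at controlled relative scores
#' (two promoter, two intron 1, one intron 2), and derives three variants:
#' a promoter SNV overlapping nothing, a 4 bp duplication inside the
#' strongest intron-1 element, and a 20 bp duplication spanning that whole
#' element. The background is locally resampled until no window outside the
#' planted sites reaches `threshold`, so the plant list is the exact
#' above-threshold inventory.
#'
#' @param seed RNG seed.
#' @param gc background GC fraction; default 0.4.
#' @param threshold relative-score threshold the fixture is guaranteed
#'   clean at; default 70.
#' @param plants data.frame like [default_plants()] (name, position,
#'   strand, target_relative).
#' @param tolerance planting tolerance in percent points; default 1.
#' @param out_dir optional directory; when given, writes `reference.fa`,
#'   `gene_model.tsv`, `variants.txt` and `truth.json`.
#' @return list with `reference` (DNA string), `model` (`gene_model`),
#'   `pwm`, `variants` (list of `cvariant`), and `truth` (planted sites
#'   with achieved scores, variant loci and expected impact categories).
#' @export
simulate_gene_fixture <- function(seed = 1L, gc = 0.4, threshold = 70,
                                  plants = default_plants(), tolerance = 1,
                                  out_dir = NULL) {
  geom <- default_gene_geometry()
  tss <- geom$promoter
  e1 <- c(tss, tss + geom$exon1)
  e2 <- c(e1[2L] + geom$intron1, e1[2L] + geom$intron1 + geom$exon2)
  e3 <- c(e2[2L] + geom$intron2, e2[2L] + geom$intron2 + geom$exon3)
  contig_len <- e3[2L] + geom$tail
  model <- gene_model(rbind(e1, e2, e3), translation_start = tss,
                      contig_id = "synthetic_gene")
  pwm <- build_pwm(dr3_matrix())
  L <- motif_length(pwm)

  with_seed(seed, {
    ref <- simulate_background(contig_len, gc = gc)
    planted <- vector("list", nrow(plants))
    for (i in seq_len(nrow(plants))) {
      pl <- plant_motif(ref, pwm, plants$position[i], plants$strand[i],
                        plants$target_relative[i], tolerance = tolerance)
      ref <- pl$seq
      planted[[i]] <- data.frame(
        name = plants$name[i], start = pl$start, end = pl$start + L,
        strand = pl$strand, site = pl$site, raw_score = pl$raw_score,
        relative_score = pl$relative_score, stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, planted)

    # local clean-up: resample (outside planted bases) any above-threshold
    # window that is not itself a planted site, so the plant list is the
    # exact inventory
    is_plant <- function(start, strand) {
      any(planted$start == start & planted$strand == strand)
    }
    p_bg <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    clean <- FALSE
    for (iter in seq_len(100L)) {
      hits <- suppressMessages(scan_sequence(pwm, ref, threshold = threshold))
      spur_mask <- if (nrow(hits)) {
        !mapply(is_plant, hits$start, hits$strand)
      } else logical(0)
      spur <- hits[spur_mask, , drop = FALSE]
      if (nrow(spur) == 0L) { clean <- TRUE; break }
      for (s in spur$start) {
        keep <- seq.int(s, s + L - 1L) + 1L
        # never touch bases inside a planted site
        touchable <- keep[vapply(keep - 1L, function(b) {
          !any(b >= planted$start & b < planted$end)
        }, logical(1))]
        fresh <- sample(DNA_BASES, length(touchable), replace = TRUE, prob = p_bg)
        for (k in seq_along(touchable)) {
          substr(ref, touchable[k], touchable[k]) <- fresh[k]
        }
      }
    }
    if (!clean) stop("could not clean background of spurious hits", call. = FALSE)

    top <- planted[which.max(planted$raw_score), ]
    e2s <- e2[1L]
    # 4 bp duplication inside the strongest intron-1 element
    dup4_start <- top$start + 7L
    dup4_off <- e2s - dup4_start                       # upstream offset of first base
    dup4_bases <- substr(ref, dup4_start + 1L, dup4_start + 4L)
    v_dup4 <- parse_cvariant(sprintf("c.42-%d_-%ddup%s", dup4_off,
                                     dup4_off - 3L, dup4_bases))
    # 20 bp duplication spanning the whole strongest element
    dup20_start <- top$start - 3L
    dup20_off <- e2s - dup20_start
    v_dup20 <- parse_cvariant(sprintf("c.42-%d_-%ddup", dup20_off,
                                      dup20_off - 19L))
    # promoter SNV overlapping no element
    snv_pos <- tss - 1053L
    ref_base <- substr(ref, snv_pos + 1L, snv_pos + 1L)
    alt_base <- setdiff(DNA_BASES, ref_base)[1L]
    v_snv <- parse_cvariant(sprintf("c.1-1053%s>%s", ref_base, alt_base))

    variants <- list(v_snv, v_dup4, v_dup20)
    truth <- list(
      seed = seed, threshold = threshold, gc = gc,
      geometry = geom, planted = planted,
      variants = data.frame(
        variant = vapply(variants, function(v) v$raw_text, character(1)),
        expected_category = c("none", "disrupts", "creates/duplicates"),
        stringsAsFactors = FALSE)
    )

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      dna <- Biostrings::DNAStringSet(ref)
      names(dna) <- model$contig_id
      Biostrings::writeXStringSet(dna, file.path(out_dir, "reference.fa"))
      gm <- data.frame(contig = model$contig_id,
                       start = c(model$exons[, 1L], model$translation_start),
                       end = c(model$exons[, 2L], model$translation_start + 1L),
                       feature = c(rep("exon", nrow(model$exons)), "CDS-start"))
      utils::write.table(gm, file.path(out_dir, "gene_model.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeLines(truth$variants$variant, file.path(out_dir, "variants.txt"))
      jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    list(reference = ref, model = model, pwm = pwm, variants = variants,
         truth = truth)
  })
}

#' Simulate a genotype-phenotype cohort
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium at the given minor
#' allele frequency; the quantitative trait (anti-FXa activity, percent of
#' a reference pool) is `baseline + effect * carrier + covariate terms +
#' Gaussian noise`. Covariates: age (years, normal around 43), sex
#' (M/F), and a background intron-1 polymorphism (rs2227589-like, HWE at
#' MAF 0.1) entering as a carrier indicator.
#'
#' @param n cohort size (>= 2).
#' @param maf minor allele frequency of the tested variant in (0, 0.5\].
#' @param effect additive shift in trait units for carriers; default -5.7
#'   (percentage points of anti-FXa activity).
#' @param covariate_effects named list with `age` (per year, centred at
#'   43), `sexM` (shift for males), `rs2227589` (shift for carriers).
#' @param noise_sd residual Gaussian sd; default 7.4.
#' @param baseline non-carrier trait mean; default 96.4.
#' @param seed RNG seed.
#' @return list with `cohort` (a `cohort_table`) and `truth` (the
#'   generating parameters plus realized carrier count).
#' @export
simulate_cohort <- function(n = 307L, maf = 0.013, effect = -5.7,
                            covariate_effects = list(age = -0.05, sexM = 1.0,
                                                     rs2227589 = -1.5),
                            noise_sd = 7.4, baseline = 96.4, seed = NULL) {
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]", call. = FALSE)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  with_seed(seed, {
    g <- sample(0:2, n, replace = TRUE,
                prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
    age <- round(stats::rnorm(n, 43, 12))
    age <- pmin(pmax(age, 18), 75)
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.45, 0.55))
    rs_maf <- 0.1
    rs <- sample(0:2, n, replace = TRUE,
                 prob = c((1 - rs_maf)^2, 2 * rs_maf * (1 - rs_maf), rs_maf^2))
    antifxa <- baseline + effect * (g > 0) +
      covariate_effects$age * (age - 43) +
      covariate_effects$sexM * (sex == "M") +
      covariate_effects$rs2227589 * (rs > 0) +
      stats::rnorm(n, 0, noise_sd)
    antifxa <- pmax(antifxa, 1)  # activities are positive percentages
    cohort <- as_cohort(data.frame(
      id = sprintf("S%04d", seq_len(n)), genotype = g, antifxa = antifxa,
      age = age, sex = sex, rs2227589 = rs, stringsAsFactors = FALSE))
    list(cohort = cohort,
         truth = list(n = n, maf = maf, effect = effect,
                      covariate_effects = covariate_effects,
                      noise_sd = noise_sd, baseline = baseline,
                      n_carriers = sum(g > 0), seed = seed))
  })
}

#' Simulate a qPCR plate with a dose-dependent fold response
#'
#' For each dose and replicate, the reference gene gets a fixed CT and each
#' target gene a CT of `base_ct - log2(fold_map(dose))` plus Gaussian
#' noise, so the planted fold change versus the control dose is exactly
#' `fold_map(dose) / fold_map(control)`.
#'
#' @param doses numeric vector, must include `control_dose`; default
#'   c(0, 40, 80, 106) (paricalcitol, ng/ml).
#' @param fold_maps named list of functions (or single function applied to
#'   a gene named `"SERPINC1"`), each mapping dose to a positive fold;
#'   default: log-linear responses reaching 1.5-fold (SERPINC1) and 2-fold
#'   (VDR) at 106 ng/ml.
#' @param ct_noise_sd Gaussian CT noise sd; default 0.15 cycles.
#' @param replicates replicates per dose; default 6.
#' @param control_dose untreated dose; default 0.
#' @param reference reference gene name; default `"ACTB"`.
#' @param base_ct named CTs: reference and target baseline; defaults 24
#'   (reference) and 26 (targets).
#' @param seed RNG seed.
#' @return list with `plate` (a `qpcr_plate`) and `truth` (planted fold at
#'   each dose per gene).
#' @export
simulate_qpcr <- function(doses = c(0, 40, 80, 106),
                          fold_maps = list(
                            SERPINC1 = function(d) 1.5^(d / 106),
                            VDR = function(d) 2^(d / 106)),
                          ct_noise_sd = 0.15, replicates = 6L,
                          control_dose = 0, reference = "ACTB",
                          base_ct = c(reference = 24, target = 26),
                          seed = NULL) {
  if (!control_dose %in% doses) stop("doses must include the control dose",
                                     call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (is.function(fold_maps)) fold_maps <- list(SERPINC1 = fold_maps)
  for (g in names(fold_maps)) {
    if (any(vapply(doses, fold_maps[[g]], numeric(1)) <= 0)) {
      stop("fold map for ", g, " must be positive at every dose", call. = FALSE)
    }
  }
  with_seed(seed, {
    rows <- list()
    for (d in doses) {
      for (r in seq_len(replicates)) {
        sid <- sprintf("d%s_r%d", format(d), r)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, gene = reference, dose = d, replicate = r,
          ct = base_ct[["reference"]], stringsAsFactors = FALSE)
        for (g in names(fold_maps)) {
          ct <- base_ct[["target"]] - log2(fold_maps[[g]](d)) +
            stats::rnorm(1L, 0, ct_noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, gene = g, dose = d, replicate = r, ct = ct,
            stringsAsFactors = FALSE)
        }
      }
    }
    plate <- as_qpcr(do.call(rbind, rows))
    truth_fold <- do.call(rbind, lapply(names(fold_maps), function(g) {
      data.frame(gene = g, dose = doses,
                 fold = vapply(doses, fold_maps[[g]], numeric(1)) /
                        fold_maps[[g]](control_dose),
                 stringsAsFactors = FALSE)
    }))
    list(plate = plate,
         truth = list(fold = truth_fold, ct_noise_sd = ct_noise_sd,
                      replicates = replicates, control_dose = control_dose,
                      reference = reference, seed = seed))
  })
}
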