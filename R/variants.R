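#' Parse a coding-anchored variant string
#'
#' Accepts the compact clinical dialect used for promoter and intron-1
#' variants of this kind — `c.1-1053C>T` (1053 bp upstream of the ATG;
#' standard HGVS `c.-1053C>T` also parses), `c.42-1060_-1057dupTTGA`
#' (intron offsets anchored at coding position 42, the first base of exon
#' 2), plain coding SNVs, and `del`/`ins` forms. Whitespace around `>` is
#' tolerated.
#'
#' @param text variant string, e.g. `"c.42-1060_-1057dupTTGA"`.
#' @return A `cvariant` object: list with `raw_text`, `kind` (`snv`, `dup`,
#'   `del`, `ins`), `anchor` (`upstream`, `intronic`, `coding`), `anchor_c`
#'   (the coding position the offsets hang from; 1 for upstream),
#'   `start_offset`/`end_offset` (upstream distances; 0 for plain coding),
#'   `ref_bases`, `alt_bases`.
#' @examples
#' parse_cvariant("c.42-1060_-1057dupTTGA")
#' parse_cvariant("c.1-171 C>G")
#' @export
parse_cvariant <- function(text) {
  raw <- text
  s <- gsub("\\s+", "", text)
  if (!grepl("^c\\.", s)) stop("variant must start with 'c.': '", raw, "'", call. = FALSE)
  s <- sub("^c\\.", "", s)

  # one anchored position: "1-1053", "-1053", "42-1060", "123"
  pos_re <- "(?:([0-9]+)-([0-9]+)|-([0-9]+)|([0-9]+))"
  m <- regmatches(s, regexec(paste0(
    "^", pos_re, "(?:_", "(?:([0-9]+)-)?(-?[0-9]+)", ")?",
    "(dup|del|ins|[ACGTacgt]>[ACGTacgt])([ACGTacgt]*)$"), s))[[1L]]
  if (length(m) == 0L || m[[1L]] == "") {
    stop("cannot parse variant '", raw, "'", call. = FALSE)
  }
  num <- function(x) if (nzchar(x)) as.integer(x) else NA_integer_

  a_c <- num(m[[2L]]); a_off <- num(m[[3L]])
  bare_up <- num(m[[4L]]); coding <- num(m[[5L]])
  if (!is.na(a_c)) {               # "A-N" form
    if (a_off == 0L) stop("offset 0 is illegal in '", raw, "'", call. = FALSE)
    anchor_c <- a_c; start_off <- a_off
  } else if (!is.na(bare_up)) {    # "-N" standard upstream
    if (bare_up == 0L) stop("offset 0 is illegal in '", raw, "'", call. = FALSE)
    anchor_c <- 1L; start_off <- bare_up
  } else {                         # plain coding position
    anchor_c <- coding; start_off <- 0L
  }
  anchor <- if (anchor_c == 1L && start_off > 0L) "upstream"
            else if (start_off > 0L) "intronic"
            else "coding"
  if (anchor != "coding" && start_off == 0L) {
    stop("offset 0 is illegal in '", raw, "'", call. = FALSE)
  }

  end_off <- start_off
  if (nzchar(m[[7L]])) {           # ranged: second breakpoint
    e2 <- as.integer(m[[7L]])
    a2 <- num(m[[6L]])
    if (!is.na(a2) && a2 != anchor_c) {
      stop("range breakpoints use different anchors in '", raw, "'", call. = FALSE)
    }
    if (anchor == "coding") {
      if (e2 < anchor_c) stop("reversed range in '", raw, "'", call. = FALSE)
      end_off <- 0L
      end_c <- e2
    } else {
      e2 <- abs(e2)                # written "-1057": distance upstream
      if (e2 == 0L) stop("offset 0 is illegal in '", raw, "'", call. = FALSE)
      if (e2 > start_off) stop("reversed range in '", raw, "'", call. = FALSE)
      end_off <- e2
    }
  }

  op <- m[[8L]]; tail_bases <- toupper(m[[9L]])
  if (grepl(">", op, fixed = TRUE)) {
    if (nzchar(tail_bases)) stop("trailing bases after SNV in '", raw, "'", call. = FALSE)
    bases <- strsplit(toupper(op), ">", fixed = TRUE)[[1L]]
    kind <- "snv"; ref_bases <- bases[[1L]]; alt_bases <- bases[[2L]]
    if (end_off != start_off) stop("SNV cannot span a range in '", raw, "'", call. = FALSE)
  } else if (op == "dup") {
    kind <- "dup"; ref_bases <- tail_bases; alt_bases <- ""
  } else if (op == "del") {
    kind <- "del"; ref_bases <- tail_bases; alt_bases <- ""
  } else if (op == "ins") {
    kind <- "ins"; ref_bases <- ""; alt_bases <- tail_bases
    if (!nzchar(alt_bases)) stop("ins requires inserted bases in '", raw, "'", call. = FALSE)
  } else stop("unknown operation in '", raw, "'", call. = FALSE)

  end_c <- if (exists("end_c", inherits = FALSE)) end_c else anchor_c
  structure(list(raw_text = raw, kind = kind, anchor = anchor,
                 anchor_c = anchor_c, end_anchor_c = end_c,
                 start_offset = start_off, end_offset = end_off,
                 ref_bases = ref_bases, alt_bases = alt_bases),
            class = "cvariant")
}

#' @export
print.cvariant <- function(x, ...) {
  cat("c-variant ", x$raw_text, " [", x$kind, ", ", x$anchor, " anchor c.",
      x$anchor_c, ", offsets -", x$start_offset, "..-", x$end_offset, "]\n",
      sep = "")
  invisible(x)
}

# 0-based half-open contig interval touched by a variant
variant_interval <- function(model, v) {
  offs <- c_to_contig(model, v)
  start <- offs[["start"]]
  end <- offs[["end"]] + 1L   # inclusive end base -> half-open
  if (v$anchor == "coding" && v$end_anchor_c != v$anchor_c) {
    end <- c_to_contig(model, list(anchor = "coding", anchor_c = v$end_anchor_c,
                                   offset = 0L)) + 1L
  }
  if (end <= start) stop("degenerate variant interval for '", v$raw_text, "'",
                         call. = FALSE)
  c(start = start, end = end)
}

#' Apply a variant to the reference sequence
#'
#' SNVs substitute one base; `dup` inserts a second copy of the duplicated
#' interval immediately 3' of it; `del` removes the interval; `ins` inserts
#' `alt_bases` after the anchor base. Stated reference bases (SNV ref, dup
#' and del bases) are checked against the reference at the mapped interval.
#'
#' @param reference contig DNA string (or `DNAString`).
#' @param model a `gene_model`.
#' @param v a `cvariant`.
#' @return list with `seq` (mutant DNA), `interval` (0-based half-open
#'   reference interval affected) and `length_change` (bases inserted minus
#'   deleted).
#' @export
apply_variant <- function(reference, model, v) {
  stopifnot(inherits(v, "cvariant"))
  if (inherits(reference, "DNAString")) reference <- as.character(reference)
  reference <- toupper(reference)
  iv <- variant_interval(model, v)
  if (iv[["end"]] > nchar(reference)) {
    stop("variant interval beyond reference end", call. = FALSE)
  }
  found <- substr(reference, iv[["start"]] + 1L, iv[["end"]])
  check_ref <- function(expected) {
    if (nzchar(expected) && !identical(found, expected)) {
      stop("reference mismatch at ", iv[["start"]], "-", iv[["end"]],
           ": expected '", expected, "', found '", found, "'", call. = FALSE)
    }
  }
  left <- substr(reference, 1L, iv[["start"]])
  right <- substr(reference, iv[["end"]] + 1L, nchar(reference))
  out <- switch(v$kind,
    snv = {
      if (iv[["end"]] - iv[["start"]] != 1L) stop("SNV interval must be 1 base", call. = FALSE)
      check_ref(v$ref_bases)
      list(seq = paste0(left, v$alt_bases, right), delta = 0L)
    },
    dup = {
      check_ref(v$ref_bases)
      list(seq = paste0(left, found, found, right),
           delta = nchar(found))
    },
    del = {
      check_ref(v$ref_bases)
      list(seq = paste0(left, right), delta = -nchar(found))
    },
    ins = {
      # anchor base(s) untouched; insertion lands after the interval start base
      ins_left <- substr(reference, 1L, iv[["start"]] + 1L)
      ins_right <- substr(reference, iv[["start"]] + 2L, nchar(reference))
      list(seq = paste0(ins_left, v$alt_bases, ins_right),
           delta = nchar(v$alt_bases))
    }
  )
  list(seq = out$seq, interval = iv, length_change = out$delta)
}
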