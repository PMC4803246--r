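#' Construct a gene model
#'
#' Exon structure on a forward-strand contig, anchoring coding ("c.")
#' coordinates: `c.1` is the A of the ATG at `translation_start`, and
#' intron offsets such as `c.42-N` count upstream from the first base of
#' the exon holding coding position 42.
#'
#' @param exons two-column matrix or data.frame of 0-based half-open
#'   `[start, end)` exon intervals on the contig, ascending.
#' @param translation_start 0-based contig offset of the A of the ATG;
#'   must lie inside exon 1.
#' @param contig_id contig name.
#' @param gene_strand +1 (forward, fully supported) or -1 (experimental).
#' @return A `gene_model` object.
#' @examples
#' gm <- gene_model(rbind(c(1500, 1541), c(3541, 3691)), translation_start = 1500)
#' @export
gene_model <- function(exons, translation_start, contig_id = "contig",
                       gene_strand = 1L) {
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("exons must have 2 columns (start, end)", call. = FALSE)
  storage.mode(exons) <- "integer"
  if (any(exons[, 2L] <= exons[, 1L])) stop("empty exon interval", call. = FALSE)
  if (nrow(exons) > 1L) {
    if (any(diff(exons[, 1L]) <= 0) || any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
      stop("exons must be non-overlapping and ascending", call. = FALSE)
    }
  }
  if (translation_start < exons[1L, 1L] || translation_start >= exons[1L, 2L]) {
    stop("translation_start must lie inside exon 1", call. = FALSE)
  }
  if (!gene_strand %in% c(1L, -1L)) stop("gene_strand must be +1 or -1", call. = FALSE)
  if (gene_strand == -1L) {
    warning("reverse-strand gene models are experimental", call. = FALSE)
  }
  dimnames(exons) <- list(NULL, c("start", "end"))
  structure(list(contig_id = contig_id, exons = exons,
                 translation_start = as.integer(translation_start),
                 gene_strand = as.integer(gene_strand)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model on '", x$contig_id, "': ", nrow(x$exons),
      " exon(s), ATG at ", x$translation_start, " (0-based)\n", sep = "")
  invisible(x)
}

#' Read a gene model from a BED-like TSV
#'
#' Expects columns `contig`, `start`, `end`, `feature` (0-based half-open),
#' with one `CDS-start` row (its `start` is the ATG offset) and one or more
#' `exon` rows.
#'
#' @param path TSV file path.
#' @return A `gene_model`.
#' @export
read_gene_model <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "feature")
  if (!all(need %in% names(tab))) {
    stop("gene model TSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  ex <- tab[tab$feature == "exon", , drop = FALSE]
  cds <- tab[tab$feature == "CDS-start", , drop = FALSE]
  if (nrow(cds) != 1L) stop("gene model TSV needs exactly one CDS-start row", call. = FALSE)
  ex <- ex[order(ex$start), , drop = FALSE]
  gene_model(as.matrix(ex[, c("start", "end")]), translation_start = cds$start[1L],
             contig_id = tab$contig[1L])
}

# cumulative coding offset (c. position, 1-based) of the first base of each exon,
# assuming translation starts inside exon 1
exon_first_cpos <- function(model) {
  widths <- model$exons[, "end"] - model$exons[, "start"]
  w1 <- model$exons[1L, "end"] - model$translation_start
  cum <- cumsum(c(w1, widths[-1L]))
  c(1L, cum[-length(cum)] + 1L)  # c. position of exon i's first base (exon1 -> c.1 anchor)
}

#' Map an anchored c.-dialect position to a contig offset
#'
#' Upstream positions (`c.1-N`, equivalently standard `c.-N`) map to
#' `translation_start - N`; intronic positions anchored at an exon start
#' (`c.42-N`) map to `exon_start - N`; plain coding positions map through
#' the spliced exon structure.
#'
#' @param model a `gene_model`.
#' @param variant a `cvariant` (both breakpoints are mapped) or a single
#'   anchored position list with fields `anchor`, `anchor_c`, `offset`.
#' @return 0-based contig offset(s), named `start`/`end` for a variant.
#' @export
c_to_contig <- function(model, variant) {
  stopifnot(inherits(model, "gene_model"))
  map_one <- function(anchor, anchor_c, offset) {
    if (anchor == "upstream") {
      pos <- model$translation_start - offset
    } else if (anchor == "intronic") {
      firsts <- exon_first_cpos(model)
      ei <- match(anchor_c, firsts)
      if (is.na(ei) || ei < 2L) {
        stop("c.", anchor_c, " is not the first base of exon 2..n in this model",
             call. = FALSE)
      }
      if (nrow(model$exons) < 2L) stop("intronic coordinates need >= 2 exons", call. = FALSE)
      pos <- model$exons[ei, "start"] - offset
    } else if (anchor == "coding") {
      firsts <- exon_first_cpos(model)
      widths <- model$exons[, "end"] - model$exons[, "start"]
      lasts <- firsts + c(model$exons[1L, "end"] - model$translation_start,
                          widths[-1L]) - 1L
      ei <- which(anchor_c >= firsts & anchor_c <= lasts)
      if (!length(ei)) stop("coding position c.", anchor_c, " beyond model exons",
                            call. = FALSE)
      base0 <- if (ei == 1L) model$translation_start else model$exons[ei, "start"]
      pos <- base0 + (anchor_c - firsts[ei])
    } else stop("unknown anchor '", anchor, "'", call. = FALSE)
    if (pos < 0) stop("mapped offset ", pos, " outside contig", call. = FALSE)
    unname(pos)
  }
  if (inherits(variant, "cvariant")) {
    v <- variant
    c(start = map_one(v$anchor, v$anchor_c, v$start_offset),
      end = map_one(v$anchor, v$anchor_c, v$end_offset))
  } else {
    map_one(variant$anchor, variant$anchor_c, variant$offset)
  }
}

#' Extract a named gene region from the reference
#'
#' @param model a `gene_model`.
#' @param reference contig DNA as a string or `DNAString`.
#' @param region one of `"promoter"`, `"intron"`, `"exon"`.
#' @param index intron/exon number (1-based); ignored for the promoter.
#' @param promoter_length bases upstream of the ATG for `"promoter"`;
#'   default 1500.
#' @return list with `seq` (DNA string), `start`, `end` (0-based half-open
#'   contig interval) and `name`.
#' @export
extract_region <- function(model, reference, region = c("promoter", "intron", "exon"),
                           index = 1L, promoter_length = 1500L) {
  stopifnot(inherits(model, "gene_model"))
  region <- match.arg(region)
  if (inherits(reference, "DNAString")) reference <- as.character(reference)
  iv <- switch(region,
    promoter = {
      if (promoter_length > model$translation_start) {
        stop("promoter length ", promoter_length, " exceeds upstream sequence",
             call. = FALSE)
      }
      c(model$translation_start - promoter_length, model$translation_start)
    },
    intron = {
      if (index < 1L || index > nrow(model$exons) - 1L) {
        stop("intron index ", index, " out of range", call. = FALSE)
      }
      c(model$exons[index, "end"], model$exons[index + 1L, "start"])
    },
    exon = {
      if (index < 1L || index > nrow(model$exons)) {
        stop("exon index ", index, " out of range", call. = FALSE)
      }
      model$exons[index, ]
    }
  )
  iv <- as.integer(iv)
  if (iv[2L] > nchar(reference)) stop("region extends beyond reference", call. = FALSE)
  list(name = if (region == "promoter") "promoter" else paste0(region, index),
       seq = substr(reference, iv[1L] + 1L, iv[2L]),
       start = iv[1L], end = iv[2L])
}
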