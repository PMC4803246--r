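#' Read a JASPAR-format position frequency matrix
#'
#' Parses JASPAR PFM text: an optional `>ID NAME` header followed by four
#' rows of per-position base counts, either in the bracketed 2016 style
#' (`A [ 4 19 0 ... ]`) or as a bare whitespace-separated 4-row matrix in
#' A, C, G, T order. Row order in labelled files is normalized to
#' A, C, G, T regardless of the order on disk.
#'
#' @param source path to a PFM file, or a character vector of its lines.
#' @return A `count_matrix` object: list with `motif_id` and a 4 x L
#'   integer `counts` matrix with rownames A, C, G, T.
#' @examples
#' pfm <- read_jaspar(c(">TOY test", "A [ 10 0 ]", "C [ 0 0 ]",
#'                      "G [ 0 10 ]", "T [ 0 0 ]"))
#' pfm$counts
#' @export
read_jaspar <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty PFM input", call. = FALSE)

  motif_id <- "unnamed"
  if (startsWith(lines[[1L]], ">")) {
    motif_id <- sub("^>\\s*", "", lines[[1L]])
    lines <- lines[-1L]
  }
  if (length(lines) < 4L) {
    stop("PFM must have 4 base rows; found ", length(lines), call. = FALSE)
  }
  lines <- lines[seq_len(4L)]

  parse_row <- function(line) {
    label <- NA_character_
    m <- regmatches(line, regexec("^([ACGTacgt])\\s*[:\\[]?", line))[[1L]]
    body <- line
    if (length(m) == 2L && grepl("^[ACGTacgt]([^0-9]|$)", line)) {
      label <- toupper(m[[2L]])
      body <- sub("^[ACGTacgt]\\s*", "", line)
    }
    body <- gsub("\\[|\\]", " ", body)
    fields <- strsplit(trimws(body), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) == 0L || anyNA(vals)) {
      stop("cannot parse PFM row: '", line, "'", call. = FALSE)
    }
    if (any(vals < 0)) stop("negative counts in PFM row: '", line, "'", call. = FALSE)
    list(label = label, counts = vals)
  }

  rows <- lapply(lines, parse_row)
  lens <- vapply(rows, function(r) length(r$counts), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("ragged PFM rows: lengths ", paste(lens, collapse = ", "), call. = FALSE)
  }
  labels <- vapply(rows, function(r) r$label, character(1))
  counts <- do.call(rbind, lapply(rows, function(r) r$counts))
  if (!anyNA(labels)) {
    missing <- setdiff(DNA_BASES, labels)
    if (length(missing)) {
      stop("PFM missing base row(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    counts <- counts[match(DNA_BASES, labels), , drop = FALSE]
  } else if (any(!is.na(labels))) {
    stop("PFM mixes labelled and unlabelled rows", call. = FALSE)
  }
  rownames(counts) <- DNA_BASES
  count_matrix(counts, motif_id = motif_id)
}

#' Construct a base-count matrix
#'
#' @param counts 4 x L numeric matrix of non-negative base counts; rows are
#'   taken in A, C, G, T order (rownames, if present, must match).
#' @param motif_id identifier carried into hit reports.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, motif_id = "unnamed") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("count matrix must have 4 rows (A,C,G,T)", call. = FALSE)
  if (ncol(counts) < 1L) stop("count matrix must have at least 1 column", call. = FALSE)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative", call. = FALSE)
  if (all(colSums(counts) == 0)) stop("all columns have zero total", call. = FALSE)
  if (!is.null(rownames(counts)) && !identical(toupper(rownames(counts)), DNA_BASES)) {
    counts <- counts[match(DNA_BASES, toupper(rownames(counts))), , drop = FALSE]
    if (anyNA(counts)) stop("rownames must be A,C,G,T", call. = FALSE)
  }
  rownames(counts) <- DNA_BASES
  colnames(counts) <- NULL
  structure(list(motif_id = motif_id, counts = counts), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Position count matrix '", x$motif_id, "' (", ncol(x$counts),
      " positions)\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Motif length of a count matrix or PWM
#' @param x a `count_matrix` or `pwm`.
#' @return integer number of motif positions.
#' @export
motif_length <- function(x) {
  if (inherits(x, "count_matrix")) ncol(x$counts)
  else if (inherits(x, "pwm")) ncol(x$weights)
  else stop("not a count_matrix or pwm", call. = FALSE)
}
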