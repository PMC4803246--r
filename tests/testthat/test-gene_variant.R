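test_that("variant strings in the clinical dialect parse correctly", {
  v <- parse_cvariant("c.42-1060_-1057dupTTGA")
  expect_equal(v$kind, "dup")
  expect_equal(v$anchor, "intronic")
  expect_equal(v$anchor_c, 42L)
  expect_equal(v$start_offset, 1060L)
  expect_equal(v$end_offset, 1057L)
  expect_equal(v$ref_bases, "TTGA")

  v <- parse_cvariant("c.1-171 C>G")  # whitespace around the operation
  expect_equal(v$kind, "snv")
  expect_equal(v$anchor, "upstream")
  expect_equal(v$start_offset, 171L)
  expect_equal(v$ref_bases, "C")
  expect_equal(v$alt_bases, "G")

  # standard HGVS upstream spelling is synonymous
  v2 <- parse_cvariant("c.-171C>G")
  expect_equal(v2$anchor, "upstream")
  expect_equal(v2$start_offset, 171L)

  v <- parse_cvariant("c.42-1087_-1068dup")  # 20 bp dup, bases unstated
  expect_equal(v$kind, "dup")
  expect_equal(v$start_offset, 1087L)
  expect_equal(v$end_offset, 1068L)
  expect_equal(v$ref_bases, "")

  v <- parse_cvariant("c.42-1060_-1059insTT")
  expect_equal(v$kind, "ins")
  expect_equal(v$alt_bases, "TT")

  # error contracts
  expect_error(parse_cvariant("c.1-0C>T"), "offset 0")
  expect_error(parse_cvariant("c.42-1057_-1060dupTTGA"), "reversed")
  expect_error(parse_cvariant("c.42-1060covTTGA"), "parse")
  expect_error(parse_cvariant("g.1234A>T"), "c\\.")
})

test_that("anchored coordinates map to the stated contig offsets", {
  m <- toy_model()
  up <- function(n) c_to_contig(m, list(anchor = "upstream", anchor_c = 1L, offset = n))
  intr <- function(n) c_to_contig(m, list(anchor = "intronic", anchor_c = 42L, offset = n))
  expect_equal(up(171), 1329)
  expect_equal(intr(1), 3540)      # last base of intron 1
  expect_equal(intr(1060), 2481)
  # a variant maps both breakpoints
  v <- parse_cvariant("c.42-1060_-1057dupTTGA")
  expect_equal(unname(c_to_contig(m, v)), c(2481, 2484))
  # monotone: larger upstream offset, smaller contig offset
  offs <- sapply(c(1, 10, 100, 1000), up)
  expect_true(all(diff(offs) < 0))
  offs <- sapply(c(1, 10, 100, 1000, 2000), intr)
  expect_true(all(diff(offs) < 0))
  # errors: unknown anchor position, beyond-contig offset
  expect_error(c_to_contig(m, list(anchor = "intronic", anchor_c = 50L, offset = 5)),
               "not the first base")
  expect_error(up(2000), "outside contig")
})

test_that("variant application edits, checks and round-trips the reference", {
  m <- toy_model()
  set.seed(7)
  ref <- random_dna(3700)

  # duplication: length +4 and tandem copy across the locus
  dup_iv <- c(2481, 2485)
  bases <- substr(ref, dup_iv[1] + 1, dup_iv[2])
  v <- parse_cvariant(sprintf("c.42-1060_-1057dup%s", bases))
  out <- apply_variant(ref, m, v)
  expect_equal(nchar(out$seq), nchar(ref) + 4L)
  expect_equal(substr(out$seq, 2482, 2489), paste0(bases, bases))
  # flanks untouched
  expect_equal(substr(out$seq, 1, 2481), substr(ref, 1, 2481))
  expect_equal(substr(out$seq, 2490, nchar(out$seq)), substr(ref, 2486, nchar(ref)))

  # stated bases must match the reference
  wrong <- chartr("ACGT", "CAGT", bases)
  if (wrong == bases) wrong <- chartr("ACGT", "GTAC", bases)
  vbad <- parse_cvariant(sprintf("c.42-1060_-1057dup%s", wrong))
  expect_error(apply_variant(ref, m, vbad), "mismatch")

  # SNV involution: C>G then G>C restores the original
  pos <- 1329  # c.1-171
  rb <- substr(ref, pos + 1, pos + 1)
  ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
  v1 <- parse_cvariant(sprintf("c.1-171%s>%s", rb, ab))
  v2 <- parse_cvariant(sprintf("c.1-171%s>%s", ab, rb))
  once <- apply_variant(ref, m, v1)
  expect_equal(substr(once$seq, pos + 1, pos + 1), ab)
  expect_equal(apply_variant(once$seq, m, v2)$seq, ref)

  # deletion then re-insertion restores the reference
  del <- parse_cvariant("c.42-1060_-1057del")
  removed <- substr(ref, 2482, 2485)
  cut <- apply_variant(ref, m, del)
  expect_equal(nchar(cut$seq), nchar(ref) - 4L)
  reins <- parse_cvariant(sprintf("c.42-1061ins%s", removed))
  expect_equal(apply_variant(cut$seq, m, reins)$seq, ref)
})

test_that("region extraction returns the stated intervals", {
  m <- toy_model()
  set.seed(8)
  ref <- random_dna(3700)
  pr <- extract_region(m, ref, "promoter", promoter_length = 1500)
  expect_equal(c(pr$start, pr$end), c(0, 1500))
  expect_equal(pr$seq, substr(ref, 1, 1500))
  i1 <- extract_region(m, ref, "intron", 1)
  expect_equal(c(i1$start, i1$end), c(1541, 3541))
  expect_equal(nchar(i1$seq), 2000)
  expect_error(extract_region(m, ref, "exon", 9), "out of range")
  expect_error(extract_region(m, ref, "promoter", promoter_length = 1600),
               "exceeds")

  # mapped intronic variant loci lie inside the intron they are anchored to
  for (off in c(1, 500, 1999)) {
    pos <- c_to_contig(m, list(anchor = "intronic", anchor_c = 42L, offset = off))
    expect_true(pos >= i1$start && pos < i1$end)
  }
  # upstream loci lie inside the promoter
  for (off in c(1, 700, 1500)) {
    pos <- c_to_contig(m, list(anchor = "upstream", anchor_c = 1L, offset = off))
    expect_true(pos >= 0 && pos < 1500)
  }
})

test_that("gene models validate their geometry and read from TSV", {
  expect_error(gene_model(rbind(c(10, 20), c(15, 30)), 12), "non-overlapping")
  expect_error(gene_model(rbind(c(10, 20)), 25), "inside exon 1")
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write.table(data.frame(contig = "toy",
                         start = c(1500L, 3541L, 1500L),
                         end = c(1541L, 3691L, 1501L),
                         feature = c("exon", "exon", "CDS-start")),
              tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_gene_model(tmp)
  expect_equal(m$translation_start, 1500L)
  expect_equal(nrow(m$exons), 2L)
})
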