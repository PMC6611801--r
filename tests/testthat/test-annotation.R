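make_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gtf_row <- function(chrom, src, type, start1, end1, strand, attrs) {
  paste(chrom, src, type, start1, end1, ".", strand, ".", attrs, sep = "\t")
}

test_that("GTF reading converts 1-based closed to 0-based half-open and unions transcripts", {
  path <- make_gtf(c(
    gtf_row("chr1", "test", "transcript", 1001, 5000, "+",
            'gene_id "G1"; gene_name "GeneOne"; gene_biotype "protein_coding";'),
    gtf_row("chr1", "test", "transcript", 1001, 3000, "+",
            'gene_id "G2"; gene_name "GeneTwo"; gene_biotype "protein_coding";'),
    gtf_row("chr1", "test", "transcript", 2501, 5000, "+",
            'gene_id "G2"; gene_name "GeneTwo"; gene_biotype "protein_coding";'),
    gtf_row("chr1", "test", "gene", 7001, 7500, "-",
            'gene_id "L1"; gene_name "LncOne"; gene_biotype "lncRNA";'),
    gtf_row("chr1", "test", "gene", 9001, 9100, "+",
            'gene_id "R1"; gene_name "Rrna"; gene_biotype "rRNA";')))
  ann <- read_annotation_gtf(path)
  g1 <- ann$genes[ann$genes$gene_id == "G1", ]
  expect_equal(c(g1$start0, g1$end0), c(1000, 5000))
  g2 <- ann$genes[ann$genes$gene_id == "G2", ]
  expect_equal(c(g2$start0, g2$end0), c(1000, 5000))  # union of the two spans
  expect_equal(ann$lncrnas$lnc_id, "L1")
  expect_false("R1" %in% c(ann$genes$gene_id, ann$lncrnas$lnc_id))
})

test_that("malformed GTF lines and conflicting gene records are rejected", {
  bad <- make_gtf(c(
    gtf_row("chr1", "t", "gene", 1, 10, "+",
            'gene_id "G1"; gene_biotype "protein_coding";'),
    "chr1\tonly\tthree"))
  expect_error(read_annotation_gtf(bad), "line 2")
  conflict <- make_gtf(c(
    gtf_row("chr1", "t", "transcript", 1, 100, "+",
            'gene_id "G1"; gene_biotype "protein_coding";'),
    gtf_row("chr2", "t", "transcript", 1, 100, "+",
            'gene_id "G1"; gene_biotype "protein_coding";')))
  expect_error(read_annotation_gtf(conflict), "conflicting")
})

test_that("TSV dialect round-trips an annotation set", {
  set.seed(31)
  ann <- random_annotation(20, 10)
  path <- tempfile(fileext = ".tsv")
  write_annotation_tsv(ann, path)
  back <- read_annotation_tsv(path)
  expect_equal(back$genes[order(back$genes$gene_id), ],
               ann$genes[order(ann$genes$gene_id), ],
               ignore_attr = TRUE)
  expect_equal(back$lncrnas$lnc_id, ann$lncrnas$lnc_id)
  expect_equal(back$lncrnas$start0, ann$lncrnas$start0)
})

test_that("annotation invariants are enforced", {
  g <- data.frame(gene_id = "G1", symbol = "G1", chrom = "chr1",
                  start0 = 0, end0 = 100, strand = "+")
  l <- data.frame(lnc_id = "L1", aliases = "", chrom = "chr1",
                  start0 = 10, end0 = 20, strand = "-")
  expect_s3_class(annotation_set(g, l), "annotation_set")
  expect_error(annotation_set(rbind(g, g), l), "duplicate")
  expect_error(annotation_set(transform(g, end0 = 0), l), "end <= start")
  expect_error(annotation_set(transform(g, strand = "."), l), "strand")
  expect_error(annotation_set(g, transform(l, aliases = "G1")), "collide")
  expect_error(annotation_set(g, l, chrom_sizes = c(chr1 = 50)), "beyond")
  expect_error(annotation_set(g, l, chrom_sizes = c(chr2 = 500)), "absent")
})

test_that("gap_distance matches the worked examples and is symmetric", {
  iv <- function(s, e, chrom = "chr1") list(chrom = chrom, start0 = s, end0 = e)
  expect_equal(gap_distance(iv(1000, 5000), iv(6000, 7000)),
               list(gap = 1000, overlap = FALSE))
  expect_equal(gap_distance(iv(1000, 5000), iv(4999, 7000)),
               list(gap = 0, overlap = TRUE))
  expect_equal(gap_distance(iv(1000, 5000), iv(5000, 7000)),
               list(gap = 0, overlap = FALSE))  # book-ended, not overlapping
  expect_error(gap_distance(iv(0, 1), iv(0, 1, "chr2")), "different chromosomes")
  set.seed(17)
  for (i in 1:200) {
    a <- sort(sample.int(1e5, 2)); b <- sort(sample.int(1e5, 2))
    if (a[1] == a[2] || b[1] == b[2]) next
    expect_identical(gap_distance(iv(a[1], a[2]), iv(b[1], b[2])),
                     gap_distance(iv(b[1], b[2]), iv(a[1], a[2])))
  }
})

test_that("interval index equals a brute-force scan on random queries", {
  set.seed(23)
  ann <- random_annotation(200, 0)
  idx <- build_interval_index(ann)
  for (i in 1:1000) {
    chrom <- sample(c("chr1", "chr2", "chr3", "chrUn"), 1)
    s <- sample.int(1e6, 1); e <- s + sample.int(5000, 1)
    got <- sort(index_overlaps(idx, chrom, s, e))
    g <- ann$genes
    want <- sort(g$gene_id[g$chrom == chrom & g$start0 < e & s < g$end0])
    expect_identical(got, want)
    nn <- index_nearest(idx, chrom, s, e)
    on_chr <- g[g$chrom == chrom, ]
    if (nrow(on_chr) == 0) {
      expect_length(nn$gene_ids, 0)
    } else {
      gaps <- pmax(on_chr$start0 - e, s - on_chr$end0, 0)
      expect_equal(nn$gap, min(gaps))
      expect_setequal(nn$gene_ids, on_chr$gene_id[gaps == min(gaps)])
    }
  }
  expect_identical(index_overlaps(idx, "chrZ", 0, 100), character(0))
})

test_that("BED6 export keeps half-open coordinates and feature ids", {
  g <- data.frame(gene_id = c("A", "B"), symbol = c("A", "B"),
                  chrom = "chr1", start0 = c(100, 900), end0 = c(500, 950),
                  strand = c("+", "-"))
  path <- tempfile(fileext = ".bed")
  write_bed6(g, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, c(100, 900))
  expect_equal(bed$V3, c(500, 950))
  expect_equal(bed$V4, c("A", "B"))
  expect_equal(bed$V5, c(0, 0))
  expect_equal(bed$V6, c("+", "-"))
})
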