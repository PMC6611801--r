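one_gene_ann <- function(lnc_start, lnc_end, lnc_strand,
                         gene = c(1000, 5000), gene_strand = "+") {
  annotation_set(
    data.frame(gene_id = "G1", symbol = "G1", chrom = "chr1",
               start0 = gene[1], end0 = gene[2], strand = gene_strand),
    data.frame(lnc_id = "L1", aliases = "", chrom = "chr1",
               start0 = lnc_start, end0 = lnc_end, strand = lnc_strand))
}

test_that("definitional examples classify as expected", {
  sense <- classify_all(one_gene_ann(2000, 3000, "+"))
  expect_equal(sense$spatial_class, "intragenic_sense")
  expect_equal(sense$partner_gene_ids, "G1")
  expect_equal(sense$gap_bp, 0)

  anti <- classify_all(one_gene_ann(2000, 3000, "-"))
  expect_equal(anti$spatial_class, "intragenic_antisense")

  nb <- classify_all(one_gene_ann(6000, 7000, "+"))
  expect_equal(nb$spatial_class, "linc_neighbor")
  expect_equal(nb$gap_bp, 1000)
  expect_equal(nb$relative_position, "downstream")  # 3' of a + gene
  expect_true(nb$same_strand_as_partner)
  expect_true(nb$proximal_flag)

  # gap of exactly the window is orphan (strict comparison)
  orf <- classify_all(one_gene_ann(55000, 57000, "+"))
  expect_equal(orf$gap_bp[orf$spatial_class == "linc_neighbor"], numeric(0))
  expect_equal(orf$spatial_class, "linc_orphan")
  at_50k <- classify_all(one_gene_ann(55000, 56000, "+"))
  expect_equal(at_50k$spatial_class, "linc_orphan")
  just_in <- classify_all(one_gene_ann(54999, 56000, "+"))
  expect_equal(just_in$spatial_class, "linc_neighbor")
  expect_equal(just_in$gap_bp, 49999)
})

test_that("upstream/downstream is expressed in the partner gene's frame", {
  up_plus <- classify_all(one_gene_ann(100, 500, "+"))
  expect_equal(up_plus$relative_position, "upstream")
  down_minus <- classify_all(one_gene_ann(100, 500, "+", gene_strand = "-"))
  expect_equal(down_minus$relative_position, "downstream")
  expect_false(down_minus$same_strand_as_partner)
})

test_that("sense wins when a lncRNA overlaps genes on both strands; partners keep all", {
  ann <- annotation_set(
    data.frame(gene_id = c("Gp", "Gm"), symbol = c("Gp", "Gm"), chrom = "chr1",
               start0 = c(1000, 1500), end0 = c(5000, 6000),
               strand = c("+", "-")),
    data.frame(lnc_id = "L1", aliases = "", chrom = "chr1",
               start0 = 2000, end0 = 3000, strand = "+"))
  cl <- classify_all(ann)
  expect_equal(cl$spatial_class, "intragenic_sense")
  expect_setequal(strsplit(cl$partner_gene_ids, ",")[[1]], c("Gp", "Gm"))
})

test_that("classification partitions the lncRNA set and matches the all-pairs oracle", {
  set.seed(71)
  for (i in 1:10) {
    ann <- random_annotation(sample(5:40, 1), sample(1:30, 1))
    cl <- classify_all(ann)
    expect_equal(nrow(cl), nrow(ann$lncrnas))
    expect_true(all(cl$spatial_class %in% c("intragenic_sense", "intragenic_antisense",
                                            "linc_neighbor", "linc_orphan")))
    expect_true(classification_agrees(ann))
  }
  expect_equal(nrow(classify_all(random_annotation(10, 0))), 0)
})

test_that("enlarging the window never turns a neighbor into an orphan", {
  set.seed(72)
  for (i in 1:5) {
    ann <- random_annotation(20, 15)
    small <- classify_all(ann, window_bp = 10000)
    big <- classify_all(ann, window_bp = 80000)
    was_nb <- small$lnc_id[small$spatial_class == "linc_neighbor"]
    now <- big$spatial_class[match(was_nb, big$lnc_id)]
    expect_true(all(now == "linc_neighbor"))
  }
})

test_that("flipping every strand swaps sense/antisense but no intragenic/linc calls", {
  set.seed(73)
  ann <- random_annotation(30, 20)
  flip <- function(s) ifelse(s == "+", "-", "+")
  ann2 <- annotation_set(transform(ann$genes, strand = flip(strand)),
                         transform(ann$lncrnas, strand = flip(strand)))
  a <- classify_all(ann); b <- classify_all(ann2)
  expect_identical(a$spatial_class %in% c("linc_neighbor", "linc_orphan"),
                   b$spatial_class %in% c("linc_neighbor", "linc_orphan"))
  expect_identical(a$spatial_class, b$spatial_class)  # both members flipped
})

test_that("host gene rollup counts distinct DE lncRNAs with a sense/antisense split", {
  ann <- annotation_set(
    data.frame(gene_id = c("H1", "H2"), symbol = c("H1", "H2"), chrom = "chr1",
               start0 = c(1000, 200000), end0 = c(100000, 300000), strand = "+"),
    data.frame(lnc_id = paste0("L", 1:4), aliases = "", chrom = "chr1",
               start0 = c(2000, 5000, 9000, 210000),
               end0 = c(3000, 6000, 10000, 211000),
               strand = c("+", "+", "-", "+")))
  cl <- classify_all(ann)
  roll <- host_gene_rollup(cl, de_lnc_ids = c("L1", "L2", "L3"))
  expect_equal(roll$gene_id, "H1")  # H2's lncRNA is not DE -> absent
  expect_equal(roll$n_total, 3)
  expect_equal(roll$n_sense, 2)
  expect_equal(roll$n_antisense, 1)
  expect_equal(nrow(host_gene_rollup(cl, character(0))), 0)
})
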