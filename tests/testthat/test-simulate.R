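small_cfg <- function(seed = 1, ...) {
  simulation_config(seed = seed,
                    planted_counts = c(intragenic_sense = 2, intragenic_antisense = 2,
                                       linc_neighbor = 2, linc_orphan = 2),
                    n_coding = 12, n_chroms = 2, chrom_length = 4e6, ...)
}

test_that("generator is deterministic under a fixed seed", {
  a <- generate_annotation(small_cfg(5))
  b <- generate_annotation(small_cfg(5))
  expect_identical(a, b)
  ea <- generate_expression(small_cfg(5), a$ann, a$truth)
  eb <- generate_expression(small_cfg(5), b$ann, b$truth)
  expect_identical(ea, eb)
  ca <- generate_ct_table(small_cfg(5), a$truth)
  cb <- generate_ct_table(small_cfg(5), b$truth)
  expect_identical(ca, cb)
  c2 <- generate_annotation(small_cfg(6))
  expect_false(identical(a$ann$genes$start0, c2$ann$genes$start0))
})

test_that("planted classes are recovered exactly by the classifier", {
  for (seed in 1:8) {
    counts <- c(intragenic_sense = sample(0:4, 1), intragenic_antisense = sample(0:4, 1),
                linc_neighbor = sample(0:6, 1), linc_orphan = sample(0:3, 1))
    cfg <- simulation_config(seed = seed, planted_counts = counts,
                             n_coding = 20, n_chroms = 2, chrom_length = 6e6)
    ga <- generate_annotation(cfg)
    cl <- classify_all(ga$ann)
    got <- table(factor(cl$spatial_class, levels = names(counts)))
    expect_equal(as.vector(got), as.vector(counts))
    # per-lncRNA class and partner agree with ground truth
    m <- merge(cl, ga$truth$class, by = "lnc_id")
    expect_true(all(m$spatial_class == m$true_class))
    has_partner <- !is.na(m$partner_gene_id)
    expect_true(all(m$partner_gene_ids[has_partner] == m$partner_gene_id[has_partner]))
    nb <- m$true_class == "linc_neighbor"
    expect_equal(m$gap_bp.x[nb], m$gap_bp.y[nb])
  }
})

test_that("zero planted lncRNAs yields genes only", {
  cfg <- simulation_config(seed = 2,
                           planted_counts = c(intragenic_sense = 0, intragenic_antisense = 0,
                                              linc_neighbor = 0, linc_orphan = 0),
                           n_coding = 10, n_chroms = 2, chrom_length = 4e6)
  ga <- generate_annotation(cfg)
  expect_equal(nrow(ga$ann$genes), 10)
  expect_equal(nrow(ga$ann$lncrnas), 0)
})

test_that("noise-free expression reproduces the planted fold change exactly", {
  cfg <- small_cfg(3, log2_sigma = 0, de_log2fc = log2(2.5))
  ga <- generate_annotation(cfg)
  ex <- generate_expression(cfg, ga$ann, ga$truth)
  de24 <- ga$truth$de[ga$truth$de$stratum == "24w", ]
  case_cols <- ex$samples$sample[ex$samples$group == "ob" & ex$samples$stratum == "24w"]
  ctrl_cols <- ex$samples$sample[ex$samples$group == "wt" & ex$samples$stratum == "24w"]
  ratio <- 2^(rowMeans(ex$mat[, case_cols]) - rowMeans(ex$mat[, ctrl_cols]))
  up <- de24$feature_id[de24$direction == "up"]
  expect_equal(unname(ratio[up]), rep(2.5, length(up)))
  not_de <- setdiff(rownames(ex$mat), de24$feature_id)
  expect_equal(unname(ratio[not_de]), rep(1, length(not_de)))
})

test_that("planted log2 fold changes are recovered within 3 SE on average", {
  cfg <- small_cfg(9, log2_sigma = 0.25)
  ga <- generate_annotation(cfg)
  ex <- generate_expression(cfg, ga$ann, ga$truth)
  de24 <- ga$truth$de[ga$truth$de$stratum == "24w", ]
  de <- call_de(ex$mat, ex$samples, "24w", "ob", "wt")
  est <- de$log2fc[match(de24$feature_id, de$feature_id)]
  sgn <- ifelse(de24$direction == "up", 1, -1)
  se <- 0.25 * sqrt(2 / cfg$n_replicates) / sqrt(nrow(de24))
  expect_lt(abs(mean(est * sgn) - cfg$de_log2fc), 3 * se)
})

test_that("noise-free Ct tables obey the ddCt identities", {
  cfg <- small_cfg(4, sigma_ct = 0, de_log2fc = 1)
  ga <- generate_annotation(cfg)
  ct <- generate_ct_table(cfg, ga$truth)
  expect_true(all(table(ct$sample, ct$gene) == 3))  # triplicates everywhere
  targets <- setdiff(unique(ct$gene), "Ppib")
  de24 <- ga$truth$de[ga$truth$de$stratum == "24w", ]
  for (g in targets) {
    r <- ddct(ct, g, "Ppib", "ob", "wt", "24w")
    dir <- de24$direction[de24$feature_id == g]
    want <- if (length(dir) == 0) 1 else if (dir == "up") 2 else 0.5
    expect_equal(r$fold_change, want, tolerance = 1e-12)
  }
  ref <- ddct(ct, "Ppib", "Ppib", "ob", "wt", "24w")
  expect_identical(ref$fold_change, 1)
})

test_that("the default concordance plan mirrors the planted proximal structure", {
  plan <- default_concordance_plan(c(intragenic_sense = 8, intragenic_antisense = 6,
                                     linc_neighbor = 20, linc_orphan = 6))
  prox <- plan[plan$relation == "neighbor" & !is.na(plan$proximal) & plan$proximal, ]
  expect_equal(nrow(prox), 13)
  expect_equal(sum(prox$gene_direction == prox$lnc_direction), 12)
  expect_equal(sum(prox$position == "downstream"), 12)
  expect_equal(sum(prox$same_strand), 11)
  expect_equal(sum(plan$relation == "sense"), 8)
  expect_equal(sum(plan$relation == "antisense"), 6)
})

test_that("infeasible placement fails with an advisory error", {
  expect_error(simulation_config(seed = 1, n_coding = 60, n_chroms = 1,
                                 chrom_length = 1e6),
               "chrom_length")
})
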