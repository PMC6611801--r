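de_row <- function(id, dir, sig = TRUE) {
  data.frame(feature_id = id, log2fc = ifelse(dir == "up", 1.5, -1.5),
             fc = ifelse(dir == "up", 2.8, 1 / 2.8), direction = dir,
             significant = sig, stringsAsFactors = FALSE)
}

simple_classified <- data.frame(
  lnc_id = c("L1", "L2", "L3", "L4"),
  spatial_class = c("intragenic_sense", "intragenic_antisense",
                    "linc_neighbor", "linc_orphan"),
  partner_gene_ids = c("G1", "G2", "G3", ""),
  gap_bp = c(0, 0, 4999, NA),
  relative_position = c(NA, NA, "downstream", NA),
  same_strand_as_partner = c(NA, NA, TRUE, NA),
  proximal_flag = c(TRUE, TRUE, TRUE, NA),
  stringsAsFactors = FALSE)

test_that("pairs join only co-located significant features", {
  de_lnc <- rbind(de_row("L1", "up"), de_row("L2", "down"),
                  de_row("L3", "up"), de_row("L4", "up"))
  de_gene <- rbind(de_row("G1", "up"), de_row("G2", "up"),
                   de_row("G3", "down"), de_row("G9", "up"))
  pairs <- build_pairs(simple_classified, de_lnc, de_gene, "24w")
  expect_equal(nrow(pairs), 3)  # orphan L4 contributes nothing
  expect_equal(pairs$pattern[pairs$lnc_id == "L1"], "gene_up_lnc_up")
  expect_equal(pairs$pattern[pairs$lnc_id == "L2"], "gene_up_lnc_down")
  expect_equal(pairs$pattern[pairs$lnc_id == "L3"], "gene_down_lnc_up")
  expect_equal(pairs$relation, c("sense", "antisense", "neighbor"))
  # non-significant partner gene drops the pair
  de_gene2 <- rbind(de_row("G1", "up", sig = FALSE), de_row("G2", "up"),
                    de_row("G3", "down"))
  pairs2 <- build_pairs(simple_classified, de_lnc, de_gene2, "24w")
  expect_false("L1" %in% pairs2$lnc_id)
  # non-significant lncRNA likewise
  de_lnc2 <- rbind(de_row("L1", "up", sig = FALSE), de_row("L2", "down"),
                   de_row("L3", "up"), de_row("L4", "up"))
  expect_false("L1" %in% build_pairs(simple_classified, de_lnc2, de_gene, "24w")$lnc_id)
})

test_that("a multi-lncRNA host gene yields one pair per lncRNA (many-to-many)", {
  cl <- data.frame(lnc_id = c("La", "Lb"),
                   spatial_class = "intragenic_sense",
                   partner_gene_ids = "G1", gap_bp = 0,
                   relative_position = NA, same_strand_as_partner = NA,
                   proximal_flag = TRUE, stringsAsFactors = FALSE)
  pairs <- build_pairs(cl, rbind(de_row("La", "up"), de_row("Lb", "down")),
                       de_row("G1", "up"), "24w")
  expect_equal(nrow(pairs), 2)
  conc <- concordance_table(pairs)
  expect_equal(unique(conc$n), 2)
  expect_equal(unique(conc$n_genes), 1)  # distinct-gene margin
})

test_that("concordance table equals a brute-force tally and zero-fills patterns", {
  set.seed(81)
  n <- 40
  pairs <- data.frame(
    lnc_id = paste0("L", 1:n), gene_id = paste0("G", 1:n),
    relation = sample(c("sense", "antisense", "neighbor"), n, replace = TRUE),
    stratum = sample(c("16w", "24w"), n, replace = TRUE),
    lnc_direction = sample(c("up", "down"), n, replace = TRUE),
    gene_direction = sample(c("up", "down"), n, replace = TRUE),
    gap_bp = 0, same_strand = TRUE, relative_position = NA,
    stringsAsFactors = FALSE)
  pairs$pattern <- paste0("gene_", pairs$gene_direction, "_lnc_", pairs$lnc_direction)
  tab <- concordance_table(pairs)
  for (i in seq_len(nrow(tab))) {
    want <- sum(pairs$relation == tab$relation[i] & pairs$stratum == tab$stratum[i] &
                  pairs$pattern == tab$pattern[i])
    expect_equal(tab$count[i], want)
  }
  # four patterns per populated cell; counts sum to n within each cell
  cells <- split(tab, list(tab$relation, tab$stratum), drop = TRUE)
  for (cell in cells) {
    expect_equal(nrow(cell), 4)
    expect_equal(sum(cell$count), cell$n[1])
  }
  expect_equal(sum(tab$count), nrow(pairs))
  expect_equal(nrow(concordance_table(pairs[0, ])), 0)
})

test_that("proximal analysis uses a strict threshold and is monotone in it", {
  pairs <- data.frame(
    lnc_id = c("L1", "L2", "L3"), gene_id = c("G1", "G2", "G3"),
    relation = "neighbor", stratum = "24w",
    lnc_direction = c("up", "up", "down"), gene_direction = c("up", "down", "down"),
    pattern = c("gene_up_lnc_up", "gene_down_lnc_up", "gene_down_lnc_down"),
    gap_bp = c(4999, 5000, 1200), same_strand = c(TRUE, FALSE, TRUE),
    relative_position = c("downstream", "upstream", "downstream"),
    stringsAsFactors = FALSE)
  s <- proximal_analysis(pairs, 5000)
  expect_equal(s$n_proximal, 2)       # gap 5000 excluded
  expect_equal(s$n_same_pattern, 2)
  expect_equal(s$n_downstream, 2)
  expect_equal(s$n_same_strand, 2)
  thresholds <- c(1000, 2000, 5000, 10000)
  ns <- vapply(thresholds, function(t) proximal_analysis(pairs, t)$n_proximal, numeric(1))
  expect_true(all(diff(ns) >= 0))
  empty <- proximal_analysis(pairs[pairs$relation == "sense", ])
  expect_equal(unlist(empty), c(n_proximal = 0, n_same_pattern = 0,
                                n_downstream = 0, n_same_strand = 0))
})

test_that("venn membership matches brute-force set arithmetic", {
  mk_de <- function(sig_ids, all_ids) {
    data.frame(feature_id = all_ids, direction = "up",
               significant = all_ids %in% sig_ids, stringsAsFactors = FALSE)
  }
  ids <- paste0("F", 1:30)
  set.seed(82)
  s8 <- sample(ids, 8); s16 <- sample(ids, 12); s24 <- sample(ids, 15)
  v <- venn_membership(list(`8w` = mk_de(s8, ids), `16w` = mk_de(s16, ids),
                            `24w` = mk_de(s24, ids)))
  expect_equal(sum(v$regions$count), length(unique(c(s8, s16, s24))))
  for (f in unique(c(s8, s16, s24))) {
    want <- paste(c("8w", "16w", "24w")[c(f %in% s8, f %in% s16, f %in% s24)],
                  collapse = ",")
    expect_equal(v$membership$strata[v$membership$feature_id == f], want)
  }
  # disjoint strata -> all singleton regions
  v2 <- venn_membership(list(a = mk_de(ids[1:5], ids), b = mk_de(ids[6:10], ids)))
  expect_setequal(v2$regions$region, c("a", "b"))
  expect_error(venn_membership(list(a = mk_de(ids[1:5], ids))), ">= 2 strata")
})
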