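# Independent oracles: deliberately naive implementations (plain loops,
# closed forms, enumeration) against which the package's vectorized /
# indexed paths are checked. They share no code with the package internals.

# --- brute-force spatial classifier: all-pairs scan ------------------------

oracle_gap <- function(s1, e1, s2, e2) max(s2 - e1, s1 - e2, 0)
oracle_overlap <- function(s1, e1, s2, e2) (s1 < e2) && (s2 < e1)

oracle_classify <- function(genes, lncrnas, window_bp = 50000) {
  out <- list()
  for (i in seq_len(nrow(lncrnas))) {
    l <- lncrnas[i, ]
    partners <- character(0)
    sense_hit <- FALSE
    for (j in seq_len(nrow(genes))) {
      g <- genes[j, ]
      if (g$chrom != l$chrom) next
      if (oracle_overlap(l$start0, l$end0, g$start0, g$end0)) {
        partners <- c(partners, g$gene_id)
        if (g$strand == l$strand) sense_hit <- TRUE
      }
    }
    if (length(partners) > 0) {
      cls <- if (sense_hit) "intragenic_sense" else "intragenic_antisense"
      gap <- 0
    } else {
      gaps <- c()
      ids <- c()
      for (j in seq_len(nrow(genes))) {
        g <- genes[j, ]
        if (g$chrom != l$chrom) next
        gaps <- c(gaps, oracle_gap(l$start0, l$end0, g$start0, g$end0))
        ids <- c(ids, g$gene_id)
      }
      if (length(gaps) > 0 && min(gaps) < window_bp) {
        cls <- "linc_neighbor"
        gap <- min(gaps)
        partners <- ids[gaps == gap]
      } else {
        cls <- "linc_orphan"
        gap <- NA_real_
        partners <- character(0)
      }
    }
    out[[i]] <- data.frame(lnc_id = l$lnc_id, spatial_class = cls,
                           partners = paste(sort(partners), collapse = ","),
                           gap_bp = gap, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# random annotation with arbitrary overlaps (no planting), for property tests
random_annotation <- function(n_genes, n_lnc, n_chroms = 3, span = 1e6) {
  chroms <- paste0("chr", seq_len(n_chroms))
  g_len <- sample(1000:50000, n_genes, replace = TRUE)
  g_start <- sample.int(span, n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    symbol = sprintf("G%04d", seq_len(n_genes)),
    chrom = sample(chroms, n_genes, replace = TRUE),
    start0 = g_start, end0 = g_start + g_len,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  l_len <- sample(200:5000, n_lnc, replace = TRUE)
  l_start <- sample.int(span, n_lnc, replace = TRUE)
  lncrnas <- data.frame(
    lnc_id = sprintf("L%04d", seq_len(n_lnc)),
    aliases = rep("", n_lnc),
    chrom = sample(chroms, n_lnc, replace = TRUE),
    start0 = l_start, end0 = l_start + l_len,
    strand = sample(c("+", "-"), n_lnc, replace = TRUE),
    stringsAsFactors = FALSE)
  annotation_set(genes, lncrnas)
}

# compare package classification against the all-pairs oracle
classification_agrees <- function(ann, window_bp = 50000) {
  got <- classify_all(ann, window_bp = window_bp)
  want <- oracle_classify(ann$genes, ann$lncrnas, window_bp = window_bp)
  got_partners <- vapply(strsplit(got$partner_gene_ids, ","), function(x)
    paste(sort(x), collapse = ","), character(1))
  identical(got$lnc_id, want$lnc_id) &&
    identical(got$spatial_class, want$spatial_class) &&
    identical(got_partners, want$partners) &&
    isTRUE(all.equal(got$gap_bp, want$gap_bp))
}

# --- step-up BH by literal enumeration --------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  rank_of <- integer(m)
  rank_of[ord] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    cands <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) p[j] * m / rank_of[j] else Inf
    }, numeric(1))
    min(1, min(cands))
  }, numeric(1))
}

# --- hypergeometric upper tail by mass summation (choose() arithmetic) ------

oracle_hyper_upper <- function(N, K, n, k) {
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  ks <- max(k, lo):hi
  if (k > hi) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# --- scalar-loop moderated t (literal formulas) -----------------------------

oracle_moderated_t <- function(mean1, mean2, n1, n2, s2, d_g, d0, s0_sq) {
  t_out <- p_out <- numeric(length(s2))
  for (i in seq_along(s2)) {
    s2_post <- (d0 * s0_sq + d_g * s2[i]) / (d0 + d_g)
    t_out[i] <- (mean1[i] - mean2[i]) / sqrt(s2_post * (1 / n1 + 1 / n2))
    p_out[i] <- 2 * pt(-abs(t_out[i]), df = d0 + d_g)
  }
  list(t_mod = t_out, p = p_out)
}

# all permutations of 1..n, recursively
combinat_permutations <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- combinat_permutations(n - 1)
  out <- list()
  for (p in smaller)
    for (pos in 0:(n - 1))
      out[[length(out) + 1]] <- append(p, n, after = pos)
  out
}

# --- small expression fixture -----------------------------------------------

two_group_matrix <- function(n_feat, n1 = 4, n2 = 4, delta = rep(0, n_feat),
                             sigma = 0.25) {
  mat <- cbind(
    matrix(rnorm(n_feat * n1, mean = delta, sd = sigma), n_feat, n1),
    matrix(rnorm(n_feat * n2, mean = 0, sd = sigma), n_feat, n2))
  rownames(mat) <- sprintf("F%05d", seq_len(n_feat))
  colnames(mat) <- c(sprintf("case_%d", 1:n1), sprintf("ctrl_%d", 1:n2))
  mat
}

two_group_sheet <- function(n1 = 4, n2 = 4, stratum = "24w") {
  data.frame(sample = c(sprintf("case_%d", 1:n1), sprintf("ctrl_%d", 1:n2)),
             group = c(rep("ob", n1), rep("wt", n2)),
             stratum = stratum, stringsAsFactors = FALSE)
}
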