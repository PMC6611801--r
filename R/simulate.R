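# Synthetic-data generator: annotation with planted spatial classes,
# group-structured log2 expression with planted fold changes, and qPCR Ct
# tables with a stable reference gene. Every draw is driven by the single
# integer seed in the config (sub-stages use fixed offsets of it), so a
# config reproduces its fixtures byte-identically.

# Allocate n items over categories by proportions, largest-remainder rounding.
alloc_counts <- function(n, props) {
  raw <- n * props / sum(props)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  base
}

#' Default regulation-concordance plan for the generator
#'
#' Builds a deterministic plan of planted DE lncRNA-mRNA pairs: one row per
#' paired lncRNA giving its relation, both regulation directions, and (for
#' neighbors) gap class, position and strand relation. The default mirrors
#' the structure reported for late-stage diabetic glomeruli at desk scale:
#' sense pairs predominantly up/up, antisense pairs mostly discordant, and
#' a proximal lincRNA subset of 13 pairs of which 12 are concordant, 12 lie
#' downstream of their partner gene and 11 share its strand.
#'
#' @param planted_counts named vector with intragenic_sense,
#'   intragenic_antisense, linc_neighbor, linc_orphan.
#' @param strata stratum labels; all pairs are planted DE in the last
#'   stratum, and a small subset additionally in the first (when >= 2
#'   strata), giving a non-trivial Venn structure.
#' @return data.frame, one row per paired planted lncRNA.
#' @export
default_concordance_plan <- function(planted_counts, strata = c("16w", "24w")) {
  n_s <- planted_counts[["intragenic_sense"]]
  n_a <- planted_counts[["intragenic_antisense"]]
  n_nb <- planted_counts[["linc_neighbor"]]
  main <- strata[length(strata)]
  pattern_of <- function(g, l) paste0("gene_", g, "_lnc_", l)
  rows <- list()
  mk <- function(relation, gene_dir, lnc_dir, proximal = NA, position = NA_character_,
                 same_strand = NA) {
    data.frame(relation = relation, gene_direction = gene_dir,
               lnc_direction = lnc_dir, proximal = proximal,
               position = position, same_strand = same_strand,
               strata = main, stringsAsFactors = FALSE)
  }
  if (n_s > 0) {
    cnt <- alloc_counts(n_s, c(up_up = 148, up_down = 8, down_down = 4))
    rows$sense <- rbind(
      if (cnt[1] > 0) do.call(rbind, replicate(cnt[1], mk("sense", "up", "up"), simplify = FALSE)),
      if (cnt[2] > 0) do.call(rbind, replicate(cnt[2], mk("sense", "up", "down"), simplify = FALSE)),
      if (cnt[3] > 0) do.call(rbind, replicate(cnt[3], mk("sense", "down", "down"), simplify = FALSE)))
  }
  if (n_a > 0) {
    cnt <- alloc_counts(n_a, c(up_up = 3, up_down = 7, down_down = 4))
    rows$antisense <- rbind(
      if (cnt[1] > 0) do.call(rbind, replicate(cnt[1], mk("antisense", "up", "up"), simplify = FALSE)),
      if (cnt[2] > 0) do.call(rbind, replicate(cnt[2], mk("antisense", "up", "down"), simplify = FALSE)),
      if (cnt[3] > 0) do.call(rbind, replicate(cnt[3], mk("antisense", "down", "down"), simplify = FALSE)))
  }
  if (n_nb > 0) {
    n_prox <- min(13, n_nb)
    n_dist <- n_nb - n_prox
    prox <- NULL
    if (n_prox > 0) {
      n_conc <- if (n_prox >= 2) n_prox - 1 else n_prox
      cnt <- alloc_counts(n_conc, c(up_up = 2, down_down = 1))
      dirs <- rbind(
        if (cnt[1] > 0) data.frame(g = rep("up", cnt[1]), l = rep("up", cnt[1])),
        if (cnt[2] > 0) data.frame(g = rep("down", cnt[2]), l = rep("down", cnt[2])),
        if (n_prox > n_conc) data.frame(g = "up", l = "down"))
      n_downstr <- if (n_prox >= 2) n_prox - 1 else n_prox
      n_same <- max(n_prox - 2, if (n_prox > 0) 1 else 0)
      n_same <- min(n_same, n_prox)
      prox <- do.call(rbind, lapply(seq_len(n_prox), function(i)
        mk("neighbor", dirs$g[i], dirs$l[i], proximal = TRUE,
           position = if (i <= n_downstr) "downstream" else "upstream",
           same_strand = i <= n_same)))
    }
    dist <- NULL
    if (n_dist > 0) {
      cnt <- alloc_counts(n_dist, c(up_up = 11, up_down = 13, down_down = 13))
      dirs <- rbind(
        if (cnt[1] > 0) data.frame(g = rep("up", cnt[1]), l = rep("up", cnt[1])),
        if (cnt[2] > 0) data.frame(g = rep("up", cnt[2]), l = rep("down", cnt[2])),
        if (cnt[3] > 0) data.frame(g = rep("down", cnt[3]), l = rep("down", cnt[3])))
      dist <- do.call(rbind, lapply(seq_len(n_dist), function(i)
        mk("neighbor", dirs$g[i], dirs$l[i], proximal = FALSE,
           position = if (i %% 2 == 1) "downstream" else "upstream",
           same_strand = i %% 2 == 1)))
    }
    rows$neighbor <- rbind(prox, dist)
  }
  plan <- do.call(rbind, rows)
  rownames(plan) <- NULL
  if (!is.null(plan)) {
    plan$pattern <- pattern_of(plan$gene_direction, plan$lnc_direction)
    # a small subset is DE in the first stratum too (cross-stratum Venn)
    if (length(strata) >= 2 && nrow(plan) > 0) {
      extra <- c(which(plan$relation == "sense")[1:2],
                 which(plan$relation == "neighbor" & plan$proximal)[1:2])
      extra <- extra[!is.na(extra)]
      plan$strata[extra] <- paste(strata[1], main, sep = ",")
    }
  }
  plan
}

#' Simulation configuration
#'
#' Defines the synthetic study: genome layout, planted spatial-class
#' counts, replication, noise, planted effect sizes and the
#' regulation-concordance plan. Defaults emulate a two-group (wt vs ob)
#' glomerular array study with 4 replicates per group and a planted
#' |log2 fold change| of 1.322 (linear fold change 2.5, just above the 2.0
#' significance gate).
#'
#' @param seed integer master seed; every stage derives its stream from it.
#' @param n_chroms,chrom_length genome layout (chr1..chrN, equal lengths).
#' @param n_coding number of protein-coding genes.
#' @param planted_counts named vector of planted lncRNA counts per class.
#' @param neighbor_gap_range gap range (bases) for distal neighbor lincRNAs.
#' @param proximal_gap_range gap range for the proximal (< 5 kb) subset.
#' @param n_replicates biological replicates per group per stratum.
#' @param log2_sigma residual SD of log2 intensities.
#' @param de_log2fc planted |log2 fold change| for DE features.
#' @param de_fraction fraction of unpaired features given background DE.
#' @param strata stratum (age-group) labels.
#' @param concordance_plan pair plan; NULL builds
#'   \code{\link{default_concordance_plan}}.
#' @param sigma_ct Ct measurement SD for the qPCR generator.
#' @param n_ct_animals animals per group in the Ct generator.
#' @param retry_cap rejection-sampling retries per feature placement.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1,
                              n_chroms = 4,
                              chrom_length = 10e6,
                              n_coding = 60,
                              planted_counts = c(intragenic_sense = 8,
                                                 intragenic_antisense = 6,
                                                 linc_neighbor = 20,
                                                 linc_orphan = 6),
                              neighbor_gap_range = c(6000, 49000),
                              proximal_gap_range = c(200, 4800),
                              n_replicates = 4,
                              log2_sigma = 0.1,
                              de_log2fc = 1.322,
                              de_fraction = 0.1,
                              strata = c("16w", "24w"),
                              concordance_plan = NULL,
                              sigma_ct = 0.1,
                              n_ct_animals = 6,
                              retry_cap = 1000) {
  stopifnot(all(planted_counts >= 0), de_log2fc > 0, n_replicates >= 2,
            length(strata) >= 1, de_fraction >= 0, de_fraction <= 1,
            log2_sigma >= 0, sigma_ct >= 0)
  need <- c("intragenic_sense", "intragenic_antisense", "linc_neighbor", "linc_orphan")
  if (!all(need %in% names(planted_counts)))
    stop("planted_counts must name: ", paste(need, collapse = ", "))
  n_paired <- planted_counts[["intragenic_sense"]] +
    planted_counts[["intragenic_antisense"]] + planted_counts[["linc_neighbor"]]
  if (n_coding < ceiling(n_paired * 0.8) + 2)
    stop("n_coding too small for the planted pair structure")
  # rough feasibility: each gene needs ~max gene length + separation of space
  per_chrom <- ceiling(n_coding / n_chroms)
  if (per_chrom * 220000 > chrom_length - 200000)
    stop("chrom_length too small to place ", n_coding,
         " genes without unintended overlap; increase chrom_length")
  if (is.null(concordance_plan))
    concordance_plan <- default_concordance_plan(planted_counts, strata)
  structure(list(seed = seed, n_chroms = n_chroms, chrom_length = chrom_length,
                 n_coding = n_coding, planted_counts = planted_counts,
                 neighbor_gap_range = neighbor_gap_range,
                 proximal_gap_range = proximal_gap_range,
                 n_replicates = n_replicates, log2_sigma = log2_sigma,
                 de_log2fc = de_log2fc, de_fraction = de_fraction,
                 strata = strata, concordance_plan = concordance_plan,
                 sigma_ct = sigma_ct, n_ct_animals = n_ct_animals,
                 retry_cap = retry_cap),
            class = "simulation_config")
}

place_genes <- function(cfg) {
  min_sep <- 120000  # edge-to-edge separation guaranteeing unambiguous classes
  margin <- 60000    # keeps up/downstream lincRNA placements on-chromosome
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_of <- rep(chroms, length.out = cfg$n_coding)
  placed <- data.frame(gene_id = sprintf("GENE%03d", seq_len(cfg$n_coding)),
                       symbol = sprintf("Gene%03d", seq_len(cfg$n_coding)),
                       chrom = chrom_of, start0 = NA_real_, end0 = NA_real_,
                       strand = sample(c("+", "-"), cfg$n_coding, replace = TRUE),
                       stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_coding)) {
    len <- round(runif(1, 20000, 80000))
    ok <- FALSE
    for (try in seq_len(cfg$retry_cap)) {
      s <- round(runif(1, margin, cfg$chrom_length - len - margin))
      prior <- placed[!is.na(placed$start0) & placed$chrom == placed$chrom[i], ]
      if (nrow(prior) == 0 ||
          all(gap0(s, s + len, prior$start0, prior$end0) >= min_sep)) {
        placed$start0[i] <- s
        placed$end0[i] <- s + len
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place gene ", placed$gene_id[i], " after ",
                  cfg$retry_cap, " retries; increase chrom_length")
  }
  placed
}

#' Generate annotation with planted spatial classes
#'
#' Places protein-coding genes well separated along the synthetic
#' chromosomes (rejection sampling with a retry cap), then plants each
#' lncRNA so that it satisfies its class by construction: sense lncRNAs
#' inside a host gene on its strand, antisense lncRNAs inside a host on the
#' opposite strand, neighbor lincRNAs at a drawn gap (< 50 kb) from a
#' dedicated partner gene on the planned side/strand, and orphan lincRNAs
#' more than 50 kb from every gene. The gene separation guarantees no
#' accidental overlap or partner ambiguity.
#'
#' @param cfg simulation_config.
#' @return list(ann = annotation_set, truth = ground-truth list with
#'   elements \code{class} (per-lncRNA true class/partner/gap),
#'   \code{de} (planted DE flags per feature x stratum), and
#'   \code{pairs} (the realized concordance plan with ids)).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(is(cfg, "simulation_config"))
  set.seed(cfg$seed)
  genes <- place_genes(cfg)
  plan <- cfg$concordance_plan
  pc <- cfg$planted_counts
  n_s <- pc[["intragenic_sense"]]; n_a <- pc[["intragenic_antisense"]]
  n_nb <- pc[["linc_neighbor"]]; n_or <- pc[["linc_orphan"]]

  # host/partner gene assignment: a few hosts are shared to exercise the
  # multi-lncRNA host rollup. Shared hosts must carry one regulation
  # direction, so sharing is restricted to plan rows whose gene_direction
  # agrees; neighbor partners are distinct genes.
  plan_rel <- if (!is.null(plan)) plan$relation else character(0)
  assign_hosts <- function(dirs, max_shared, base) {
    n <- length(dirs)
    if (n == 0) return(integer(0))
    host <- integer(n)
    maj <- names(sort(table(dirs), decreasing = TRUE))[1]
    shared_idx <- which(dirs == maj)[seq_len(min(max_shared, sum(dirs == maj)))]
    host[shared_idx] <- base
    rest <- setdiff(seq_len(n), shared_idx)
    host[rest] <- base + seq_along(rest)
    host
  }
  dirs_of <- function(rel, n) {
    if (n == 0) return(character(0))
    if (is.null(plan)) return(rep("up", n))
    d <- plan$gene_direction[plan_rel == rel][seq_len(n)]
    d[is.na(d)] <- "up"  # lncRNAs beyond the plan: direction irrelevant
    d
  }
  dirs_s <- dirs_of("sense", n_s)
  dirs_a <- dirs_of("antisense", n_a)
  host_s <- assign_hosts(dirs_s, 3, 1)
  base_a <- max(c(host_s, 0)) + 1
  host_a <- assign_hosts(dirs_a, 2, base_a)
  base_nb <- max(c(host_s, host_a, 0)) + 1
  part_nb <- if (n_nb > 0) seq_len(n_nb) + base_nb - 1 else integer(0)
  if (length(part_nb) > 0 && max(part_nb) > nrow(genes))
    stop("n_coding too small for planted pair structure")

  lnc_rows <- list()
  truth_rows <- list()
  plan_rel <- if (!is.null(plan)) plan$relation else character(0)
  idx_sense <- which(plan_rel == "sense")
  idx_anti <- which(plan_rel == "antisense")
  idx_nb <- which(plan_rel == "neighbor")
  k <- 0
  add_lnc <- function(id, chrom, s, e, strand) {
    data.frame(lnc_id = id, aliases = paste0("NONMMUT", sprintf("%06d", k)),
               chrom = chrom, start0 = s, end0 = e, strand = strand,
               stringsAsFactors = FALSE)
  }
  # intragenic (sense then antisense)
  for (j in seq_len(n_s + n_a)) {
    sense <- j <= n_s
    host <- genes[if (sense) host_s[j] else host_a[j - n_s], ]
    k <- k + 1
    len <- round(runif(1, 500, 2000))
    s <- round(runif(1, host$start0 + 100, host$end0 - len - 100))
    strand <- if (sense) host$strand else setdiff(valid_strands, host$strand)
    id <- sprintf("LNC%03d", k)
    lnc_rows[[k]] <- add_lnc(id, host$chrom, s, s + len, strand)
    truth_rows[[k]] <- data.frame(
      lnc_id = id,
      true_class = if (sense) "intragenic_sense" else "intragenic_antisense",
      partner_gene_id = host$gene_id, gap_bp = 0,
      position = NA_character_, same_strand = sense, proximal = TRUE,
      stringsAsFactors = FALSE)
  }
  # neighbor lincRNAs
  for (j in seq_len(n_nb)) {
    p <- genes[part_nb[j], ]
    row <- if (length(idx_nb) >= j) plan[idx_nb[j], ] else
      data.frame(proximal = FALSE, position = "downstream", same_strand = TRUE)
    gr <- if (isTRUE(row$proximal)) cfg$proximal_gap_range else cfg$neighbor_gap_range
    gap <- round(runif(1, gr[1], gr[2]))
    k <- k + 1
    len <- round(runif(1, 500, 2000))
    # "downstream" is 3' of the partner in the partner's frame
    right_side <- (row$position == "downstream") == (p$strand == "+")
    s <- if (right_side) p$end0 + gap else p$start0 - gap - len
    strand <- if (isTRUE(row$same_strand)) p$strand else setdiff(valid_strands, p$strand)
    id <- sprintf("LNC%03d", k)
    lnc_rows[[k]] <- add_lnc(id, p$chrom, s, s + len, strand)
    truth_rows[[k]] <- data.frame(
      lnc_id = id, true_class = "linc_neighbor", partner_gene_id = p$gene_id,
      gap_bp = gap, position = row$position, same_strand = isTRUE(row$same_strand),
      proximal = gap < 5000, stringsAsFactors = FALSE)
  }
  # orphan lincRNAs: > 50 kb from every gene, rejection-sampled
  for (j in seq_len(n_or)) {
    k <- k + 1
    len <- round(runif(1, 500, 2000))
    chrom <- paste0("chr", 1 + (j - 1) %% cfg$n_chroms)
    gch <- genes[genes$chrom == chrom, ]
    ok <- FALSE
    for (try in seq_len(cfg$retry_cap)) {
      s <- round(runif(1, 0, cfg$chrom_length - len))
      if (nrow(gch) == 0 || all(gap0(s, s + len, gch$start0, gch$end0) > 50000)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place orphan lincRNA after ", cfg$retry_cap,
                  " retries; increase chrom_length")
    id <- sprintf("LNC%03d", k)
    lnc_rows[[k]] <- add_lnc(id, chrom, s, s + len, sample(valid_strands, 1))
    truth_rows[[k]] <- data.frame(
      lnc_id = id, true_class = "linc_orphan", partner_gene_id = NA_character_,
      gap_bp = NA_real_, position = NA_character_, same_strand = NA,
      proximal = NA, stringsAsFactors = FALSE)
  }
  lncrnas <- if (k > 0) do.call(rbind, lnc_rows) else
    data.frame(lnc_id = character(0), aliases = character(0), chrom = character(0),
               start0 = numeric(0), end0 = numeric(0), strand = character(0),
               stringsAsFactors = FALSE)
  truth_class <- if (k > 0) do.call(rbind, truth_rows) else NULL
  chrom_sizes <- setNames(rep(cfg$chrom_length, cfg$n_chroms),
                          paste0("chr", seq_len(cfg$n_chroms)))
  ann <- annotation_set(genes[, c("gene_id", "symbol", "chrom", "start0",
                                  "end0", "strand")],
                        lncrnas, chrom_sizes = chrom_sizes)

  # realized pair plan with ids + planted DE flags
  paired_idx <- c(seq_len(n_s), n_s + seq_len(n_a), n_s + n_a + seq_len(n_nb))
  pairs <- NULL
  de <- list()
  main <- cfg$strata[length(cfg$strata)]
  if (!is.null(plan) && nrow(plan) > 0 && length(paired_idx) > 0) {
    ord <- c(idx_sense, idx_anti, idx_nb)
    pairs <- plan[ord, ]
    pairs$lnc_id <- truth_class$lnc_id[paired_idx]
    pairs$gene_id <- truth_class$partner_gene_id[paired_idx]
    pairs$gap_bp <- truth_class$gap_bp[paired_idx]
    for (i in seq_len(nrow(pairs))) {
      for (st in strsplit(pairs$strata[i], ",")[[1]]) {
        de[[length(de) + 1]] <- data.frame(
          feature_id = c(pairs$lnc_id[i], pairs$gene_id[i]),
          stratum = st,
          direction = c(pairs$lnc_direction[i], pairs$gene_direction[i]),
          stringsAsFactors = FALSE)
      }
    }
  }
  # background DE among unpaired coding genes and orphan lincRNAs (main stratum)
  unpaired <- c(setdiff(genes$gene_id, if (is.null(pairs)) character(0) else pairs$gene_id),
                truth_class$lnc_id[truth_class$true_class == "linc_orphan"])
  if (length(unpaired) > 0 && cfg$de_fraction > 0) {
    n_bg <- round(cfg$de_fraction * length(unpaired))
    if (n_bg > 0) {
      bg <- sample(unpaired, n_bg)
      de[[length(de) + 1]] <- data.frame(
        feature_id = bg, stratum = main,
        direction = sample(c("up", "down"), n_bg, replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  de_df <- if (length(de) > 0) unique(do.call(rbind, de)) else
    data.frame(feature_id = character(0), stratum = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  rownames(de_df) <- NULL
  if (!is.null(pairs)) rownames(pairs) <- NULL
  list(ann = ann, truth = list(class = truth_class, de = de_df, pairs = pairs))
}

#' Generate group-structured log2 expression and a sample sheet
#'
#' Log2 intensity = feature baseline + group shift + Gaussian noise. Case
#' samples of a stratum receive a shift of +/- de_log2fc for features
#' planted DE in that stratum, 0 otherwise.
#'
#' @param cfg simulation_config.
#' @param ann,truth from \code{\link{generate_annotation}}.
#' @param case,control group labels (defaults "ob", "wt").
#' @return list(mat = features x samples matrix, samples = sample sheet
#'   with columns sample, group, stratum).
#' @export
generate_expression <- function(cfg, ann, truth, case = "ob", control = "wt") {
  set.seed(cfg$seed + 104729L)  # sub-stream: fixed offset of the master seed
  features <- c(ann$genes$gene_id, ann$lncrnas$lnc_id)
  baseline <- runif(length(features), 6, 12)
  names(baseline) <- features
  sheets <- list()
  for (st in cfg$strata) {
    for (g in c(control, case)) {
      sheets[[length(sheets) + 1]] <- data.frame(
        sample = sprintf("%s_%s_%d", g, st, seq_len(cfg$n_replicates)),
        group = g, stratum = st, stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, sheets)
  shift <- matrix(0, nrow = length(features), ncol = nrow(samples),
                  dimnames = list(features, samples$sample))
  if (nrow(truth$de) > 0) {
    for (i in seq_len(nrow(truth$de))) {
      f <- truth$de$feature_id[i]
      cols <- samples$sample[samples$stratum == truth$de$stratum[i] &
                             samples$group == case]
      sgn <- if (truth$de$direction[i] == "up") 1 else -1
      shift[f, cols] <- sgn * cfg$de_log2fc
    }
  }
  noise <- matrix(rnorm(length(features) * nrow(samples), 0, cfg$log2_sigma),
                  nrow = length(features))
  mat <- matrix(baseline, nrow = length(features), ncol = nrow(samples)) +
    shift + noise
  dimnames(mat) <- list(features, samples$sample)
  list(mat = mat, samples = samples)
}

#' Generate a qPCR Ct table with a stable reference gene
#'
#' Ct = per-gene baseline - log2(relative abundance) + Normal(0, sigma_ct),
#' with triplicate technical replicates per animal. Case animals of the
#' main stratum have relative abundance 2^(+/- de_log2fc) for planted-DE
#' genes; the reference gene ("Ppib", cyclophilin B) has no group shift.
#'
#' @param cfg simulation_config.
#' @param truth ground truth from \code{\link{generate_annotation}}.
#' @param genes genes to measure; defaults to the reference plus the first
#'   planted sense pair and the first proximal neighbor pair.
#' @param reference_gene reference gene name.
#' @param case,control group labels.
#' @return data.frame(sample, group, stratum, gene, replicate, ct).
#' @export
generate_ct_table <- function(cfg, truth, genes = NULL,
                              reference_gene = "Ppib",
                              case = "ob", control = "wt") {
  set.seed(cfg$seed + 224737L)
  main <- cfg$strata[length(cfg$strata)]
  if (is.null(genes)) {
    genes <- character(0)
    if (!is.null(truth$pairs) && nrow(truth$pairs) > 0) {
      p <- truth$pairs
      pick <- c(which(p$relation == "sense")[1],
                which(p$relation == "neighbor" & isTRUE_vec(p$proximal))[1])
      pick <- pick[!is.na(pick)]
      genes <- unique(c(p$gene_id[pick], p$lnc_id[pick]))
    }
  }
  all_genes <- c(reference_gene, setdiff(genes, reference_gene))
  baselines <- setNames(runif(length(all_genes), 18, 26), all_genes)
  de_main <- truth$de[truth$de$stratum == main, ]
  shift_of <- setNames(rep(0, length(all_genes)), all_genes)
  hit <- intersect(all_genes, de_main$feature_id)
  for (f in hit) {
    sgn <- if (de_main$direction[de_main$feature_id == f][1] == "up") 1 else -1
    shift_of[f] <- sgn * cfg$de_log2fc
  }
  shift_of[reference_gene] <- 0
  rows <- list()
  for (g in c(control, case)) {
    for (a in seq_len(cfg$n_ct_animals)) {
      smp <- sprintf("%s_%s_a%d", g, main, a)
      for (gene in all_genes) {
        log2_abund <- if (g == case) shift_of[[gene]] else 0
        ct_true <- baselines[[gene]] - log2_abund
        rows[[length(rows) + 1]] <- data.frame(
          sample = smp, group = g, stratum = main, gene = gene,
          replicate = 1:3, ct = ct_true + rnorm(3, 0, cfg$sigma_ct),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Run the full generator and write all fixtures to a directory
#'
#' Emits annotation.tsv (flat dialect), expression.tsv, samples.tsv,
#' ct.tsv, and ground-truth TSVs (truth_class.tsv, truth_de.tsv,
#' truth_pairs.tsv).
#'
#' @param cfg simulation_config.
#' @param outdir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
simulate_study <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ga <- generate_annotation(cfg)
  expr <- generate_expression(cfg, ga$ann, ga$truth)
  ct <- generate_ct_table(cfg, ga$truth)
  write_annotation_tsv(ga$ann, file.path(outdir, "annotation.tsv"))
  emat <- data.frame(feature_id = rownames(expr$mat), expr$mat,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(emat, file.path(outdir, "expression.tsv"))
  write_tsv(expr$samples, file.path(outdir, "samples.tsv"))
  write_tsv(ct, file.path(outdir, "ct.tsv"))
  write_tsv(ga$truth$class, file.path(outdir, "truth_class.tsv"))
  write_tsv(ga$truth$de, file.path(outdir, "truth_de.tsv"))
  if (!is.null(ga$truth$pairs))
    write_tsv(ga$truth$pairs, file.path(outdir, "truth_pairs.tsv"))
  invisible(list(ann = ga$ann, truth = ga$truth, expr = expr, ct = ct))
}
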