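# End-to-end orchestration: simulate -> de -> classify -> pair ->
# chromstats -> enrich -> qpcr -> compare, each stage writing TSVs under
# one output directory, with a manifest (stage, parameters, row counts,
# output hashes) proving determinism.

#' Pipeline configuration
#'
#' Validates the thresholds of the joint significance rule and the spatial
#' windows, and carries the simulation config plus group labels.
#'
#' @param sim simulation_config driving the simulate stage.
#' @param outdir output directory.
#' @param fc_high,fc_low,fdr joint-rule thresholds (2.0, 0.5, 0.05).
#' @param window_bp neighbor window (50000).
#' @param proximal_bp proximal threshold (5000).
#' @param case,control group labels.
#' @param n_perm SAM permutations for the compare stage.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = simulation_config(), outdir = tempfile("cislncde_"),
                            fc_high = 2.0, fc_low = 0.5, fdr = 0.05,
                            window_bp = 50000, proximal_bp = 5000,
                            case = "ob", control = "wt", n_perm = 200) {
  if (!(fc_high > 1 && 1 > fc_low && fc_low > 0))
    stop("invalid fold-change thresholds: need fc_high > 1 > fc_low > 0")
  if (!(fdr > 0 && fdr < 1)) stop("fdr must lie in (0, 1)")
  if (!(window_bp > proximal_bp && proximal_bp > 0))
    stop("need window_bp > proximal_bp > 0")
  stopifnot(is(sim, "simulation_config"))
  structure(list(sim = sim, outdir = outdir, fc_high = fc_high, fc_low = fc_low,
                 fdr = fdr, window_bp = window_bp, proximal_bp = proximal_bp,
                 case = case, control = control, n_perm = n_perm),
            class = "pipeline_config")
}

#' Run the full pipeline on a synthetic study
#'
#' Executes the eight stages on generator output, writes every stage's
#' TSVs under \code{cfg$outdir}, and returns the in-memory results plus a
#' manifest data.frame (stage, n_rows, parameter string, md5 of each
#' written file). Rerunning with an identical config reproduces identical
#' hashes. Any stage failure aborts with the stage name.
#'
#' @param cfg pipeline_config.
#' @return invisible list with elements ann, truth, expr, de (per stratum,
#'   lnc and gene tables), classified, pairs, concordance, proximal, venn,
#'   chromstats, enrichment, qpcr, sam, harmonized, manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(is(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, n_rows, params, files) {
    hashes <- paste(vapply(files, function(f)
      unname(tools::md5sum(file.path(cfg$outdir, f))), character(1)),
      collapse = ",")
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, n_rows = n_rows, params = params,
      files = paste(files, collapse = ","), md5 = hashes,
      stringsAsFactors = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # 1. simulate
  sim <- stage("simulate", simulate_study(cfg$sim, cfg$outdir))
  note("simulate", nrow(sim$ann$genes) + nrow(sim$ann$lncrnas),
       paste0("seed=", cfg$sim$seed),
       c("annotation.tsv", "expression.tsv", "samples.tsv", "ct.tsv"))
  ann <- sim$ann
  truth <- sim$truth
  mat <- sim$expr$mat
  samples <- sim$expr$samples
  lnc_ids <- ann$lncrnas$lnc_id
  gene_ids <- ann$genes$gene_id

  # 2. de (per stratum, split into lncRNA and gene tables)
  de <- stage("de", {
    lapply(setNames(cfg$sim$strata, cfg$sim$strata), function(st) {
      full <- call_de(mat, samples, st, cfg$case, cfg$control,
                      fc_high = cfg$fc_high, fc_low = cfg$fc_low, fdr = cfg$fdr)
      list(lnc = full[full$feature_id %in% lnc_ids, ],
           gene = full[full$feature_id %in% gene_ids, ])
    })
  })
  for (st in names(de)) {
    write_tsv(de[[st]]$lnc, file.path(cfg$outdir, paste0("de_lnc_", st, ".tsv")))
    write_tsv(de[[st]]$gene, file.path(cfg$outdir, paste0("de_gene_", st, ".tsv")))
  }
  note("de", sum(vapply(de, function(d) nrow(d$lnc) + nrow(d$gene), numeric(1))),
       sprintf("fc_high=%g,fc_low=%g,fdr=%g", cfg$fc_high, cfg$fc_low, cfg$fdr),
       as.vector(outer(c("de_lnc_", "de_gene_"), names(de), paste0)) |>
         paste0(".tsv"))

  # 3. classify
  classified <- stage("classify",
                      classify_all(ann, cfg$window_bp, cfg$proximal_bp))
  write_tsv(classified, file.path(cfg$outdir, "classification.tsv"))
  note("classify", nrow(classified), sprintf("window_bp=%d", cfg$window_bp),
       "classification.tsv")

  # 4. pair (+ concordance, proximal, venn, host rollup)
  main <- cfg$sim$strata[length(cfg$sim$strata)]
  pair_out <- stage("pair", {
    pairs <- do.call(rbind, lapply(names(de), function(st)
      build_pairs(classified, de[[st]]$lnc, de[[st]]$gene, st)))
    conc <- concordance_table(pairs)
    prox <- proximal_analysis(pairs[pairs$stratum == main, ], cfg$proximal_bp)
    venn <- if (length(de) >= 2)
      venn_membership(lapply(de, `[[`, "lnc")) else NULL
    rollup <- host_gene_rollup(classified,
                               de[[main]]$lnc$feature_id[de[[main]]$lnc$significant])
    list(pairs = pairs, conc = conc, prox = prox, venn = venn, rollup = rollup)
  })
  write_tsv(pair_out$pairs, file.path(cfg$outdir, "pairs.tsv"))
  write_tsv(pair_out$conc, file.path(cfg$outdir, "concordance.tsv"))
  write_tsv(as.data.frame(pair_out$prox), file.path(cfg$outdir, "proximal.tsv"))
  if (!is.null(pair_out$venn))
    write_tsv(pair_out$venn$regions, file.path(cfg$outdir, "venn.tsv"))
  write_tsv(pair_out$rollup, file.path(cfg$outdir, "host_rollup.tsv"))
  note("pair", nrow(pair_out$pairs),
       sprintf("proximal_bp=%d", cfg$proximal_bp),
       c("pairs.tsv", "concordance.tsv", "proximal.tsv", "host_rollup.tsv"))

  # 5. chromstats
  cs <- stage("chromstats", {
    de_gene_ids <- de[[main]]$gene$feature_id[de[[main]]$gene$significant]
    de_lnc_ids <- de[[main]]$lnc$feature_id[de[[main]]$lnc$significant]
    list(coding = chrom_stats(ann, de_gene_ids, "coding"),
         lncRNA = chrom_stats(ann, de_lnc_ids, "lncRNA_all", classified))
  })
  write_tsv(cs$coding$per_chrom, file.path(cfg$outdir, "chromstats_coding.tsv"))
  write_tsv(cs$lncRNA$per_chrom, file.path(cfg$outdir, "chromstats_lncrna.tsv"))
  note("chromstats", nrow(cs$coding$per_chrom) + nrow(cs$lncRNA$per_chrom),
       "categories=coding,lncRNA_all",
       c("chromstats_coding.tsv", "chromstats_lncrna.tsv"))

  # 6. enrich: DE genes against sets built from the annotation (host genes
  # of planted pairs vs the rest), demonstrating the ORA stage on known
  # structure
  enr <- stage("enrich", {
    universe <- gene_ids
    paired_genes <- unique(if (!is.null(truth$pairs)) truth$pairs$gene_id else character(0))
    sets <- list(paired_host_or_partner = paired_genes,
                 unpaired = setdiff(universe, paired_genes))
    coll <- gene_set_collection(sets, universe)
    query <- de[[main]]$gene$feature_id[de[[main]]$gene$significant]
    ora(query, coll)
  })
  write_tsv(enr, file.path(cfg$outdir, "enrichment.tsv"))
  note("enrich", nrow(enr), "collection=planted-structure", "enrichment.tsv")

  # 7. qpcr
  qp <- stage("qpcr", {
    ct <- sim$ct
    targets <- setdiff(unique(ct$gene), "Ppib")
    do.call(rbind, lapply(targets, function(g) {
      r <- ddct(ct, g, reference_gene = "Ppib", case_group = cfg$case,
                control_group = cfg$control, stratum = main)
      data.frame(gene = r$gene, stratum = r$stratum, fold_change = r$fold_change,
                 sd_fold = r$sd_fold, p_anova = r$p_anova,
                 significant = r$significant, stringsAsFactors = FALSE)
    }))
  })
  write_tsv(qp, file.path(cfg$outdir, "qpcr.tsv"))
  note("qpcr", nrow(qp), "reference=Ppib", "qpcr.tsv")

  # 8. compare: SAM on the main-stratum matrix + harmonization of the two
  # strata's DE tables as pseudo-datasets
  cmp <- stage("compare", {
    cols <- samples$sample[samples$stratum == main]
    sam <- sam_test(mat[, cols], samples$group[match(cols, samples$sample)],
                    n_perm = cfg$n_perm, seed = cfg$sim$seed)
    tabs <- lapply(de, function(d) {
      rbind(d$lnc, d$gene)[, c("feature_id", "fc", "significant")] |>
        (\(x) data.frame(gene_id = x$feature_id, fc = x$fc,
                         significant = x$significant,
                         stringsAsFactors = FALSE))()
    })
    harm <- if (length(tabs) >= 2) harmonize(tabs) else NULL
    list(sam = sam, harm = harm)
  })
  write_tsv(cmp$sam, file.path(cfg$outdir, "sam.tsv"))
  if (!is.null(cmp$harm))
    write_tsv(cmp$harm, file.path(cfg$outdir, "harmonized.tsv"))
  note("compare", nrow(cmp$sam), sprintf("n_perm=%d", cfg$n_perm), "sam.tsv")

  manifest <- do.call(rbind, manifest)
  write_tsv(manifest, file.path(cfg$outdir, "manifest.tsv"))
  invisible(list(ann = ann, truth = truth, expr = sim$expr, ct = sim$ct,
                 de = de, classified = classified, pairs = pair_out$pairs,
                 concordance = pair_out$conc, proximal = pair_out$prox,
                 venn = pair_out$venn, rollup = pair_out$rollup,
                 chromstats = cs, enrichment = enr, qpcr = qp,
                 sam = cmp$sam, harmonized = cmp$harm, manifest = manifest))
}
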