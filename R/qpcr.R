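# Reference-gene-normalized relative quantification (2^-ddCt), group fold
# change with per-animal dispersion and a one-way ANOVA gate, plus the
# Ct-ratio expression banding used for cell-panel localization.

check_ct_table <- function(ct) {
  need <- c("sample", "group", "stratum", "gene", "replicate", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0) stop("Ct table missing column(s): ", paste(miss, collapse = ", "))
  invisible(ct)
}

# Mean Ct per sample after averaging technical replicates; undetected wells
# (NA ct) drop out, an all-undetected sample yields NA.
sample_mean_ct <- function(ct, gene_name) {
  d <- ct[ct$gene == gene_name, ]
  if (nrow(d) == 0) return(NULL)
  agg <- do.call(rbind, lapply(split(d, d$sample), function(x) {
    data.frame(sample = x$sample[1], group = x$group[1], stratum = x$stratum[1],
               mean_ct = if (all(is.na(x$ct))) NA_real_ else mean(x$ct, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg
}

#' Relative quantification by the 2^-ddCt method
#'
#' Technical triplicates are averaged per animal first; the animal is the
#' unit of replication. dCt = Ct_gene - Ct_reference per animal;
#' ddCt = mean dCt(case) - mean dCt(control); fold change = 2^-ddCt.
#' Dispersion is the SD of per-animal 2^-(dCt - mean dCt(control)) values
#' in the case group, and the significance gate is a one-way ANOVA on
#' per-animal dCt across the two groups (equivalent to the pooled t-test).
#'
#' @param ct Ct table (sample, group, stratum, gene, replicate, ct);
#'   undetected wells are NA.
#' @param gene target gene.
#' @param reference_gene reference (default "Ppib", cyclophilin B).
#' @param case_group,control_group group labels.
#' @param stratum stratum to analyze.
#' @param alpha significance level (default 0.05).
#' @return list(gene, stratum, fold_change, sd_fold, p_anova, significant,
#'   n_case, n_control); fold_change is NA when the gene is undetected in
#'   all animals of a group.
#' @export
ddct <- function(ct, gene, reference_gene = "Ppib", case_group, control_group,
                 stratum, alpha = 0.05) {
  check_ct_table(ct)
  ct <- ct[ct$stratum == stratum, ]
  if (nrow(ct) == 0) stop("stratum not present in Ct table: ", stratum)
  ref <- sample_mean_ct(ct, reference_gene)
  if (is.null(ref)) stop("reference gene absent: ", reference_gene)
  tgt <- sample_mean_ct(ct, gene)
  if (is.null(tgt)) stop("gene absent from Ct table: ", gene)
  if (any(is.na(ref$mean_ct)))
    stop("reference gene undetected in sample(s): ",
         paste(ref$sample[is.na(ref$mean_ct)], collapse = ", "))
  missing_ref <- setdiff(tgt$sample, ref$sample)
  if (length(missing_ref) > 0)
    stop("reference gene missing for sample(s): ", paste(missing_ref, collapse = ", "))
  m <- merge(tgt, ref[, c("sample", "mean_ct")], by = "sample",
             suffixes = c("", "_ref"))
  m$dct <- m$mean_ct - m$mean_ct_ref
  case <- m[m$group == case_group & !is.na(m$dct), ]
  ctrl <- m[m$group == control_group & !is.na(m$dct), ]
  if (nrow(case) == 0 && nrow(ctrl) == 0)
    return(list(gene = gene, stratum = stratum, fold_change = NA_real_,
                sd_fold = NA_real_, p_anova = NA_real_, significant = NA,
                n_case = 0, n_control = 0))
  if (nrow(case) < 2 || nrow(ctrl) < 2)
    stop("need >= 2 biological replicates per group with detected Ct")
  ddct_val <- mean(case$dct) - mean(ctrl$dct)
  fold <- 2^(-ddct_val)
  per_animal_fold <- 2^(-(case$dct - mean(ctrl$dct)))
  two <- rbind(case, ctrl)
  fit <- stats::lm(dct ~ group, data = two)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((two$dct - mean(two$dct))^2)
  if (ss_res <= 1e-12 * max(ss_tot, 1)) {
    # degenerate (noise-free) case: identical within-group dCt
    p <- if (abs(mean(case$dct) - mean(ctrl$dct)) > 0) 0 else 1
  } else {
    p <- stats::anova(fit)[["Pr(>F)"]][1]
  }
  list(gene = gene, stratum = stratum, fold_change = fold,
       sd_fold = sd(per_animal_fold), p_anova = p,
       significant = p < alpha, n_case = nrow(case), n_control = nrow(ctrl))
}

#' Ct-ratio expression banding for a cell sample
#'
#' ratio = mean Ct(gene) / mean Ct(reference) over the wells of one cell
#' sample. A low ratio (< 1.0) indicates high expression, a high ratio
#' (> 1.8) low expression, values between are intermediate; an undetected
#' gene yields no_expression.
#'
#' @param ct Ct table restricted by \code{cell_label} on the sample column.
#' @param gene target gene.
#' @param reference_gene reference gene.
#' @param cell_label sample label of the cell preparation.
#' @return list(ratio, band) with band one of high_expression,
#'   intermediate, low_expression, no_expression.
#' @export
ct_ratio_band <- function(ct, gene, reference_gene, cell_label) {
  check_ct_table(ct)
  d <- ct[ct$sample == cell_label, ]
  if (nrow(d) == 0) stop("cell sample absent: ", cell_label)
  ref_ct <- d$ct[d$gene == reference_gene]
  if (length(ref_ct) == 0 || all(is.na(ref_ct)))
    stop("reference gene undetected in cell sample ", cell_label)
  g_ct <- d$ct[d$gene == gene]
  if (length(g_ct) == 0) stop("gene absent in cell sample: ", gene)
  if (all(is.na(g_ct))) return(list(ratio = NA_real_, band = "no_expression"))
  ratio <- mean(g_ct, na.rm = TRUE) / mean(ref_ct, na.rm = TRUE)
  band <- if (ratio < 1.0) "high_expression"
          else if (ratio > 1.8) "low_expression"
          else "intermediate"
  list(ratio = ratio, band = band)
}
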