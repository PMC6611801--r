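# Per-chromosome density of differentially expressed features: the
# percentage of encoded features of a category that are DE, with the
# cross-chromosome mean and sample SD.

named_chrom_pattern <- "^(chr)?([0-9]+|[XY]|MT?)$"

is_named_chrom <- function(chrom) grepl(named_chrom_pattern, chrom)

#' Per-chromosome DE density for a feature category
#'
#' For each named chromosome (unplaced scaffolds are excluded) counts the
#' encoded features of the category, the significant ones among them, and
#' the percentage 100 * n_de / n_encoded; chromosomes encoding no feature
#' of the category are flagged and excluded from the cross-chromosome mean
#' and sample (n - 1) SD.
#'
#' @param ann annotation_set.
#' @param de_ids ids of significant features (must belong to the category).
#' @param category one of \code{coding}, \code{lncRNA_all},
#'   \code{lncRNA_intragenic}, \code{lncRNA_intergenic}.
#' @param classified classification table (required for the lncRNA
#'   subcategories; intragenic = sense + antisense, intergenic =
#'   neighbor + orphan, so the two subsets partition lncRNA_all).
#' @return list(per_chrom = data.frame(chrom, n_encoded, n_de, pct,
#'   defined), mean_pct, sd_pct).
#' @export
chrom_stats <- function(ann, de_ids,
                        category = c("coding", "lncRNA_all",
                                     "lncRNA_intragenic", "lncRNA_intergenic"),
                        classified = NULL) {
  category <- match.arg(category)
  if (category == "coding") {
    feats <- data.frame(id = ann$genes$gene_id, chrom = ann$genes$chrom,
                        stringsAsFactors = FALSE)
  } else {
    feats <- data.frame(id = ann$lncrnas$lnc_id, chrom = ann$lncrnas$chrom,
                        stringsAsFactors = FALSE)
    if (category != "lncRNA_all") {
      if (is.null(classified))
        stop("classified table required for category ", category)
      intragenic <- classified$lnc_id[classified$spatial_class %in%
                                        c("intragenic_sense", "intragenic_antisense")]
      keep <- if (category == "lncRNA_intragenic") intragenic
              else setdiff(classified$lnc_id, intragenic)
      feats <- feats[feats$id %in% keep, ]
    }
  }
  if (nrow(feats) == 0) stop("empty feature category: ", category)
  bad <- setdiff(de_ids, feats$id)
  if (length(bad) > 0)
    stop("de_ids outside the ", category, " category: ",
         paste(head(bad, 5), collapse = ", "))
  feats <- feats[is_named_chrom(feats$chrom), ]
  chroms <- sort(unique(feats$chrom))
  per <- do.call(rbind, lapply(chroms, function(ch) {
    n_enc <- sum(feats$chrom == ch)
    n_de <- sum(feats$chrom == ch & feats$id %in% de_ids)
    data.frame(chrom = ch, n_encoded = n_enc, n_de = n_de,
               pct = if (n_enc > 0) 100 * n_de / n_enc else NA_real_,
               defined = n_enc > 0, stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  pcts <- per$pct[per$defined]
  list(per_chrom = per,
       mean_pct = mean(pcts),
       sd_pct = if (length(pcts) > 1) sd(pcts) else NA_real_)
}
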