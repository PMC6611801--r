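# Positional taxonomy of lncRNAs relative to protein-coding genes.
#
# Classes:
#   intragenic_sense     overlap (>= 1 base) with a gene's transcriptional
#                        unit on the same strand
#   intragenic_antisense overlap on the opposite strand only
#   linc_neighbor        no overlap, nearest gene within the window (< 50 kb)
#   linc_orphan          no overlap, no gene within the window
#
# A lncRNA overlapping both same- and opposite-strand genes is labelled
# sense (single-label priority rule); all overlapping genes remain listed
# as partners. The neighbor window test is strict (<), so a gap of exactly
# window_bp is orphan. relative_position is expressed in the partner gene's
# frame: a lincRNA 3' of the gene's TES on the gene's strand is downstream.

classify_empty <- function() {
  data.frame(lnc_id = character(0), spatial_class = character(0),
             partner_gene_ids = character(0), gap_bp = numeric(0),
             relative_position = character(0), same_strand_as_partner = logical(0),
             proximal_flag = logical(0), stringsAsFactors = FALSE)
}

relative_position_of <- function(lnc_start0, lnc_end0, gene, gene_strand) {
  # position of the lincRNA in the partner gene's frame
  after <- lnc_start0 >= gene$end0    # lnc lies right of the gene
  before <- lnc_end0 <= gene$start0
  if (gene_strand == "+") {
    if (after) "downstream" else if (before) "upstream" else NA_character_
  } else {
    if (before) "downstream" else if (after) "upstream" else NA_character_
  }
}

#' Classify every lncRNA by position relative to protein-coding genes
#'
#' @param ann annotation_set.
#' @param window_bp neighbor window in bases (default 50000); a lincRNA
#'   whose gap to the nearest gene is strictly below the window is a
#'   \code{linc_neighbor}, otherwise \code{linc_orphan}.
#' @param proximal_bp strict threshold for the proximal flag (default 5000).
#' @return data.frame with one row per lncRNA: \code{lnc_id},
#'   \code{spatial_class}, \code{partner_gene_ids} (comma-separated; all
#'   overlapping genes for intragenic lncRNAs, all nearest in-window genes
#'   for neighbors, empty for orphans), \code{gap_bp} (0 for intragenic, NA
#'   for orphans), \code{relative_position} (neighbors only, in the partner
#'   gene's frame; ties use the first partner), \code{same_strand_as_partner}
#'   (neighbors only), \code{proximal_flag} (gap_bp < proximal_bp).
#' @export
classify_all <- function(ann, window_bp = 50000, proximal_bp = 5000) {
  stopifnot(is(ann, "annotation_set"))
  nl <- nrow(ann$lncrnas)
  if (nl == 0) return(classify_empty())
  idx <- build_interval_index(ann)
  genes <- ann$genes
  gene_by_id <- genes
  rownames(gene_by_id) <- genes$gene_id

  # one findOverlaps call for all lncRNAs at once
  ov <- GenomicRanges::findOverlaps(idx$lnc_gr, idx$genes_gr, minoverlap = 1L,
                                    ignore.strand = TRUE)
  ov_by_lnc <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))

  out <- vector("list", nl)
  for (i in seq_len(nl)) {
    lnc <- ann$lncrnas[i, ]
    hits <- ov_by_lnc[[as.character(i)]]
    if (!is.null(hits) && length(hits) > 0) {
      partner_strands <- genes$strand[hits]
      cls <- if (any(partner_strands == lnc$strand)) "intragenic_sense"
             else "intragenic_antisense"
      out[[i]] <- data.frame(
        lnc_id = lnc$lnc_id, spatial_class = cls,
        partner_gene_ids = paste(genes$gene_id[hits], collapse = ","),
        gap_bp = 0, relative_position = NA_character_,
        same_strand_as_partner = NA, proximal_flag = 0 < proximal_bp,
        stringsAsFactors = FALSE)
    } else {
      nn <- index_nearest(idx, lnc$chrom, lnc$start0, lnc$end0)
      if (length(nn$gene_ids) > 0 && nn$gap < window_bp) {
        partner1 <- gene_by_id[nn$gene_ids[1], ]
        out[[i]] <- data.frame(
          lnc_id = lnc$lnc_id, spatial_class = "linc_neighbor",
          partner_gene_ids = paste(nn$gene_ids, collapse = ","),
          gap_bp = nn$gap,
          relative_position = relative_position_of(lnc$start0, lnc$end0,
                                                   partner1, partner1$strand),
          same_strand_as_partner = partner1$strand == lnc$strand,
          proximal_flag = nn$gap < proximal_bp,
          stringsAsFactors = FALSE)
      } else {
        out[[i]] <- data.frame(
          lnc_id = lnc$lnc_id, spatial_class = "linc_orphan",
          partner_gene_ids = "", gap_bp = NA_real_,
          relative_position = NA_character_, same_strand_as_partner = NA,
          proximal_flag = NA, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify a single lncRNA against a prebuilt gene index
#'
#' @param lnc one-row data.frame with \code{lnc_id}, \code{chrom},
#'   \code{start0}, \code{end0}, \code{strand}.
#' @param index interval_index built over protein-coding genes.
#' @param window_bp,proximal_bp see \code{\link{classify_all}}.
#' @return one-row classification data.frame.
#' @export
classify_lncrna <- function(lnc, index, window_bp = 50000, proximal_bp = 5000) {
  ann <- annotation_set(index$genes,
                        data.frame(lnc_id = lnc$lnc_id, aliases = "",
                                   chrom = lnc$chrom, start0 = lnc$start0,
                                   end0 = lnc$end0, strand = lnc$strand,
                                   stringsAsFactors = FALSE))
  classify_all(ann, window_bp = window_bp, proximal_bp = proximal_bp)
}

#' Count DE intragenic lncRNAs per host gene
#'
#' For every protein-coding gene hosting at least one differentially
#' expressed intragenic lncRNA, counts the distinct DE lncRNAs overlapping
#' its transcriptional unit, split into sense and antisense, sorted by
#' total count descending. Genes hosting none are absent.
#'
#' @param classified output of \code{\link{classify_all}}.
#' @param de_lnc_ids character vector of DE lncRNA ids.
#' @return data.frame with gene_id, n_total, n_sense, n_antisense.
#' @export
host_gene_rollup <- function(classified, de_lnc_ids) {
  intr <- classified[classified$spatial_class %in%
                       c("intragenic_sense", "intragenic_antisense") &
                     classified$lnc_id %in% de_lnc_ids, ]
  if (nrow(intr) == 0)
    return(data.frame(gene_id = character(0), n_total = integer(0),
                      n_sense = integer(0), n_antisense = integer(0),
                      stringsAsFactors = FALSE))
  long <- do.call(rbind, lapply(seq_len(nrow(intr)), function(i) {
    data.frame(gene_id = strsplit(intr$partner_gene_ids[i], ",")[[1]],
               lnc_id = intr$lnc_id[i], sense = intr$spatial_class[i] == "intragenic_sense",
               stringsAsFactors = FALSE)
  }))
  long <- unique(long)
  agg <- do.call(rbind, lapply(split(long, long$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], n_total = nrow(d),
               n_sense = sum(d$sense), n_antisense = sum(!d$sense),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(-agg$n_total, agg$gene_id), ]
  rownames(agg) <- NULL
  agg
}
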