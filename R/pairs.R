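# Join differentially expressed lncRNAs to differentially expressed
# protein-coding genes by spatial relationship and tabulate the four
# regulation patterns (gene up/down x lncRNA up/down), plus the proximal
# lincRNA sub-analysis and Venn membership across strata.

pair_patterns <- c("gene_up_lnc_up", "gene_up_lnc_down",
                   "gene_down_lnc_down", "gene_down_lnc_up")

relation_of_class <- c(intragenic_sense = "sense",
                       intragenic_antisense = "antisense",
                       linc_neighbor = "neighbor")

#' Build DE lncRNA x DE gene pair records
#'
#' One record per (significant lncRNA, significant partner gene)
#' combination within a stratum: intragenic lncRNAs pair with every
#' overlapping DE gene, neighbor lincRNAs with their nearest in-window DE
#' partner(s); orphans produce no pairs. Pairing is many-to-many: a gene
#' hosting several DE lncRNAs yields several records.
#'
#' @param classified output of \code{\link{classify_all}}.
#' @param de_lnc,de_genes DE tables (from \code{\link{call_de}}) for
#'   lncRNAs and protein-coding genes in the same stratum.
#' @param stratum stratum label recorded on each pair.
#' @return data.frame of pair records: lnc_id, gene_id, relation, stratum,
#'   lnc_direction, gene_direction, pattern, gap_bp, same_strand,
#'   relative_position.
#' @export
build_pairs <- function(classified, de_lnc, de_genes, stratum) {
  for (tab in list(de_lnc, de_genes))
    if (!all(c("feature_id", "direction", "significant") %in% names(tab)))
      stop("DE tables need feature_id, direction, significant columns")
  sig_lnc <- de_lnc[de_lnc$significant, ]
  sig_gene <- de_genes[de_genes$significant, ]
  empty <- data.frame(lnc_id = character(0), gene_id = character(0),
                      relation = character(0), stratum = character(0),
                      lnc_direction = character(0), gene_direction = character(0),
                      pattern = character(0), gap_bp = numeric(0),
                      same_strand = logical(0), relative_position = character(0),
                      stringsAsFactors = FALSE)
  cl <- classified[classified$lnc_id %in% sig_lnc$feature_id &
                   classified$spatial_class != "linc_orphan", ]
  if (nrow(cl) == 0) return(empty)
  lnc_dir <- setNames(sig_lnc$direction, sig_lnc$feature_id)
  gene_dir <- setNames(sig_gene$direction, sig_gene$feature_id)
  recs <- list()
  for (i in seq_len(nrow(cl))) {
    partners <- strsplit(cl$partner_gene_ids[i], ",")[[1]]
    partners <- partners[partners %in% sig_gene$feature_id]
    if (length(partners) == 0) next
    ld <- lnc_dir[[cl$lnc_id[i]]]
    recs[[length(recs) + 1]] <- data.frame(
      lnc_id = cl$lnc_id[i], gene_id = partners,
      relation = unname(relation_of_class[cl$spatial_class[i]]),
      stratum = stratum, lnc_direction = ld,
      gene_direction = unname(gene_dir[partners]),
      pattern = paste0("gene_", unname(gene_dir[partners]), "_lnc_", ld),
      gap_bp = cl$gap_bp[i], same_strand = cl$same_strand_as_partner[i],
      relative_position = cl$relative_position[i], stringsAsFactors = FALSE)
  }
  if (length(recs) == 0) return(empty)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Tabulate regulation patterns of co-located DE pairs
#'
#' Counts pairs per (relation, stratum, pattern). All four patterns are
#' reported in every populated cell (zero-filled), alongside the pair total
#' n and the distinct-gene margin n_genes (a gene hosting several DE
#' lncRNAs contributes several pairs but one gene).
#'
#' @param pairs output of \code{\link{build_pairs}} (strata may be mixed).
#' @return long-format data.frame: relation, stratum, pattern, count, plus
#'   one \code{total} row per (relation, stratum) carrying n and n_genes.
#' @export
concordance_table <- function(pairs) {
  if (nrow(pairs) == 0)
    return(data.frame(relation = character(0), stratum = character(0),
                      pattern = character(0), count = integer(0),
                      n = integer(0), n_genes = integer(0),
                      stringsAsFactors = FALSE))
  cells <- split(pairs, list(pairs$relation, pairs$stratum), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(d) {
    cnt <- vapply(pair_patterns, function(p) sum(d$pattern == p), integer(1))
    data.frame(relation = d$relation[1], stratum = d$stratum[1],
               pattern = pair_patterns, count = unname(cnt),
               n = nrow(d), n_genes = length(unique(d$gene_id)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Proximal lincRNA-gene sub-analysis
#'
#' Over neighbor pairs with gap strictly below the threshold: the total
#' count, how many show the same regulation direction in lincRNA and gene,
#' how many lincRNAs lie downstream of the partner, and how many share its
#' strand.
#'
#' @param pairs output of \code{\link{build_pairs}}.
#' @param threshold_bp strict gap threshold (default 5000).
#' @return list(n_proximal, n_same_pattern, n_downstream, n_same_strand).
#' @export
proximal_analysis <- function(pairs, threshold_bp = 5000) {
  nb <- pairs[pairs$relation == "neighbor" & pairs$gap_bp < threshold_bp, ]
  list(n_proximal = nrow(nb),
       n_same_pattern = sum(nb$lnc_direction == nb$gene_direction),
       n_downstream = sum(nb$relative_position == "downstream", na.rm = TRUE),
       n_same_strand = sum(nb$same_strand, na.rm = TRUE))
}

#' Stratum membership of significant features (Venn regions)
#'
#' Maps each feature that is significant in at least one stratum to the set
#' of strata where it is significant, and counts features per Venn region.
#'
#' @param de_tables named list of DE tables, one per stratum.
#' @param feature_subset optional feature ids to restrict to (e.g. lncRNAs).
#' @return list(membership = data.frame(feature_id, strata), regions =
#'   data.frame(region, count) with region a comma-joined stratum set).
#' @export
venn_membership <- function(de_tables, feature_subset = NULL) {
  if (length(de_tables) < 2) stop("venn_membership needs >= 2 strata")
  if (is.null(names(de_tables)) || any(!nzchar(names(de_tables))))
    stop("de_tables must be named by stratum")
  sig <- lapply(de_tables, function(t) t$feature_id[t$significant])
  if (!is.null(feature_subset))
    sig <- lapply(sig, intersect, feature_subset)
  universe <- sort(unique(unlist(sig)))
  strata <- names(de_tables)
  if (length(universe) == 0)
    return(list(membership = data.frame(feature_id = character(0),
                                        strata = character(0),
                                        stringsAsFactors = FALSE),
                regions = data.frame(region = character(0), count = integer(0),
                                     stringsAsFactors = FALSE)))
  member <- vapply(sig, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, strata))
  region_of <- apply(member, 1, function(r) paste(strata[r], collapse = ","))
  membership <- data.frame(feature_id = universe, strata = unname(region_of),
                           stringsAsFactors = FALSE)
  tab <- table(region_of)
  regions <- data.frame(region = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  list(membership = membership, regions = regions)
}
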