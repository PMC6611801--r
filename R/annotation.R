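#' @importFrom methods is
#' @importFrom stats var sd median quantile rnorm runif setNames complete.cases
#' @importFrom utils read.delim write.table head combn
NULL

# Internal coordinate convention: 0-based, half-open [start0, end0).
# GTF/GFF are 1-based closed; conversion happens only at the I/O boundary.

valid_strands <- c("+", "-")

check_intervals <- function(df, id_col) {
  stopifnot(is.data.frame(df))
  need <- c(id_col, "chrom", "start0", "end0", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("annotation table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(invisible(df))
  if (anyDuplicated(df[[id_col]]))
    stop("duplicate ", id_col, ": ",
         paste(unique(df[[id_col]][duplicated(df[[id_col]])]), collapse = ", "))
  if (any(!nzchar(df$chrom))) stop("empty chromosome name")
  if (any(df$start0 < 0)) stop("negative start coordinate")
  if (any(df$end0 <= df$start0)) stop("interval with end <= start")
  bad <- !df$strand %in% valid_strands
  if (any(bad)) stop("invalid strand token(s): ", paste(unique(df$strand[bad]), collapse = ", "))
  invisible(df)
}

#' Construct a validated annotation set
#'
#' Bundles protein-coding gene models and lncRNA gene models under a single
#' internal coordinate convention (0-based, half-open intervals) and checks
#' the structural invariants: unique ids, valid intervals, strands restricted
#' to \code{+}/\code{-}, and (when chromosome sizes are supplied) every
#' feature contained in a known chromosome.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{symbol},
#'   \code{chrom}, \code{start0}, \code{end0}, \code{strand}. The coordinates
#'   delimit the gene's transcriptional unit (TSS-most to TES-most position,
#'   introns included).
#' @param lncrnas data.frame with columns \code{lnc_id}, \code{aliases}
#'   (comma-separated alternative ids, may be empty), \code{chrom},
#'   \code{start0}, \code{end0}, \code{strand}.
#' @param chrom_sizes optional named integer vector of chromosome lengths.
#' @return An object of class \code{annotation_set}: a list with elements
#'   \code{genes}, \code{lncrnas}, \code{chrom_sizes}.
#' @export
annotation_set <- function(genes, lncrnas, chrom_sizes = NULL) {
  if (!"symbol" %in% names(genes) && nrow(genes) > 0) genes$symbol <- genes$gene_id
  if (nrow(genes) == 0 && !"symbol" %in% names(genes)) genes$symbol <- character(0)
  if (!"aliases" %in% names(lncrnas)) lncrnas$aliases <- rep("", nrow(lncrnas))
  genes$biotype <- rep("protein_coding", nrow(genes))
  lncrnas$biotype <- rep("lncRNA", nrow(lncrnas))
  check_intervals(genes, "gene_id")
  check_intervals(lncrnas, "lnc_id")
  alias_tokens <- unlist(strsplit(lncrnas$aliases[nzchar(lncrnas$aliases)], ","))
  clash <- intersect(alias_tokens, genes$gene_id)
  if (length(clash) > 0)
    stop("lncRNA aliases collide with gene ids: ", paste(clash, collapse = ", "))
  if (!is.null(chrom_sizes)) {
    chroms <- unique(c(genes$chrom, lncrnas$chrom))
    unknown <- setdiff(chroms, names(chrom_sizes))
    if (length(unknown) > 0)
      stop("chromosome(s) absent from chrom_sizes: ", paste(unknown, collapse = ", "))
    over_g <- genes$end0 > chrom_sizes[genes$chrom]
    over_l <- lncrnas$end0 > chrom_sizes[lncrnas$chrom]
    if (any(over_g) || any(over_l)) stop("feature extends beyond chromosome length")
  }
  structure(list(genes = genes, lncrnas = lncrnas, chrom_sizes = chrom_sizes),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$genes), "protein-coding genes,",
      nrow(x$lncrnas), "lncRNAs on",
      length(unique(c(x$genes$chrom, x$lncrnas$chrom))), "chromosome(s)\n")
  invisible(x)
}

#' Read gene-level annotation from a GTF file
#'
#' Reads a standard 9-column GTF (1-based, closed intervals), collapses all
#' rows sharing a \code{gene_id} to the union span of their coordinates (the
#' transcriptional unit), converts to the internal 0-based half-open
#' convention, and splits features into protein-coding genes and lncRNAs by
#' the \code{gene_biotype} attribute. Features whose biotype is not in
#' \code{biotype_filter} (e.g. rRNA, snRNA, piRNA) are dropped.
#'
#' @param path GTF file path.
#' @param biotype_filter character vector of biotypes to retain.
#' @return An \code{annotation_set}.
#' @export
read_annotation_gtf <- function(path, biotype_filter = c("protein_coding", "lncRNA")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  body <- !startsWith(raw, "#") & nzchar(raw)
  nf <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nf < 9)) {
    lineno <- which(body)[which(nf < 9)[1]]
    stop("malformed GTF line ", lineno, ": expected 9 tab-separated fields, got ",
         nf[which(nf < 9)[1]])
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id)) stop("GTF lacks gene_id attributes")
  biotype <- if (!is.null(md$gene_biotype)) md$gene_biotype else md$gene_type
  if (is.null(biotype)) stop("GTF lacks gene_biotype/gene_type attributes")
  keep <- biotype %in% biotype_filter
  gr <- gr[keep]
  biotype <- biotype[keep]
  md <- S4Vectors::mcols(gr)
  df <- data.frame(
    gene_id = md$gene_id,
    symbol  = if (!is.null(md$gene_name)) md$gene_name else md$gene_id,
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    start0  = GenomicRanges::start(gr) - 1L,  # 1-based closed -> 0-based half-open
    end0    = GenomicRanges::end(gr),
    strand  = as.character(GenomicRanges::strand(gr)),
    biotype = biotype,
    stringsAsFactors = FALSE
  )
  collapse_one <- function(d) {
    if (length(unique(d$chrom)) > 1 || length(unique(d$strand)) > 1)
      stop("gene_id ", d$gene_id[1], " has rows with conflicting chrom/strand")
    data.frame(gene_id = d$gene_id[1], symbol = d$symbol[1], chrom = d$chrom[1],
               start0 = min(d$start0), end0 = max(d$end0), strand = d$strand[1],
               biotype = d$biotype[1], stringsAsFactors = FALSE)
  }
  collapsed <- do.call(rbind, lapply(split(df, df$gene_id), collapse_one))
  rownames(collapsed) <- NULL
  genes <- collapsed[collapsed$biotype == "protein_coding",
                     c("gene_id", "symbol", "chrom", "start0", "end0", "strand")]
  lnc <- collapsed[collapsed$biotype != "protein_coding", ]
  lncrnas <- data.frame(lnc_id = lnc$gene_id, aliases = rep("", nrow(lnc)),
                        chrom = lnc$chrom, start0 = lnc$start0, end0 = lnc$end0,
                        strand = lnc$strand, stringsAsFactors = FALSE)
  rownames(genes) <- rownames(lncrnas) <- NULL
  annotation_set(genes, lncrnas)
}

#' Read annotation from the flat TSV dialect
#'
#' Columns: \code{id}, \code{symbol}, \code{chrom}, \code{start0},
#' \code{end0}, \code{strand}, \code{biotype} (and optionally
#' \code{aliases}). Coordinates are already 0-based half-open.
#'
#' @param path TSV path.
#' @return An \code{annotation_set}.
#' @export
read_annotation_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "symbol", "chrom", "start0", "end0", "strand", "biotype")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("annotation TSV missing column(s): ", paste(miss, collapse = ", "))
  if (!"aliases" %in% names(df)) df$aliases <- ""
  df$aliases[is.na(df$aliases)] <- ""
  g <- df[df$biotype == "protein_coding", ]
  l <- df[df$biotype == "lncRNA", ]
  genes <- data.frame(gene_id = g$id, symbol = g$symbol, chrom = g$chrom,
                      start0 = g$start0, end0 = g$end0, strand = g$strand,
                      stringsAsFactors = FALSE)
  lncrnas <- data.frame(lnc_id = l$id, aliases = l$aliases, chrom = l$chrom,
                        start0 = l$start0, end0 = l$end0, strand = l$strand,
                        stringsAsFactors = FALSE)
  annotation_set(genes, lncrnas)
}

#' Write an annotation set as the flat TSV dialect
#' @param ann annotation_set.
#' @param path output path.
#' @export
write_annotation_tsv <- function(ann, path) {
  stopifnot(is(ann, "annotation_set"))
  g <- ann$genes
  l <- ann$lncrnas
  out <- rbind(
    data.frame(id = g$gene_id, symbol = g$symbol, chrom = g$chrom,
               start0 = g$start0, end0 = g$end0, strand = g$strand,
               biotype = "protein_coding", aliases = "", stringsAsFactors = FALSE),
    data.frame(id = l$lnc_id, symbol = l$lnc_id, chrom = l$chrom,
               start0 = l$start0, end0 = l$end0, strand = l$strand,
               biotype = "lncRNA", aliases = l$aliases, stringsAsFactors = FALSE)
  )
  write_tsv(out, path)
  invisible(path)
}

#' Export features as BED6
#'
#' BED is 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged. Score is 0, name is the feature id.
#'
#' @param features data.frame with id, chrom, start0, end0, strand columns
#'   (gene or lncRNA table of an annotation_set, or any subset).
#' @param path output path.
#' @export
write_bed6 <- function(features, path) {
  id_col <- intersect(c("id", "gene_id", "lnc_id"), names(features))[1]
  if (is.na(id_col)) stop("no id column found")
  bed <- data.frame(features$chrom, features$start0, features$end0,
                    features[[id_col]], 0L, features$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#' @param path TSV with chromosome name and length.
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.integer(df[[2]]), df[[1]])
}

# Vectorized gap under the half-open convention: 0 when overlapping or
# book-ended, else number of bases strictly between the intervals.
gap0 <- function(s1, e1, s2, e2) pmax(s2 - e1, s1 - e2, 0)

overlaps0 <- function(s1, e1, s2, e2) (s1 < e2) & (s2 < e1)

#' Gap distance between two genomic intervals
#'
#' Both intervals are 0-based half-open and must lie on the same chromosome.
#' Overlapping intervals (at least one shared base) report distance 0 with
#' \code{overlap = TRUE}; book-ended intervals report gap 0 without overlap;
#' otherwise the number of bases strictly between the two intervals.
#'
#' @param a,b lists or one-row data.frames with \code{chrom}, \code{start0},
#'   \code{end0}.
#' @return list with elements \code{gap} (non-negative integer) and
#'   \code{overlap} (logical).
#' @export
gap_distance <- function(a, b) {
  if (a$chrom != b$chrom) stop("gap_distance: intervals on different chromosomes")
  list(gap = unname(gap0(a$start0, a$end0, b$start0, b$end0)),
       overlap = unname(overlaps0(a$start0, a$end0, b$start0, b$end0)))
}

features_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start0 + 1L, end = df$end0),
    strand = df$strand
  )
}

#' Build an interval index over an annotation set
#'
#' Wraps the gene and lncRNA tables in GRanges objects so that overlap and
#' nearest-by-gap queries run through interval trees rather than linear
#' scans. Query results are defined to equal a brute-force scan (this is
#' exercised against one in the test suite).
#'
#' @param ann annotation_set.
#' @return object of class \code{interval_index}.
#' @export
build_interval_index <- function(ann) {
  stopifnot(is(ann, "annotation_set"))
  structure(list(
    genes_gr = features_to_granges(ann$genes),
    gene_ids = ann$genes$gene_id,
    genes = ann$genes,
    lnc_gr = features_to_granges(ann$lncrnas),
    lnc_ids = ann$lncrnas$lnc_id
  ), class = "interval_index")
}

#' Overlap query against the gene index
#'
#' @param index interval_index.
#' @param chrom,start0,end0 query interval (0-based half-open).
#' @return character vector of gene_ids overlapping the query by >= 1 base
#'   (strand-blind). Empty when the chromosome is absent.
#' @export
index_overlaps <- function(index, chrom, start0, end0) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  # a query chromosome absent from the index is a legal empty result
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, index$genes_gr, minoverlap = 1L,
                                ignore.strand = TRUE))
  index$gene_ids[S4Vectors::subjectHits(hits)]
}

#' Nearest-gene query by gap distance
#'
#' @param index interval_index.
#' @param chrom,start0,end0 query interval.
#' @return list(gene_ids, gap): all genes attaining the minimum gap (ties
#'   kept), or zero-length ids with gap NA when the chromosome has no genes.
#' @export
index_nearest <- function(index, chrom, start0, end0) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  dtn <- suppressWarnings(
    GenomicRanges::distanceToNearest(q, index$genes_gr, ignore.strand = TRUE))
  if (length(dtn) == 0) return(list(gene_ids = character(0), gap = NA_real_))
  mn <- S4Vectors::mcols(dtn)$distance
  # enumerate ties: all genes within mn of the query, keep those at exactly mn
  cand <- suppressWarnings(
    GenomicRanges::findOverlaps(q, index$genes_gr, maxgap = mn,
                                minoverlap = 0L, ignore.strand = TRUE))
  ci <- S4Vectors::subjectHits(cand)
  g <- index$genes[ci, ]
  gaps <- gap0(start0, end0, g$start0, g$end0)
  list(gene_ids = g$gene_id[gaps == mn], gap = unname(mn))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)
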