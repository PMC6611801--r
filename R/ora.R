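# Hypergeometric over-representation of a query gene list against
# user-supplied gene-set collections (GMT), BH-corrected across sets.

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, fields name, description, then members,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Build a gene-set collection restricted to a universe
#'
#' @param sets named list of gene-id vectors.
#' @param universe background gene ids; set members outside it are dropped.
#' @return list of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  universe <- unique(universe)
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' For each set, p = P[X >= k] with X ~ hypergeometric(N, K, n): N universe
#' size, K set size within the universe, n query size, k overlap.
#' One-sided (enrichment only); BH adjustment across all sets of the
#' collection. Query ids outside the universe are dropped (the count is
#' reported as an attribute).
#'
#' @param query character vector of gene ids.
#' @param collection gene_set_collection.
#' @return data.frame sorted by q then decreasing k: set_name, k, n_query,
#'   K, N, p, q, member_ids (comma-joined overlap).
#' @export
ora <- function(query, collection) {
  stopifnot(is(collection, "gene_set_collection"))
  query <- unique(query)
  if (length(query) == 0) stop("empty query")
  n_dropped <- sum(!query %in% collection$universe)
  query <- intersect(query, collection$universe)
  if (length(query) == 0) stop("no query ids inside the universe")
  N <- length(collection$universe)
  n <- length(query)
  res <- do.call(rbind, lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    hit <- intersect(query, set)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, n_query = n, K = K, N = N, p = p,
               member_ids = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  res$q <- bh_adjust(res$p)
  res <- res[order(res$q, -res$k, res$set_name),
             c("set_name", "k", "n_query", "K", "N", "p", "q", "member_ids")]
  rownames(res) <- NULL
  attr(res, "n_query_dropped") <- n_dropped
  res
}
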