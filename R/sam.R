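# SAM-style permutation differential expression (Tusher d-statistic with a
# variance fudge factor s0 and permutation q-values) and cross-dataset
# harmonization of DE tables by stable gene id.

sam_d_components <- function(mat, groups, g1, g2) {
  i1 <- which(groups == g1)
  i2 <- which(groups == g2)
  n1 <- length(i1); n2 <- length(i2)
  x1 <- mat[, i1, drop = FALSE]
  x2 <- mat[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  # Tusher gene-specific scatter: pooled SD of the mean difference
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  list(diff = m1 - m2, s = s)
}

# Tusher grid search: among the percentiles of s, pick the s0 minimizing
# the coefficient of variation of the windowed MAD of d across s windows.
choose_s0 <- function(diff, s) {
  cand <- unique(quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE))
  qs <- quantile(s, probs = seq(0, 1, by = 0.01), names = FALSE)
  win <- cut(s, breaks = unique(qs), include.lowest = TRUE)
  cv_of <- function(s0) {
    d <- diff / (s + s0)
    mads <- tapply(d, win, stats::mad)
    mads <- mads[!is.na(mads) & mads > 0]
    if (length(mads) < 2) return(Inf)
    sd(mads) / mean(mads)
  }
  cvs <- vapply(cand, cv_of, numeric(1))
  cand[which.min(cvs)]
}

permute_labels <- function(groups, g1, n_perm, seed) {
  n <- length(groups)
  n1 <- sum(groups == g1)
  all_comb <- choose(n, n1)
  if (all_comb <= n_perm) {
    idx <- combn(n, n1, simplify = FALSE)
  } else {
    set.seed(seed)
    idx <- replicate(n_perm, sort(sample.int(n, n1)), simplify = FALSE)
  }
  idx
}

#' SAM permutation test for a two-group contrast
#'
#' d_i = (mean1 - mean2) / (s_i + s0), with s_i the pooled standard error
#' of the mean difference. s0 = "auto" runs the grid search over
#' percentiles of s_i minimizing the coefficient of variation of windowed
#' median absolute deviations of d. q-values follow the original SAM FDR:
#' for each observed |d| as threshold, the median number of permutation
#' |d*| values at or above it divided by the observed call count, then
#' monotonized so that q never decreases as |d| decreases. When fewer
#' distinct label permutations exist than requested, the exhaustive set is
#' used (with a message).
#'
#' @param mat features x samples matrix (rownames required).
#' @param groups group label per column (exactly two distinct labels).
#' @param n_perm maximum number of permutations (default 1000).
#' @param seed RNG seed for permutation sampling.
#' @param s0 "auto" or a fixed non-negative value; s0 = 0 reduces d to the
#'   ordinary pooled two-sample t statistic.
#' @return data.frame: feature_id, d, s, s0, q, direction.
#' @export
sam_test <- function(mat, groups, n_perm = 1000, seed = 1, s0 = "auto") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)),
            length(groups) == ncol(mat))
  labs <- unique(groups)
  if (length(labs) != 2) stop("sam_test needs exactly two groups")
  if (min(table(groups)) < 2) stop("need >= 2 samples per group")
  g1 <- labs[1]; g2 <- labs[2]
  obs <- sam_d_components(mat, groups, g1, g2)
  s0_val <- if (identical(s0, "auto")) choose_s0(obs$diff, obs$s) else {
    stopifnot(is.numeric(s0), s0 >= 0)
    s0
  }
  d_obs <- obs$diff / (obs$s + s0_val)
  perms <- permute_labels(groups, g1, n_perm, seed)
  if (length(perms) < n_perm)
    message("sam_test: only ", length(perms),
            " distinct permutations exist; using the exhaustive set")
  abs_obs <- abs(d_obs)
  ord <- order(abs_obs, decreasing = TRUE)
  thresholds <- abs_obs[ord]
  n_feat <- length(d_obs)
  exceed <- matrix(0L, nrow = length(perms), ncol = n_feat)
  for (b in seq_along(perms)) {
    gp <- rep(g2, length(groups))
    gp[perms[[b]]] <- g1
    pb <- sam_d_components(mat, gp, g1, g2)
    d_p <- sort(abs(pb$diff / (pb$s + s0_val)), decreasing = TRUE)
    # count of permutation |d*| >= t  ==  #{-|d*| <= -t}, -d_p is increasing
    exceed[b, ] <- findInterval(-thresholds, -d_p)
  }
  med_false <- apply(exceed, 2, median)
  called <- seq_len(n_feat)
  fdr <- pmin(1, med_false / called)
  # monotonize: q non-increasing in |d|
  q_sorted <- rev(cummin(rev(fdr)))
  q <- numeric(n_feat)
  q[ord] <- q_sorted
  data.frame(feature_id = rownames(mat), d = unname(d_obs), s = unname(obs$s),
             s0 = s0_val, q = q,
             direction = ifelse(d_obs > 0, "up", ifelse(d_obs < 0, "down", "none")),
             stringsAsFactors = FALSE)
}

#' Harmonize DE tables across studies by stable gene id
#'
#' Joins per-study DE tables on gene_id. Duplicate ids within a study keep
#' the entry with the largest |log2 fold change| (with a warning). A
#' feature is retained when present in at least \code{min_datasets}
#' studies; per-feature agreement is TRUE when all significant entries
#' share one direction (NA when fewer than two studies call it
#' significant).
#'
#' @param datasets named list of data.frames with columns gene_id, fc
#'   (linear fold change), significant.
#' @param join "inner" (present in all studies) or "outer" (present in
#'   >= min_datasets).
#' @param min_datasets minimum number of studies a feature must appear in
#'   (default 2).
#' @return data.frame with gene_id, per-study fc_<name> and sig_<name>
#'   columns, n_present, n_significant, agreement.
#' @export
harmonize <- function(datasets, join = c("outer", "inner"), min_datasets = 2) {
  join <- match.arg(join)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    stop("datasets must be a named list")
  nms <- names(datasets)
  datasets <- lapply(nms, function(nm) {
    d <- datasets[[nm]]
    if (!all(c("gene_id", "fc", "significant") %in% names(d)))
      stop("dataset ", nm, " needs gene_id, fc, significant columns")
    if (anyDuplicated(d$gene_id)) {
      warning("dataset ", nm, ": duplicate gene_id entries; keeping the ",
              "largest |log2 fold change| per gene")
      d <- d[order(-abs(log2(d$fc))), ]
      d <- d[!duplicated(d$gene_id), ]
    }
    d
  })
  names(datasets) <- nms
  all_ids <- sort(unique(unlist(lapply(datasets, `[[`, "gene_id"))))
  out <- data.frame(gene_id = all_ids, stringsAsFactors = FALSE)
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    m <- match(all_ids, d$gene_id)
    out[[paste0("fc_", nms[i])]] <- d$fc[m]
    out[[paste0("sig_", nms[i])]] <- d$significant[m]
  }
  fc_cols <- paste0("fc_", nms)
  sig_cols <- paste0("sig_", nms)
  out$n_present <- rowSums(!is.na(as.matrix(out[fc_cols])))
  out$n_significant <- rowSums(as.matrix(out[sig_cols]) == TRUE, na.rm = TRUE)
  dirs <- as.matrix(out[fc_cols]) > 1
  sigm <- as.matrix(out[sig_cols]) == TRUE
  out$agreement <- vapply(seq_len(nrow(out)), function(i) {
    dd <- dirs[i, sigm[i, ] %in% TRUE]
    if (length(dd) < 2) NA else length(unique(dd)) == 1
  }, logical(1))
  keep <- if (join == "inner") out$n_present == length(datasets)
          else out$n_present >= min_datasets
  out <- out[keep, ]
  rownames(out) <- NULL
  out
}
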