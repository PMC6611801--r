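# Empirical-Bayes moderated two-group contrasts on log2 expression,
# Smyth-style method-of-moments hyperparameter estimation, and the joint
# fold-change / FDR significance rule used throughout the pipeline.

# Newton solve of trigamma(y) = x, vectorized; used by the moment estimator.
trigamma_inverse <- function(x) {
  stopifnot(all(x > 0 | is.na(x)))
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y), na.rm = TRUE) < 1e-10) break
  }
  y
}

#' Fit the empirical-Bayes variance prior
#'
#' Estimates the hyperparameters (d0, s0^2) of a scaled inverse-chi-squared
#' prior on per-feature residual variances by the method of moments on log
#' variances: with e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2), the mean
#' of e_g locates s0^2 and the excess of var(e_g) over trigamma(d_g/2)
#' determines d0. When the empirical excess is <= 0 the prior degrees of
#' freedom are unbounded (d0 = Inf) and s0^2 is the pooled mean variance.
#'
#' @param s2_values per-feature residual variances of log2 expression.
#'   Non-positive values are excluded (a warning reports how many).
#' @param d_g residual degrees of freedom shared by all features.
#' @return list of class \code{ebayes_prior} with \code{d0}, \code{s0_sq},
#'   and \code{n_used}.
#' @export
fit_ebayes_prior <- function(s2_values, d_g) {
  usable <- s2_values[!is.na(s2_values) & s2_values > 0]
  n_dropped <- length(s2_values) - length(usable)
  if (n_dropped > 0)
    warning(n_dropped, " zero/negative-variance feature(s) excluded from prior fitting")
  if (length(usable) < 10)
    stop("fit_ebayes_prior: need at least 10 features with positive variance, have ",
         length(usable))
  e <- log(usable) - digamma(d_g / 2) + log(d_g / 2)
  n <- length(e)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (n - 1)
  excess <- evar - trigamma(d_g / 2)
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond chi^2 sampling noise: unbounded prior df; the
    # pooled mean variance is then the natural location estimate
    d0 <- Inf
    s0_sq <- mean(usable)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = n), class = "ebayes_prior")
}

#' Moderated t-statistic for a two-group contrast
#'
#' Shrinks each feature's residual variance toward the prior:
#' s2_post = (d0 * s0^2 + d_g * s2) / (d0 + d_g), then
#' t = (mean1 - mean2) / sqrt(s2_post * (1/n1 + 1/n2)) with two-sided
#' p-values on d0 + d_g degrees of freedom. With d0 = 0 this is the
#' ordinary pooled two-sample t; with d0 = Inf every feature is tested
#' against s0^2. For a two-group design this coincides with the per-contrast
#' moderated ANOVA used for expression arrays.
#'
#' @param mean1,mean2 per-feature group means of log2 expression (case, control).
#' @param n1,n2 group sizes (>= 2).
#' @param s2 per-feature pooled residual variances.
#' @param d_g residual degrees of freedom (n1 + n2 - 2 for the pooled design).
#' @param prior an \code{ebayes_prior}.
#' @return list with vectors \code{t_mod}, \code{p}, and scalar \code{df_total}.
#' @export
moderated_t <- function(mean1, mean2, n1, n2, s2, d_g, prior) {
  stopifnot(n1 >= 2, n2 >= 2)
  d0 <- prior$d0
  s0_sq <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else (d0 * s0_sq + d_g * s2) / (d0 + d_g)
  if (any(s2_post == 0)) stop("moderated_t: degenerate posterior variance (0)")
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- unname((mean1 - mean2) / se)
  df_total <- d0 + d_g
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  list(t_mod = t_mod, p = p, df_total = df_total)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; input order is preserved and values are clipped
#' to 1.
#'
#' @param p_values numeric vector in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Two-group moderated differential expression with the joint significance rule
#'
#' For one stratum (e.g. one age group) computes, per feature, the case vs
#' control log2 fold change, linear fold change fc = 2^log2fc, a moderated
#' t-statistic with empirical-Bayes variance shrinkage, BH-adjusted q-values,
#' and the joint significance call: a feature is significant iff
#' (fc > fc_high or fc < fc_low) and q < fdr.
#'
#' @param mat numeric matrix of log2 intensities, rows = features
#'   (rownames required), columns = samples.
#' @param samples data.frame with columns \code{sample}, \code{group},
#'   \code{stratum}; \code{sample} values must match \code{colnames(mat)}.
#' @param stratum stratum label to analyze.
#' @param case,control group labels.
#' @param fc_high,fc_low,fdr thresholds of the joint rule
#'   (defaults 2.0, 0.5, 0.05).
#' @return data.frame with columns feature_id, log2fc, fc, s2, t_mod, p, q,
#'   direction, significant.
#' @export
call_de <- function(mat, samples, stratum, case, control,
                    fc_high = 2.0, fc_low = 0.5, fdr = 0.05) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (!all(c("sample", "group", "stratum") %in% names(samples)))
    stop("sample sheet needs columns sample, group, stratum")
  sub <- samples[samples$stratum == stratum, ]
  if (nrow(sub) == 0) stop("unknown stratum: ", stratum)
  if (!all(c(case, control) %in% sub$group))
    stop("unknown group label(s) for stratum ", stratum)
  case_cols <- sub$sample[sub$group == case]
  ctrl_cols <- sub$sample[sub$group == control]
  if (length(case_cols) < 2 || length(ctrl_cols) < 2)
    stop("need >= 2 replicates per group")
  missing_cols <- setdiff(c(case_cols, ctrl_cols), colnames(mat))
  if (length(missing_cols) > 0)
    stop("samples absent from matrix: ", paste(missing_cols, collapse = ", "))
  x1 <- mat[, case_cols, drop = FALSE]
  x2 <- mat[, ctrl_cols, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  d_g <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d_g
  prior <- suppressWarnings(fit_ebayes_prior(s2, d_g))
  mt <- moderated_t(m1, m2, n1, n2, s2, d_g, prior)
  q <- bh_adjust(mt$p)
  log2fc <- m1 - m2
  fc <- 2^log2fc
  data.frame(
    feature_id = rownames(mat),
    log2fc = unname(log2fc),
    fc = unname(fc),
    s2 = unname(s2),
    t_mod = unname(mt$t_mod),
    p = unname(mt$p),
    q = unname(q),
    direction = ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none")),
    significant = unname((fc > fc_high | fc < fc_low) & q < fdr),
    stringsAsFactors = FALSE
  )
}
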