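#' Per-gene log fold change (tumor minus normal)
#'
#' @param em An [expression_matrix()] on the log2 scale.
#' @return Named numeric vector: mean(tumor) - mean(normal) per gene, in
#'   log2 units.
#' @export
log_fold_change <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  tum <- em$groups == "tumor"
  nrm <- em$groups == "normal"
  if (!any(tum) || !any(nrm))
    stop("both 'tumor' and 'normal' samples are required")
  rowMeans(em$values[, tum, drop = FALSE]) -
    rowMeans(em$values[, nrm, drop = FALSE])
}

de_table <- function(gene_id, lfc, t_stat, df, p, stat) {
  out <- data.frame(gene_id = gene_id, lfc = lfc, t = t_stat, df = df,
                    p = p, q = NA_real_,
                    upregulated = lfc > 0 & p < 0.05,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "stat") <- stat
  class(out) <- c("de_result", "data.frame")
  out
}

group_stats <- function(em) {
  tum <- em$groups == "tumor"
  nrm <- em$groups == "normal"
  n1 <- sum(tum); n2 <- sum(nrm)
  if (n1 < 2L || n2 < 2L)
    stop("need at least 2 samples per group (variance undefined otherwise)")
  xt <- em$values[, tum, drop = FALSE]
  xn <- em$values[, nrm, drop = FALSE]
  v1 <- apply(xt, 1, stats::var)
  v2 <- apply(xn, 1, stats::var)
  list(
    lfc = rowMeans(xt) - rowMeans(xn),
    s2 = ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2),
    n1 = n1, n2 = n2, df = n1 + n2 - 2
  )
}

#' Ordinary two-group pooled-variance t-test per gene
#'
#' Equivalent to a one-way ANOVA with two groups (F = t^2). Genes with
#' zero pooled variance carry no information and are assigned t = 0,
#' p = 1 rather than being dropped.
#'
#' @param em An [expression_matrix()] with >= 2 samples per group.
#' @return A `de_result` data frame with columns `gene_id`, `lfc`, `t`,
#'   `df`, `p`, `q` (NA until [bh_adjust()] is applied) and
#'   `upregulated` (lfc > 0 and unadjusted p < 0.05).
#' @export
ordinary_t <- function(em) {
  gs <- group_stats(em)
  se <- sqrt(gs$s2 * (1 / gs$n1 + 1 / gs$n2))
  t_stat <- ifelse(se > 0, gs$lfc / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t_stat), gs$df), 1)
  de_table(rownames(em$values), gs$lfc, t_stat, rep(gs$df, length(se)), p,
           "ordinary")
}

# Inverse of trigamma by Newton iteration (monotone decreasing target).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Estimate empirical-Bayes variance moderation parameters
#'
#' Method-of-moments fit on the log sample variances. Under the usual
#' hierarchical model (residual variances scaled inverse chi-square with
#' d0 degrees of freedom and scale s0^2), `log(s_g^2)` has mean
#' `log(s0^2) + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)` and
#' variance `trigamma(d/2) + trigamma(d0/2)`; both moments are matched.
#' When the observed spread of log variances is no larger than the
#' sampling component `trigamma(d/2)`, d0 is effectively infinite and is
#' capped at 1e6.
#'
#' @param s2 Per-gene pooled sample variances (zeros are dropped for the
#'   fit).
#' @param df Residual degrees of freedom of each `s2` (scalar).
#' @return List with `d0` (prior degrees of freedom) and `s0_sq` (prior
#'   variance).
#' @export
estimate_moderation <- function(s2, df) {
  z <- log(s2[s2 > 0])
  if (length(z) < 2L) stop("need at least two positive variances to fit")
  evar <- stats::var(z) - trigamma(df / 2)
  if (evar > 1e-10) {
    d0 <- 2 * trigamma_inverse(evar)
    if (d0 > 1e6) d0 <- 1e6
  } else {
    d0 <- 1e6
  }
  s0_sq <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-group t-test per gene
#'
#' Shrinks each gene's pooled variance toward a prior:
#' `s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d)`, then
#' `t = lfc / (s_tilde * sqrt(1/n1 + 1/n2))` with `d0 + d` degrees of
#' freedom. With `d0 = 0` this reduces exactly to [ordinary_t()]; with
#' very large `d0` every gene effectively uses `s0^2`.
#'
#' @param em An [expression_matrix()] with >= 2 samples per group.
#' @param params Either `NULL` (estimate d0 and s0^2 from the data via
#'   [estimate_moderation()]) or a list with elements `d0` (>= 0) and
#'   `s0_sq` (> 0).
#' @return A `de_result` data frame (see [ordinary_t()]); the fitted
#'   `d0` and `s0_sq` are attached as attribute `"moderation"`.
#' @export
moderated_t <- function(em, params = NULL) {
  gs <- group_stats(em)
  if (is.null(params)) params <- estimate_moderation(gs$s2, gs$df)
  if (!is.numeric(params$d0) || is.na(params$d0) || params$d0 < 0)
    stop("`d0` must be >= 0")
  if (params$d0 > 1e6) params$d0 <- 1e6  # "infinite" prior cap
  if (params$d0 > 0 && (!is.numeric(params$s0_sq) || params$s0_sq <= 0))
    stop("`s0_sq` must be > 0")
  s0_sq <- if (params$d0 > 0) params$s0_sq else 0
  s2_post <- (params$d0 * s0_sq + gs$df * gs$s2) / (params$d0 + gs$df)
  se <- sqrt(s2_post * (1 / gs$n1 + 1 / gs$n2))
  df_post <- params$d0 + gs$df
  t_stat <- ifelse(se > 0, gs$lfc / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t_stat), df_post), 1)
  out <- de_table(rownames(em$values), gs$lfc, t_stat,
                  rep(df_post, length(se)), p, "moderated")
  attr(out, "moderation") <- params
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted p-values (q-values), same order as input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- numeric(n)
  q[o] <- pmin(1, cummin(n / (n:1) * p[o]))
  q
}

#' Select upregulated genes at the screening thresholds
#'
#' A gene is selected when its (unadjusted or BH-adjusted) p-value is
#' strictly below `p_max` and its log fold change strictly exceeds
#' `lfc_min`. Downregulated genes (lfc <= 0) are always excluded. The
#' fold-change threshold is read on the log2 scale by default
#' (`lfc_min = 1.5` means log2 FC > 1.5, about 2.8-fold); set
#' `lfc_units = "fold"` to threshold on the plain fold change instead.
#'
#' @param de A `de_result` from [ordinary_t()] or [moderated_t()].
#' @param p_max P-value threshold (default 0.05, strict `<`).
#' @param lfc_min Fold-change threshold (default 1.5, strict `>`).
#' @param use_adjusted Use the `q` column instead of `p` (computed on the
#'   fly with [bh_adjust()] if absent).
#' @param lfc_units `"log2"` (default) or `"fold"`.
#' @return Character vector of selected gene ids.
#' @export
select_upregulated <- function(de, p_max = 0.05, lfc_min = 1.5,
                               use_adjusted = FALSE,
                               lfc_units = c("log2", "fold")) {
  stopifnot(inherits(de, "de_result"))
  if (p_max <= 0 || lfc_min <= 0) stop("thresholds must be positive")
  lfc_units <- match.arg(lfc_units)
  cut <- if (lfc_units == "fold") log2(lfc_min) else lfc_min
  pv <- if (use_adjusted) {
    if (all(is.na(de$q))) bh_adjust(de$p) else de$q
  } else de$p
  de$gene_id[pv < p_max & de$lfc > cut]
}

#' Write a per-dataset differential-expression table as TSV
#'
#' @param de A `de_result`.
#' @param path Output path.
#' @return Invisibly, `de`.
#' @export
write_de_tsv <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(de)
}
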