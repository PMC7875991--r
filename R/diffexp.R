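#' Median-of-ratios size factors
#'
#' Per-sample scaling constants: the median, over features with nonzero
#' counts in every sample, of the sample's count ratios to the
#' per-feature geometric mean. After dividing columns by these factors,
#' the per-sample median ratio to the geometric-mean reference is 1.
#'
#' @param mat Numeric matrix (features x samples) or `count_matrix`.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(mat) {
  m <- if (inherits(mat, "count_matrix")) as.matrix(mat) else as.matrix(mat)
  use <- rowSums(m > 0) == ncol(m)
  if (!any(use)) {
    stop("no feature has nonzero counts in all samples; supply a ",
         "pseudo-reference or filter samples")
  }
  logm <- log(m[use, , drop = FALSE])
  loggeo <- rowMeans(logm)
  apply(logm, 2, function(col) median(exp(col - loggeo)))
}

#' Mean normalized count per feature (baseMean)
#'
#' @param mat Numeric matrix or `count_matrix`.
#' @param factors Size factors from [size_factors()].
#' @return Named numeric vector of per-feature means of
#'   count/size-factor.
#' @export
base_mean <- function(mat, factors = size_factors(mat)) {
  m <- if (inherits(mat, "count_matrix")) as.matrix(mat) else as.matrix(mat)
  rowMeans(sweep(m, 2, factors, "/"))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (the standard BH procedure, via [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}

#' Simplified negative-binomial Wald test for two-condition designs
#'
#' A documented, testable surrogate for a default negative-binomial
#' differential-expression analysis: median-of-ratios normalization;
#' features kept at `baseMean > base_mean_cutoff` (strict); per-feature
#' moment-estimated dispersion `alpha = max((s^2 - mu)/mu^2, 1e-8)`
#' pooled across the two groups on normalized counts;
#' `log2FC = log2((mean_B + 0.5)/(mean_A + 0.5))` on normalized counts;
#' Wald `z = log2FC/SE` with the delta-method standard error
#' `SE^2 = [(mu_B + alpha mu_B^2)/n_B/(mu_B + 0.5)^2 +
#' (mu_A + alpha mu_A^2)/n_A/(mu_A + 0.5)^2] / ln(2)^2`; two-sided normal
#' p-values; BH adjustment. No dispersion shrinkage, outlier filtering or
#' independent filtering is performed.
#'
#' @param mat Count matrix (features x samples) or `count_matrix`.
#' @param condition Character/factor of length `ncol(mat)`; two levels,
#'   control first (log2FC > 0 means higher in the second level).
#' @param base_mean_cutoff Features with baseMean at or below this are
#'   excluded from testing (default 10).
#' @param alpha Significance threshold stored for downstream summaries.
#' @return Tibble of class `isotail_de`: `mirna_id`, `baseMean`,
#'   `log2FC`, `lfcSE`, `stat`, `pvalue`, `padj`, `direction`.
#' @export
nb_wald_test <- function(mat, condition, base_mean_cutoff = 10,
                         alpha = 0.05) {
  m <- if (inherits(mat, "count_matrix")) as.matrix(mat) else as.matrix(mat)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("condition must have exactly two levels")
  if (any(table(condition) < 2)) {
    stop("at least two samples per condition required")
  }
  lev <- levels(condition)
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  bm <- rowMeans(norm)
  keep <- bm > base_mean_cutoff
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  norm <- norm[keep, , drop = FALSE]
  ids <- rownames(m)[keep]
  a <- norm[, condition == lev[1], drop = FALSE]
  b <- norm[, condition == lev[2], drop = FALSE]
  n_a <- ncol(a); n_b <- ncol(b)
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  v_a <- apply(a, 1, var); v_b <- apply(b, 1, var)
  disp_of <- function(v, mu) ifelse(mu > 0, (v - mu) / mu^2, 0)
  disp <- pmax(((n_a - 1) * disp_of(v_a, mu_a) +
                  (n_b - 1) * disp_of(v_b, mu_b)) / (n_a + n_b - 2),
               1e-8)
  log2fc <- log2((mu_b + 0.5) / (mu_a + 0.5))
  var_mean_a <- (mu_a + disp * mu_a^2) / n_a
  var_mean_b <- (mu_b + disp * mu_b^2) / n_b
  se <- sqrt(var_mean_b / (mu_b + 0.5)^2 + var_mean_a / (mu_a + 0.5)^2) /
    log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pnorm(-abs(z))
  res <- tibble::tibble(
    mirna_id = ids,
    baseMean = bm[keep],
    log2FC = log2fc,
    lfcSE = se,
    stat = z,
    pvalue = p,
    padj = bh_adjust(p),
    direction = sign(log2fc))
  structure(res, class = c("isotail_de", class(res)),
            alpha = alpha, conditions = lev,
            n_samples = c(n_a, n_b), n_input = nrow(m))
}

#' @method tidy isotail_de
#' @export
tidy.isotail_de <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @method glance isotail_de
#' @export
glance.isotail_de <- function(x, ...) {
  alpha <- attr(x, "alpha")
  tibble::tibble(
    n_input = attr(x, "n_input"),
    n_tested = nrow(x),
    n_significant = sum(x$padj < alpha, na.rm = TRUE),
    n_up = sum(x$padj < alpha & x$log2FC > 0, na.rm = TRUE),
    n_down = sum(x$padj < alpha & x$log2FC < 0, na.rm = TRUE),
    alpha = alpha)
}

#' Cross-experiment log2FC signature regression
#'
#' Joins two differential-expression result sets on miRNAs significant
#' (padj < `alpha`) in both, and regresses the second experiment's log2
#' fold changes on the first's by ordinary least squares. A negative
#' slope means the second experiment's signature inverts the first's.
#'
#' @param results_x,results_y `isotail_de` tibbles (or any tibble with
#'   `mirna_id`, `log2FC`, `padj`).
#' @param alpha Joint significance threshold (default 0.05).
#' @return Object of class `isotail_sigreg` with `tidy()` and `glance()`
#'   methods: slope, intercept, R^2, joined size, concordant/discordant
#'   direction counts, and the joined points.
#' @export
signature_regression <- function(results_x, results_y, alpha = 0.05) {
  sig_x <- results_x[!is.na(results_x$padj) & results_x$padj < alpha,
                     c("mirna_id", "log2FC")]
  sig_y <- results_y[!is.na(results_y$padj) & results_y$padj < alpha,
                     c("mirna_id", "log2FC")]
  joined <- dplyr::inner_join(sig_x, sig_y, by = "mirna_id",
                              suffix = c("_x", "_y"))
  if (nrow(joined) < 3) {
    stop("fewer than 3 miRNAs jointly significant; cannot regress")
  }
  fit <- lm(log2FC_y ~ log2FC_x, data = joined)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit))$r.squared,
    n = nrow(joined),
    concordant = sum(sign(joined$log2FC_x) == sign(joined$log2FC_y)),
    discordant = sum(sign(joined$log2FC_x) != sign(joined$log2FC_y)),
    points = joined,
    fit = fit), class = "isotail_sigreg")
}

#' @export
print.isotail_sigreg <- function(x, ...) {
  cat("<isotail_sigreg> n =", x$n, " slope =", signif(x$slope, 4),
      " R^2 =", signif(x$r_squared, 4), "\n",
      "concordant/discordant directions:", x$concordant, "/",
      x$discordant, "\n")
  invisible(x)
}

#' @method tidy isotail_sigreg
#' @export
tidy.isotail_sigreg <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance isotail_sigreg
#' @export
glance.isotail_sigreg <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, n = x$n,
                 concordant = x$concordant, discordant = x$discordant)
}
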