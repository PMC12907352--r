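# Inter-coder reliability: Cohen's kappa for categorical codings and the
# two-way random absolute-agreement ICC for continuous ratings.

#' Cohen's kappa between two aligned codings
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with expected
#' agreement `p_e` from the product of the two coders' marginal distributions.
#' When both coders are constant and identical (`p_e = 1`), kappa is defined
#' as 1.
#'
#' @param codes_a,codes_b Equal-length category sequences (character or factor).
#' @return A list of class `reliability_result`: `kappa`, `p_o`, `p_e`,
#'   `n_items`.
#' @examples
#' cohens_kappa(c("a", "b", "a"), c("a", "b", "a"))$kappa  # 1
#' @export
cohens_kappa <- function(codes_a, codes_b) {
  if (length(codes_a) != length(codes_b))
    stop("codings must have equal length")
  if (!length(codes_a)) stop("empty codings")
  lev <- sort(unique(c(as.character(codes_a), as.character(codes_b))))
  a <- factor(as.character(codes_a), levels = lev)
  b <- factor(as.character(codes_b), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    if (p_o >= 1) 1 else NA_real_
  } else (p_o - p_e) / (1 - p_e)
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, n_items = n),
            class = "reliability_result")
}

#' Intraclass correlation for paired continuous ratings
#'
#' Two-way random-effects, single-measure, absolute-agreement ICC (ICC(A,1)),
#' computed from the ANOVA decomposition of the items-by-raters table. Unlike
#' a Pearson correlation, a constant shift between raters lowers the ICC.
#'
#' @param values_a,values_b Equal-length numeric rating vectors (one item per
#'   position, two raters).
#' @return A list of class `reliability_result`: `icc`, `n_items`.
#' @export
icc_agreement <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("ratings must have equal length")
  n <- length(values_a)
  if (n < 2) stop("need at least 2 items")
  x <- cbind(as.numeric(values_a), as.numeric(values_b))
  k <- 2L
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- if (abs(denom) < .Machine$double.eps^0.5) {
    if (abs(msr - mse) < .Machine$double.eps^0.5) 1 else NA_real_
  } else (msr - mse) / denom
  structure(list(icc = icc, n_items = n), class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  if (!is.null(x$kappa))
    cat("Cohen's kappa = ", format(x$kappa, digits = 4),
        " (n = ", x$n_items, ")\n", sep = "")
  else
    cat("ICC(A,1) = ", format(x$icc, digits = 4),
        " (n = ", x$n_items, ")\n", sep = "")
  invisible(x)
}
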