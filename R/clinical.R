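# Intervention-response analysis: responder definition, class-stratified
# rates, logistic odds, covariate-adjusted contrasts, entropy mediation.

#' Responder flags from baseline/post symptom totals
#'
#' A child responds when the relative decrease `(baseline - post) / baseline`
#' reaches `threshold` (inclusive at the boundary).
#'
#' @param baseline,post Numeric score vectors (baseline must be > 0).
#' @param threshold Minimum relative decrease (default 0.20).
#' @return Logical responder vector.
#' @examples
#' response_flags(c(20, 20, 10), c(16, 17, 12))  # TRUE FALSE FALSE
#' @export
response_flags <- function(baseline, post, threshold = 0.20) {
  if (length(baseline) != length(post)) stop("baseline/post length mismatch")
  if (any(baseline <= 0, na.rm = TRUE))
    stop("baseline scores must be > 0 for the relative-change rule")
  (baseline - post) / baseline >= threshold
}

# round half up to integer (printed response rates use this convention)
.round_half_up <- function(x) floor(x + 0.5)

#' Per-class intervention response rates
#'
#' Tabulates responders by latent class and reports the integer percentage
#' (round half up). Empty classes get an `NA` rate.
#'
#' @param labels Class labels (factor or vector), aligned with `flags`.
#' @param flags Logical responder flags.
#' @return A `response_result` data frame: `class`, `responders`, `total`,
#'   `rate` (integer percent).
#' @examples
#' labels <- rep(c("high", "medium", "low"), c(31, 38, 26))
#' flags <- rep(rep(c(TRUE, FALSE), 3), c(21, 10, 16, 22, 5, 21))
#' response_rates(labels, flags)  # rates 68, 19, 42 (alphabetical classes)
#' @export
response_rates <- function(labels, flags) {
  if (length(labels) != length(flags)) stop("labels/flags length mismatch")
  labels <- as.factor(labels)
  out <- do.call(rbind, lapply(levels(labels), function(l) {
    f <- flags[labels == l]
    data.frame(class = l, responders = sum(f), total = length(f),
               rate = if (length(f)) .round_half_up(100 * sum(f) / length(f))
                      else NA_real_)
  }))
  rownames(out) <- NULL
  structure(out, class = c("response_result", "data.frame"))
}

#' Logistic regression for intervention response odds
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of responder
#' status on latent class (dummy-coded against a reference class) and an
#' optional age covariate, with Wald 95% confidence intervals on the odds
#' ratios. Complete separation raises an error rather than returning silently
#' penalized estimates.
#'
#' @param y Logical/0-1 responder outcomes.
#' @param category Class labels (coerced to factor).
#' @param age Optional numeric covariate (e.g., months).
#' @param ref Reference class level (default: first factor level).
#' @return A `logistic_fit` list: `coef`, `or`, `ci` (matrix of OR bounds),
#'   `se`, `p`, `converged`, `model` (the underlying `glm`).
#' @export
logistic_fit <- function(y, category, age = NULL, ref = NULL) {
  y <- as.numeric(y)
  if (length(unique(y[!is.na(y)])) < 2)
    stop("outcome has fewer than 2 levels")
  category <- as.factor(category)
  if (!is.null(ref)) category <- stats::relevel(category, ref = ref)
  dat <- data.frame(y = y, category = category)
  form <- y ~ category
  if (!is.null(age)) { dat$age <- as.numeric(age); form <- y ~ category + age }
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = dat))
  cf <- stats::coef(fit)
  mu <- stats::fitted(fit)
  if (any(abs(cf) > 10) && any(mu < 1e-8 | mu > 1 - 1e-8))
    stop("complete (or quasi-complete) separation detected: ",
         "coefficient(s) diverging [",
         paste(names(cf)[abs(cf) > 10], collapse = ", "), "]")
  sm <- summary(fit)$coefficients
  ci <- exp(cbind(lower = cf - 1.96 * sm[, "Std. Error"],
                  upper = cf + 1.96 * sm[, "Std. Error"]))
  structure(list(coef = cf, or = exp(cf), ci = ci,
                 se = sm[, "Std. Error"], p = sm[, 4],
                 converged = fit$converged, model = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic response model (odds ratios, Wald 95% CI):\n")
  print(round(cbind(OR = x$or, x$ci, p = x$p), 4))
  invisible(x)
}

#' Covariate-adjusted group difference (ANCOVA-style)
#'
#' Linear model `score ~ group + covariates`; the reported contrast is the
#' group coefficient with its 95% confidence interval and p-value. With
#' balanced (or constant) covariates this reduces to the raw mean difference.
#' Exactly collinear covariates raise an error naming the offending pair.
#'
#' @param score Numeric outcome.
#' @param group Two-level grouping factor; the contrast is level 2 minus
#'   level 1 (reference).
#' @param covariates Optional data frame of numeric/binary covariates.
#' @return List with `difference`, `ci`, `p`, `model`.
#' @export
adjusted_mean_difference <- function(score, group, covariates = NULL) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly 2 levels")
  dat <- data.frame(score = as.numeric(score), group = group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (anyNA(covariates) || anyNA(score)) stop("missing values not supported")
    # constant covariates carry no information; drop them so the contrast
    # reduces to the unadjusted difference
    const <- vapply(covariates, function(v) length(unique(v)) == 1L, TRUE)
    covariates <- covariates[!const]
    num <- covariates[vapply(covariates, is.numeric, TRUE)]
    if (ncol(num) >= 2) {
      cm <- suppressWarnings(stats::cor(num))
      cm[!is.finite(cm)] <- 0
      diag(cm) <- 0
      if (any(abs(cm) > 1 - 1e-10)) {
        ij <- which(abs(cm) > 1 - 1e-10, arr.ind = TRUE)[1, ]
        stop("collinear covariates: ", colnames(num)[ij[1]], " and ",
             colnames(num)[ij[2]])
      }
    }
    dat <- cbind(dat, covariates)
  }
  fit <- stats::lm(score ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design (aliased term: ",
         paste(dropped, collapse = ", "), ")")
  }
  term <- paste0("group", levels(group)[2])
  est <- stats::coef(fit)[[term]]
  ci <- stats::confint(fit)[term, ]
  p <- summary(fit)$coefficients[term, 4]
  list(difference = est, ci = unname(ci), p = p, model = fit)
}

#' Mediation of class effects on response through behavioral entropy
#'
#' Product-of-coefficients mediation: path `a` from the linear regression of
#' the mediator on the (numerically coded) class score, path `b` as the
#' mediator coefficient in the logistic regression of the outcome on mediator
#' plus class, indirect effect `a * b`, with a nonparametric percentile
#' bootstrap confidence interval.
#'
#' @param class_score Numeric class coding (e.g., graded 1..K or a dummy).
#' @param mediator Numeric mediator (behavioral entropy).
#' @param outcome Logical/0-1 outcome (responder flag).
#' @param B Bootstrap resamples (>= 100; default 1000).
#' @param seed Optional seed.
#' @param conf Confidence level (default 0.95).
#' @return A `mediation_result` list: `a`, `b`, `indirect`, `ci`, `B`.
#' @export
mediation_product <- function(class_score, mediator, outcome, B = 1000,
                              seed = NULL, conf = 0.95) {
  if (B < 100) stop("B must be >= 100")
  class_score <- as.numeric(class_score)
  mediator <- as.numeric(mediator)
  outcome <- as.numeric(outcome)
  n <- length(outcome)
  if (length(class_score) != n || length(mediator) != n)
    stop("inputs must be aligned")
  if (stats::sd(mediator) == 0) stop("mediator has zero variance")
  point <- function(idx) {
    cs <- class_score[idx]; md <- mediator[idx]; y <- outcome[idx]
    a <- stats::coef(stats::lm(md ~ cs))[["cs"]]
    b <- tryCatch(
      stats::coef(suppressWarnings(
        stats::glm(y ~ md + cs, family = stats::binomial())))[["md"]],
      error = function(e) NA_real_)
    c(a = a, b = b)
  }
  ab <- point(seq_len(n))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  boots <- vapply(seq_len(B), function(b) {
    v <- point(sample.int(n, n, replace = TRUE))
    v[["a"]] * v[["b"]]
  }, 0)
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  structure(list(a = ab[["a"]], b = ab[["b"]],
                 indirect = ab[["a"]] * ab[["b"]],
                 ci = ci, B = B, boot = boots),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation (product of coefficients): a = ", format(x$a, digits = 4),
      ", b = ", format(x$b, digits = 4),
      ", indirect = ", format(x$indirect, digits = 4),
      "\n  ", length(x$boot), "-resample percentile CI: [",
      format(x$ci[1], digits = 4), ", ", format(x$ci[2], digits = 4), "]\n",
      sep = "")
  invisible(x)
}
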