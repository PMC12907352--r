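# Bernoulli-mixture latent class analysis: EM estimation, information
# criteria, adjusted and bootstrap likelihood-ratio tests, model selection.

.THETA_FLOOR <- 1e-6

# internal: n x K matrix of log component densities + log mixing weights
.lca_log_components <- function(X, pi_k, theta) {
  lw <- X %*% log(theta) + (1 - X) %*% log(1 - theta)
  sweep(lw, 2, log(pi_k), `+`)
}

# internal: row-wise log-sum-exp (pmax over columns; avoids apply overhead)
.lse <- function(m) {
  mx <- do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
  mx + log(rowSums(exp(m - mx)))
}

.lca_loglik <- function(X, pi_k, theta) sum(.lse(.lca_log_components(X, pi_k, theta)))

#' Dichotomize indicator frequencies
#'
#' Converts an n-by-I numeric frequency table into the binary indicator
#' matrix consumed by [fit_lca()]. The default rule splits each indicator at
#' its median (values strictly above the median become 1, ties go low);
#' `"z>0"` thresholds the per-column z score at zero; explicit numeric
#' thresholds may be supplied instead.
#'
#' @param freqs Numeric matrix or data frame (children x indicators), no
#'   missing values.
#' @param rule `"median"` (default), `"z>0"`, or a numeric vector of explicit
#'   thresholds (length 1 or I); values strictly above the threshold map to 1.
#' @return An `indicator_matrix`: binary matrix with a `"binarization"`
#'   attribute recording the rule and per-column thresholds.
#' @export
binarize_indicators <- function(freqs, rule = "median") {
  M <- as.matrix(freqs)
  if (!is.numeric(M)) stop("freqs must be numeric")
  if (anyNA(M)) stop("missing values in freqs are not supported")
  I <- ncol(M)
  if (is.numeric(rule)) {
    thr <- rep_len(rule, I)
    lab <- "explicit"
  } else if (identical(rule, "median")) {
    thr <- apply(M, 2, stats::median)
    lab <- "median"
    const <- which(apply(M, 2, function(v) length(unique(v)) == 1L))
    if (length(const))
      stop("constant column(s) under median rule: ",
           paste(colnames(M)[const] %||% const, collapse = ", "))
  } else if (identical(rule, "z>0")) {
    thr <- colMeans(M)
    lab <- "z>0"
  } else stop("unknown binarization rule")
  X <- 1L * sweep(M, 2, thr, `>`)
  structure(X, binarization = list(rule = lab, thresholds = thr),
            class = c("indicator_matrix", class(X)))
}

#' Fit a Bernoulli-mixture latent class model by EM
#'
#' Maximum-likelihood estimation of the K-class mixture of independent
#' Bernoulli indicators,
#' `P(x) = sum_k pi_k prod_i theta_ik^x_i (1 - theta_ik)^(1 - x_i)`,
#' by expectation-maximization with multiple random restarts. Responsibilities
#' are computed in log space (log-sum-exp); class-conditional probabilities
#' are floored at `1e-6` from both ends. Classes of the returned model are
#' ordered by decreasing mixing proportion. For `K = 1` the closed form
#' (`theta` = column means) is returned.
#'
#' @param X Binary matrix (children x indicators) or [binarize_indicators()]
#'   output.
#' @param K Number of classes (>= 1, < n).
#' @param restarts Number of random initializations (best log-likelihood
#'   kept; default 20).
#' @param tol Relative convergence tolerance: iteration stops once the
#'   log-likelihood increment falls below `tol * (|logLik| + tol)`
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param seed Optional integer seed for the restarts.
#' @return An `lca_model`: list with `K`, `pi` (mixing proportions), `theta`
#'   (I x K class-conditional probabilities), `loglik`, `loglik_trace` (best
#'   restart), `posteriors` (n x K), `n`, `n_params`, `bic`, `aic`,
#'   `rel_entropy`, `converged`, `restarts`.
#' @export
fit_lca <- function(X, K, restarts = 20, tol = 1e-6, max_iter = 500,
                    seed = NULL) {
  X <- as.matrix(X)
  if (!all(X %in% c(0, 1))) stop("X must be binary (0/1)")
  storage.mode(X) <- "double"
  n <- nrow(X); I <- ncol(X)
  if (K < 1 || K != round(K)) stop("K must be a positive integer")
  if (n <= K) stop("need n > K")
  if (restarts < 1) stop("restarts must be >= 1")
  clip <- function(v) pmin(pmax(v, .THETA_FLOOR), 1 - .THETA_FLOOR)

  if (K == 1) {
    theta <- matrix(clip(colMeans(X)), ncol = 1,
                    dimnames = list(colnames(X), "class1"))
    ll <- .lca_loglik(X, 1, theta)
    post <- matrix(1, n, 1)
    return(.finish_lca(K, 1, theta, ll, ll, post, n, converged = TRUE,
                       restarts = 1L))
  }

  run_one <- function() {
    pi_k <- rep(1 / K, K)
    theta <- clip(matrix(stats::runif(I * K, 0.15, 0.85), I, K))
    ll_old <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      lc <- .lca_log_components(X, pi_k, theta)
      lse <- .lse(lc)
      ll <- sum(lse)
      trace <- c(trace, ll)
      resp <- exp(lc - lse)
      nk <- colSums(resp)
      pi_k <- nk / n
      theta <- clip(sweep(t(X) %*% resp, 2, nk, `/`))
      # relative criterion: flat-likelihood ridges (redundant classes) shed
      # absolute increments that decay geometrically but stay above any tiny
      # absolute cutoff for thousands of iterations
      if (is.finite(ll_old) && ll - ll_old < tol * (abs(ll) + tol)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    list(pi = pi_k, theta = theta, loglik = ll, trace = trace,
         resp = resp, converged = converged)
  }

  best <- NULL
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  for (r in seq_len(restarts)) {
    fit <- run_one()
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$pi, decreasing = TRUE)
  theta <- best$theta[, ord, drop = FALSE]
  dimnames(theta) <- list(colnames(X), paste0("class", seq_len(K)))
  .finish_lca(K, best$pi[ord], theta, best$loglik, best$trace,
              best$resp[, ord, drop = FALSE], n,
              converged = best$converged, restarts = restarts)
}

.finish_lca <- function(K, pi_k, theta, loglik, trace, post, n, converged,
                        restarts) {
  I <- nrow(theta)
  n_params <- K * I + (K - 1)
  rel_entropy <- if (K == 1) 1 else {
    pl <- post * log(pmax(post, 1e-300))
    1 - (-sum(pl)) / (n * log(K))
  }
  structure(list(K = K, pi = unname(pi_k), theta = theta, loglik = loglik,
                 loglik_trace = trace, posteriors = post, n = n,
                 n_params = n_params,
                 bic = -2 * loglik + n_params * log(n),
                 aic = -2 * loglik + 2 * n_params,
                 rel_entropy = rel_entropy,
                 converged = converged, restarts = restarts),
            class = "lca_model")
}

#' @export
print.lca_model <- function(x, ...) {
  cat("Bernoulli-mixture LCA: K = ", x$K, ", n = ", x$n,
      ", logLik = ", format(x$loglik, digits = 6),
      ", BIC = ", format(x$bic, digits = 6),
      ", entropy = ", format(x$rel_entropy, digits = 3), "\n", sep = "")
  cat("pi:", paste(format(x$pi, digits = 3), collapse = " "), "\n")
  print(round(x$theta, 3))
  invisible(x)
}

#' Information criteria and classification entropy of a fitted model
#'
#' `BIC = -2 logLik + p log n`, `AIC = -2 logLik + 2p` with
#' `p = K*I + (K - 1)`, and the relative classification entropy
#' `1 - (-sum p_nk log p_nk) / (n log K)` (1 for `K = 1`; 0 for uniform
#' posteriors).
#'
#' @param model An `lca_model` from [fit_lca()].
#' @return List with `bic`, `aic`, `rel_entropy`.
#' @export
information_criteria <- function(model) {
  stopifnot(inherits(model, "lca_model"))
  list(bic = model$bic, aic = model$aic, rel_entropy = model$rel_entropy)
}

#' Likelihood-ratio test for K versus K-1 classes
#'
#' Default `"lmr_approx"` applies the ad hoc adjusted likelihood-ratio
#' approximation: the statistic `2 * (logLik_K - logLik_{K-1})` is shrunk by
#' `1 / (1 + 1/(d log n))` (`d` the parameter difference) and referred to a
#' chi-square with `d` degrees of freedom. This approximation is convenient
#' but can be anticonservative at mixture boundaries; `"bootstrap"` runs a
#' parametric bootstrap of the statistic under the (K-1)-class fit (`B`
#' refits) and is the robust choice.
#'
#' @param model_k,model_km1 `lca_model`s fitted on the same data with K and
#'   K-1 classes.
#' @param variant `"lmr_approx"` (default) or `"bootstrap"`.
#' @param B Bootstrap replications (bootstrap variant). With the add-one
#'   convention `p = (1 + #\{LR_b >= LR\}) / (B + 1)`, `B = 1` gives the
#'   degenerate values 1/2 or 1 and is useful for smoke tests only.
#' @param restarts Restarts per bootstrap refit (default 5).
#' @param seed Optional seed for the bootstrap.
#' @return List with `statistic` (raw `2 dLL`), `df`, `p`, `variant`.
#' @export
lmr_test <- function(model_k, model_km1, variant = c("lmr_approx", "bootstrap"),
                     B = 100, restarts = 5, seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(model_k, "lca_model"), inherits(model_km1, "lca_model"))
  if (model_k$K - model_km1$K != 1)
    stop("models must have adjacent class counts (K and K-1)")
  if (model_k$n != model_km1$n)
    stop("models must be fitted on the same data")
  n <- model_k$n
  lr <- 2 * (model_k$loglik - model_km1$loglik)
  df <- model_k$n_params - model_km1$n_params
  if (variant == "lmr_approx") {
    adj <- lr / (1 + 1 / (df * log(n)))
    p <- stats::pchisq(max(adj, 0), df, lower.tail = FALSE)
  } else {
    if (B < 1) stop("B must be >= 1")
    I <- nrow(model_km1$theta)
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
      set.seed(seed)
    }
    lr_b <- vapply(seq_len(B), function(b) {
      cls <- sample.int(model_km1$K, n, replace = TRUE, prob = model_km1$pi)
      Xb <- matrix(stats::rbinom(n * I, 1,
                                 t(model_km1$theta)[cls, , drop = FALSE]), n, I)
      f0 <- fit_lca(Xb, model_km1$K, restarts = restarts)
      f1 <- fit_lca(Xb, model_k$K, restarts = restarts)
      2 * (f1$loglik - f0$loglik)
    }, 0)
    p <- (1 + sum(lr_b >= lr)) / (B + 1)
  }
  list(statistic = lr, df = df, p = p, variant = variant)
}

#' Scan the number of latent classes
#'
#' Fits the mixture for each `k` in `[kmin, kmax]`, tabulating BIC, AIC,
#' relative entropy and the K-vs-(K-1) likelihood-ratio p-value. The chosen
#' class count is the BIC minimizer among converged fits, stepped down while
#' its own likelihood-ratio test fails (p > 0.05) but the next-smaller
#' solution is supported — the two-stage rule combining information criteria
#' with adjacent-model testing.
#'
#' @param X Binary indicator matrix.
#' @param kmin,kmax Scan range (defaults 2-5).
#' @param restarts Restarts per fit (default 20).
#' @param seed Optional seed.
#' @param lmr_variant Passed to [lmr_test()].
#' @return A `model_selection` list: `table` (data frame over k), `chosen_k`,
#'   `models` (fitted `lca_model`s, including the `kmin - 1` reference).
#' @export
select_classes <- function(X, kmin = 2, kmax = 5, restarts = 20, seed = NULL,
                           lmr_variant = "lmr_approx") {
  X <- as.matrix(X)
  if (kmin < 1 || kmax < kmin) stop("need 1 <= kmin <= kmax")
  if (kmax >= nrow(X)) stop("kmax must be < n")
  ks <- kmin:kmax
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  fit_k <- function(k) fit_lca(X, k, restarts = if (k == 1) 1 else restarts)
  models <- stats::setNames(lapply(c(kmin - 1, ks), function(k)
    if (k >= 1) fit_k(k) else NULL), paste0("k", c(kmin - 1, ks)))
  tab <- do.call(rbind, lapply(ks, function(k) {
    m <- models[[paste0("k", k)]]
    prev <- models[[paste0("k", k - 1)]]
    lmr_p <- if (!is.null(prev))
      lmr_test(m, prev, variant = lmr_variant)$p else NA_real_
    data.frame(k = k, loglik = m$loglik, bic = m$bic, aic = m$aic,
               rel_entropy = m$rel_entropy, lmr_p = lmr_p,
               converged = m$converged)
  }))
  ok <- which(tab$converged)
  if (!length(ok)) stop("no class solution converged")
  if (length(ok) < nrow(tab))
    warning("non-converged solution(s) excluded from BIC selection: k = ",
            paste(tab$k[-ok], collapse = ", "))
  chosen <- tab$k[ok][which.min(tab$bic[ok])]
  repeat {
    row <- which(tab$k == chosen)
    below <- which(tab$k == chosen - 1)
    if (!length(below) || is.na(tab$lmr_p[row]) || tab$lmr_p[row] <= 0.05 ||
        is.na(tab$lmr_p[below]) || tab$lmr_p[below] > 0.05) break
    chosen <- chosen - 1
  }
  structure(list(table = tab, chosen_k = chosen, models = models,
                 rule = "min BIC + LMR support"),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 5)
  cat("chosen_k =", x$chosen_k, "(", x$rule, ")\n")
  invisible(x)
}

#' Modal class assignment
#'
#' Assigns each observation to its maximum-posterior class; posterior ties
#' break deterministically toward the lower class index.
#'
#' @param model An `lca_model`.
#' @param X Optional binary matrix to classify (defaults to the posteriors
#'   stored in the model).
#' @return List with `labels` (integer class indices) and `posteriors`.
#' @export
assign_classes <- function(model, X = NULL) {
  stopifnot(inherits(model, "lca_model"))
  post <- if (is.null(X)) model$posteriors else {
    X <- as.matrix(X)
    lc <- .lca_log_components(X, model$pi, model$theta)
    exp(lc - .lse(lc))
  }
  labels <- apply(post, 1, which.max)  # which.max ties -> lowest index
  list(labels = as.integer(labels), posteriors = post)
}

# internal: all permutations of 1..k
.perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .perms(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' Match estimated classes to reference classes
#'
#' Finds the permutation of estimated class columns minimizing the total
#' absolute difference between `theta_est` and `theta_true` (exhaustive over
#' `K!`; refuses `K > 8`). Used to align mixture labels for recovery studies.
#'
#' @param theta_est,theta_true I x K class-conditional probability matrices.
#' @return Integer permutation `perm` such that
#'   `theta_est[, perm]` aligns with `theta_true`.
#' @export
match_labels <- function(theta_est, theta_true) {
  theta_est <- as.matrix(theta_est); theta_true <- as.matrix(theta_true)
  K <- ncol(theta_est)
  if (ncol(theta_true) != K) stop("class counts differ")
  if (K > 8) stop("exhaustive matching refused for K > 8")
  P <- .perms(K)
  costs <- apply(P, 1, function(p)
    sum(abs(theta_est[, p, drop = FALSE] - theta_true)))
  as.integer(P[which.min(costs), ])
}
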