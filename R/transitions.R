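# Lag-sequential machinery: transition count/probability matrices, multi-step
# transitions, stationary distributions, cyclicity/transitivity.

#' Lag-k transition counts from an event log
#'
#' Counts `N(i -> j)`: the number of positions where event `t` has category
#' `i` and event `t + lag` has category `j`. Counting never crosses
#' child/session boundaries.
#'
#' @param log An [event_log()].
#' @param lag Positive integer lag (default 1).
#' @return A `transition_matrix` with integer `counts`, `row_totals`, and
#'   `probs = NULL` (see [transition_probabilities()]).
#' @export
transition_counts <- function(log, lag = 1) {
  if (!nrow(log)) stop("empty event log")
  if (lag < 1 || lag != round(lag)) stop("lag must be a positive integer")
  alphabet <- attr(log, "alphabet")
  K <- alphabet_size(alphabet)
  counts <- matrix(0L, K, K, dimnames = list(alphabet$code, alphabet$code))
  seqs <- split(log$category, paste(log$child_id, log$session, sep = "\r"))
  for (s in seqs) {
    n <- length(s)
    if (n <= lag) next
    i <- match(s[seq_len(n - lag)], alphabet$code)
    j <- match(s[seq_len(n - lag) + lag], alphabet$code)
    for (t in seq_along(i)) counts[i[t], j[t]] <- counts[i[t], j[t]] + 1L
  }
  structure(list(alphabet = alphabet, counts = counts,
                 row_totals = rowSums(counts), probs = NULL, lag = lag),
            class = "transition_matrix")
}

#' Row-stochastic transition probabilities
#'
#' Converts counts into conditional probabilities
#' `P(j | i) = (N(i->j) + alpha) / (N(i) + alpha * K)`. With `alpha = 0`,
#' rows for states that never occur as antecedents are undefined (`NA`) and
#' recorded in `undefined_rows`; aggregate metrics exclude them.
#'
#' @param tm A `transition_matrix` from [transition_counts()], or a raw count
#'   matrix.
#' @param alpha Nonnegative smoothing pseudo-count (default 0, raw ratios).
#' @return The `transition_matrix` with `probs` filled in.
#' @export
transition_probabilities <- function(tm, alpha = 0) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (is.matrix(tm))
    tm <- structure(list(alphabet = NULL, counts = tm,
                         row_totals = rowSums(tm), probs = NULL, lag = 1L),
                    class = "transition_matrix")
  K <- ncol(tm$counts)
  probs <- (tm$counts + alpha) / (tm$row_totals + alpha * K)
  undef <- which(tm$row_totals == 0 & alpha == 0)
  if (length(undef)) probs[undef, ] <- NA_real_
  tm$probs <- probs
  tm$alpha <- alpha
  tm$undefined_rows <- undef
  tm
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat("Transition matrix (lag ", x$lag, "), ", sum(x$counts),
      " transitions\n", sep = "")
  if (!is.null(x$probs)) print(round(x$probs, digits)) else print(x$counts)
  invisible(x)
}

#' Multi-step transition matrix with temporal decay
#'
#' Chapman--Kolmogorov `T`-step transition `lambda^T * P^T`. With
#' `lambda = 1` and `T = 1` this is the lag-1 matrix itself; the decay weight
#' discounts multi-step predictions, reflecting the weakening of behavioral
#' dependence over longer horizons.
#'
#' @param tm A `transition_matrix` with `probs` defined on all rows, or a
#'   row-stochastic matrix.
#' @param T_steps Positive integer number of steps.
#' @param lam Decay weight per step, in (0, 1].
#' @return A list of class `multi_step_transition` with `matrix`, `T`, `lam`.
#' @export
k_step_transition <- function(tm, T_steps, lam = 1.0) {
  P <- if (inherits(tm, "transition_matrix")) tm$probs else tm
  if (is.null(P)) stop("transition probabilities not computed")
  if (anyNA(P))
    stop("undefined rows in P; apply smoothing (alpha > 0) upstream")
  if (T_steps < 1 || T_steps != round(T_steps))
    stop("T_steps must be a positive integer")
  if (lam <= 0 || lam > 1) stop("lam must be in (0, 1]")
  M <- diag(nrow(P))
  dimnames(M) <- dimnames(P)
  for (t in seq_len(T_steps)) M <- M %*% P
  structure(list(matrix = lam^T_steps * M, T = T_steps, lam = lam),
            class = "multi_step_transition")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left Perron eigenvector of `P`, normalized to sum to 1.
#'
#' @param P Row-stochastic matrix (or `transition_matrix` with `probs`).
#' @return Numeric stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  if (inherits(P, "transition_matrix")) P <- P$probs
  if (anyNA(P)) stop("P has undefined rows")
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Cyclicity and transitivity of a behavior process
#'
#' Cyclicity is the weighted probability of immediately repeating the same
#' behavior, `sum_i w_i * P(i|i)`; transitivity, the probability of switching
#' category, is its complement. Weights default to the stationary distribution
#' of `P` and are renormalized (with a warning) if they do not sum to 1.
#'
#' @param tm A `transition_matrix` with `probs`, or a row-stochastic matrix.
#' @param weights Optional state weights (stationary used when `NULL`).
#' @return List with `cyclicity`, `transitivity`, `weights`.
#' @export
cyclicity <- function(tm, weights = NULL) {
  P <- if (inherits(tm, "transition_matrix")) tm$probs else tm
  if (is.null(P)) stop("transition probabilities not computed")
  if (is.null(weights)) weights <- stationary_distribution(P)
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-8) {
    warning("weights do not sum to 1; renormalizing")
    weights <- weights / sum(weights)
  }
  used <- weights > 0
  if (anyNA(P[used, , drop = FALSE]))
    stop("P undefined on a row with positive weight")
  cyc <- sum(weights[used] * diag(P)[used])
  list(cyclicity = cyc, transitivity = 1 - cyc, weights = weights)
}
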