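# Sequence complexity metrics and frequent-chain mining.

# internal: category sequences per child/session
.session_sequences <- function(log) {
  split(log$category, paste(log$child_id, log$session, sep = "\r"))
}

# internal: split one session's events into episodes by inter-event gap
.episodes <- function(onsets, offsets, gap_threshold) {
  if (!length(onsets)) return(integer(0))
  gaps <- onsets[-1] - offsets[-length(offsets)]
  cumsum(c(1L, as.integer(gaps > gap_threshold)))
}

#' Shannon entropy of a behavior sequence
#'
#' Plug-in Shannon entropy (bits) of the empirical distribution of behavioral
#' units. The default support is the lag-1 bigram distribution (ordered
#' category pairs, at most `K^2` cells), which measures the diversity of
#' behavior-to-behavior transitions; `"unigram"` uses single-category
#' frequencies. Pairs are pooled across child/sessions but never span a
#' session boundary. `0 * log 0` is taken as 0.
#'
#' @param log An [event_log()].
#' @param support `"bigram"` (default) or `"unigram"`.
#' @return A list of class `sequence_metrics` with `H` (bits), `support`,
#'   `n_cells` (support cells with positive probability), and `p` (named
#'   probability vector).
#' @examples
#' ab <- behavior_alphabet()
#' ev <- data.frame(child_id = 1, session = 1,
#'                  category = rep(c("avoidance", "joint_attention"), 5),
#'                  onset = seq(0, 45, by = 5), offset = seq(4, 49, by = 5))
#' behavioral_entropy(event_log(ev, ab))$H  # 1 bit: two equiprobable bigrams
#' @export
behavioral_entropy <- function(log, support = c("bigram", "unigram")) {
  support <- match.arg(support)
  if (!nrow(log)) stop("empty event log")
  if (support == "unigram") {
    units <- log$category
  } else {
    seqs <- .session_sequences(log)
    units <- unlist(lapply(seqs, function(s) {
      if (length(s) < 2) return(character(0))
      paste(s[-length(s)], s[-1], sep = ">")
    }), use.names = FALSE)
    if (!length(units))
      stop("bigram support needs at least 2 events in some session")
  }
  tab <- table(units)
  p <- as.numeric(tab) / length(units)
  names(p) <- names(tab)
  H <- -sum(p * log2(p))
  structure(list(H = H, support = support, n_cells = length(p), p = p),
            class = "sequence_metrics")
}

#' @export
print.sequence_metrics <- function(x, ...) {
  cat("Behavioral entropy (", x$support, "): H = ",
      format(x$H, digits = 4), " bits over ", x$n_cells, " cells\n", sep = "")
  invisible(x)
}

#' Average sequence length
#'
#' Events are partitioned into interaction episodes wherever the gap between
#' consecutive events (next onset minus previous offset) within a
#' child/session exceeds `gap_threshold`; the average sequence length is the
#' mean number of events per episode, pooled over all episodes in the log.
#'
#' @param log An [event_log()].
#' @param gap_threshold Episode-delimiting gap in seconds (default 5).
#' @return Mean events per episode (>= 1).
#' @export
average_sequence_length <- function(log, gap_threshold = 5.0) {
  if (gap_threshold <= 0) stop("gap_threshold must be > 0")
  if (!nrow(log)) stop("empty event log")
  pieces <- split(as.data.frame(log), paste(log$child_id, log$session, sep = "\r"))
  lens <- unlist(lapply(pieces, function(d) {
    ep <- .episodes(d$onset, d$offset, gap_threshold)
    tabulate(ep)
  }), use.names = FALSE)
  mean(lens)
}

#' Mine high-frequency behavior chains
#'
#' Enumerates category n-grams within interaction episodes, pooled across the
#' cohort. Each chain is reported with its pooled count, its conditional
#' probability given the first state (count of the chain divided by the count
#' of all same-order chains starting in that state), and its support (the
#' fraction of children in whom it occurs at least once). Chains below
#' `min_support` are dropped; the table is sorted by decreasing probability.
#'
#' @param log An [event_log()] covering one or many children.
#' @param order N-gram length (>= 2; default 2).
#' @param min_support Minimum fraction of children exhibiting the chain
#'   (default 0.1).
#' @param gap_threshold Episode-delimiting gap in seconds (default 5).
#' @return A `chain_table` data frame: `chain`, `count`, `probability`,
#'   `support`.
#' @export
mine_chains <- function(log, order = 2, min_support = 0.1, gap_threshold = 5.0) {
  if (order < 2 || order != round(order)) stop("order must be an integer >= 2")
  if (!nrow(log)) stop("empty event log")
  pieces <- split(as.data.frame(log), paste(log$child_id, log$session, sep = "\r"))
  rows <- list()
  for (d in pieces) {
    ep <- .episodes(d$onset, d$offset, gap_threshold)
    for (e in split(d$category, ep)) {
      n <- length(e)
      if (n < order) next
      for (t in seq_len(n - order + 1L)) {
        rows[[length(rows) + 1L]] <- data.frame(
          child_id = d$child_id[1], first = e[t],
          chain = paste(e[t:(t + order - 1L)], collapse = " -> "),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(chain = character(0), count = integer(0),
                      probability = numeric(0), support = numeric(0))
    return(structure(out, class = c("chain_table", "data.frame")))
  }
  grams <- do.call(rbind, rows)
  n_children <- length(unique(log$child_id))
  counts <- table(grams$chain)
  first_of <- vapply(strsplit(names(counts), " -> ", fixed = TRUE), `[`, "", 1)
  first_tot <- table(grams$first)
  supp <- vapply(names(counts), function(ch)
    length(unique(grams$child_id[grams$chain == ch])) / n_children, 0)
  out <- data.frame(chain = names(counts),
                    count = as.integer(counts),
                    probability = as.numeric(counts) /
                      as.numeric(first_tot[first_of]),
                    support = as.numeric(supp),
                    stringsAsFactors = FALSE)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(-out$probability, out$chain), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("chain_table", "data.frame"))
}

#' Welch (or pooled) two-sample t test from group summaries
#'
#' Computes `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` from group means,
#' standard deviations and sizes, with Welch--Satterthwaite degrees of freedom
#' and a two-sided p-value. `pooled = TRUE` gives the equal-variance Student
#' variant.
#'
#' @param a,b Lists (or named vectors) with elements `mean`, `sd`, `n`.
#' @param pooled Use the pooled-variance Student t (default `FALSE`, Welch).
#' @return List with `t`, `df`, `p`, `method`.
#' @examples
#' welch_t(list(mean = 2.14, sd = 0.32, n = 60),
#'         list(mean = 3.08, sd = 0.41, n = 40))
#' @export
welch_t <- function(a, b, pooled = FALSE) {
  a <- as.list(a); b <- as.list(b)
  if (a$n < 2 || b$n < 2) stop("both groups need n >= 2")
  if (a$sd == 0 && b$sd == 0) stop("zero variance in both groups")
  if (pooled) {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       method = if (pooled) "pooled" else "welch")
}

#' Chi-square test of independence with adjusted residuals
#'
#' Pearson chi-square on an observed count table (no continuity correction),
#' `df = (r-1)(c-1)`, with cell-level adjusted (standardized) residuals for
#' path-level inspection.
#'
#' @param observed Count matrix.
#' @return List with `statistic`, `df`, `p`, `expected`,
#'   `adjusted_residuals`.
#' @export
chi_square <- function(observed) {
  observed <- as.matrix(observed)
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
    stop("zero row or column margin in contingency table")
  res <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  if (any(res$expected <= 0)) stop("expected cell count <= 0")
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected,
       adjusted_residuals = res$stdres)
}
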