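# Shared fixture builders: every fixture is generated in code.

# event log from a plain category sequence; consecutive events are spaced so
# nothing merges (gap 0.6 s) and everything clears its minimum duration
seq_log <- function(categories, alphabet = behavior_alphabet(),
                    child_id = "c1", session = 1, gap = 0.6, dur = 3.5,
                    t0 = 0) {
  n <- length(categories)
  onset <- t0 + (seq_len(n) - 1) * (dur + gap)
  event_log(data.frame(child_id = rep(child_id, n), session = rep(session, n),
                       category = categories, onset = onset,
                       offset = onset + dur, stringsAsFactors = FALSE),
            alphabet)
}

# stack several children's sequences into one cohort log
cohort_log <- function(seq_list, alphabet = behavior_alphabet()) {
  rows <- do.call(rbind, lapply(names(seq_list), function(id)
    as.data.frame(seq_log(seq_list[[id]], alphabet, child_id = id))))
  event_log(rows, alphabet)
}

# brute-force lag-k pair counter, independent of transition_counts
brute_counts <- function(categories_by_session, codes, lag = 1) {
  K <- length(codes)
  m <- matrix(0L, K, K, dimnames = list(codes, codes))
  for (s in categories_by_session) {
    n <- length(s)
    if (n <= lag) next
    for (t in seq_len(n - lag)) {
      i <- match(s[t], codes); j <- match(s[t + lag], codes)
      m[i, j] <- m[i, j] + 1L
    }
  }
  m
}

# naive matrix power
brute_power <- function(P, k) {
  M <- diag(nrow(P))
  for (i in seq_len(k)) M <- M %*% P
  M
}

asd_chain_log <- function(n_events, seed, alphabet = behavior_alphabet(),
                          kernel = asd_kernel()) {
  set.seed(seed)
  st <- as.vector(simulate_markov(kernel, n_events, 1))
  seq_log(alphabet$code[st], alphabet)
}
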