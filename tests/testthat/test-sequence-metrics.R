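# Entropy, average sequence length, chain mining, group-difference tests.

test_that("bigram entropy hits analytic values on constructed sequences", {
  A <- "avoidance"; B <- "joint_attention"
  # strict alternation (odd length so AB and BA counts tie) -> exactly 1 bit
  alt <- seq_log(c(rep(c(A, B), 10), A))
  expect_equal(behavioral_entropy(alt)$H, 1)
  # constant sequence: degenerate distribution -> 0 bits
  expect_equal(behavioral_entropy(seq_log(rep(A, 12)))$H, 0)
  expect_equal(behavioral_entropy(seq_log(rep(A, 12)), "unigram")$H, 0)
  # iid-uniform 6-category stream converges to log2(36)
  ab <- behavior_alphabet()
  set.seed(5)
  big <- seq_log(sample(ab$code, 30000, TRUE))
  expect_equal(behavioral_entropy(big)$H, log2(36), tolerance = 0.02)
  expect_equal(behavioral_entropy(big, "unigram")$H, log2(6), tolerance = 0.01)
  expect_error(behavioral_entropy(seq_log(A)), "2 events")
})

test_that("entropy is bounded, maximized by uniformity, and label-invariant", {
  ab <- behavior_alphabet()
  set.seed(8)
  for (rep in 1:5) {
    s <- sample(ab$code[1:3], 40, TRUE)
    m <- behavioral_entropy(seq_log(s))
    expect_gte(m$H, 0)
    expect_lte(m$H, log2(m$n_cells) + 1e-12)
    # relabeling categories permutes cells but not entropy
    relab <- setNames(ab$code[c(4, 5, 6, 1, 2, 3)], ab$code)
    expect_equal(behavioral_entropy(seq_log(unname(relab[s])))$H, m$H)
  }
})

test_that("average sequence length partitions episodes at the gap threshold", {
  ab <- behavior_alphabet()
  A <- "avoidance"
  # episodes of 3 and 5 events -> asl 4
  d1 <- as.data.frame(seq_log(rep(A, 3)))
  d2 <- as.data.frame(seq_log(rep(A, 5), t0 = max(d1$offset) + 10))
  lg <- event_log(rbind(d1, d2), ab)
  expect_equal(average_sequence_length(lg), 4)
  # all gaps below threshold -> one episode of all events
  expect_equal(average_sequence_length(seq_log(rep(A, 7))), 7)
  expect_error(average_sequence_length(lg, gap_threshold = 0), "gap_threshold")
})

test_that("chain mining finds deterministic and planted chains", {
  ab <- behavior_alphabet()
  A <- "avoidance"; B <- "joint_attention"; C <- "emotional_sharing"
  # deterministic A -> B: probability 1
  lg <- cohort_log(list(c1 = c(A, B, C, A, B), c2 = c(A, B, A, B)))
  ch <- as.data.frame(mine_chains(lg))
  ab_row <- ch[ch$chain == paste(A, "->", B), ]
  expect_equal(ab_row$probability, 1)
  expect_equal(ab_row$support, 1)
  # order exceeding the longest episode -> empty table
  expect_equal(nrow(mine_chains(seq_log(c(A, B)), order = 5)), 0L)
  # support filter drops idiosyncratic chains
  lg2 <- cohort_log(list(c1 = c(A, B), c2 = c(A, B), c3 = c(C, C)))
  ch2 <- as.data.frame(mine_chains(lg2, min_support = 0.5))
  expect_false(paste(C, "->", C) %in% ch2$chain)
  expect_error(mine_chains(lg, order = 1), "order")
})

test_that("mined chain probabilities estimate the generating conditionals", {
  # cohort from the 7-category kernel with the avoidance->stereotypy loop
  ab7 <- behavior_alphabet("full7")
  P <- asd_kernel7()
  set.seed(31)
  rows <- lapply(1:20, function(i) {
    s <- as.vector(simulate_markov(P, 150, 1))
    as.data.frame(seq_log(ab7$code[s], ab7, child_id = sprintf("c%02d", i)))
  })
  lg <- event_log(do.call(rbind, rows), ab7)
  ch <- as.data.frame(mine_chains(lg, min_support = 0.5))
  expect_equal(ch$chain[1], "avoidance -> stereotypy")
  expect_equal(ch$probability[1], P["avoidance", "stereotypy"],
               tolerance = 0.05)
})

test_that("welch t reproduces the group-entropy contrast and scaling laws", {
  same <- list(mean = 2, sd = 0.5, n = 30)
  res0 <- welch_t(same, same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # printed group summaries: recomputed t is about -12.2 (not the printed value)
  res <- welch_t(list(mean = 2.14, sd = 0.32, n = 60),
                 list(mean = 3.08, sd = 0.41, n = 40))
  expect_equal(res$t, -12.2, tolerance = 0.01)
  expect_lt(res$p, 1e-10)
  # doubling both n scales |t| by sqrt(2)
  res2 <- welch_t(list(mean = 2.14, sd = 0.32, n = 120),
                  list(mean = 3.08, sd = 0.41, n = 80))
  expect_equal(res2$t / res$t, sqrt(2), tolerance = 1e-10)
  # agreement with stats::t.test on raw data
  set.seed(12)
  x <- rnorm(25, 1); y <- rnorm(35, 1.4, 2)
  mine <- welch_t(list(mean = mean(x), sd = sd(x), n = 25),
                  list(mean = mean(y), sd = sd(y), n = 35))
  ref <- t.test(x, y)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  pooled <- welch_t(list(mean = mean(x), sd = sd(x), n = 25),
                    list(mean = mean(y), sd = sd(y), n = 35), pooled = TRUE)
  refp <- t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$t, unname(refp$statistic), tolerance = 1e-10)
  expect_error(welch_t(list(mean = 1, sd = 0, n = 5),
                       list(mean = 2, sd = 0, n = 5)), "variance")
})

test_that("chi-square matches hand evaluation and flags degenerate margins", {
  expect_equal(chi_square(matrix(10, 2, 2))$statistic, 0)
  perfect <- chi_square(matrix(c(20, 0, 0, 20), 2, 2))
  expect_equal(perfect$statistic, 40)
  expect_equal(perfect$df, 1)
  # the printed 3x2 responder table recomputes to ~13.6 by direct evaluation
  tab <- matrix(c(21, 10, 16, 22, 5, 21), nrow = 3, byrow = TRUE)
  res <- chi_square(tab)
  hand <- sum((tab - res$expected)^2 / res$expected)
  expect_equal(res$statistic, hand, tolerance = 1e-12)
  expect_equal(res$statistic, 13.6, tolerance = 0.005)
  expect_equal(res$df, 2)
  # adjusted residuals: each 2x2 margin collapses consistently, and the
  # residual matrix has mean zero by construction symmetry
  expect_equal(dim(res$adjusted_residuals), dim(tab))
  expect_error(chi_square(matrix(c(0, 0, 1, 2), 2, 2)), "margin")
})
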