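# Event-log construction, preprocessing, durations, coder reliability.

test_that("alphabet presets carry the coding scheme and reject bad input", {
  ab <- behavior_alphabet()
  expect_equal(alphabet_size(ab), 6L)
  expect_equal(alphabet_size(behavior_alphabet("full7")), 7L)
  expect_equal(ab$min_duration[ab$code == "avoidance"], 3)
  expect_error(behavior_alphabet(categories = data.frame(
    code = c("a", "a"), display_name = c("A", "A"), min_duration = c(1, 1))),
    "unique")
  expect_error(behavior_alphabet(categories = data.frame(
    code = "a", display_name = "A", min_duration = -1)), "min_duration")
})

test_that("event log round-trips through file I/O and validates records", {
  ab <- behavior_alphabet()
  lg <- seq_log(c("avoidance", "joint_attention", "avoidance"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(lg, path)
  back <- read_event_log(path, ab)
  expect_equal(as.data.frame(back), as.data.frame(lg))
  expect_equal(nrow(back), 3L)

  # unknown category named in the error
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("child_id,session,category,onset_s,offset_s",
               "c1,1,flapping,0,2"), bad)
  expect_error(read_event_log(bad, ab), "flapping")

  # degenerate interval reported with its row
  deg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("child_id,session,category,onset_s,offset_s",
               "c1,1,avoidance,0,4", "c1,1,avoidance,5,5"), deg)
  expect_error(read_event_log(deg, ab), "row")

  # missing column is a format error
  mc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("child_id,category,onset_s,offset_s", "c1,avoidance,0,4"), mc)
  expect_error(read_event_log(mc, ab), "missing column")
})

test_that("event_log enforces ordering, alphabet membership and non-overlap", {
  ab <- behavior_alphabet()
  ev <- data.frame(child_id = "c", session = 1,
                   category = c("avoidance", "joint_attention"),
                   onset = c(10, 0), offset = c(14, 2))
  lg <- event_log(ev, ab)
  expect_equal(lg$onset, c(0, 10))  # sorted
  expect_error(event_log(transform(ev, category = c("avoidance", "nope")), ab),
               "nope")
  expect_error(event_log(data.frame(child_id = "c", session = 1,
                                    category = c("avoidance", "avoidance"),
                                    onset = c(0, 2), offset = c(4, 6)), ab),
               "overlap")
})

test_that("segment_events merges sub-threshold same-category gaps and drops short events", {
  ab <- behavior_alphabet()
  # two avoidance fragments 0.3 s apart -> one event spanning both
  ev <- data.frame(child_id = "c", session = 1,
                   category = c("avoidance", "avoidance"),
                   onset = c(0, 4.3), offset = c(4, 8))
  out <- segment_events(event_log(ev, ab))
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$onset, out$offset), c(0, 8))

  # 0.6 s gap stays unmerged
  ev2 <- transform(ev, onset = c(0, 4.6), offset = c(4, 8.6))
  expect_equal(nrow(segment_events(event_log(ev2, ab))), 2L)

  # 0.4 s avoidance event dies against its 3 s minimum duration
  short <- event_log(data.frame(child_id = "c", session = 1,
                                category = "avoidance", onset = 0,
                                offset = 0.4), ab)
  expect_equal(nrow(segment_events(short)), 0L)
  expect_error(segment_events(short, min_interval = -1), "min_interval")
})

test_that("segment_events is idempotent and never increases coded time", {
  ab <- behavior_alphabet()
  set.seed(42)
  for (rep in 1:5) {
    n <- 30
    onset <- cumsum(runif(n, 0.1, 3))
    dur <- runif(n, 0.2, 5)
    offset <- onset + pmin(dur, c(diff(onset), Inf) - 0.01)
    ev <- data.frame(child_id = "c", session = 1,
                     category = sample(ab$code, n, TRUE),
                     onset = onset, offset = pmax(offset, onset + 0.05))
    lg <- event_log(ev, ab)
    once <- segment_events(lg)
    twice <- segment_events(once)
    expect_equal(as.data.frame(twice), as.data.frame(once))
    expect_lte(total_coded_time(once), total_coded_time(lg) + 1e-9)
  }
})

test_that("mean_duration averages event durations and flags empty categories", {
  ab <- behavior_alphabet()
  ev <- data.frame(child_id = "c", session = 1,
                   category = c("avoidance", "avoidance"),
                   onset = c(0, 10), offset = c(2, 14))
  lg <- event_log(ev, ab)
  ds <- mean_duration(lg, "avoidance")
  expect_equal(ds$T, 3)        # mean of 2 and 4
  expect_equal(ds$N, 2L)
  expect_gte(ds$T, min(ds$durations))
  expect_lte(ds$T, max(ds$durations))
  empty <- mean_duration(lg, "joint_attention")
  expect_true(empty$undefined)
  expect_equal(empty$N, 0L)
  expect_error(mean_duration(lg, "nope"), "unknown")
})

test_that("kappa matches hand computation, relabeling invariance, and the e1071 oracle", {
  # identical codings
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a"))$kappa, 1)
  # 2x2 confusion [[45,5],[5,45]]: p_o = 0.9, p_e = 0.5 -> kappa = 0.8
  a <- rep(c("x", "x", "y", "y"), c(45, 5, 5, 45))
  b <- rep(c("x", "y", "x", "y"), c(45, 5, 5, 45))
  expect_equal(cohens_kappa(a, b)$kappa, 0.8)
  # invariant under relabeling applied to both coders
  relab <- c(x = "q", y = "r")
  expect_equal(cohens_kappa(relab[a], relab[b])$kappa, 0.8)
  # independent codings with uniform marginals -> kappa near 0
  set.seed(1)
  u <- sample(letters[1:4], 4000, TRUE)
  v <- sample(letters[1:4], 4000, TRUE)
  expect_lt(abs(cohens_kappa(u, v)$kappa), 0.05)
  expect_error(cohens_kappa(c("a"), c("a", "b")), "equal length")
  # constant identical codings: defined as 1
  expect_equal(cohens_kappa(rep("a", 5), rep("a", 5))$kappa, 1)
  skip_if_not_installed("e1071")
  tab <- table(a, b)
  expect_equal(cohens_kappa(a, b)$kappa,
               e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
})

test_that("ICC is 1 on identical ratings, penalizes shifts, and vanishes for noise", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(icc_agreement(x, x)$icc, 1)
  shifted <- icc_agreement(x, x + 2)
  expect_lt(shifted$icc, 1)      # absolute agreement penalizes the shift
  expect_gt(shifted$icc, 0)
  # hand ANOVA decomposition for a constant shift d: MSE = 0,
  # MSR = k * var(x), MSC = n * d^2 / 2, so
  # ICC = MSR / (MSR + (k/n) * MSC) = 5 / (5 + 4) here
  expect_equal(shifted$icc, 5 / 9)
  set.seed(2)
  noise <- icc_agreement(rnorm(2000), rnorm(2000))
  expect_lt(abs(noise$icc), 0.06)
  expect_error(icc_agreement(1, 1), "at least 2")
  expect_error(icc_agreement(1:3, 1:4), "equal length")
})
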