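# Bernoulli-mixture LCA: binarization, EM, information criteria, LMR,
# selection, label matching.

test_that("binarization rules split columns as documented", {
  M <- cbind(a = c(1, 2, 3, 4), b = c(-2, -1, 1, 2))
  X <- binarize_indicators(M)
  expect_equal(unname(X[, "a"]), c(0, 0, 1, 1))  # median split, ties low
  Xz <- binarize_indicators(M, "z>0")
  expect_equal(unname(Xz[, "b"]), c(0, 0, 1, 1))
  Xt <- binarize_indicators(M, rule = 0)
  expect_equal(unname(Xt[, "a"]), c(1, 1, 1, 1))  # any occurrence
  expect_error(binarize_indicators(cbind(a = rep(2, 4))), "constant")
  expect_error(binarize_indicators(cbind(a = c(1, NA))), "missing")
})

test_that("K=1 equals the closed form and EM log-likelihood never decreases", {
  set.seed(13)
  X <- matrix(rbinom(200, 1, 0.3), 50, 4)
  m1 <- fit_lca(X, 1)
  expect_equal(as.numeric(m1$theta), colMeans(X), tolerance = 1e-9)
  expect_equal(m1$rel_entropy, 1)
  m3 <- fit_lca(X, 3, restarts = 5, seed = 2)
  # monotone at every EM iteration of the best restart
  expect_true(all(diff(m3$loglik_trace) > -1e-8))
  expect_equal(sum(m3$pi), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(m3$posteriors)), rep(1, 50), tolerance = 1e-9)
  expect_true(all(m3$theta >= 1e-6 & m3$theta <= 1 - 1e-6))
  expect_error(fit_lca(matrix(c(0, 2), 2, 1), 1), "binary")
  expect_error(fit_lca(X, 51), "n > K")
})

test_that("a separable two-class structure is recovered exactly", {
  X <- rbind(matrix(1, 20, 5), matrix(0, 20, 5))
  m <- fit_lca(X, 2, restarts = 10, seed = 3)
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-6)
  th <- m$theta[, match_labels(m$theta, cbind(rep(1, 5), rep(0, 5)))]
  expect_true(all(th[, 1] > 0.999))
  expect_true(all(th[, 2] < 0.001))
  labs <- assign_classes(m)$labels
  expect_equal(length(unique(labs[1:20])), 1L)
  expect_true(labs[1] != labs[21])
})

test_that("information criteria match their formulas on a toy fit", {
  set.seed(14)
  X <- matrix(rbinom(60, 1, 0.5), 20, 3)
  m <- fit_lca(X, 2, restarts = 5, seed = 1)
  p <- 2 * 3 + 1
  expect_equal(m$n_params, p)
  expect_equal(m$bic, -2 * m$loglik + p * log(20), tolerance = 1e-12)
  expect_equal(m$aic, -2 * m$loglik + 2 * p, tolerance = 1e-12)
  ic <- information_criteria(m)
  expect_equal(ic$bic, m$bic)
  # uniform posteriors give zero relative entropy
  fake <- m; fake$posteriors <- matrix(0.5, 20, 2)
  re <- 1 - (-sum(fake$posteriors * log(fake$posteriors))) / (20 * log(2))
  expect_equal(re, 0, tolerance = 1e-12)
})

test_that("posterior ties break toward the lower class index", {
  m <- structure(list(K = 2, pi = c(0.5, 0.5),
                      theta = matrix(0.5, 2, 2),
                      posteriors = matrix(0.5, 3, 2)),
                 class = "lca_model")
  expect_equal(assign_classes(m)$labels, c(1L, 1L, 1L))
})

test_that("label matching equals brute force and undoes permutations", {
  set.seed(15)
  th <- matrix(runif(12), 4, 3)
  expect_equal(match_labels(th, th), 1:3)
  expect_equal(match_labels(th[, c(2, 3, 1)], th), c(3, 1, 2))
  # brute force over all 6 permutations on a noisy copy
  est <- pmin(pmax(th[, c(3, 1, 2)] + rnorm(12, 0, 0.05), 0), 1)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  costs <- vapply(perms, function(p) sum(abs(est[, p] - th)), 0)
  expect_equal(match_labels(est, th), perms[[which.min(costs)]])
  expect_error(match_labels(matrix(0.5, 2, 9), matrix(0.5, 2, 9)), "K > 8")
})

test_that("the three-class generator family is recovered within tolerance", {
  th <- default_indicator_theta()
  set.seed(160)
  ok_theta <- ok_pi <- logical(8)
  for (r in 1:8) {
    cls <- sample(colnames(th), 300, TRUE, prob = c(0.35, 0.40, 0.25))
    X <- generate_indicators(cls, th)
    m <- fit_lca(X, 3, restarts = 20)
    perm <- match_labels(m$theta, th)
    ok_theta[r] <- mean(abs(m$theta[, perm] - th)) <= 0.07
    emp <- prop.table(table(factor(cls, colnames(th))))
    ok_pi[r] <- max(abs(m$pi[perm] - as.numeric(emp))) <= 0.07
  }
  expect_gte(mean(ok_theta), 0.75)
  expect_gte(mean(ok_pi), 0.75)
})

test_that("likelihood-ratio tests separate adjacent class counts sensibly", {
  th <- default_indicator_theta()
  set.seed(17)
  cls <- sample(colnames(th), 300, TRUE, prob = c(0.35, 0.40, 0.25))
  X <- generate_indicators(cls, th)
  m2 <- fit_lca(X, 2, restarts = 10, seed = 4)
  m3 <- fit_lca(X, 3, restarts = 10, seed = 4)
  m4 <- fit_lca(X, 4, restarts = 10, seed = 4)
  p32 <- lmr_test(m3, m2)$p
  p43 <- lmr_test(m4, m3)$p
  expect_lt(p32, 0.01)   # true 3-class structure strongly supported
  expect_gt(p43, p32)    # overfitting step is weaker
  expect_error(lmr_test(m4, m2), "adjacent")
  # bootstrap variant: degenerate smoke case and a real small-B run
  pb <- lmr_test(m3, m2, variant = "bootstrap", B = 1, restarts = 3, seed = 9)$p
  expect_true(pb %in% c(0.5, 1))
  pb2 <- lmr_test(m3, m2, variant = "bootstrap", B = 19, restarts = 3,
                  seed = 9)$p
  expect_lte(pb2, 0.1)   # observed LR far beyond the null resamples
})

test_that("class-count selection scans k and applies the two-stage rule", {
  th <- default_indicator_theta()
  set.seed(18)
  cls <- sample(colnames(th), 300, TRUE, prob = c(0.35, 0.40, 0.25))
  X <- generate_indicators(cls, th)
  sel <- suppressWarnings(select_classes(X, 2, 5, restarts = 10, seed = 5))
  expect_equal(sel$chosen_k, 3)
  expect_equal(sel$table$k, 2:5)
  expect_true(all(diff(sel$table$loglik) > -1e-6))  # more classes never fit worse
  # single-k scan degenerates to that k
  sel2 <- select_classes(X, 2, 2, restarts = 5, seed = 5)
  expect_equal(sel2$chosen_k, 2)
  expect_equal(nrow(sel2$table), 1L)
  # one-class data: BIC prefers the smallest scanned k with unsupportive LMR
  set.seed(19)
  X1 <- matrix(rbinom(300 * 6, 1, rep(c(0.3, 0.6, 0.5, 0.2, 0.4, 0.7),
                                      each = 300)), 300, 6)
  sel1 <- suppressWarnings(select_classes(X1, 2, 3, restarts = 10, seed = 6))
  expect_equal(sel1$chosen_k, 2)
})
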