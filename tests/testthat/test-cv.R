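test_that("fold assignment is deterministic, stratified and Y-free", {
  site <- rep(c("A", "B", "C", "D"), each = 8)
  f1 <- make_folds(site, 7, seed = 3)
  f2 <- make_folds(site, 7, seed = 3)
  expect_identical(f1, f2)
  expect_true(all(tabulate(f1, 7) %in% 4:5))
  # each fold mixes sites
  for (k in 1:7) expect_gte(length(unique(site[f1 == k])), 2)
  expect_false(identical(f1, make_folds(site, 7, seed = 4)))
  # single-site data cannot be stratified
  expect_error(make_folds(rep("A", 10), 5, seed = 1), "single site")
  expect_error(make_folds(site, 1, seed = 1), "at least 2")
  # unstratified mode covers 1..k
  expect_setequal(unique(make_folds(NULL, 4, seed = 1, n = 12)), 1:4)
})

test_that("cross_validate equals the brute-force per-fold refit loop", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(15:25, 1); K <- sample(4:8, 1); M <- sample(2:5, 1)
    A <- sample(1:3, 1); folds <- sample(5:7, 1)
    b <- random_blocks(n, K, M, seed = 50 + s)
    cv <- cross_validate(b$X, b$Y, A, folds = folds, seed = s)
    bf <- brute_force_cv(b$X, b$Y, A, cv$fold)
    expect_lt(max(abs(cv$press - bf$press)), 1e-10)
    expect_lt(max(abs(cv$ss0 - bf$ss0)), 1e-10)
    expect_lt(max(abs(cv$q2y - bf$q2y)), 1e-10)
    expect_lt(abs(cv$q2cum - bf$q2cum), 1e-10)
    # invariant identities
    expect_equal(cv$q2y, 1 - cv$press / cv$ss0, tolerance = 1e-12)
    expect_equal(cv$q2cum, 1 - sum(cv$press) / sum(cv$ss0),
                 tolerance = 1e-12)
  }
})

test_that("near-perfect signal gives Q2 near one under leave-one-out", {
  set.seed(11)
  X <- matrix(rnorm(20 * 5), 20)
  y <- cbind(dup = X[, 2] + 0.05 * rnorm(20))
  cv <- cross_validate(X, y, 3, folds = 20, seed = 1)
  expect_gt(cv$q2y[["dup"]], 0.95)
})

test_that("independent noise responses have negative mean Q2", {
  set.seed(12)
  q2 <- replicate(50, {
    X <- matrix(rnorm(24 * 6), 24)
    Y <- matrix(rnorm(24 * 3), 24)
    mean(cross_validate(X, Y, 2, folds = 6,
                        seed = sample.int(1e6, 1))$q2y)
  })
  expect_lt(mean(q2), 0)
})

test_that("CV-ANOVA matches the F-distribution arithmetic", {
  fake <- structure(list(n = 32, ncomp = 3, responses = "r1",
                         press = c(r1 = 4), ss0 = c(r1 = 10)),
                    class = "cv_result")
  out <- cv_anova(fake)
  F_ref <- ((10 - 4) / 3) / (4 / (32 - 3 - 1))
  expect_equal(out$F, F_ref, tolerance = 1e-12)
  expect_equal(out$p, stats::pf(F_ref, 3, 28, lower.tail = FALSE),
               tolerance = 1e-10)

  # no predictive gain: F = 0, p = 1
  tie <- structure(list(n = 20, ncomp = 2, responses = "r1",
                        press = c(r1 = 5), ss0 = c(r1 = 5)),
                   class = "cv_result")
  expect_equal(cv_anova(tie)$F, 0)
  expect_equal(cv_anova(tie)$p, 1)

  # perfect prediction limit: p -> 0
  perfect <- structure(list(n = 20, ncomp = 2, responses = "r1",
                            press = c(r1 = 0), ss0 = c(r1 = 5)),
                       class = "cv_result")
  expect_equal(cv_anova(perfect)$p, 0)

  # p monotone decreasing in F at fixed df
  Fs <- seq(0, 10, by = 0.5)
  ps <- stats::pf(Fs, 3, 28, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))

  small <- structure(list(n = 3, ncomp = 2, responses = "r1",
                          press = c(r1 = 1), ss0 = c(r1 = 2)),
                     class = "cv_result")
  expect_error(cv_anova(small), "n > ncomp")
})

test_that("VIP satisfies its normalization identities", {
  # K = 1: VIP is exactly 1
  set.seed(3)
  x1 <- matrix(rnorm(12), 12, 1)
  y <- x1 + 0.1 * rnorm(12)
  expect_equal(unname(compute_vip(fit_pls(x1, y, 1))), 1)
  # mean squared VIP = 1 for arbitrary fits
  for (s in 1:4) {
    b <- random_blocks(n = 15, K = 3 + s, M = 3, seed = 200 + s)
    v <- compute_vip(fit_pls(b$X, b$Y, 2))
    expect_lt(abs(mean(v^2) - 1), 1e-10)
  }
})

test_that("one-component VIP reduces to the scaled weight formula", {
  b <- random_blocks(n = 12, K = 3, M = 2, seed = 9)
  m <- fit_pls(b$X, b$Y, 1)
  w <- m$W[, 1]
  expect_equal(unname(compute_vip(m)),
               unname(sqrt(3) * abs(w) / sqrt(sum(w^2))), tolerance = 1e-12)
})

test_that("jackknife VIP inference flags a planted strong predictor", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 32
    site_score <- rep(rnorm(4), each = 8)
    X <- matrix(rnorm(n * 10), n,
                dimnames = list(NULL, sprintf("x%d", 1:10)))
    X[, 1] <- site_score + 0.3 * rnorm(n)
    Y <- cbind(r = site_score + 0.2 * rnorm(n))
    v <- vip_significance(X, Y, 1, folds = 7, seed = s,
                          site = rep(paste0("S", 1:4), each = 8))
    v$table$p[v$table$variable == "x1"] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("a variable with VIP pinned at 1 in every fold gets p = 1", {
  # K = 1 forces VIP = 1 exactly in the full model and every fold model,
  # so the jackknife se is 0 and the convention yields p = 1
  set.seed(13)
  x <- matrix(rnorm(24), 24, 1, dimnames = list(NULL, "only"))
  y <- cbind(r = x[, 1] + 0.3 * rnorm(24))
  v <- vip_significance(x, y, 1, folds = 6, seed = 1)
  expect_equal(v$table$vip, 1)
  expect_equal(v$table$se, 0)
  expect_equal(v$table$p, 1)
})

test_that("loading signs report the construction direction", {
  set.seed(21)
  n <- 32
  site_score <- rep(c(-1.5, -0.5, 0.5, 1.5), each = 8)
  X <- matrix(rnorm(n * 6), n, dimnames = list(NULL, sprintf("x%d", 1:6)))
  X[, 1] <- site_score + 0.2 * rnorm(n)     # correlates + with the factor
  X[, 2] <- -site_score + 0.2 * rnorm(n)    # correlates - with the factor
  Y <- cbind(r = site_score + 0.1 * rnorm(n))
  v <- vip_significance(X, Y, 1, folds = 7, seed = 2,
                        site = rep(paste0("S", 1:4), each = 8))
  expect_true(v$loading_sign["x1", 1] != v$loading_sign["x2", 1])
  expect_setequal(unname(v$loading_sign[c("x1", "x2"), 1]), c("+", "-"))
})
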