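# Small study shapes used across the suite (full-size defaults are exercised
# in the acceptance tests).
small_config <- function(seed = 1, ...) {
  args <- list(n_sites = 4, n_events_per_site = 4, n_analytes = 30,
               frac_never_detected = 0.5, n_active_contaminants = 5,
               n_samples_per_site = 4, n_metabolites = 40,
               n_responsive_metabolites = 10, effect_size = 3, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# random named X/Y blocks
random_blocks <- function(n, K, M, seed) {
  set.seed(seed)
  list(X = matrix(rnorm(n * K), n, K,
                  dimnames = list(NULL, sprintf("x%d", seq_len(K)))),
       Y = matrix(rnorm(n * M), n, M,
                  dimnames = list(NULL, sprintf("y%d", seq_len(M)))))
}

# independent cross-validation bookkeeping: manual per-fold refit loop
brute_force_cv <- function(X, Y, ncomp, fold) {
  Y <- as.matrix(Y)
  M <- ncol(Y)
  press <- numeric(M)
  ss0 <- numeric(M)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    m <- fit_pls(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], ncomp)
    yhat <- predict(m, X[!tr, , drop = FALSE], ncomp = ncomp)
    press <- press + colSums((Y[!tr, , drop = FALSE] - yhat)^2)
    mu <- colMeans(Y[tr, , drop = FALSE])
    ss0 <- ss0 + colSums(sweep(Y[!tr, , drop = FALSE], 2, mu, "-")^2)
  }
  list(press = press, ss0 = ss0, q2y = 1 - press / ss0,
       q2cum = 1 - sum(press) / sum(ss0))
}

# inverse of the compact letter display: letters -> set of site pairs
decode_letter_pairs <- function(strings) {
  shared <- unique(unlist(strsplit(unname(strings), "")))
  pairs <- lapply(sort(shared), function(l) {
    members <- names(strings)[vapply(strings, function(s) {
      l %in% strsplit(s, "")[[1]]
    }, logical(1))]
    stopifnot(length(members) == 2)
    sort(members)
  })
  unique(pairs)
}

# one-way ANOVA F and Tukey-Kramer adjusted p computed from first principles
# (explicit sums of squares + ptukey), independent of aov()/TukeyHSD()
reference_anova_tukey <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  n <- length(y)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  grand <- mean(y)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  df1 <- k - 1
  df2 <- n - k
  ms_within <- ss_within / df2
  Fstat <- (ss_between / df1) / ms_within
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  combs <- utils::combn(levels(g), 2)
  tukey <- apply(combs, 2, function(pr) {
    se <- sqrt(ms_within / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    q <- abs(means[pr[1]] - means[pr[2]]) / se
    stats::ptukey(q, k, df2, lower.tail = FALSE)
  })
  names(tukey) <- apply(combs, 2, paste, collapse = "-")
  list(F = Fstat, p = p, tukey = tukey)
}
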