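#' Deterministic (optionally site-stratified) fold assignment
#'
#' Assigns samples to `k` cross-validation folds. With site labels supplied,
#' samples are shuffled within site (seeded) and dealt round-robin across the
#' folds in site order, so every fold mixes sites and fold sizes differ by at
#' most one. The assignment depends only on `(n, k, seed, site labels)` --
#' never on any response values.
#'
#' @param site Character vector of site labels (or `NULL` for unstratified
#'   assignment); its length sets the number of samples.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @param n Number of samples when `site` is `NULL`.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(site, k, seed, n = length(site)) {
  k <- as.integer(k)
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  if (n < k) stop("more folds than samples", call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  if (is.null(site)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    ord <- unlist(lapply(split(seq_len(n), site), function(ix) {
      if (length(ix) == 1) ix else sample(ix)
    }), use.names = FALSE)
    fold[ord] <- rep_len(seq_len(k), n)
    for (f in seq_len(k)) {
      if (length(unique(site[fold == f])) < 2) {
        stop("fold ", f, " would contain samples from a single site; ",
             "use fewer folds or unstratified assignment", call. = FALSE)
      }
    }
  }
  fold
}

#' Cross-validated predictive assessment of a PLS model
#'
#' For each fold, centering/scaling and the PLS fit are redone on the
#' training samples only (no leakage), the held-out samples are predicted,
#' and squared errors are accumulated on the original Y scale. Per response
#' `j`, `PRESS_j` is the held-out squared error of the model and `SS0_j` the
#' held-out squared error of the training-fold mean (the cross-validated
#' null model), giving `Q2Y_j = 1 - PRESS_j / SS0_j` and the pooled
#' `Q2Cum = 1 - sum(PRESS) / sum(SS0)`. Per-response CV-ANOVA F statistics
#' and p-values (see [cv_anova()]) are attached.
#'
#' A response with `SS0 = 0` (constant across held-out samples and training
#' means) carries no information; it gets `Q2Y = 0`, `F = 0`, `p = 1` by
#' convention.
#'
#' @param X,Y Numeric blocks, samples in rows.
#' @param ncomp Number of PLS components.
#' @param folds Number of folds (default 7, the usual chemometrics choice).
#' @param seed Seed for the fold assignment.
#' @param site Optional site labels for stratified folds.
#' @param scale Scaling policy, see [autoscale()].
#' @param keep_models Keep the per-fold `pls_model`s (used for jackknife VIP
#'   inference).
#' @return An object of class `cv_result`: fold assignment, `press`, `ss0`,
#'   `q2y`, `q2cum`, `q2cum_by_ncomp` (cumulative Q2 at 1..ncomp
#'   components), `F`, `p`, `df`, and optionally `models`.
#' @export
cross_validate <- function(X, Y, ncomp, folds = 7, seed = 1, site = NULL,
                           scale = "uv", keep_models = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); M <- ncol(Y)
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("y%d", seq_len(M))
  fold <- make_folds(site, folds, seed, n = n)
  ncomp <- as.integer(ncomp)
  min_train <- n - max(tabulate(fold, nbins = folds))
  if (ncomp > min(min_train - 1, ncol(X))) {
    stop("ncomp too large for the training folds", call. = FALSE)
  }
  press <- matrix(0, ncomp, M)
  ss0 <- numeric(M)
  models <- if (keep_models) vector("list", folds) else NULL
  for (f in seq_len(folds)) {
    tr <- fold != f
    m <- fit_pls(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], ncomp,
                 scale = scale)
    Yte <- Y[!tr, , drop = FALSE]
    for (a in seq_len(ncomp)) {
      yhat <- predict(m, X[!tr, , drop = FALSE], ncomp = a)
      press[a, ] <- press[a, ] + colSums((Yte - yhat)^2)
    }
    mu_tr <- colMeans(Y[tr, , drop = FALSE])
    ss0 <- ss0 + colSums(sweep(Yte, 2, mu_tr, "-")^2)
    if (keep_models) models[[f]] <- m
  }
  informative <- ss0 > 0
  q2y <- ifelse(informative, 1 - press[ncomp, ] / ss0, 0)
  q2cum_by_ncomp <- if (any(informative)) {
    1 - rowSums(press[, informative, drop = FALSE]) / sum(ss0[informative])
  } else {
    rep(0, ncomp)
  }
  res <- structure(list(
    fold = fold, ncomp = ncomp, n = n, folds = folds, seed = seed,
    responses = colnames(Y),
    press = stats::setNames(press[ncomp, ], colnames(Y)),
    ss0 = stats::setNames(ss0, colnames(Y)),
    q2y = stats::setNames(q2y, colnames(Y)),
    q2cum = q2cum_by_ncomp[ncomp],
    q2cum_by_ncomp = q2cum_by_ncomp,
    informative = stats::setNames(informative, colnames(Y)),
    models = models), class = "cv_result")
  ft <- cv_anova(res)
  res$F <- stats::setNames(ft$F, colnames(Y))
  res$p <- stats::setNames(ft$p, colnames(Y))
  res$df <- c(ncomp, n - ncomp - 1)
  res
}

#' CV-ANOVA significance of cross-validated predictions
#'
#' Per-response F test comparing the cross-validated residuals of the PLS
#' model against those of the null (training-mean) model:
#' `F_j = ((SS0_j - PRESS_j) / A) / (PRESS_j / (n - A - 1))`, clamped at 0
#' when the model does not beat the mean, with p the upper tail of the F
#' distribution on `(A, n - A - 1)` degrees of freedom. Responses with
#' `SS0 = 0` get `F = 0`, `p = 1`.
#'
#' @param cv A `cv_result`.
#' @param response Optional response name(s) to return; default all.
#' @return A tibble with columns `response`, `F`, `p`.
#' @export
cv_anova <- function(cv, response = NULL) {
  n <- cv$n; A <- cv$ncomp
  if (n <= A + 1) {
    stop("CV-ANOVA needs n > ncomp + 1", call. = FALSE)
  }
  press <- cv$press; ss0 <- cv$ss0
  Fv <- ifelse(ss0 > 0 & press > 0,
               pmax(0, (ss0 - press) / A) / (press / (n - A - 1)),
               ifelse(ss0 > 0 & press == 0, Inf, 0))
  p <- ifelse(ss0 > 0, stats::pf(Fv, A, n - A - 1, lower.tail = FALSE), 1)
  out <- tibble::tibble(response = cv$responses, F = unname(Fv),
                        p = unname(p))
  if (!is.null(response)) out <- out[match(response, out$response), ]
  out
}

#' Choose the number of PLS components by cross-validated gain
#'
#' Adds component `a` as long as the cumulative Q2 improves by at least
#' `gain_threshold` over `a - 1` and `a` does not exceed `max_ncomp`;
#' at least one component is always returned. A single cross-validation at
#' the upper bound supplies the whole gain curve, because NIPALS components
#' are computed sequentially.
#'
#' @inheritParams cross_validate
#' @param gain_threshold Minimum Q2Cum gain to accept one more component.
#' @param max_ncomp Upper bound; default `min(n - 1, ncol(X), 10)` capped by
#'   the training-fold size.
#' @return Integer number of components.
#' @export
choose_components <- function(X, Y, folds = 7, seed = 1,
                              gain_threshold = 0.01, max_ncomp = NULL,
                              site = NULL, scale = "uv") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  fold <- make_folds(site, folds, seed, n = n)
  min_train <- n - max(tabulate(fold, nbins = folds))
  upper <- min(n - 1, ncol(X), 10, min_train - 1)
  if (!is.null(max_ncomp)) upper <- min(upper, max_ncomp)
  upper <- max(upper, 1)
  cv <- NULL
  while (is.null(cv) && upper >= 1) {
    cv <- tryCatch(
      cross_validate(X, Y, upper, folds = folds, seed = seed, site = site,
                     scale = scale),
      error = function(e) NULL)
    if (is.null(cv)) upper <- upper - 1
  }
  if (is.null(cv)) stop("could not cross-validate even one component",
                        call. = FALSE)
  a <- 1
  while (a < upper &&
         cv$q2cum_by_ncomp[a + 1] - cv$q2cum_by_ncomp[a] >= gain_threshold) {
    a <- a + 1
  }
  a
}

#' VIP scores with jackknife significance and loading signs
#'
#' Computes VIP on the full-data model, then recomputes it on each
#' cross-validation fold's training model and derives a delete-one-group
#' jackknife standard error per variable. The test is one-sided against the
#' null `VIP <= 1` ("no more important than average"):
#' `t_k = (VIP_k - 1) / se_k` on `folds - 1` degrees of freedom. Variables
#' whose importance is stable across folds and clearly above 1 get small p.
#' When `se = 0`, p is 0 if VIP > 1 and 1 otherwise, by convention. The sign
#' of each variable's X-loading on components 1 and 2 (`+`, `-`, or `0` for
#' magnitudes below 1e-10) is reported alongside, as biomarker tables
#' conventionally state the direction in which a variable loads.
#'
#' @inheritParams cross_validate
#' @return An object of class `vip_result`: `table` (tibble: variable, vip,
#'   se, statistic, df, p), `loading_sign` (variables x components matrix of
#'   `"+"`, `"-"`, `"0"`), and the full-data `model`.
#' @export
vip_significance <- function(X, Y, ncomp, folds = 7, seed = 1, site = NULL,
                             scale = "uv") {
  full <- fit_pls(X, Y, ncomp, scale = scale)
  vip_full <- compute_vip(full)
  cv <- cross_validate(X, Y, ncomp, folds = folds, seed = seed, site = site,
                       scale = scale, keep_models = TRUE)
  vips <- vapply(cv$models, compute_vip, numeric(length(vip_full)))
  if (is.null(dim(vips))) vips <- matrix(vips, nrow = 1)
  g <- length(cv$models)
  vbar <- rowMeans(vips)
  se <- sqrt((g - 1) / g * rowSums((vips - vbar)^2))
  tstat <- ifelse(se > 0, (vip_full - 1) / se,
                  ifelse(vip_full > 1, Inf, -Inf))
  p <- ifelse(se > 0, stats::pt(tstat, df = g - 1, lower.tail = FALSE),
              ifelse(vip_full > 1, 0, 1))
  n_sign <- min(2L, full$ncomp)
  sgn <- matrix("0", length(vip_full), n_sign,
                dimnames = list(names(vip_full),
                                paste0("comp", seq_len(n_sign))))
  for (a in seq_len(n_sign)) {
    lo <- full$P[, a]
    sgn[lo > 1e-10, a] <- "+"
    sgn[lo < -1e-10, a] <- "-"
  }
  structure(list(
    table = tibble::tibble(variable = names(vip_full),
                           vip = unname(vip_full), se = unname(se),
                           statistic = unname(tstat), df = g - 1,
                           p = unname(p)),
    loading_sign = sgn, model = full, cv = cv), class = "vip_result")
}

#' @export
print.vip_result <- function(x, ...) {
  cat("<vip_result>\n")
  n_sig <- sum(x$table$vip >= 1 & x$table$p < 0.05)
  cat(sprintf("  %d X variables; %d with VIP >= 1 and p < 0.05\n",
              nrow(x$table), n_sig))
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>\n")
  cat(sprintf("  %d samples, %d responses, %d components, %d folds\n",
              x$n, length(x$responses), x$ncomp, x$folds))
  cat(sprintf("  Q2Cum = %.3f; Q2Y range [%.3f, %.3f]\n", x$q2cum,
              min(x$q2y), max(x$q2y)))
  invisible(x)
}
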