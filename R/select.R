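# shared per-step assessment: pick a component count, cross-validate
assess_response_set <- function(X, Ysub, folds, seed, site, scale,
                                ncomp = NULL, gain_threshold = 0.01) {
  a <- if (is.null(ncomp)) {
    choose_components(X, Ysub, folds = folds, seed = seed, site = site,
                      scale = scale, gain_threshold = gain_threshold)
  } else {
    fold <- make_folds(site, folds, seed, n = nrow(X))
    min_train <- nrow(X) - max(tabulate(fold, nbins = folds))
    min(as.integer(ncomp), min_train - 1, ncol(X))
  }
  cv <- cross_validate(X, Ysub, a, folds = folds, seed = seed, site = site,
                       scale = scale)
  list(ncomp = a, cv = cv)
}

#' Backward elimination of responses by CV-ANOVA
#'
#' The elimination phase of the response-selection algorithm: fit the PLS
#' model on the current response set, compute per-response CV-ANOVA
#' p-values, and remove *all* eligible responses with `p > alpha`
#' simultaneously; iterate until a fixed point. Responses named in
#' `force_keep` (typically `"temperature"`) are never removed. The number of
#' components is re-chosen by [choose_components()] at every iteration
#' unless `ncomp` pins it.
#'
#' @param X Explanatory block (samples x variables), e.g. the screened
#'   metabolites.
#' @param Y Response block (samples x responses) with column names.
#' @param alpha Significance level for exclusion (default 0.05).
#' @param folds,seed,site,scale Cross-validation settings, see
#'   [cross_validate()].
#' @param ncomp Fixed component count, or `NULL` to re-choose each step.
#' @param force_keep Response names never eligible for removal.
#' @param gain_threshold Passed to [choose_components()].
#' @return A partial `selection_trace` (list with `global`, `elimination`,
#'   `post_elimination`); feed it to [forward_reintroduce()].
#' @export
backward_eliminate <- function(X, Y, alpha = 0.05, folds = 7, seed = 1,
                               site = NULL, scale = "uv", ncomp = NULL,
                               force_keep = character(),
                               gain_threshold = 0.01) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(Y))) stop("Y must have column names", call. = FALSE)
  if (ncol(Y) < 1) stop("need at least one response", call. = FALSE)
  force_keep <- intersect(force_keep, colnames(Y))

  glob <- assess_response_set(X, Y, folds, seed, site, scale, ncomp,
                              gain_threshold)
  global <- list(ncomp = glob$ncomp, q2y = glob$cv$q2y,
                 p = glob$cv$p, q2cum = glob$cv$q2cum)

  retained <- colnames(Y)
  iterations <- list()
  cv_cur <- glob$cv; a_cur <- glob$ncomp
  repeat {
    p <- cv_cur$p[retained]
    removable <- retained[p > alpha & !(retained %in% force_keep)]
    iterations[[length(iterations) + 1]] <- list(
      retained_before = retained,
      removed = tibble::tibble(response = removable,
                               p = unname(p[removable])),
      q2cum = cv_cur$q2cum, ncomp = a_cur)
    if (length(removable) == 0) break
    retained <- setdiff(retained, removable)
    if (length(retained) == 0) break
    step <- assess_response_set(X, Y[, retained, drop = FALSE], folds, seed,
                                site, scale, ncomp, gain_threshold)
    cv_cur <- step$cv; a_cur <- step$ncomp
  }
  post <- if (length(retained) > 0) {
    list(retained = retained, q2cum = cv_cur$q2cum, ncomp = a_cur,
         q2y = cv_cur$q2y[retained], p = cv_cur$p[retained])
  } else {
    list(retained = character(), q2cum = -Inf, ncomp = NA_integer_,
         q2y = numeric(), p = numeric())
  }
  structure(list(global = global, elimination = iterations,
                 post_elimination = post,
                 settings = list(alpha = alpha, folds = folds, seed = seed,
                                 scale = scale, ncomp = ncomp,
                                 force_keep = force_keep,
                                 gain_threshold = gain_threshold)),
            class = "selection_trace")
}

#' One-by-one re-introduction of eliminated responses
#'
#' The recovery phase: every response excluded during elimination is offered
#' back to the model one at a time, in descending order of its Q2Y in the
#' global (all-response) model with ties broken lexicographically. A
#' candidate is retained only under the dual criterion: its own CV-ANOVA
#' p-value in the augmented model is below `alpha` *and* the cumulative Q2
#' strictly increases. Accepted candidates stay in the model for all
#' subsequent trials. Every decision is recorded.
#'
#' @inheritParams backward_eliminate
#' @param trace A partial `selection_trace` from [backward_eliminate()].
#' @return The completed `selection_trace` with `reintroduction` and `final`
#'   elements.
#' @export
forward_reintroduce <- function(X, Y, trace, alpha = trace$settings$alpha,
                                folds = trace$settings$folds,
                                seed = trace$settings$seed,
                                site = NULL, scale = trace$settings$scale,
                                ncomp = trace$settings$ncomp,
                                gain_threshold = trace$settings$gain_threshold) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  retained <- trace$post_elimination$retained
  excluded <- setdiff(colnames(Y), retained)
  gq <- trace$global$q2y[excluded]
  ord <- order(-gq, excluded)
  excluded <- excluded[ord]

  q2cum_cur <- trace$post_elimination$q2cum
  decisions <- list()
  for (i in seq_along(excluded)) {
    cand <- excluded[i]
    Ytry <- Y[, c(retained, cand), drop = FALSE]
    step <- assess_response_set(X, Ytry, folds, seed, site, scale, ncomp,
                                gain_threshold)
    p_cand <- unname(step$cv$p[cand])
    accepted <- p_cand < alpha && step$cv$q2cum > q2cum_cur
    decisions[[i]] <- tibble::tibble(
      order_index = i, candidate = cand, p = p_cand,
      q2cum_before = q2cum_cur, q2cum_with = step$cv$q2cum,
      ncomp = step$ncomp, accepted = accepted)
    if (accepted) {
      retained <- c(retained, cand)
      q2cum_cur <- step$cv$q2cum
    }
  }
  trace$reintroduction <- if (length(decisions) > 0) {
    dplyr::bind_rows(decisions)
  } else {
    tibble::tibble(order_index = integer(), candidate = character(),
                   p = numeric(), q2cum_before = numeric(),
                   q2cum_with = numeric(), ncomp = integer(),
                   accepted = logical())
  }
  final <- if (length(retained) > 0) {
    fin <- assess_response_set(X, Y[, retained, drop = FALSE], folds, seed,
                               site, scale, ncomp, gain_threshold)
    list(responses = retained, q2y = fin$cv$q2y, p = fin$cv$p,
         q2cum = fin$cv$q2cum, ncomp = fin$ncomp)
  } else {
    list(responses = character(), q2y = numeric(), p = numeric(),
         q2cum = -Inf, ncomp = NA_integer_)
  }
  trace$final <- final
  validate_selection_trace(trace)
  trace
}

#' Select the contaminants that covary with the metabolome
#'
#' The full selection algorithm: [backward_eliminate()] followed by
#' [forward_reintroduce()], returning the completed trace together with a
#' ranked table of the final responses sorted by Q2Y descending (strongest
#' contaminant-metabolome relationship first), the ordering convention of
#' published prioritization tables.
#'
#' @inheritParams backward_eliminate
#' @return A completed `selection_trace` whose `ranking` element is a tibble
#'   with columns `response`, `q2y`, `p`, `force_keep`.
#' @export
select_contaminants <- function(X, Y, alpha = 0.05, folds = 7, seed = 1,
                                site = NULL, scale = "uv", ncomp = NULL,
                                force_keep = "temperature",
                                gain_threshold = 0.01) {
  if (inherits(Y, "response_block")) {
    if (is.null(site)) site <- Y$site
    force_keep <- union(force_keep, Y$force_keep)
    Y <- Y$values
  }
  if (inherits(X, "metabolite_matrix")) X <- X$values
  trace <- backward_eliminate(X, Y, alpha = alpha, folds = folds,
                              seed = seed, site = site, scale = scale,
                              ncomp = ncomp, force_keep = force_keep,
                              gain_threshold = gain_threshold)
  trace <- forward_reintroduce(X, Y, trace, site = site)
  trace$ranking <- ranked_responses(trace)
  trace
}

#' Ranked table of selected responses
#'
#' @param trace A completed `selection_trace`.
#' @return Tibble with `response`, `q2y`, `p`, `force_keep`, sorted by Q2Y
#'   descending, ties lexicographic by response name.
#' @export
ranked_responses <- function(trace) {
  fin <- trace$final
  if (length(fin$responses) == 0) {
    return(tibble::tibble(response = character(), q2y = numeric(),
                          p = numeric(), force_keep = logical()))
  }
  out <- tibble::tibble(response = fin$responses,
                        q2y = unname(fin$q2y[fin$responses]),
                        p = unname(fin$p[fin$responses]),
                        force_keep = fin$responses %in%
                          trace$settings$force_keep)
  out[order(-out$q2y, out$response), ]
}

#' Assert the structural invariants of a selection trace
#'
#' Checks the algorithm's contract: retained sets strictly shrink across
#' elimination iterations until the fixed point; every accepted
#' re-introduction satisfied the dual criterion (p < alpha and strict Q2Cum
#' increase); and the final Q2Cum is at least the post-elimination Q2Cum.
#' Called automatically at the end of [forward_reintroduce()]; errors on any
#' violation.
#'
#' @param trace A completed `selection_trace`.
#' @return The trace, invisibly, when all invariants hold.
#' @export
validate_selection_trace <- function(trace) {
  alpha <- trace$settings$alpha
  its <- trace$elimination
  for (i in seq_along(its)) {
    if (i < length(its)) {
      if (nrow(its[[i]]$removed) == 0) {
        stop("elimination iteration ", i, " removed nothing but was not ",
             "the fixed point", call. = FALSE)
      }
      nxt <- its[[i + 1]]$retained_before
      expected <- setdiff(its[[i]]$retained_before, its[[i]]$removed$response)
      if (!setequal(nxt, expected) ||
          length(nxt) >= length(its[[i]]$retained_before)) {
        stop("retained sets do not strictly shrink at iteration ", i,
             call. = FALSE)
      }
    }
    if (any(its[[i]]$removed$p <= alpha)) {
      stop("iteration ", i, " removed a response with p <= alpha",
           call. = FALSE)
    }
  }
  if (!is.null(trace$reintroduction) && nrow(trace$reintroduction) > 0) {
    acc <- trace$reintroduction[trace$reintroduction$accepted, ]
    if (any(acc$p >= alpha) || any(acc$q2cum_with <= acc$q2cum_before)) {
      stop("an accepted re-introduction violates the dual criterion",
           call. = FALSE)
    }
  }
  if (!is.null(trace$final)) {
    if (trace$final$q2cum < trace$post_elimination$q2cum - 1e-9) {
      stop("final Q2Cum fell below the post-elimination Q2Cum",
           call. = FALSE)
    }
  }
  invisible(trace)
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace>\n")
  n_rem <- sum(vapply(x$elimination, function(it) nrow(it$removed),
                      integer(1)))
  n_iter <- sum(vapply(x$elimination, function(it) nrow(it$removed) > 0,
                       logical(1)))
  cat(sprintf("  elimination: %d response(s) removed over %d iteration(s)\n",
              n_rem, n_iter))
  if (!is.null(x$reintroduction)) {
    cat(sprintf("  re-introduction: %d of %d candidates accepted\n",
                sum(x$reintroduction$accepted), nrow(x$reintroduction)))
  }
  if (!is.null(x$final)) {
    cat(sprintf("  final: %d response(s), Q2Cum = %.3f (global %.3f)\n",
                length(x$final$responses), x$final$q2cum, x$global$q2cum))
  }
  invisible(x)
}
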