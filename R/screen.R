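#' Screen metabolites for site differences by one-way ANOVA
#'
#' Runs a fixed-effects one-way ANOVA of each metabolite across deployment
#' sites, followed by Tukey's honestly-significant-difference test on all
#' site pairs (the Tukey-Kramer form when group sizes are unequal). The
#' screened subset -- metabolites with omnibus p below `alpha` -- is the
#' explanatory block used downstream in the PLS model. Tukey pairwise
#' p-values are computed for every metabolite regardless of the omnibus
#' result; only `selected` uses the omnibus p.
#'
#' Degenerate metabolites with zero within-group variance are flagged and
#' assigned p by continuity convention: 0 when any group means differ
#' (certain difference), 1 when all means are equal.
#'
#' @param mm A normalized, complete (imputed) [metabolite_matrix()].
#' @param alpha Omnibus significance level for selection (default 0.05).
#' @param log_transform Apply `log()` before testing (default FALSE: the
#'   median-scaled abundances are tested as-is).
#' @param site_order Fixed site ordering used for pair enumeration and table
#'   columns; defaults to sorted unique site labels.
#'
#' @return An object of class `screen_result`: list with `stats` (tibble:
#'   metabolite, F, p, zero_variance, selected), `group_means` (sites x
#'   metabolites), `pairwise` (site-pair x metabolite matrix of Tukey
#'   adjusted p, rows named `"A-B"`), `selected` (character vector),
#'   `sites`, `alpha`.
#' @seealso [letter_pairs()], [screen_table()]
#' @export
anova_screen <- function(mm, alpha = 0.05, log_transform = FALSE,
                         site_order = NULL) {
  if (mm$normalized == "none") {
    stop("screen expects a normalized matrix", call. = FALSE)
  }
  if (any(is.na(mm$values))) {
    stop("screen expects a complete matrix; run impute_missing() first",
         call. = FALSE)
  }
  site <- mm$sample_info$site
  if (is.null(site_order)) site_order <- sort(unique(site))
  if (!setequal(site_order, unique(site))) {
    stop("site_order must name exactly the sites present", call. = FALSE)
  }
  g <- factor(site, levels = site_order)
  n_per <- table(g)
  if (length(n_per) < 2 || any(n_per < 2)) {
    stop("need at least 2 sites with at least 2 samples each", call. = FALSE)
  }
  v <- mm$values
  if (log_transform) v <- log(v)
  mets <- colnames(v)
  pair_idx <- utils::combn(seq_along(site_order), 2)
  pair_names <- apply(pair_idx, 2, function(ij) {
    paste(site_order[ij[1]], site_order[ij[2]], sep = "-")
  })
  tukey_key <- apply(pair_idx, 2, function(ij) {
    # TukeyHSD labels a pair "later_level-earlier_level"
    paste(site_order[ij[2]], site_order[ij[1]], sep = "-")
  })
  Fv <- pv <- numeric(length(mets))
  zero_var <- logical(length(mets))
  gm <- matrix(NA_real_, length(site_order), length(mets),
               dimnames = list(site_order, mets))
  pw <- matrix(NA_real_, length(pair_names), length(mets),
               dimnames = list(pair_names, mets))
  for (j in seq_along(mets)) {
    y <- v[, j]
    means <- tapply(y, g, mean)
    gm[, j] <- means
    ss_within <- sum((y - means[g])^2)
    if (ss_within < 1e-30) {
      zero_var[j] <- TRUE
      distinct <- abs(means - means[1]) > 1e-30
      Fv[j] <- if (any(distinct)) Inf else 0
      pv[j] <- if (any(distinct)) 0 else 1
      pw[, j] <- vapply(seq_along(pair_names), function(k) {
        i1 <- pair_idx[1, k]; i2 <- pair_idx[2, k]
        if (abs(means[i1] - means[i2]) > 1e-30) 0 else 1
      }, numeric(1))
    } else {
      fit <- stats::aov(y ~ g)
      tab <- stats::anova(fit)
      Fv[j] <- tab$`F value`[1]
      pv[j] <- tab$`Pr(>F)`[1]
      tk <- stats::TukeyHSD(fit)$g
      pw[, j] <- tk[match(tukey_key, rownames(tk)), "p adj"]
    }
  }
  stats_tbl <- tibble::tibble(metabolite = mets, F = Fv, p = pv,
                              zero_variance = zero_var,
                              selected = pv < alpha)
  structure(list(stats = stats_tbl, group_means = gm, pairwise = pw,
                 selected = mets[pv < alpha], sites = site_order,
                 alpha = alpha, log_transform = log_transform),
            class = "screen_result")
}

# "a", "b", ..., "z", "aa", "ab", ... -- deterministic letter sequence
letter_seq <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  c(letters, as.vector(outer(letters, letters,
                             function(a, b) paste0(a, b))))[seq_len(n)]
}

#' Compact letter-pair display of significant site differences
#'
#' Renders Tukey results for one metabolite in the letter-pair convention of
#' multi-site monitoring tables: significant site pairs are enumerated in the
#' fixed site order, assigned letters `a`, `b`, `c`, ... in that order, and
#' each site's display string is the concatenation (in letter order) of the
#' letters of the pairs it belongs to. Two sites sharing a letter therefore
#' differ significantly; an empty string means the site is in no significant
#' pair. The encoding is injective: the significant pair set can be decoded
#' exactly from the strings.
#'
#' @param screen A `screen_result` from [anova_screen()].
#' @param metabolite Name of a screened metabolite.
#' @param alpha Pairwise significance level (defaults to the screen's alpha).
#' @return Named character vector of letter strings, one per site.
#' @export
letter_pairs <- function(screen, metabolite, alpha = screen$alpha) {
  if (!metabolite %in% colnames(screen$pairwise)) {
    stop("metabolite not screened: ", metabolite, call. = FALSE)
  }
  p <- screen$pairwise[, metabolite]
  sig <- which(p < alpha)
  out <- stats::setNames(rep("", length(screen$sites)), screen$sites)
  if (length(sig) == 0) return(out)
  lab <- letter_seq(length(sig))
  for (k in seq_along(sig)) {
    pair <- strsplit(rownames(screen$pairwise)[sig[k]], "-", fixed = TRUE)[[1]]
    out[pair[1]] <- paste0(out[pair[1]], lab[k])
    out[pair[2]] <- paste0(out[pair[2]], lab[k])
  }
  out
}

#' Site-difference table for the screened metabolites
#'
#' One row per selected metabolite with its omnibus F and p and one
#' letter-display column per site, mirroring the layout of published
#' multi-site metabolite tables.
#'
#' @param screen A `screen_result`.
#' @param alpha Pairwise alpha passed to [letter_pairs()].
#' @return A tibble.
#' @export
screen_table <- function(screen, alpha = screen$alpha) {
  rows <- lapply(screen$selected, function(m) {
    lp <- letter_pairs(screen, m, alpha)
    stat <- screen$stats[screen$stats$metabolite == m, ]
    out <- tibble::tibble(metabolite = m, F = stat$F, p = stat$p)
    for (s in screen$sites) out[[s]] <- unname(lp[s])
    out
  })
  if (length(rows) == 0) {
    out <- tibble::tibble(metabolite = character(), F = numeric(),
                          p = numeric())
    for (s in screen$sites) out[[s]] <- character()
    return(out)
  }
  dplyr::bind_rows(rows)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  cat(sprintf("  %d metabolites screened across %d sites: %d selected at p < %g\n",
              nrow(x$stats), length(x$sites), length(x$selected), x$alpha))
  invisible(x)
}
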