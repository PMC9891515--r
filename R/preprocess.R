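#' Aggregate a contaminant panel to site maxima
#'
#' Reduces the long per-event panel to a site x analyte grid of maximum
#' wet-weight concentrations. Below-detection-limit records contribute zero,
#' so an analyte censored at every event of a site gets a site maximum of
#' exactly 0 ("not detected there"). Water temperature is aggregated as the
#' maximum reading per site. The number of events with a record (censored or
#' not) is kept per cell.
#'
#' @param panel A [contaminant_panel()].
#' @return An object of class `site_aggregate`: list with
#'   `max_concentration` (sites x analytes), `n_observations` (same shape),
#'   `max_temperature` (named by site), `class_of` (named by analyte),
#'   `dropped` (analytes removed by [drop_undetected()], initially empty).
#' @export
aggregate_max_by_site <- function(panel) {
  rec <- panel$records
  if (nrow(rec) == 0) stop("panel has no records", call. = FALSE)
  sites <- sort(unique(rec$site))
  analytes <- sort(unique(rec$analyte))
  value <- ifelse(rec$censored, 0, rec$concentration)
  si <- match(rec$site, sites)
  ai <- match(rec$analyte, analytes)
  mx <- matrix(0, length(sites), length(analytes),
               dimnames = list(sites, analytes))
  nobs <- matrix(0L, length(sites), length(analytes),
                 dimnames = list(sites, analytes))
  for (k in seq_along(value)) {
    if (value[k] > mx[si[k], ai[k]]) mx[si[k], ai[k]] <- value[k]
    nobs[si[k], ai[k]] <- nobs[si[k], ai[k]] + 1L
  }
  max_temp <- rep(NA_real_, length(sites))
  names(max_temp) <- sites
  if (nrow(panel$temperature) > 0) {
    agg <- tapply(panel$temperature$temperature, panel$temperature$site, max)
    max_temp[names(agg)] <- agg
  }
  class_of <- rec$class[match(analytes, rec$analyte)]
  names(class_of) <- analytes
  structure(list(max_concentration = mx, n_observations = nobs,
                 max_temperature = max_temp, class_of = class_of,
                 dropped = character()),
            class = "site_aggregate")
}

#' Drop analytes never detected at any site
#'
#' Removes every analyte whose site maximum is zero everywhere (i.e. censored
#' at every event of every site). The removed names are recorded in the
#' `dropped` element of the returned aggregate.
#'
#' @param agg A `site_aggregate` from [aggregate_max_by_site()].
#' @return The filtered `site_aggregate`.
#' @export
drop_undetected <- function(agg) {
  keep <- colSums(agg$max_concentration > 0) > 0
  agg$dropped <- c(agg$dropped, colnames(agg$max_concentration)[!keep])
  agg$max_concentration <- agg$max_concentration[, keep, drop = FALSE]
  agg$n_observations <- agg$n_observations[, keep, drop = FALSE]
  agg$class_of <- agg$class_of[keep]
  agg
}

#' @export
print.site_aggregate <- function(x, ...) {
  cat("<site_aggregate>\n")
  cat(sprintf("  %d sites x %d analytes; %d dropped as never detected\n",
              nrow(x$max_concentration), ncol(x$max_concentration),
              length(x$dropped)))
  invisible(x)
}

#' Median-normalize a metabolite matrix
#'
#' Divides each metabolite by its non-missing median so the median of every
#' compound becomes 1, the convention used by metabolomics vendors to remove
#' day-to-day instrument variation. When run-day blocks are recorded and
#' `mode = "by_block"` (the default when blocks exist), the median is taken
#' within each block, which removes multiplicative per-block effects exactly;
#' with `mode = "global"` a single median per compound is used and the global
#' post-condition median == 1 (within 1e-12) is guaranteed.
#'
#' Normalizing an already-normalized matrix is an error: double scaling would
#' silently corrupt the abundance scale.
#'
#' @param mm A [metabolite_matrix()] with `normalized == "none"`.
#' @param mode `"global"`, `"by_block"`, or `"auto"` (by block when block
#'   labels exist, otherwise global).
#' @return The normalized `metabolite_matrix`.
#' @export
median_normalize <- function(mm, mode = c("auto", "global", "by_block")) {
  mode <- match.arg(mode)
  if (mm$normalized != "none") {
    stop("matrix is already normalized (", mm$normalized,
         "); refusing to normalize twice", call. = FALSE)
  }
  has_blocks <- !any(is.na(mm$sample_info$block))
  if (mode == "auto") mode <- if (has_blocks) "by_block" else "global"
  if (mode == "by_block" && !has_blocks) {
    stop("by-block normalization requested but block labels are missing",
         call. = FALSE)
  }
  v <- mm$values
  all_missing <- colSums(!is.na(v)) == 0
  if (any(all_missing)) {
    stop("metabolite(s) with no observed values: ",
         paste(colnames(v)[all_missing], collapse = ", "), call. = FALSE)
  }
  if (mode == "global") {
    med <- apply(v, 2, stats::median, na.rm = TRUE)
    v <- sweep(v, 2, med, "/")
  } else {
    for (b in unique(mm$sample_info$block)) {
      rows <- mm$sample_info$block == b
      med <- apply(v[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
      if (any(is.na(med))) {
        stop("metabolite(s) with no observed values in block ", b,
             call. = FALSE)
      }
      v[rows, ] <- sweep(v[rows, , drop = FALSE], 2, med, "/")
    }
  }
  mm$values <- v
  mm$normalized <- mode
  validate_metabolite_matrix(mm)
}

#' Impute missing metabolite cells
#'
#' Replaces each missing cell by the minimum (default) or half the minimum of
#' the observed values of that metabolite -- the usual metabolomics stand-in
#' for "present below the detection floor". `method = "fail"` turns any
#' missing cell into an error instead. The imputation count is recorded in
#' the matrix's `n_imputed` field.
#'
#' @param mm A normalized [metabolite_matrix()].
#' @param method `"minimum"`, `"half_minimum"`, or `"fail"`.
#' @return The completed `metabolite_matrix`.
#' @export
impute_missing <- function(mm, method = c("minimum", "half_minimum", "fail")) {
  method <- match.arg(method)
  if (mm$normalized == "none") {
    stop("impute after normalization: the pipeline order is censor/aggregate ",
         "then normalize then impute", call. = FALSE)
  }
  v <- mm$values
  n_missing <- sum(is.na(v))
  if (method == "fail") {
    if (n_missing > 0) {
      stop(n_missing, " missing cell(s) present in fail-on-missing mode",
           call. = FALSE)
    }
    return(mm)
  }
  if (n_missing > 0) {
    for (j in seq_len(ncol(v))) {
      miss <- is.na(v[, j])
      if (any(miss)) {
        fill <- min(v[!miss, j])
        if (method == "half_minimum") fill <- fill / 2
        v[miss, j] <- fill
      }
    }
  }
  mm$values <- v
  mm$n_imputed <- mm$n_imputed + n_missing
  mm
}

#' Build the response block for PLS
#'
#' Expands a site aggregate into a sample-level response matrix: every
#' animal's row is its deployment site's vector of maximum contaminant
#' concentrations, with the site's maximum water temperature appended as the
#' final column `"temperature"`. Rows are therefore constant within site by
#' construction. The aggregate must already have been through
#' [drop_undetected()] -- all-zero response columns are refused.
#'
#' @param agg A `site_aggregate`.
#' @param mm The [metabolite_matrix()] whose samples define the rows.
#' @param include_temperature Append the temperature column (default TRUE).
#' @return An object of class `response_block`: list with `values` (samples x
#'   responses), `site`, `force_keep` (the temperature column name, if
#'   present), and `provenance`.
#' @export
build_response_block <- function(agg, mm, include_temperature = TRUE) {
  sample_site <- mm$sample_info$site
  unknown <- setdiff(unique(sample_site), rownames(agg$max_concentration))
  if (length(unknown) > 0) {
    stop("sample(s) from site(s) absent from the aggregate: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(colSums(agg$max_concentration > 0) == 0)) {
    stop("aggregate still contains never-detected analytes; ",
         "run drop_undetected() first", call. = FALSE)
  }
  y <- agg$max_concentration[sample_site, , drop = FALSE]
  force_keep <- character()
  if (include_temperature) {
    tmp <- agg$max_temperature[sample_site]
    if (any(is.na(tmp))) {
      stop("no temperature reading for site(s): ",
           paste(unique(sample_site[is.na(tmp)]), collapse = ", "),
           call. = FALSE)
    }
    y <- cbind(y, temperature = tmp)
    force_keep <- "temperature"
  }
  rownames(y) <- mm$sample_info$sample
  structure(list(values = y, site = sample_site, force_keep = force_keep,
                 provenance = list(aggregation = "max_over_events",
                                   below_lod = "set_to_zero",
                                   n_sites = nrow(agg$max_concentration))),
            class = "response_block")
}

#' @export
print.response_block <- function(x, ...) {
  cat("<response_block>\n")
  cat(sprintf("  %d samples x %d responses (%s)\n", nrow(x$values),
              ncol(x$values),
              if (length(x$force_keep)) paste0("force-keep: ",
                                               paste(x$force_keep,
                                                     collapse = ", "))
              else "no force-keep"))
  invisible(x)
}
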