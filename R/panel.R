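#' Build a contaminant measurement panel
#'
#' A contaminant panel holds long-format per-event water measurements for a
#' multi-site biomonitoring study: one row per (site, sampling event, analyte)
#' with a wet-weight concentration in ppm, the assay detection limit, and a
#' contaminant class label (typically `"hormone"`, `"pesticide"` or `"ppcp"`,
#' carried as pass-through metadata). A measurement is either a numeric
#' concentration or an explicit below-detection-limit record (`censored =
#' TRUE`, `concentration = NA`), never both. Water temperature readings
#' (degrees C) are kept alongside, one per site and sampling event.
#'
#' @param records A data frame with columns `site`, `event`, `analyte`,
#'   `class`, `concentration`, `censored`, `detection_limit`.
#' @param temperature Optional data frame with columns `site`, `event`,
#'   `temperature`. Every site referenced here must also appear in `records`.
#'
#' @return An object of class `contaminant_panel`: a list with elements
#'   `records` and `temperature` (both tibbles).
#' @seealso [read_contaminant_table()], [aggregate_max_by_site()],
#'   [apply_lod_censoring()]
#' @export
contaminant_panel <- function(records, temperature = NULL) {
  records <- tibble::as_tibble(records)
  if (is.null(temperature)) {
    temperature <- tibble::tibble(site = character(), event = character(),
                                  temperature = numeric())
  }
  temperature <- tibble::as_tibble(temperature)
  panel <- structure(list(records = records, temperature = temperature),
                     class = "contaminant_panel")
  validate_contaminant_panel(panel)
}

#' @rdname contaminant_panel
#' @param panel A `contaminant_panel` to validate.
#' @export
validate_contaminant_panel <- function(panel) {
  rec <- panel$records
  required <- c("site", "event", "analyte", "class", "concentration",
                "censored", "detection_limit")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols) > 0) {
    stop("contaminant panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- paste(rec$site, rec$event, rec$analyte, sep = " / ")
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    stop("duplicate (site, event, analyte) triple(s): ",
         paste(unique(dup), collapse = "; "), call. = FALSE)
  }
  bad_cens <- rec$censored & !is.na(rec$concentration)
  bad_num <- !rec$censored & is.na(rec$concentration)
  if (any(bad_cens) || any(bad_num)) {
    stop("each record must be either a numeric concentration or a ",
         "below-detection-limit marker, never both; offending rows: ",
         paste(which(bad_cens | bad_num), collapse = ", "), call. = FALSE)
  }
  neg <- which(!is.na(rec$concentration) & rec$concentration < 0)
  if (length(neg) > 0) {
    stop("negative concentration in row(s): ", paste(neg, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(rec$detection_limit) | rec$detection_limit <= 0)) {
    stop("detection limits must be positive", call. = FALSE)
  }
  extra_sites <- setdiff(unique(panel$temperature$site), unique(rec$site))
  if (length(extra_sites) > 0) {
    stop("temperature readings reference site(s) absent from records: ",
         paste(extra_sites, collapse = ", "), call. = FALSE)
  }
  panel
}

#' Read a contaminant panel from delimited text
#'
#' Expects a header row naming at least `site`, `event`, `analyte`, `class`,
#' `concentration`, `detection_limit`. Below-detection-limit measurements are
#' encoded in the `concentration` column by a sentinel token (default `"ND"`).
#' An optional `temperature` column carries the water temperature of that
#' site/event; it is collected into the panel's per-site reading list.
#' Missing or malformed cells are reported with their line numbers; nothing is
#' ever silently coerced to zero.
#'
#' @param path Path to a CSV (or TSV) file.
#' @param delim Field delimiter, `","` by default; pass `"\t"` for TSV.
#' @param nd_token Sentinel token marking a below-detection-limit record.
#' @return A [contaminant_panel()].
#' @export
read_contaminant_table <- function(path, delim = ",", nd_token = "ND") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  required <- c("site", "event", "analyte", "class", "concentration",
                "detection_limit")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  conc_chr <- trimws(raw$concentration)
  censored <- conc_chr == nd_token
  conc <- suppressWarnings(as.numeric(conc_chr))
  bad <- which(!censored & is.na(conc))
  if (length(bad) > 0) {
    stop("malformed concentration value(s) at data line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  conc[censored] <- NA_real_
  dl <- suppressWarnings(as.numeric(raw$detection_limit))
  bad_dl <- which(is.na(dl))
  if (length(bad_dl) > 0) {
    stop("malformed detection limit at data line(s): ",
         paste(bad_dl, collapse = ", "), call. = FALSE)
  }
  records <- tibble::tibble(
    site = raw$site, event = raw$event, analyte = raw$analyte,
    class = raw$class, concentration = conc, censored = censored,
    detection_limit = dl)
  temperature <- NULL
  if ("temperature" %in% names(raw)) {
    tmp <- suppressWarnings(as.numeric(raw$temperature))
    keep <- !is.na(tmp)
    temperature <- dplyr::distinct(tibble::tibble(
      site = raw$site[keep], event = raw$event[keep], temperature = tmp[keep]))
  }
  contaminant_panel(records, temperature)
}

#' Write a contaminant panel to delimited text
#'
#' Inverse of [read_contaminant_table()]: censored records are written as the
#' sentinel token, temperatures are repeated on every row of their site/event.
#'
#' @inheritParams read_contaminant_table
#' @param panel A `contaminant_panel`.
#' @return The path, invisibly.
#' @export
write_contaminant_table <- function(panel, path, delim = ",", nd_token = "ND") {
  rec <- panel$records
  out <- tibble::tibble(
    site = rec$site, event = rec$event, analyte = rec$analyte,
    class = rec$class,
    concentration = ifelse(rec$censored, nd_token,
                           format_full(rec$concentration)),
    detection_limit = format_full(rec$detection_limit))
  if (nrow(panel$temperature) > 0) {
    key <- paste(rec$site, rec$event)
    tkey <- paste(panel$temperature$site, panel$temperature$event)
    out$temperature <- format_full(
      panel$temperature$temperature[match(key, tkey)])
  }
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

# shortest round-trippable decimal representation of a double
format_full <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = 17, format = "g"))
}

#' @export
print.contaminant_panel <- function(x, ...) {
  rec <- x$records
  cat("<contaminant_panel>\n")
  cat(sprintf("  %d records: %d sites, %d analytes, %d censored (below LOD)\n",
              nrow(rec), length(unique(rec$site)),
              length(unique(rec$analyte)), sum(rec$censored)))
  cat(sprintf("  %d temperature readings\n", nrow(x$temperature)))
  invisible(x)
}
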