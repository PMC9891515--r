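#' Build a sample-by-metabolite abundance matrix
#'
#' Holds relative metabolite abundances for the sentinel animals: one row per
#' sample (animal), one column per metabolite, with the deployment site of
#' every sample and an optional run-day block label (instrument batch).
#' Missing cells are `NA`, never zero. The `normalized` field records whether
#' per-compound median scaling has been applied (`"none"`, `"global"` or
#' `"by_block"`).
#'
#' @param values Numeric matrix (samples x metabolites) of positive abundances
#'   or `NA`; rownames are sample ids, colnames metabolite names.
#' @param site Character vector of site labels, one per row of `values`.
#' @param block Optional character vector of run-day block labels.
#' @param normalized One of `"none"`, `"global"`, `"by_block"`.
#'
#' @return An object of class `metabolite_matrix` with elements `values`,
#'   `sample_info` (tibble: sample, site, block), `normalized`.
#' @seealso [read_metabolite_matrix()], [median_normalize()], [impute_missing()]
#' @export
metabolite_matrix <- function(values, site, block = NULL,
                              normalized = "none") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("sample%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("met%03d", seq_len(ncol(values)))
  }
  if (length(site) != nrow(values)) {
    stop("`site` must have one label per sample row", call. = FALSE)
  }
  if (is.null(block)) block <- rep(NA_character_, nrow(values))
  mm <- structure(list(
    values = values,
    sample_info = tibble::tibble(sample = rownames(values),
                                 site = as.character(site),
                                 block = as.character(block)),
    normalized = normalized,
    n_imputed = 0L), class = "metabolite_matrix")
  validate_metabolite_matrix(mm)
}

#' @rdname metabolite_matrix
#' @param mm A `metabolite_matrix` to validate.
#' @export
validate_metabolite_matrix <- function(mm) {
  v <- mm$values
  if (nrow(v) != nrow(mm$sample_info)) {
    stop("value grid and sample annotation disagree on sample count",
         call. = FALSE)
  }
  dup <- mm$sample_info$sample[duplicated(mm$sample_info$sample)]
  if (length(dup) > 0) {
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(v[!is.na(v)] < 0)) {
    stop("metabolite abundances must be positive", call. = FALSE)
  }
  if (!mm$normalized %in% c("none", "global", "by_block")) {
    stop("`normalized` must be one of none/global/by_block", call. = FALSE)
  }
  if (mm$normalized == "global") {
    med <- apply(v, 2, stats::median, na.rm = TRUE)
    if (any(abs(med - 1) > 1e-12)) {
      stop("matrix flagged globally normalized but some compound medians ",
           "differ from 1", call. = FALSE)
    }
  }
  if (mm$normalized == "by_block") {
    for (b in unique(mm$sample_info$block)) {
      med <- apply(v[mm$sample_info$block == b, , drop = FALSE], 2,
                   stats::median, na.rm = TRUE)
      if (any(abs(med - 1) > 1e-12)) {
        stop("matrix flagged block-normalized but block ", b,
             " has compound medians differing from 1", call. = FALSE)
      }
    }
  }
  mm
}

#' Read a metabolite matrix from delimited text
#'
#' Layout: first column sample id, second column site label, optional `block`
#' column, remaining columns numeric abundances. Empty cells are read as
#' missing (`NA`), not zero; any other non-numeric cell is an error naming the
#' offending sample and metabolite.
#'
#' @param path Path to a CSV (or TSV) file.
#' @param delim Field delimiter.
#' @return A [metabolite_matrix()] with `normalized = "none"`.
#' @export
read_metabolite_matrix <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (ncol(raw) < 3) {
    stop("expected sample id, site and at least one metabolite column",
         call. = FALSE)
  }
  sample_id <- raw[[1]]
  site <- raw[[2]]
  block <- NULL
  value_cols <- names(raw)[-(1:2)]
  if (length(value_cols) > 0 && value_cols[1] == "block") {
    block <- raw[["block"]]
    value_cols <- value_cols[-1]
  }
  dup <- sample_id[duplicated(sample_id)]
  if (length(dup) > 0) {
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow(raw), length(value_cols),
                 dimnames = list(sample_id, value_cols))
  for (j in seq_along(value_cols)) {
    cell <- trimws(raw[[value_cols[j]]])
    empty <- is.na(cell) | cell == ""
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad) > 0) {
      stop("non-numeric cell(s) in metabolite '", value_cols[j],
           "' for sample(s): ", paste(sample_id[bad], collapse = ", "),
           call. = FALSE)
    }
    num[empty] <- NA_real_
    vals[, j] <- num
  }
  metabolite_matrix(vals, site = site, block = block)
}

#' Write a metabolite matrix to delimited text
#'
#' Missing cells are written as empty fields. Doubles are written with enough
#' digits to round-trip bit-exactly through [read_metabolite_matrix()].
#'
#' @inheritParams read_metabolite_matrix
#' @param mm A `metabolite_matrix`.
#' @return The path, invisibly.
#' @export
write_metabolite_matrix <- function(mm, path, delim = ",") {
  out <- tibble::tibble(sample = mm$sample_info$sample,
                        site = mm$sample_info$site)
  if (!all(is.na(mm$sample_info$block))) out$block <- mm$sample_info$block
  for (j in colnames(mm$values)) out[[j]] <- format_full(mm$values[, j])
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat("<metabolite_matrix>\n")
  cat(sprintf("  %d samples x %d metabolites (%d sites), %d missing cells\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_info$site)), sum(is.na(x$values))))
  cat(sprintf("  normalization: %s; imputed cells: %d\n",
              x$normalized, x$n_imputed))
  invisible(x)
}
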