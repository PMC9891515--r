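#' Top contaminants detected per site
#'
#' For each site, ranks the detected analytes (site maximum > 0) by maximum
#' concentration descending, ties broken lexicographically by analyte name,
#' and returns the top `n` rows per site with class labels and observation
#' counts -- the layout of "top ten contaminants per site" summary tables.
#'
#' @param agg A `site_aggregate`.
#' @param n Rows per site (default 10); sites with fewer detected analytes
#'   contribute fewer rows.
#' @return Tibble with columns `site`, `contaminant`, `class`,
#'   `concentration`, `n_observations`.
#' @export
top_ten_table <- function(agg, n = 10) {
  rows <- lapply(rownames(agg$max_concentration), function(s) {
    conc <- agg$max_concentration[s, ]
    det <- names(conc)[conc > 0]
    if (length(det) == 0) return(NULL)
    det <- det[order(-conc[det], det)]
    det <- utils::head(det, n)
    tibble::tibble(site = s, contaminant = det,
                   class = unname(agg$class_of[det]),
                   concentration = unname(conc[det]),
                   n_observations = unname(agg$n_observations[s, det]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(site = character(), contaminant = character(),
                          class = character(), concentration = numeric(),
                          n_observations = integer())
  }
  out
}

#' Run the full prioritization pipeline on a synthetic study
#'
#' End-to-end orchestration: simulate (or accept) a study, aggregate the
#' contaminant panel to site maxima with below-detection-limit values set to
#' zero, drop never-detected analytes, median-normalize and impute the
#' metabolite matrix, screen metabolites by ANOVA, build the response block
#' (contaminant maxima plus temperature), select covarying contaminants by
#' backward elimination / forward re-introduction, and rank metabolite
#' biomarkers by VIP. Every stage is logged in the returned manifest; when
#' `out_dir` is given, all artifacts are also written as CSV/TSV/JSON.
#'
#' @param config A [simulation_config()] (its seed drives the simulation).
#' @param study Optional pre-built study (list with `panel`, `metabolites`,
#'   optionally `truth`) to analyse instead of simulating.
#' @param alpha_screen ANOVA screen significance level.
#' @param alpha_select CV-ANOVA selection significance level.
#' @param folds,scale Cross-validation settings.
#' @param ncomp Fixed PLS component count, or `NULL` for automatic choice.
#' @param seed Seed for fold assignment (defaults to the config seed).
#' @param out_dir Optional output directory for artifacts.
#' @return Invisibly, a list with every intermediate object (`study`,
#'   `aggregate`, `metabolites`, `screen`, `response_block`, `trace`,
#'   `vip`, `top_ten`, `manifest`).
#' @export
run_study <- function(config = simulation_config(), study = NULL,
                      alpha_screen = 0.05, alpha_select = 0.05, folds = 7,
                      scale = "uv", ncomp = NULL, seed = config$seed,
                      out_dir = NULL) {
  stages <- list()
  log_stage <- function(name, ...) {
    stages[[length(stages) + 1]] <<- c(list(stage = name), list(...))
  }

  if (is.null(study)) {
    study <- simulate_study(config)
    log_stage("simulate", seed = config$seed,
              n_records = nrow(study$panel$records),
              n_samples = nrow(study$metabolites$values))
  }
  agg <- aggregate_max_by_site(study$panel)
  agg <- drop_undetected(agg)
  log_stage("aggregate", n_sites = nrow(agg$max_concentration),
            n_detected = ncol(agg$max_concentration),
            n_dropped = length(agg$dropped))

  mm <- median_normalize(study$metabolites)
  mm <- impute_missing(mm)
  log_stage("normalize", mode = mm$normalized, n_imputed = mm$n_imputed)

  screen <- anova_screen(mm, alpha = alpha_screen)
  log_stage("screen", n_metabolites = nrow(screen$stats),
            n_selected = length(screen$selected))
  if (length(screen$selected) < 2) {
    stop("fewer than 2 metabolites passed the screen; nothing to model",
         call. = FALSE)
  }
  X <- mm$values[, screen$selected, drop = FALSE]
  yb <- build_response_block(agg, mm)

  trace <- select_contaminants(X, yb, alpha = alpha_select, folds = folds,
                               seed = seed, scale = scale, ncomp = ncomp)
  log_stage("select", n_final = length(trace$final$responses),
            q2cum_global = trace$global$q2cum,
            q2cum_final = trace$final$q2cum, ncomp = trace$final$ncomp)

  vip <- NULL
  if (length(trace$final$responses) > 0) {
    Yfin <- yb$values[, trace$final$responses, drop = FALSE]
    vip <- vip_significance(X, Yfin, trace$final$ncomp, folds = folds,
                            seed = seed, site = yb$site, scale = scale)
    log_stage("vip", n_relevant = sum(vip$table$vip >= 1 &
                                        vip$table$p < 0.05))
  }
  top <- top_ten_table(agg)
  log_stage("report", n_top_rows = nrow(top))

  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = unclass(config), seed = seed,
                   parameters = list(alpha_screen = alpha_screen,
                                     alpha_select = alpha_select,
                                     folds = folds, scale = scale,
                                     ncomp = ncomp),
                   stages = stages)
  result <- list(study = study, aggregate = agg, metabolites = mm,
                 screen = screen, response_block = yb, trace = trace,
                 vip = vip, top_ten = top, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_contaminant_table(study$panel, file.path(out_dir, "panel.csv"))
    write_metabolite_matrix(study$metabolites,
                            file.path(out_dir, "metabolites.csv"))
    if (!is.null(study$truth)) {
      jsonlite::write_json(
        lapply(study$truth, function(x) if (is.matrix(x)) unclass(x) else x),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    }
    readr::write_tsv(screen_table(screen), file.path(out_dir, "table1.tsv"))
    readr::write_tsv(top, file.path(out_dir, "top10.tsv"))
    readr::write_tsv(trace$ranking, file.path(out_dir, "ranked.tsv"))
    jsonlite::write_json(selection_trace_as_list(trace),
                         file.path(out_dir, "trace.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(vip)) {
      readr::write_tsv(vip$table, file.path(out_dir, "vip.tsv"))
    }
    manifest$outputs <- list.files(out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- manifest
  }
  invisible(result)
}

# plain-list view of a trace for JSON serialization
selection_trace_as_list <- function(trace) {
  list(
    global = trace$global,
    elimination = lapply(trace$elimination, function(it) {
      list(retained_before = it$retained_before,
           removed = as.list(it$removed), q2cum = it$q2cum,
           ncomp = it$ncomp)
    }),
    post_elimination = trace$post_elimination,
    reintroduction = as.list(trace$reintroduction),
    final = trace$final,
    settings = trace$settings)
}
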