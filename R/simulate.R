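#' Configuration for a synthetic caged-biomonitoring study
#'
#' Defines the shape and signal structure of a simulated study in which caged
#' sentinel animals are deployed at several river sites, water is sampled
#' repeatedly for a large targeted contaminant panel, and animal metabolomes
#' are profiled once at retrieval. The defaults mirror a typical design of
#' this kind: 4 sites, 6 sampling events, 220 targeted analytes of which
#' about two thirds are never detected, 8 animals per site, 186 metabolites.
#'
#' Signal is planted through a low-rank site "exposure burden" construction:
#' each site draws `n_latent_factors` factor scores; the active contaminants
#' and the responsive metabolites are both lognormal functions of the *same*
#' scores, so that a subset of contaminants genuinely covaries with a subset
#' of metabolites across sites. Factor 1 loads with a common positive sign on
#' both blocks (an overall contamination-burden axis); higher factors carry
#' signed, site-contrasting structure.
#'
#' @param n_sites Number of deployment sites (>= 2).
#' @param n_events_per_site Water sampling events per site.
#' @param n_analytes Size of the targeted contaminant panel.
#' @param frac_never_detected Fraction of analytes censored at every event.
#' @param n_active_contaminants Number of detected analytes whose site means
#'   follow the latent factor scores.
#' @param n_samples_per_site Animals per site.
#' @param n_metabolites Number of profiled metabolites.
#' @param n_responsive_metabolites Number of metabolites driven by the same
#'   factor scores.
#' @param n_latent_factors Rank of the planted site structure.
#' @param effect_size Ratio of site-driven to residual (animal-level)
#'   standard deviation of responsive metabolites, on the log scale.
#' @param lod_quantile Per-analyte detection limit, as a quantile of that
#'   analyte's generated event concentrations (0 censors nothing).
#' @param block_effect_sd Log-scale sd of multiplicative run-day block
#'   effects, drawn per (block, metabolite).
#' @param noise_sd Log-scale sd of animal-level metabolite noise.
#' @param event_noise_sd Log-scale sd of event-to-event contaminant noise.
#' @param n_blocks Number of instrument run-day blocks.
#' @param seed Integer seed; identical configs (including seed) generate
#'   byte-identical studies.
#'
#' @return A validated list of class `simulation_config`.
#' @seealso [simulate_study()]
#' @export
simulation_config <- function(n_sites = 4, n_events_per_site = 6,
                              n_analytes = 220,
                              frac_never_detected = 151 / 220,
                              n_active_contaminants = 15,
                              n_samples_per_site = 8,
                              n_metabolites = 186,
                              n_responsive_metabolites = 30,
                              n_latent_factors = 2,
                              effect_size = 2,
                              lod_quantile = 0.2,
                              block_effect_sd = 0.3,
                              noise_sd = 0.4,
                              event_noise_sd = 0.5,
                              n_blocks = 2,
                              seed = 1) {
  cfg <- list(n_sites = as.integer(n_sites),
              n_events_per_site = as.integer(n_events_per_site),
              n_analytes = as.integer(n_analytes),
              frac_never_detected = frac_never_detected,
              n_active_contaminants = as.integer(n_active_contaminants),
              n_samples_per_site = as.integer(n_samples_per_site),
              n_metabolites = as.integer(n_metabolites),
              n_responsive_metabolites = as.integer(n_responsive_metabolites),
              n_latent_factors = as.integer(n_latent_factors),
              effect_size = effect_size,
              lod_quantile = lod_quantile,
              block_effect_sd = block_effect_sd,
              noise_sd = noise_sd,
              event_noise_sd = event_noise_sd,
              n_blocks = as.integer(n_blocks),
              seed = as.integer(seed))
  with(cfg, {
    if (n_sites < 2) stop("need at least 2 sites", call. = FALSE)
    if (n_events_per_site < 1) stop("need at least 1 event", call. = FALSE)
    if (frac_never_detected < 0 || frac_never_detected > 1) {
      stop("frac_never_detected must lie in [0, 1]", call. = FALSE)
    }
    if (lod_quantile < 0 || lod_quantile >= 1) {
      stop("lod_quantile must lie in [0, 1)", call. = FALSE)
    }
    n_detected <- n_analytes - round(frac_never_detected * n_analytes)
    if (n_active_contaminants > n_detected) {
      stop("infeasible config: more active contaminants (",
           n_active_contaminants, ") than detected analytes (", n_detected,
           ")", call. = FALSE)
    }
    if (n_responsive_metabolites > n_metabolites) {
      stop("infeasible config: more responsive metabolites than metabolites",
           call. = FALSE)
    }
    if (n_latent_factors < 1) stop("need at least 1 latent factor",
                                   call. = FALSE)
    if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
    if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  })
  structure(cfg, class = "simulation_config")
}

#' Simulate a complete caged-biomonitoring study
#'
#' Draws a full synthetic study from a [simulation_config()]: a raw
#' contaminant panel (with per-analyte detection limits already applied via
#' [apply_lod_censoring()]), an un-normalized metabolite matrix with run-day
#' block effects, and the ground truth used to generate both.
#'
#' Generative model, all on the natural-log scale unless noted:
#' * site factor scores `F` (sites x factors) are standard normal;
#' * an active contaminant has site mean `exp(mu + F %*% l)` and per-event
#'   concentration equal to that mean times lognormal event noise; inert
#'   detected contaminants have a site-constant mean; never-detected analytes
#'   are generated the same way and then fully censored;
#' * a responsive metabolite is `exp(b + a * F %*% l + animal noise)` with the
#'   same `F`, where `a` is set so realized site-driven sd / residual sd
#'   equals `effect_size`; non-responsive metabolites are pure lognormal
#'   noise; every metabolite is multiplied by its run-day block effect;
#' * each detected analyte's detection limit is the `lod_quantile` quantile
#'   of its own generated event values.
#'
#' Sub-streams of the random stream are derived deterministically per data
#' block (factors, contaminants, metabolites, temperature), so e.g. enlarging
#' the metabolite block does not perturb the contaminant draws.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `panel` ([contaminant_panel()]),
#'   `metabolites` ([metabolite_matrix()]), and `truth` (list:
#'   `active_contaminants`, `responsive_metabolites`, `site_factor_scores`,
#'   `contaminant_loadings`, `metabolite_loadings`, `detection_limits`).
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  subseed <- sample.int(.Machine$integer.max - 1L, 4)

  sites <- sprintf("S%d", seq_len(config$n_sites))
  events <- sprintf("E%d", seq_len(config$n_events_per_site))
  analytes <- sprintf("cec%03d", seq_len(config$n_analytes))
  mets <- sprintf("met%03d", seq_len(config$n_metabolites))
  # class labels in the proportions typical of large targeted panels
  class_frac <- c(hormone = 14, pesticide = 62, ppcp = 144) / 220
  n_cls <- diff(round(cumsum(c(0, class_frac)) * config$n_analytes))
  n_cls[3] <- config$n_analytes - sum(n_cls[1:2])
  class_of <- rep(c("hormone", "pesticide", "ppcp"), times = n_cls)
  names(class_of) <- analytes

  # latent site structure
  set.seed(subseed[1])
  F_scores <- matrix(stats::rnorm(config$n_sites * config$n_latent_factors),
                     config$n_sites, config$n_latent_factors,
                     dimnames = list(sites, NULL))

  # contaminant block
  set.seed(subseed[2])
  n_detected <- config$n_analytes -
    round(config$frac_never_detected * config$n_analytes)
  detected <- sort(sample(analytes, n_detected))
  active <- if (config$n_active_contaminants > 0) {
    sort(sample(detected, config$n_active_contaminants))
  } else character()
  mu <- stats::rnorm(config$n_analytes, mean = log(1e-4), sd = 1.5)
  names(mu) <- analytes
  L_con <- matrix(0, config$n_analytes, config$n_latent_factors,
                  dimnames = list(analytes, NULL))
  if (length(active) > 0) {
    L_con[active, 1] <- abs(stats::rnorm(length(active), sd = 0.8))
    if (config$n_latent_factors > 1) {
      L_con[active, -1] <- stats::rnorm(
        length(active) * (config$n_latent_factors - 1), sd = 0.4)
    }
  }
  site_logmean <- matrix(rep(mu, each = config$n_sites), config$n_sites,
                         config$n_analytes, dimnames = list(sites, analytes))
  site_logmean <- site_logmean + F_scores %*% t(L_con)
  n_ev <- config$n_events_per_site
  rec_site <- rep(sites, each = n_ev * config$n_analytes)
  rec_event <- rep(rep(events, each = config$n_analytes), config$n_sites)
  rec_analyte <- rep(analytes, times = n_ev * config$n_sites)
  conc <- exp(site_logmean[cbind(rec_site, rec_analyte)] +
                stats::rnorm(length(rec_site), sd = config$event_noise_sd))
  records <- tibble::tibble(site = rec_site, event = rec_event,
                            analyte = rec_analyte,
                            class = unname(class_of[rec_analyte]),
                            concentration = conc,
                            censored = FALSE,
                            detection_limit = 1)
  lods <- vapply(analytes, function(a) {
    v <- conc[rec_analyte == a]
    if (a %in% detected) {
      if (config$lod_quantile == 0) min(v) * 0.5
      else unname(stats::quantile(v, config$lod_quantile, type = 7))
    } else {
      max(v) * 1.01  # never detected: limit above every generated value
    }
  }, numeric(1))
  records$detection_limit <- unname(lods[records$analyte])

  # temperature block (independent site/event fluctuation)
  set.seed(subseed[4])
  site_base_temp <- 20 + stats::rnorm(config$n_sites, sd = 2)
  temperature <- tibble::tibble(
    site = rep(sites, each = n_ev),
    event = rep(events, config$n_sites),
    temperature = rep(site_base_temp, each = n_ev) +
      stats::rnorm(config$n_sites * n_ev, sd = 1))

  panel <- contaminant_panel(records, temperature)
  panel <- apply_lod_censoring(panel, lods, quiet = TRUE)

  # metabolite block
  set.seed(subseed[3])
  responsive <- if (config$n_responsive_metabolites > 0) {
    sort(sample(mets, config$n_responsive_metabolites))
  } else character()
  L_met <- matrix(0, config$n_metabolites, config$n_latent_factors,
                  dimnames = list(mets, NULL))
  if (length(responsive) > 0) {
    L_met[responsive, 1] <- abs(stats::rnorm(length(responsive), sd = 1))
    if (config$n_latent_factors > 1) {
      L_met[responsive, -1] <- stats::rnorm(
        length(responsive) * (config$n_latent_factors - 1), sd = 0.5)
    }
  }
  n_samples <- config$n_sites * config$n_samples_per_site
  sample_site <- rep(sites, each = config$n_samples_per_site)
  sample_id <- sprintf("%s_A%d", sample_site,
                       rep(seq_len(config$n_samples_per_site),
                           config$n_sites))
  baseline <- stats::rnorm(config$n_metabolites, sd = 1)
  g <- F_scores %*% t(L_met)                       # sites x metabolites
  g_sd <- apply(g, 2, function(x) sqrt(mean((x - mean(x))^2)))
  alpha <- ifelse(g_sd > 1e-12,
                  config$effect_size * config$noise_sd / g_sd, 0)
  logv <- matrix(rep(baseline, each = n_samples), n_samples,
                 config$n_metabolites) +
    g[sample_site, , drop = FALSE] %*% diag(alpha, config$n_metabolites) +
    matrix(stats::rnorm(n_samples * config$n_metabolites,
                        sd = config$noise_sd), n_samples)
  block <- sprintf("day%d", ((seq_len(n_samples) - 1) %% config$n_blocks) + 1)
  beta <- matrix(stats::rnorm(config$n_blocks * config$n_metabolites,
                              sd = config$block_effect_sd),
                 config$n_blocks, config$n_metabolites,
                 dimnames = list(sprintf("day%d", seq_len(config$n_blocks)),
                                 mets))
  vals <- exp(logv + beta[block, , drop = FALSE])
  dimnames(vals) <- list(sample_id, mets)
  mm <- metabolite_matrix(vals, site = sample_site, block = block)

  truth <- list(active_contaminants = active,
                responsive_metabolites = responsive,
                detected_analytes = detected,
                site_factor_scores = F_scores,
                contaminant_loadings = L_con,
                metabolite_loadings = L_met,
                detection_limits = lods)
  list(panel = panel, metabolites = mm, truth = truth)
}

#' Censor panel records below per-analyte detection limits
#'
#' A concentration is considered detected when it is equal to or above its
#' detection limit; strictly smaller values are replaced by the
#' below-detection-limit marker. The number of newly censored records is
#' stored in the `n_censored` attribute of the returned panel.
#'
#' @param panel A [contaminant_panel()].
#' @param lods Named numeric vector mapping every analyte present in the
#'   panel to its detection limit.
#' @param quiet Suppress the censoring-count message.
#' @return The censored `contaminant_panel`.
#' @export
apply_lod_censoring <- function(panel, lods, quiet = FALSE) {
  rec <- panel$records
  missing_lod <- setdiff(unique(rec$analyte), names(lods))
  if (length(missing_lod) > 0) {
    stop("no detection limit supplied for analyte(s): ",
         paste(missing_lod, collapse = ", "), call. = FALSE)
  }
  lod <- unname(lods[rec$analyte])
  hit <- !rec$censored & !is.na(rec$concentration) & rec$concentration < lod
  rec$censored[hit] <- TRUE
  rec$concentration[hit] <- NA_real_
  rec$detection_limit <- lod
  out <- contaminant_panel(rec, panel$temperature)
  attr(out, "n_censored") <- sum(hit)
  if (!quiet) message(sum(hit), " record(s) censored below detection limit")
  out
}
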