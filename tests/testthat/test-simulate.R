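test_that("identical config and seed give an identical study", {
  cfg <- small_config(seed = 5)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$panel$records, b$panel$records)
  expect_identical(a$metabolites$values, b$metabolites$values)
  expect_identical(a$truth$active_contaminants, b$truth$active_contaminants)
  # and byte-identical CSV exports
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_contaminant_table(a$panel, f1)
  write_contaminant_table(b$panel, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generated studies satisfy the panel and matrix invariants", {
  for (s in 1:3) {
    st <- simulate_study(small_config(seed = s))
    expect_s3_class(validate_contaminant_panel(st$panel), "contaminant_panel")
    expect_s3_class(validate_metabolite_matrix(st$metabolites),
                    "metabolite_matrix")
    expect_true(all(st$truth$active_contaminants %in%
                      unique(st$panel$records$analyte)))
    expect_true(all(st$truth$responsive_metabolites %in%
                      colnames(st$metabolites$values)))
  }
})

test_that("fully censored panels empty out downstream", {
  cfg <- small_config(seed = 3, frac_never_detected = 1,
                      n_active_contaminants = 0)
  st <- simulate_study(cfg)
  expect_true(all(st$panel$records$censored))
  agg <- drop_undetected(aggregate_max_by_site(st$panel))
  expect_equal(ncol(agg$max_concentration), 0)
  expect_equal(length(agg$dropped), cfg$n_analytes)
})

test_that("effect_size zero plants no site signal but keeps the labels", {
  st <- simulate_study(small_config(seed = 4, effect_size = 0))
  expect_length(st$truth$responsive_metabolites, 10)
  # site-driven log component is scaled by effect_size, so site means of
  # responsive metabolites should show no systematic separation: the ANOVA
  # screen should fire at roughly its false-positive rate
  mm <- impute_missing(median_normalize(st$metabolites))
  sc <- anova_screen(mm)
  expect_lt(length(sc$selected), 0.25 * ncol(mm$values))
})

test_that("censoring respects the detected-at-or-above-limit boundary", {
  rec <- tibble::tibble(site = "P", event = c("e1", "e2", "e3"),
                        analyte = "atrazine", class = "pesticide",
                        concentration = c(0.05, 0.10, 0.20),
                        censored = FALSE, detection_limit = 0.1)
  panel <- contaminant_panel(rec)
  out <- apply_lod_censoring(panel, c(atrazine = 0.10), quiet = TRUE)
  expect_equal(attr(out, "n_censored"), 1)
  expect_true(out$records$censored[out$records$event == "e1"])
  # value equal to the limit counts as detected
  expect_false(out$records$censored[out$records$event == "e2"])

  tiny <- apply_lod_censoring(panel, c(atrazine = 1e-12), quiet = TRUE)
  expect_equal(attr(tiny, "n_censored"), 0)

  expect_error(apply_lod_censoring(panel, c(other = 0.1)), "atrazine")
})

test_that("censored-record counts match a brute-force recount", {
  st <- simulate_study(small_config(seed = 9, lod_quantile = 0))
  lods <- stats::setNames(runif(30, 1e-6, 1e-3),
                          sprintf("cec%03d", 1:30))
  before <- st$panel
  # undo generator censoring for a clean recount on raw values
  raw <- before$records
  raw <- raw[!raw$censored, ]
  panel <- contaminant_panel(raw, before$temperature)
  out <- apply_lod_censoring(panel, lods, quiet = TRUE)
  manual <- sum(raw$concentration < lods[raw$analyte])
  expect_equal(attr(out, "n_censored"), manual)
  expect_equal(sum(out$records$censored), manual)
})

test_that("responsive site means track active contaminant site maxima", {
  # strong planted signal, low noise: per-site averages of the responsive
  # metabolites should rank-correlate with the active contaminant maxima
  rhos <- vapply(1:10, function(s) {
    cfg <- small_config(seed = s, effect_size = 5, noise_sd = 0.2,
                        event_noise_sd = 0.2, n_analytes = 60,
                        frac_never_detected = 0.4, n_metabolites = 60,
                        n_responsive_metabolites = 15, block_effect_sd = 0)
    st <- simulate_study(cfg)
    agg <- aggregate_max_by_site(st$panel)
    resp <- st$truth$responsive_metabolites
    act <- st$truth$active_contaminants
    met_site <- rowsum(st$metabolites$values[, resp, drop = FALSE],
                       st$metabolites$sample_info$site)
    stats::cor(rowMeans(scale(met_site)),
               rowMeans(scale(agg$max_concentration[, act, drop = FALSE])),
               method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0.5)
})

test_that("infeasible configurations are refused", {
  expect_error(small_config(n_active_contaminants = 20,
                            frac_never_detected = 0.9),
               "infeasible")
  expect_error(small_config(n_responsive_metabolites = 100), "infeasible")
  expect_error(small_config(lod_quantile = 1), "lod_quantile")
  expect_error(small_config(n_sites = 1), "sites")
})
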