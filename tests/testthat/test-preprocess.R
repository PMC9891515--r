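make_panel <- function(conc, censored = rep(FALSE, length(conc)),
                       site = "P", analyte = "atrazine",
                       temp = NULL) {
  rec <- tibble::tibble(site = site,
                        event = sprintf("e%d", seq_along(conc)),
                        analyte = analyte, class = "pesticide",
                        concentration = ifelse(censored, NA_real_, conc),
                        censored = censored, detection_limit = 0.01)
  contaminant_panel(rec, temp)
}

test_that("site aggregation takes maxima with below-LOD as zero", {
  p <- make_panel(c(NA, 0.3, 0.5), censored = c(TRUE, FALSE, FALSE))
  agg <- aggregate_max_by_site(p)
  expect_equal(agg$max_concentration["P", "atrazine"], 0.5)
  expect_equal(agg$n_observations["P", "atrazine"], 3L)

  all_nd <- make_panel(c(NA, NA, NA), censored = rep(TRUE, 3))
  agg2 <- aggregate_max_by_site(all_nd)
  expect_identical(agg2$max_concentration["P", "atrazine"], 0)
})

test_that("temperature aggregates as the site maximum", {
  tmp <- tibble::tibble(site = "P", event = c("e1", "e2", "e3"),
                        temperature = c(18.2, 22.4, 20.0))
  p <- make_panel(c(0.1, 0.2, 0.3), temp = tmp)
  agg <- aggregate_max_by_site(p)
  expect_equal(unname(agg$max_temperature["P"]), 22.4)
})

test_that("aggregation equals a brute-force nested-loop recomputation", {
  st <- simulate_study(small_config(seed = 6))
  agg <- aggregate_max_by_site(st$panel)
  rec <- st$panel$records
  for (s in rownames(agg$max_concentration)) {
    for (a in sample(colnames(agg$max_concentration), 8)) {
      rows <- rec[rec$site == s & rec$analyte == a, ]
      vals <- ifelse(rows$censored, 0, rows$concentration)
      expect_equal(agg$max_concentration[s, a],
                   if (nrow(rows)) max(vals) else 0)
      expect_equal(agg$n_observations[s, a], nrow(rows))
    }
  }
})

test_that("drop_undetected removes exactly the all-zero analytes", {
  st <- simulate_study(small_config(seed = 8))
  agg <- aggregate_max_by_site(st$panel)
  manual_drop <- colnames(agg$max_concentration)[
    colSums(agg$max_concentration > 0) == 0]
  dropped <- drop_undetected(agg)
  expect_setequal(dropped$dropped, manual_drop)
  expect_equal(ncol(dropped$max_concentration),
               ncol(agg$max_concentration) - length(manual_drop))
  # idempotent once clean
  again <- drop_undetected(dropped)
  expect_identical(again$max_concentration, dropped$max_concentration)
})

test_that("median normalization scales every compound median to one", {
  mm <- metabolite_matrix(cbind(m1 = c(2, 4, 8)), site = c("A", "A", "B"))
  out <- median_normalize(mm, mode = "global")
  expect_equal(unname(out$values[, "m1"]), c(0.5, 1, 2))
  expect_error(median_normalize(out), "already normalized")

  set.seed(21)
  big <- metabolite_matrix(matrix(exp(rnorm(32 * 50)), 32),
                           site = rep(c("A", "B", "C", "D"), each = 8))
  norm <- median_normalize(big, mode = "global")
  med <- apply(norm$values, 2, stats::median)
  expect_true(all(abs(med - 1) < 1e-12))
})

test_that("block-wise normalization removes multiplicative run-day effects", {
  set.seed(3)
  base <- matrix(exp(rnorm(16 * 6)), 16)
  block <- rep(c("d1", "d2"), 8)
  shift <- ifelse(block == "d1", 1, 5)  # strong day-2 intensity inflation
  mm <- metabolite_matrix(base * shift, site = rep(c("A", "B"), each = 8),
                          block = block)
  out <- median_normalize(mm)
  expect_identical(out$normalized, "by_block")
  for (b in c("d1", "d2")) {
    med <- apply(out$values[block == b, ], 2, stats::median)
    expect_true(all(abs(med - 1) < 1e-12))
  }
  # the day effect is gone: block means comparable
  expect_lt(abs(mean(out$values[block == "d1", ]) -
                  mean(out$values[block == "d2", ])), 0.5)
})

test_that("normalization refuses metabolites with no observed values", {
  v <- cbind(m1 = c(1, 2, 3), m2 = c(NA, NA, NA))
  mm <- metabolite_matrix(v, site = c("A", "A", "B"))
  expect_error(median_normalize(mm, mode = "global"), "m2")
})

test_that("imputation fills with the per-metabolite minimum", {
  v <- cbind(m1 = c(0.5, 1, NA, 2))
  mm <- metabolite_matrix(v, site = rep("A", 4), normalized = "none")
  mm$normalized <- "global"  # bypass flag for a direct unit check
  mm$values <- v             # values unchanged; flag-only adjustment
  out <- impute_missing(mm)
  expect_equal(unname(out$values[3, 1]), 0.5)
  expect_equal(out$n_imputed, 1L)
  half <- impute_missing(mm, method = "half_minimum")
  expect_equal(unname(half$values[3, 1]), 0.25)
  expect_error(impute_missing(mm, method = "fail"), "missing")

  complete <- metabolite_matrix(cbind(m1 = c(1, 2, 3)), site = rep("A", 3))
  complete$normalized <- "global"
  expect_identical(impute_missing(complete)$values, complete$values)
})

test_that("random missingness is always imputed to the column minimum", {
  set.seed(14)
  v <- matrix(exp(rnorm(20 * 10)), 20)
  holes <- matrix(runif(200) < 0.1, 20)
  v[holes] <- NA
  v[1, ] <- pmax(v[1, ], 1e-9, na.rm = TRUE)  # keep every column observed
  mm <- metabolite_matrix(v, site = rep(c("A", "B"), each = 10))
  mm <- impute_missing(median_normalize(mm, mode = "global"))
  for (j in seq_len(ncol(v))) {
    miss <- which(is.na(v[, j]))
    if (length(miss)) {
      observed_min <- min(mm$values[-miss, j])
      expect_true(all(mm$values[miss, j] == observed_min))
    }
  }
})

test_that("pipeline order is enforced: normalize before impute and screen", {
  st <- simulate_study(small_config(seed = 2))
  expect_error(impute_missing(st$metabolites), "normalize")
  expect_error(anova_screen(st$metabolites), "normalized")
})

test_that("response block repeats each site's aggregate row exactly", {
  st <- simulate_study(small_config(seed = 10))
  agg <- drop_undetected(aggregate_max_by_site(st$panel))
  mm <- st$metabolites
  yb <- build_response_block(agg, mm)
  expect_equal(colnames(yb$values),
               c(colnames(agg$max_concentration), "temperature"))
  expect_identical(yb$force_keep, "temperature")
  for (i in sample(nrow(yb$values), 5)) {
    s <- mm$sample_info$site[i]
    expect_equal(unname(yb$values[i, seq_len(ncol(agg$max_concentration))]),
                 unname(agg$max_concentration[s, ]))
    expect_equal(unname(yb$values[i, "temperature"]),
                 unname(agg$max_temperature[s]))
  }
  # rows are site-constant
  for (s in unique(mm$sample_info$site)) {
    rows <- yb$values[mm$sample_info$site == s, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(col) all(col == col[1]))))
  }
})

test_that("response block refuses unknown sites and undropped aggregates", {
  st <- simulate_study(small_config(seed = 10))
  agg_raw <- aggregate_max_by_site(st$panel)
  mm <- st$metabolites
  expect_error(build_response_block(agg_raw, mm), "drop_undetected")
  agg <- drop_undetected(agg_raw)
  bad <- mm
  bad$sample_info$site[1] <- "S99"
  expect_error(build_response_block(agg, bad), "S99")
})

test_that("a single-site response block cannot be fitted", {
  # all rows identical -> zero response variance -> the fit must refuse
  y <- matrix(rep(c(1, 2, 3), each = 6), 6, 3)
  x <- matrix(rnorm(6 * 4), 6)
  expect_error(fit_pls(x, y, 1), "no variance")
})
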