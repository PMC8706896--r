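test_that("semi-quantification implements the IS normalisation formula", {
  areas <- tibble::tibble(
    sample_id = "S1",
    transition_id = c("PE 16:0_18:1", "15:0-18:1(d7) PE"),
    area = c(1000, 1000))
  samples <- tibble::tibble(sample_id = "S1", weight_mg = 100)
  compounds <- tibble::tibble(transition_id = "PE 16:0_18:1", class = "PE")
  conc <- semi_quantify(areas, samples, compounds, is_amount_ug = 150)
  expect_equal(conc$conc_ug_g, 1500)  # ratio 1 x 150 ug / 0.1 g

  samples$weight_mg <- 200
  conc2 <- semi_quantify(areas, samples, compounds, is_amount_ug = 150)
  expect_equal(conc2$conc_ug_g, conc$conc_ug_g / 2)
})

test_that("semi-quantification errors name the offending sample and class", {
  areas <- tibble::tibble(sample_id = "S7",
                          transition_id = "PE 16:0_18:1", area = 10)
  samples <- tibble::tibble(sample_id = "S7", weight_mg = 100)
  compounds <- tibble::tibble(transition_id = "PE 16:0_18:1", class = "PE")
  expect_error(semi_quantify(areas, samples, compounds), "PE.*S7")
  samples$weight_mg <- 0
  expect_error(semi_quantify(areas, samples, compounds), "weight")
})

test_that("noise-free forward simulation inverts to planted concentrations", {
  design <- maturation_design(noise_cv = 0, missing_rate = 0,
                              brix_jitter_sd = 0, weight_mg_sd = 0)
  compounds <- default_study_compounds(n_per_class = 4)
  sim <- simulate_maturation(design, compounds, seed = 5)
  conc <- semi_quantify(sim$areas, sim$samples, compounds = compounds)

  truth <- sim$truth$compounds
  study <- sim$samples[sim$samples$role == "study", ]
  one <- conc[conc$sample_id == study$sample_id[1], ]
  planted <- exp(truth$baseline_log +
                   truth$slope * (study$brix[1] - sim$truth$brix_centre))
  expect_equal(one$conc_ug_g[match(truth$transition_id, one$transition_id)],
               planted, tolerance = 1e-12)
})

test_that("imputation draws lie in (0, min/2), is seeded and leaves complete data alone", {
  conc <- tibble::tibble(
    sample_id = rep(c("a", "b", "c"), 2),
    transition_id = rep(c("x", "y"), each = 3),
    class = "PE",
    conc_ug_g = c(10, 20, NA, 4, NA, 8))
  out1 <- impute_missing(conc, seed = 3)
  out2 <- impute_missing(conc, seed = 3)
  expect_identical(out1, out2)
  expect_false(anyNA(out1$conc_ug_g))
  expect_true(out1$conc_ug_g[3] > 0 && out1$conc_ug_g[3] < 5)   # min 10 -> (0, 5)
  expect_true(out1$conc_ug_g[5] > 0 && out1$conc_ug_g[5] < 2)   # min 4  -> (0, 2)

  complete <- conc[!is.na(conc$conc_ug_g), ]
  expect_identical(impute_missing(complete, seed = 3), complete)

  allna <- conc
  allna$conc_ug_g[allna$transition_id == "y"] <- NA
  expect_error(impute_missing(allna, seed = 3), "no observed value")
})

test_that("CV percent matches hand-computed values and is scale invariant", {
  expect_equal(cv_percent(c(5, 5, 5)), 0)
  expect_equal(cv_percent(c(8, 10, 12)), 20)   # sd 2, mean 10
  v <- c(3.2, 4.8, 4.1, 3.9)
  expect_equal(cv_percent(v * 17), cv_percent(v))
  expect_error(cv_percent(5), "at least 2")
  expect_error(cv_percent(c(-1, 1)), "zero mean")
})

test_that("recovery averages replicates within level then levels within class", {
  spikes <- tidyr::crossing(class = "PI", level = c(0.1, 0.5, 1),
                            replicate = 1:5)
  spikes$expected <- spikes$level
  per_level <- c(`0.1` = 0.7, `0.5` = 0.8, `1` = 0.9)
  spikes$measured <- spikes$expected * per_level[as.character(spikes$level)]
  out <- recovery(spikes)
  expect_equal(out$recovery_pct, 80)           # mean of 70, 80, 90
  expect_equal(out$recovery_0.1, 70)

  ident <- spikes
  ident$measured <- ident$expected
  expect_equal(recovery(ident)$recovery_pct, 100)
  scaled <- spikes
  scaled$measured <- scaled$expected * 0.8
  expect_equal(recovery(scaled)$recovery_pct, 80)

  expect_error(recovery(spikes[spikes$level != 0.5, ]), "0.5")
})

test_that("linearity search finds the accurate contiguous run and its LOQ/LOD", {
  conc <- c(0.1, 0.5, 1, 5, 10, 50)
  perfect <- 100 * conc
  fit <- linearity_lod(conc, perfect, noise = 5)
  expect_equal(fit$range, c(0.1, 50))
  expect_equal(fit$loq, 0.1)
  expect_equal(fit$lod, 3.3 * 5 / fit$slope, tolerance = 1e-9)
  expect_equal(fit$flag, "ok")

  saturated <- perfect
  saturated[6] <- saturated[5] * 1.05   # detector ceiling
  fit2 <- linearity_lod(conc, saturated, noise = 5)
  expect_equal(fit2$range, c(0.1, 10))

  fit3 <- linearity_lod(conc, perfect, noise = 0)
  expect_equal(fit3$lod, 0)
  expect_equal(fit3$flag, "lod_below_lowest_level")

  expect_error(linearity_lod(conc[1:4], perfect[1:4]), ">= 5")
  flat <- linearity_lod(conc, rep(3, 6) + c(5, -5, 5, -5, 5, -5))
  expect_equal(flat$flag, "no_linear_range")
})

test_that("validation filter is an inclusive-CV and Kendrick conjunction", {
  rec <- tibble::tibble(
    transition_id = paste0("t", 1:4), class = "PE",
    repeatability_cv = c(10, 20, 20.5, 19),
    kmd_flag = c("pass", "pass", "pass", "diagonal_violation"))
  out <- validation_filter(rec)
  expect_setequal(out$retained$transition_id, c("t1", "t2"))  # 20.0 retained
  expect_equal(out$summary$validated, 2)

  all_ok <- rec
  all_ok$repeatability_cv <- 10
  all_ok$kmd_flag <- "pass"
  expect_equal(nrow(validation_filter(all_ok)$retained), 4)

  # monotone: tightening the threshold never adds compounds
  loose <- validation_filter(rec, cv_threshold = 20)$retained$transition_id
  tight <- validation_filter(rec, cv_threshold = 15)$retained$transition_id
  expect_true(all(tight %in% loose))
})

test_that("intra/inter-day thresholds can be applied as exclusions", {
  rec <- tibble::tibble(
    transition_id = c("a", "b"), class = "PE",
    repeatability_cv = c(10, 10), kmd_flag = "pass",
    intra_day_cv = c(10, 16), inter_day_cv = c(10, 10))
  out <- validation_filter(rec, apply_intra_inter = TRUE)
  expect_equal(out$retained$transition_id, "a")
  expect_error(validation_filter(rec[, 1:4], apply_intra_inter = TRUE),
               "not present")
})
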