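demo_design <- function(n_wells = 2, duration = 36, interval = 0.25,
                        blanks = 2, blank_level = 0.05) {
  plate_design(
    groups = list(list(label = "s", params = br_params(),
                       n_wells = n_wells)),
    duration = duration, interval = interval,
    blank_wells = blanks, blank_level = blank_level
  )
}

test_that("the default schedule yields duration/interval timepoints", {
  plate <- generate_plate(demo_design(), noise_model(seed = 1))
  tt <- sort(unique(plate$time))
  expect_length(tt, 144)
  expect_equal(tt[1], 0)
  expect_equal(tt[144], 35.75)
  # the law holds for other valid designs
  p2 <- generate_plate(demo_design(duration = 12, interval = 0.5),
                       noise_model(seed = 1))
  expect_length(unique(p2$time), 24)
  expect_error(plate_design(groups = demo_design()$groups, duration = 36,
                            interval = 0.7),
               class = "growthmedia_design_error")
})

test_that("noise-free generation inverts the closed form exactly", {
  plate <- generate_plate(demo_design(blanks = 0, blank_level = 0),
                          noise_model(additive_sd = 0, seed = 1))
  curve <- plate_strain(plate, "s")
  tt <- sort(unique(curve$time))
  for (w in unique(curve$well)) {
    expect_equal(curve$od[curve$well == w],
                 evaluate_growth(br_params(), tt), tolerance = 1e-14)
  }
})

test_that("generation is byte-identical under a fixed seed", {
  a <- generate_plate(demo_design(), noise_model(seed = 33))
  b <- generate_plate(demo_design(), noise_model(seed = 33))
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- generate_plate(demo_design(), noise_model(seed = 34))
  expect_false(identical(a$od, c$od))
})

test_that("blank wells carry only background plus noise", {
  plate <- generate_plate(demo_design(blanks = 4, blank_level = 0.05),
                          noise_model(additive_sd = 0, seed = 1))
  blanks <- attr(plate, "blank_wells")
  expect_length(blanks, 4)
  expect_true(all(plate$od[plate$well %in% blanks] == 0.05))
  # blank correction then recovers the clean curves
  curve <- plate_strain(blank_correct(plate, blanks), "s")
  tt <- sort(unique(curve$time))
  expect_equal(curve$od[curve$well == curve$well[1]],
               evaluate_growth(br_params(), tt), tolerance = 1e-12)
})

test_that("full pipeline closure: generate, correct, fit, summarise", {
  # one seeded replicate of the design at the default noise level; the
  # 20-seed median-error version of this check lives in the acceptance
  # suite where the runtime budget is spent deliberately
  truth <- params_from_summary(n0 = 0.13, k = 1.37, mu_max = 0.59,
                               lag_hours = 2.27)
  design <- plate_design(
    groups = list(list(label = "ZJ625", params = truth, n_wells = 6)),
    blank_wells = 4)
  plate <- generate_plate(design, noise_model(additive_sd = 0.02,
                                              seed = 21))
  curve <- plate_strain(blank_correct(plate, attr(plate, "blank_wells")),
                        "ZJ625")
  ks <- derive_kinetics(fit_model_family(curve, seed = 21))
  expect_lt(abs(ks$mu_max - 0.59) / 0.59, 0.10)
  expect_lt(abs(ks$lag_hours - 2.27) / 2.27, 0.10)
  expect_lt(abs(ks$max_density - 1.37) / 1.37, 0.10)
})

test_that("synthetic omission data recover their truth labels", {
  truth <- setNames(
    rep(c("essential", "stimulatory", "non_essential"), length.out = 37),
    paste0("component_", sprintf("%02d", 1:37)))
  ds <- generate_soe_dataset(truth, control_od = 4.5,
                             noise_model(additive_sd = 0.02 * 4.5,
                                         seed = 8))
  expect_equal(nrow(ds), 37)
  calls <- analyze_soe_table(ds, control_od_24h = c(synthetic = 4.5))
  expect_equal(calls$call, unname(truth))
  # noise-free, one per class
  t3 <- c(a = "essential", b = "stimulatory", c = "non_essential")
  d3 <- generate_soe_dataset(t3, control_od = 4,
                             noise_model(additive_sd = 0, seed = 1))
  expect_equal(analyze_soe_table(d3, control_od_24h = c(synthetic = 4))$call,
               unname(t3))
  # determinism and domain errors
  expect_identical(
    generate_soe_dataset(t3, 4, noise_model(seed = 5)),
    generate_soe_dataset(t3, 4, noise_model(seed = 5)))
  expect_error(generate_soe_dataset(t3, control_od = 0),
               class = "growthmedia_domain_error")
})
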