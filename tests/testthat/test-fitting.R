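test_that("blank correction subtracts the per-timepoint blank mean", {
  gc <- growth_curve(data.frame(
    time = rep(c(0, 1), 4),
    well = rep(c("S1", "S2", "B1", "B2"), each = 2),
    od = c(0.15, 0.30, 0.20, 0.40, 0.05, 0.06, 0.05, 0.04)
  ))
  out <- blank_correct(gc, c("B1", "B2"))
  expect_setequal(unique(out$well), c("S1", "S2"))
  expect_equal(out$od[out$well == "S1" & out$time == 0], 0.10)
  expect_equal(out$od[out$well == "S1" & out$time == 1], 0.25)
  expect_true(attr(out, "blank_corrected"))
  # floor rule
  low <- growth_curve(data.frame(time = 0, well = c("S1", "B1"),
                                 od = c(0.04, 0.05)))
  expect_equal(blank_correct(low, "B1", floor = 1e-3)$od, 1e-3)
  # empty blank list is the identity on the readings
  expect_equal(blank_correct(gc, character())$od, gc$od)
  expect_error(blank_correct(gc, "nope"),
               class = "growthmedia_lookup_error")
})

test_that("initial-parameter heuristics land near the truth", {
  p <- growth_params(n0 = 0.1, r = 0.8, k = 1.2)
  curve <- clean_curve(p)
  guess <- guess_initial_parameters(curve, model_spec("Logistic"))
  expect_lt(abs(guess$k - 1.2) / 1.2, 0.05)
  expect_gt(guess$r, 0)
  expect_gt(guess$n0, 0)
  # flat series is degenerate
  flat <- growth_curve(data.frame(time = 0:9, well = "w", od = 0.1))
  expect_error(guess_initial_parameters(flat, model_spec("Logistic")),
               class = "growthmedia_degenerate_input")
  # decreasing series clips r at the small positive minimum
  dec <- growth_curve(data.frame(time = 0:9, well = "w",
                                 od = seq(1, 0.1, length.out = 10)))
  gd <- guess_initial_parameters(dec, model_spec("Logistic"))
  expect_equal(gd$r, 1e-3)
})

test_that("BIC follows n log(rss/n) + k log(n) and flags rss = 0", {
  expect_equal(compute_bic(144, 144, 6), 6 * log(144))
  expect_equal(compute_bic(10, 10, 3), 3 * log(10))
  # random triples against a literal evaluation
  with_seed_local(5, {
    for (i in 1:20) {
      rss <- runif(1, 0.01, 50); n <- sample(10:500, 1); k <- sample(1:6, 1)
      expect_equal(compute_bic(rss, n, k), n * log(rss / n) + k * log(n))
    }
  })
  expect_identical(compute_bic(0, 100, 3), -Inf)
  expect_error(compute_bic(1, 3, 3), class = "growthmedia_domain_error")
})

test_that("noise-free curves are recovered near-exactly", {
  p <- growth_params(n0 = 0.1, r = 0.8, k = 1.2)
  curve <- clean_curve(p)  # 144 points
  fit <- fit_single_model(curve, model_spec("Logistic"), seed = 2)
  est <- fit$params
  expect_lt(abs(est$n0 - p$n0) / p$n0, 1e-3)
  expect_lt(abs(est$r - p$r) / p$r, 1e-3)
  expect_lt(abs(est$k - p$k) / p$k, 1e-3)
  # fitting the generating lagged model on its own data: near-perfect fit
  pb <- br_params()
  fitb <- fit_single_model(clean_curve(pb), model_spec("BaranyiRoberts"),
                           init = pb, seed = 2)
  expect_lt(fitb$rss, 1e-10)
})

test_that("noisy replicate wells recover LogisticLag2 parameters", {
  # median over seeded replicates of the 30-well, sigma = 0.02 design
  # (replicate count kept small here; the full-scale recovery check is an
  # acceptance criterion)
  truth <- growth_params(n0 = 0.13, r = 0.7, k = 1.37, v = 1,
                         q0 = 0.15, m = 0.7)
  errs <- sapply(1:5, function(seed) {
    curve <- noisy_curve(truth, n_wells = 30, sd = 0.02, seed = seed)
    fit <- fit_single_model(curve, model_spec("LogisticLag2"), seed = seed)
    vapply(c("n0", "r", "k", "q0", "m"), function(nm) {
      abs(fit$params[[nm]] - truth[[nm]]) / truth[[nm]]
    }, numeric(1))
  })
  expect_true(all(apply(errs, 1, median) < 0.05))
})

test_that("family ranking favours the generating structure", {
  # logistic truth: the no-lag, v = 1 member must win
  p <- growth_params(n0 = 0.1, r = 0.8, k = 1.2)
  fam <- fit_model_family(noisy_curve(p, n_wells = 3, sd = 0.02, seed = 4),
                          seed = 4)
  expect_equal(fam$model[1], "Logistic")
  # pronounced lag: the top-ranked model must carry a lag term
  pl <- growth_params(n0 = 0.13, r = 0.7, k = 1.37, v = 1,
                      q0 = 0.05, m = 0.7)
  faml <- fit_model_family(noisy_curve(pl, n_wells = 3, sd = 0.02, seed = 4),
                           seed = 4)
  expect_true(faml$model[1] %in% c("LogisticLag2", "BaranyiRoberts"))
  # nested refits never increase RSS (warm-started, Logistic vs B-R chain)
  tab <- glance(faml)
  expect_lte(tab$rss[tab$model == "BaranyiRoberts"],
             tab$rss[tab$model == "LogisticLag2"] + 1e-10)
  expect_lte(tab$rss[tab$model == "LogisticLag2"],
             tab$rss[tab$model == "Logistic"] + 1e-10)
  # single-spec family returns that fit alone
  solo <- fit_model_family(clean_curve(p), family = list(model_spec("Logistic")),
                           seed = 4)
  expect_equal(nrow(solo), 1)
  expect_equal(solo$model, "Logistic")
})

test_that("perfect fits rank by parameter count", {
  p <- growth_params(n0 = 0.1, r = 0.8, k = 1.2)
  curve <- clean_curve(p, times = seq(0, 35.75, 0.25))
  fam <- fit_model_family(curve, seed = 6)
  # noise-free logistic data: every member can fit near-perfectly, so the
  # tie margin (or -Inf BIC rule) must put the 3-parameter model first
  expect_equal(fam$model[1], "Logistic")
})

test_that("derived kinetics match their definitions", {
  # per-capita logistic rate is decreasing, so mu_max = r(1 - n0/k) at t = 0
  ks <- derive_kinetics(growth_params(0.01, 1, 1), window = c(0, 24))
  expect_equal(ks$mu_max, 0.99, tolerance = 1e-4)
  expect_equal(ks$min_doubling_time * ks$mu_max, log(2), tolerance = 1e-12)
  # doubling-time identity at the published rate
  expect_equal(round(log(2) / 0.59, 2), 1.17)
  # AUC of an (almost) saturated curve approaches K * T
  flatish <- growth_params(n0 = 0.999999, r = 5, k = 1)
  expect_equal(derive_kinetics(flatish, window = c(0, 10))$auc, 10,
               tolerance = 1e-4)
  # lag against an independent dense-grid tangent construction
  p <- growth_params(n0 = 0.1, r = 0.8, k = 1.3, v = 1, q0 = 0.05, m = 2)
  tt <- seq(0, 36, 1e-3)
  dn <- growth_rate(p, tt)
  i <- which.max(dn)
  lag_oracle <- tt[i] - (evaluate_growth(p, tt[i]) - p$n0) / dn[i]
  expect_equal(derive_kinetics(p, window = c(0, 36))$lag_hours, lag_oracle,
               tolerance = 1e-3)
})

test_that("kinetics refuse a non-converged fit", {
  p <- growth_params(0.1, 0.8, 1.2)
  fit <- fit_single_model(clean_curve(p), model_spec("Logistic"), seed = 1)
  fit$converged <- FALSE
  expect_error(derive_kinetics(fit),
               class = "growthmedia_convergence_error")
})
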