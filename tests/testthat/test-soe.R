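test_that("relative growth is the plain 24-h OD ratio", {
  expect_equal(relative_growth(5, 5), 100)
  expect_equal(relative_growth(0, 4.4), 0)
  expect_equal(relative_growth(2.2, 4.4), 50)
  # scale invariance
  with_seed_local(2, {
    x <- runif(10, 0.1, 5); y <- runif(10, 0.5, 6); a <- runif(10, 0.1, 9)
    expect_equal(relative_growth(a * x, a * y), relative_growth(x, y))
  })
  expect_error(relative_growth(1, 0), class = "growthmedia_domain_error")
  expect_error(relative_growth(-1, 1), class = "growthmedia_domain_error")
})

test_that("threshold rule: <40 essential, 40-80 stimulatory, >80 not", {
  expect_equal(classify_essentiality(2.0), "essential")
  expect_equal(classify_essentiality(60.24), "stimulatory")
  expect_equal(classify_essentiality(110.20), "non_essential")
  # boundary convention: both cutpoints belong to "stimulatory"
  expect_equal(classify_essentiality(c(39.999, 40, 80, 80.001)),
               c("essential", "stimulatory", "stimulatory",
                 "non_essential"))
  # monotone step function, exhaustive over [0, inf)
  grid <- seq(0, 200, by = 0.25)
  calls <- classify_essentiality(grid)
  rank <- c(essential = 1, stimulatory = 2, non_essential = 3)[calls]
  expect_true(all(diff(rank) >= 0))
  expect_true(all(calls %in% c("essential", "stimulatory",
                               "non_essential")))
  expect_error(classify_essentiality(-1),
               class = "growthmedia_domain_error")
})

test_that("the bundled omission table reproduces every printed call", {
  soe <- soe_table()
  expect_equal(nrow(soe), 74)
  calls <- analyze_soe_table(soe)
  expect_equal(calls$call, soe$call_printed)
  expect_equal(calls$omitted, soe$omitted)  # order preserved
})

test_that("batch classification needs a control or a precomputed value", {
  expect_equal(nrow(analyze_soe_table(data.frame())), 0)
  obs <- data.frame(omitted = "X", strain = "S1", od_0h = 0.1, od_24h = 2)
  expect_error(analyze_soe_table(obs),
               class = "growthmedia_config_error")
  expect_error(analyze_soe_table(obs, control_od_24h = c(S2 = 4)),
               class = "growthmedia_config_error")
  got <- analyze_soe_table(obs, control_od_24h = c(S1 = 4))
  expect_equal(got$relative_growth_pct, 50)
  expect_equal(got$call, "stimulatory")
})

test_that("minimal media are composed by call with explicit overrides", {
  ls <- compose_published_mdm("ZJ614")
  expect_setequal(ls$components$component,
                  mdm_medium("ls")$components$component)
  lr <- compose_published_mdm("ZJ625")
  expect_setequal(lr$components$component,
                  mdm_medium("lr")$components$component)
  # concentrations are copied unchanged from the complete medium
  cdm <- cdm_medium()
  joined <- merge(ls$components, cdm$components, by = "component")
  expect_equal(joined$concentration.x, joined$concentration.y)
})

test_that("composition handles edge cases and inconsistencies", {
  cdm <- cdm_medium()
  # all non-essential calls, no overrides: only un-called components stay
  calls <- data.frame(component = c("L-Alanine", "Biotin"),
                      call = "non_essential")
  out <- compose_minimal_medium(cdm, calls)
  expect_equal(nrow(out$components), 47)
  expect_false(any(c("L-Alanine", "Biotin") %in%
                     out$components$component))
  # calls for unknown components are a consistency error
  expect_error(
    compose_minimal_medium(cdm, data.frame(component = "Unobtainium",
                                           call = "essential")),
    class = "growthmedia_consistency_error")
})

test_that("medium union is the published co-culture medium", {
  ls <- mdm_medium("ls"); lr <- mdm_medium("lr")
  un <- union_medium(ls, lr)
  expect_setequal(un$components$component,
                  mdm_medium("lslr")$components$component)
  # valine only from one side, alanine only from the other, adenine absent
  expect_true("L-Valine" %in% un$components$component)
  expect_true("L-Alanine" %in% un$components$component)
  expect_false("Adenine" %in% un$components$component)
  # idempotent and commutative on the component set
  expect_equal(union_medium(ls, ls)$components, ls$components)
  expect_setequal(union_medium(lr, ls)$components$component,
                  un$components$component)
  # conflicting concentration for a shared component
  b <- ls
  b$components$concentration[b$components$component == "Glucose"] <- 10
  expect_error(union_medium(ls, b),
               class = "growthmedia_consistency_error")
})

test_that("the complete medium fixture has the documented structure", {
  cdm <- cdm_medium()
  expect_equal(nrow(cdm$components), 49)
  expect_equal(anyDuplicated(cdm$components$component), 0)
  expect_true(all(cdm$components$concentration > 0))
})
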