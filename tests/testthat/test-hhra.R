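test_that("ingestion and dermal doses match hand-evaluated formulas", {
  sc <- builtin_scenarios()
  expect_equal(add_ingestion(0.87, sc$adult, "nc"),
               0.87 * 100 * 350 * 24 / (65 * 8760) * 1e-6)
  expect_equal(add_ingestion(0.87, sc$adult, "nc"), 1.2835e-6,
               tolerance = 1e-4)
  expect_equal(add_ingestion(0.87, sc$child, "ca"), 8.995e-7,
               tolerance = 1e-4)
  expect_equal(add_dermal(0.87, sc$adult, 0.001, "nc"), 3.908e-9,
               tolerance = 1e-4)
  expect_equal(add_dermal(69.0, sc$child, 0.001, "nc"), 1.3316e-6,
               tolerance = 1e-4)
  expect_equal(add_ingestion(0, sc$adult, "ca"), 0)
  expect_equal(add_dermal(0, sc$child, 0.5, "nc"), 0)
  expect_error(add_ingestion(-1, sc$adult), "non-negative")
  expect_error(add_dermal(1, sc$adult, abs = 0), "0, 1")
})

test_that("built-in scenarios satisfy the averaging-time convention", {
  sc <- builtin_scenarios()
  for (s in sc) {
    expect_equal(s$AT_nc, s$ED * 365)
    expect_equal(s$AT_ca, s$LT * 365)
  }
  expect_equal(sc$adult$AT_ca, 25550)
  expect_equal(sc$child$AT_ca, 25550)
  expect_error(exposure_scenario("bad", IngR = -1, EF = 350, ED = 6,
                                 BW = 15, SA = 1600, AF = 0.2),
               "positive")
})

test_that("hazard quotients reproduce published town averages", {
  sc <- builtin_scenarios()
  h <- hazard_index(0.87, "Cd", sc$adult)
  expect_lt(rel_err(h$hq_ing, 1.28e-3), 0.01)
  expect_lt(rel_err(h$hq_derm, 3.90e-4), 0.01)
  expect_lt(rel_err(h$hi, 1.67e-3), 0.01)
  h2 <- hazard_index(69.0, "Pb", sc$child)
  expect_lt(rel_err(h2$hi, 2.40e-1), 0.01)
  z <- hazard_index(0, "Zn", sc$adult)
  expect_equal(c(z$hq_ing, z$hq_derm, z$hi), c(0, 0, 0))
  expect_false(z$hi_exceeds_1)
})

test_that("carcinogenic risk uses the ingestion slope factor only", {
  sc <- builtin_scenarios()
  cr <- carcinogenic_risk(0.87, "Cd", sc$child)
  expect_lt(rel_err(cr$cr, 1.35e-5), 0.01)
  expect_equal(as.character(cr$cr_category), "acceptable")
  cr2 <- carcinogenic_risk(69.0, "Pb", sc$adult)
  expect_lt(rel_err(cr2$cr, 2.97e-7), 0.01)
  expect_equal(as.character(cr2$cr_category), "virtually_safe")
  expect_equal(carcinogenic_risk(0, "Cd", sc$adult)$cr, 0)
  # non-carcinogens are a hard error, never silently zero
  expect_error(carcinogenic_risk(10, "Cu", sc$adult), "slope factor")
  expect_error(carcinogenic_risk(10, "Zn", sc$adult), "slope factor")
})

test_that("risk category boundaries follow the regulatory bands", {
  expect_equal(as.character(cr_category(c(1e-7, 1e-6, 2e-6, 9e-5, 1e-4))),
               c("virtually_safe", "virtually_safe", "acceptable",
                 "acceptable", "unacceptable"))
})

test_that("doses and risks are exactly linear in concentration", {
  sc <- builtin_scenarios()
  set.seed(31)
  conc <- runif(200, 0, 100)
  k <- 1000
  for (fn in list(function(cc) add_ingestion(cc, sc$adult, "nc"),
                  function(cc) add_dermal(cc, sc$child, 0.001, "ca"),
                  function(cc) hazard_index(cc, "Pb", sc$adult)$hi,
                  function(cc) carcinogenic_risk(cc, "Cd", sc$child)$cr)) {
    expect_equal(fn(k * conc), k * fn(conc))
    expect_equal(fn(mean(conc)), mean(fn(conc)))
  }
})

test_that("child ingestion quotients exceed adult by the scenario dose ratio", {
  sc <- builtin_scenarios()
  ratio <- (200 * 350 * 6 / (15.9 * 2190)) /
           (100 * 350 * 24 / (65 * 8760))
  expect_equal(ratio, 8.177, tolerance = 1e-3)
  for (m in c("Cd", "Cu", "Pb", "Zn")) {
    hq_a <- hazard_index(10, m, sc$adult)$hq_ing
    hq_c <- hazard_index(10, m, sc$child)$hq_ing
    expect_equal(hq_c / hq_a, ratio)
    expect_gt(hq_c, hq_a)
  }
})

test_that("risk_table averages per-sample risks exactly (linearity)", {
  sv <- random_survey(30, seed = 17)
  rt <- risk_table(sv)
  sc <- builtin_scenarios()
  for (tn in unique(sv$town)) {
    conc <- sv$Pb[sv$town == tn]
    per_sample_hi <- vapply(conc, function(cc)
      hazard_index(cc, "Pb", sc$adult)$hi, numeric(1))
    got <- rt$hi[rt$town == tn & rt$receptor == "adult" & rt$metal == "Pb"]
    expect_equal(got, mean(per_sample_hi))
  }
})

test_that("risk_table degenerate inputs behave as identities", {
  one <- random_survey(1, towns = "A", seed = 4)
  rt1 <- risk_table(one)
  sc <- builtin_scenarios()
  h <- hazard_index(one$Cd, "Cd", sc$adult)
  expect_equal(rt1$hi[rt1$receptor == "adult" & rt1$metal == "Cd"], h$hi)
  # n identical samples give the single-sample result
  rep8 <- one[rep(1, 8), ]
  rep8$sample_id <- paste0("S", 1:8)
  rt8 <- risk_table(rep8)
  expect_equal(rt8$hi, rt1$hi)
  expect_equal(rt8$cr, rt1$cr)
})

test_that("toxicity overrides propagate", {
  tox <- builtin_toxicity()
  tox$sf_ing[tox$metal == "Zn"] <- 1e-2
  sc <- builtin_scenarios()
  cr <- carcinogenic_risk(100, "Zn", sc$adult, tox)
  expect_equal(cr$cr, add_ingestion(100, sc$adult, "ca") * 1e-2)
})
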