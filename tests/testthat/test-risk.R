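test_that("odds ratios follow the printed arithmetic and identities", {
  expect_equal(round(odds_ratio(0.339, 0.402), 2), 0.76)
  expect_equal(odds_ratio(0.37, 0.37), 1)
  expect_equal(odds_ratio(0.5, 0.25), 3)
  expect_error(odds_ratio(0, 0.5), "strictly inside")
  expect_error(odds_ratio(0.5, 1), "strictly inside")
  set.seed(1)
  for (i in 1:25) {
    a <- stats::runif(1, 0.01, 0.99); b <- stats::runif(1, 0.01, 0.99)
    expect_equal(odds_ratio(a, b) * odds_ratio(b, a), 1, tolerance = 1e-12)
  }
})

scenario_pair <- function() {
  ev <- list("0" = c(age_group = "55", ltpa = "inactive",
                     smoking = "never"))
  tgt <- ev
  tgt[["1"]] <- c(ltpa = "active")
  list(cur = ev, tgt = tgt)
}

test_that("scenario comparison contrasts forecasts correctly", {
  m <- toy_model()
  ## both scenarios pin the slice-1 activity level, so the toy's risks are
  ## read straight off the memory CPT: 0.8 under inactivity, 0.2 under the
  ## intervention
  sp <- scenario_pair()
  sp$cur[["1"]] <- c(ltpa = "inactive")
  ## identical evidence -> no effect
  same <- compare_scenarios(m, sp$cur, sp$cur, 1, "memory", draws = 0)
  expect_equal(same$absolute_reduction_pp, 0)
  expect_equal(same$odds_ratio, 1)
  ## intervention flips outcome risk 0.8 -> 0.2
  cmp <- compare_scenarios(m, sp$cur, sp$tgt, 1, "memory", draws = 0)
  expect_equal(cmp$p_current, 0.8, tolerance = 1e-12)
  expect_equal(cmp$p_target, 0.2, tolerance = 1e-12)
  expect_equal(cmp$absolute_reduction_pp, 60, tolerance = 1e-9)
  expect_equal(cmp$odds_ratio, 0.0625, tolerance = 1e-9)
  ## antisymmetry under swapping scenarios
  rev <- compare_scenarios(m, sp$cur, sp$tgt, 1, "memory", draws = 0)
  fwd <- compare_scenarios(m, sp$tgt, sp$cur, 1, "memory", draws = 0)
  expect_equal(rev$odds_ratio * fwd$odds_ratio, 1, tolerance = 1e-12)
  expect_equal(rev$absolute_reduction_pp, -fwd$absolute_reduction_pp)
  ## guards
  expect_error(compare_scenarios(m, sp$cur, sp$tgt, 1, "ltpa", draws = 0),
               "not an outcome")
  bad <- sp$tgt
  bad[["0"]]["ltpa"] <- "active"
  expect_error(compare_scenarios(m, sp$cur, bad, 1, "memory", draws = 0),
               "future-slice")
})

test_that("credible intervals are seeded, consistent and concentrate", {
  m <- toy_model()
  sp <- scenario_pair()
  ci1 <- credible_interval(m, sp$cur, sp$tgt, 1, "memory", draws = 300,
                           seed = 11)
  ci2 <- credible_interval(m, sp$cur, sp$tgt, 1, "memory", draws = 300,
                           seed = 11)
  expect_identical(ci1, ci2)

  cmp <- compare_scenarios(m, sp$cur, sp$tgt, 1, "memory", draws = 2000,
                           seed = 5)
  expect_lt(cmp$credible_interval[["low"]], cmp$odds_ratio)
  expect_gt(cmp$credible_interval[["high"]], cmp$odds_ratio)

  ## scaling the counts towards the infinite-data limit shrinks the interval
  m_big <- m
  m_big$initial <- lapply(m_big$initial, function(f) {
    f$counts <- f$counts * 1e6; f })
  m_big$transition <- lapply(m_big$transition, function(f) {
    if (!f$deterministic) f$counts <- f$counts * 1e6; f })
  ci_big <- credible_interval(m_big, sp$cur, sp$tgt, 1, "memory",
                              draws = 300, seed = 2)
  expect_lt(ci_big[["high"]] - ci_big[["low"]], 0.02)
  expect_lt(abs(mean(ci_big) - cmp$odds_ratio), 0.05)
})

test_that("the decision heatmap has exact status-quo cells and is dynamic", {
  m <- toy_model()
  cur <- list("0" = c(age_group = "55", ltpa = "inactive",
                      smoking = "never"))
  hm <- decision_heatmap(m, cur, "memory")
  cells <- hm$cells
  ## the status-quo cell of every factor has delta exactly 0
  expect_true(all(cells$delta_pp[cells$status_quo] == 0))
  ## only the LTPA row moves the outcome in this toy
  expect_true(all(cells$delta_pp[cells$factor == "smoking"] == 0))
  expect_true(any(cells$delta_pp[cells$factor == "ltpa"] != 0))
  ## cells equal an independent direct forecast
  tgt <- cur
  tgt[["1"]] <- c(ltpa = "active")
  direct <- forecast_risk(m, tgt, 1)$outcome_probabilities["1", "memory"]
  expect_equal(cells$risk[cells$factor == "ltpa" &
                            cells$level == "active"],
               unname(direct), tolerance = 1e-12)
  ## committing the best LTPA cell re-bases the matrix on that choice
  best <- cells[cells$factor == "ltpa", ]
  best <- best[which.min(best$risk), ]
  hm2 <- decision_heatmap(m, cur, "memory",
                          committed = c(ltpa = best$level))
  expect_equal(hm2$baseline_risk, best$risk, tolerance = 1e-12)
  expect_error(decision_heatmap(m, cur, "memory",
                                committed = c(ltpa = "active",
                                              ltpa = "inactive")),
               "conflict")
  expect_error(decision_heatmap(m, list("0" = c(age_group = "55")),
                                "memory"),
               "modifiable")
})

test_that("sampled cross/autocorrelations behave as constructed", {
  ## outcome independent of everything and a perfectly persistent factor
  m <- toy_model(p_mem_inactive = 0.5, p_mem_active = 0.5, persist = 1)
  res <- outcome_cross_correlations(
    m, list("0" = c(age_group = "55")), horizon = 2,
    n_samples = 20000, seed = 3)
  expect_equal(res$auto["ltpa", "lag1"], 1, tolerance = 1e-12)
  expect_lt(abs(res$auto["memory", "lag1"]), 3 / sqrt(20000) * 2)
  res2 <- outcome_cross_correlations(
    m, list("0" = c(age_group = "55")), horizon = 2,
    n_samples = 20000, seed = 3)
  expect_identical(res$auto, res2$auto)
  ## degenerate indicators give NA, not an error
  expect_true(is.na(res$auto["age_group", "lag1"]) ||
                is.finite(res$auto["age_group", "lag1"]))
  expect_error(outcome_cross_correlations(m, list("0" = c(age_group = "55")),
                                          n_samples = 10),
               ">= 1000")
})

test_that("correlated outcomes through a shared cause show positive phi", {
  ## two outcomes both driven by ltpa
  reg <- variable_registry(list(
    list(name = "age_group", domain = c("55", "60"), role = "dynamic"),
    list(name = "ltpa", domain = c("inactive", "active"), role = "dynamic"),
    list(name = "memory", domain = c("good", "declined"), role = "outcome"),
    list(name = "learning", domain = c("good", "declined"),
         role = "outcome")))
  cpt <- matrix(c(0.2, 0.8, 0.8, 0.2), 2, byrow = TRUE)
  age_t <- matrix(c(0, 1, 0, 1), 2, byrow = TRUE)
  attr(age_t, "deterministic") <- TRUE
  m <- manual_model(reg,
                    list(memory = "ltpa", learning = "ltpa"),
                    list(age_group = matrix(c(1, 0), 1),
                         ltpa = matrix(c(0.5, 0.5), 1),
                         memory = cpt, learning = cpt),
                    list(age_group = age_t,
                         ltpa = matrix(c(0.9, 0.1, 0.1, 0.9), 2,
                                       byrow = TRUE)))
  res <- outcome_cross_correlations(m, list("0" = c(age_group = "55")),
                                    horizon = 1, n_samples = 20000, seed = 9)
  expect_gt(res$cross[[1]]["memory", "learning"], 0.2)
})
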