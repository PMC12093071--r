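two_var_copy_cohort <- function(n = 100, seed = 5) {
  set.seed(seed)
  reg <- variable_registry(list(
    list(name = "x", domain = c("a", "b"), role = "dynamic"),
    list(name = "y", domain = c("u", "v"), role = "outcome")))
  x <- sample(c("a", "b"), n, TRUE)
  df <- data.frame(id = as.character(seq_len(n)), phase = 1, x = x,
                   y = c(u = "u", a = "u", b = "v")[x],
                   stringsAsFactors = FALSE)
  df$y <- ifelse(x == "a", "u", "v")
  list(reg = reg, tab = as_cohort(df, reg))
}

test_that("candidate parents follow the expert ordering", {
  reg <- default_registry()
  expect_identical(candidate_parents("age_group", reg), character(0))
  expect_identical(candidate_parents("gender", reg), "age_group")
  expect_length(candidate_parents("learning", reg), 16)
  expect_error(candidate_parents("nope", reg), "unknown variable")
})

test_that("a deterministic copy relationship is learned", {
  fx <- two_var_copy_cohort()
  st <- learn_structure(fx$tab, fx$reg)
  expect_identical(st$intra_parents$y, "x")
  expect_identical(st$intra_parents$x, character(0))
  rep <- structure_report(st)
  expect_identical(rep$parents[rep$node == "y"], "x")
  expect_gt(rep$margin[rep$node == "y"], 0)
})

test_that("independent uniform variables mostly get empty parent sets", {
  doms <- list(c("a","b"), c("a","b","c"), c("a","b"), c("a","b","c"),
               c("a","b"), c("a","b"))
  reg <- variable_registry(lapply(seq_along(doms), function(i)
    list(name = paste0("v", i), domain = doms[[i]], role = "dynamic")))
  set.seed(99)
  empty_frac <- replicate(20, {
    df <- data.frame(id = as.character(1:500), phase = 1,
                     stringsAsFactors = FALSE)
    for (i in seq_along(doms))
      df[[paste0("v", i)]] <- sample(doms[[i]], 500, TRUE)
    st <- learn_structure(as_cohort(df, reg), reg)
    mean(lengths(st$intra_parents) == 0)
  })
  expect_gte(mean(empty_frac), 0.8)
})

test_that("exhaustive search equals the re-enumeration oracle on small nets", {
  for (seed in c(3, 17)) {
    set.seed(seed)
    doms <- list(c("a","b","c"), c("a","b"), c("a","b"), c("a","b","c"),
                 c("a","b"), c("a","b"))
    reg <- variable_registry(lapply(seq_along(doms), function(i)
      list(name = paste0("v", i), domain = doms[[i]], role = "dynamic")))
    n <- 300
    df <- data.frame(id = as.character(seq_len(n)), phase = 1,
                     stringsAsFactors = FALSE)
    df$v1 <- sample(doms[[1]], n, TRUE)
    df$v2 <- ifelse(stats::runif(n) < 0.7, c(a="a", b="b", c="a")[df$v1],
                    sample(doms[[2]], n, TRUE))
    for (i in 3:6) df[[paste0("v", i)]] <- sample(doms[[i]], n, TRUE)
    ## inject some missingness
    df$v3[sample(n, 30)] <- NA
    tab <- suppressWarnings(as_cohort(df, reg))
    st <- suppressWarnings(learn_structure(tab, reg))
    oracle <- oracle_search(tab, reg)
    for (v in names(reg$vars)) {
      expect_identical(sort(st$intra_parents[[v]]),
                       sort(oracle[[v]]$parents), info = v)
      expect_equal(st$scores[[v]], oracle[[v]]$score, info = v)
    }
    expect_equal(st$total_score, sum(st$scores))
  }
})

test_that("every selected parent precedes its child; parent cap is respected", {
  tab <- planted_cohort_5k()
  reg <- default_registry()
  st <- memoize("planted5k_structure",
                function() suppressWarnings(learn_structure(tab, reg)))
  ord <- vapply(reg$vars, function(v) v$ordering_index, integer(1))
  for (v in names(st$intra_parents)) {
    ps <- st$intra_parents[[v]]
    expect_lte(length(ps), 3L)
    if (length(ps)) expect_true(all(ord[ps] < ord[[v]]))
  }
  expect_identical(st$temporal, scdforecast:::reg_temporal(reg))
})

test_that("raising the parent cap never lowers the total score", {
  fx <- two_var_copy_cohort(n = 60, seed = 8)
  reg6 <- variable_registry(list(
    list(name = "x", domain = c("a", "b"), role = "dynamic"),
    list(name = "z", domain = c("a", "b", "c"), role = "dynamic"),
    list(name = "y", domain = c("u", "v"), role = "outcome")))
  set.seed(21)
  n <- 400
  df <- data.frame(id = as.character(1:n), phase = 1,
                   x = sample(c("a", "b"), n, TRUE),
                   z = sample(c("a", "b", "c"), n, TRUE),
                   stringsAsFactors = FALSE)
  df$y <- ifelse((df$x == "a") == (df$z != "c"), "u", "v")
  tab <- as_cohort(df, reg6)
  totals <- vapply(0:2, function(mp)
    learn_structure(tab, reg6, max_parents = mp)$total_score, numeric(1))
  expect_true(all(diff(totals) >= -1e-12))
})

test_that("planted outcome parents are recovered from synthetic data", {
  tab <- planted_cohort_5k()
  reg <- default_registry()
  st <- memoize("planted5k_structure",
                function() suppressWarnings(learn_structure(tab, reg)))
  planted <- c("gender", "alcohol", "ltpa")
  for (o in c("concentration", "memory", "learning")) {
    hits <- sum(planted %in% st$intra_parents[[o]])
    expect_gte(hits, 2L)
  }
})
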