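test_that("posteriors reduce to CPT rows / prior marginals in edge cases", {
  m <- toy_model()
  ## evidence fixes the only parent of memory -> posterior is the CPT row
  post <- slice_posteriors(m, c(age_group = "55", ltpa = "inactive"))
  expect_equal(unname(post$memory), c(0.2, 0.8), tolerance = 1e-12)
  ## no evidence -> prior marginals
  post0 <- slice_posteriors(m)
  expect_equal(unname(post0$ltpa), c(0.6, 0.4))
  expect_equal(unname(post0$memory), c(0.6 * 0.2 + 0.4 * 0.8,
                                       0.6 * 0.8 + 0.4 * 0.2))
  ## every posterior sums to 1
  for (p in post0) expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("a 3-node chain posterior matches hand enumeration", {
  reg <- variable_registry(list(
    list(name = "A", domain = c("0", "1"), role = "dynamic"),
    list(name = "B", domain = c("0", "1"), role = "dynamic"),
    list(name = "C", domain = c("0", "1"), role = "outcome")))
  probs <- list(
    A = matrix(c(0.7, 0.3), 1),
    B = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
    C = matrix(c(0.6, 0.4, 0.1, 0.9), 2, byrow = TRUE))
  m <- manual_model(reg, list(B = "A", C = "B"), probs)
  post <- slice_posteriors(m, c(C = "1"))
  ## hand enumeration: P(A, C=1) = sum_B P(A) P(B|A) P(C=1|B)
  pa <- c(0.7 * (0.9 * 0.4 + 0.1 * 0.9), 0.3 * (0.2 * 0.4 + 0.8 * 0.9))
  expect_equal(unname(post$A), pa / sum(pa), tolerance = 1e-12)
  expect_equal(enum_posterior(m, evidence = c(C = "1"), query = "A"),
               post$A, tolerance = 1e-12)
})

test_that("elimination agrees with joint enumeration on random networks", {
  for (seed in c(2, 9, 23)) {
    m <- random_small_model(n_nodes = 8, max_card = 3, max_parents = 3,
                            seed = seed)
    nodes <- names(m$registry$vars)
    set.seed(seed + 1000)
    ev_vars <- sample(nodes, 2)
    ev <- vapply(ev_vars, function(v)
      sample(m$registry$vars[[v]]$domain, 1), character(1))
    post <- slice_posteriors(m, ev)
    for (q in setdiff(nodes, ev_vars))
      expect_equal(post[[q]], enum_posterior(m, ev, query = q),
                   tolerance = 1e-9, info = paste(seed, q))
  }
})

test_that("impossible evidence raises a distinct error", {
  m <- toy_model()
  ## age is deterministic across slices: claiming age 55 at slice 1 after
  ## starting at 55 contradicts the +5y clock
  ev <- list("0" = c(age_group = "55"), "1" = c(age_group = "55"))
  expect_error(forecast_risk(m, ev, 1), "impossible evidence")
})

test_that("MAP states take the marginal mode with low-index ties", {
  expect_identical(map_states(list(x = c(a = 0.6, b = 0.4))), c(x = "a"))
  expect_identical(map_states(list(x = c(a = 0.5, b = 0.5))), c(x = "a"))
  expect_identical(map_states(list(x = c(a = 0.2, b = 0.3, c = 0.5))),
                   c(x = "c"))
})

test_that("forecasting propagates MAP states and honours future evidence", {
  m <- toy_model(persist = 0.9)
  ev <- list("0" = c(age_group = "55", ltpa = "inactive",
                     smoking = "never"))
  ## H = 0 equals the initial-slice posteriors
  f0 <- forecast_risk(m, ev, 0)
  expect_equal(f0$slices[[1]]$posteriors,
               slice_posteriors(m, ev[["0"]]))
  ## slice 1: MAP carries ltpa = inactive forward; P(inactive at 1) = 0.9,
  ## so P(memory declined at 1) = 0.9 * 0.8 + 0.1 * 0.2
  f1 <- forecast_risk(m, ev, 1)
  expect_equal(unname(f1$outcome_probabilities["1", "memory"]),
               0.9 * 0.8 + 0.1 * 0.2, tolerance = 1e-12)
  expect_identical(unname(f1$slices[[2]]$map[["age_group"]]), "60")
  ## future evidence overrides the propagated state at its slice only
  ev2 <- ev
  ev2[["1"]] <- c(ltpa = "active")
  f2 <- forecast_risk(m, ev2, 1)
  expect_equal(f2$slices[[1]]$posteriors, f1$slices[[1]]$posteriors)
  expect_equal(unname(f2$outcome_probabilities["1", "memory"]), 0.2,
               tolerance = 1e-12)
})

test_that("a fully deterministic toy follows the hand-computed trajectory", {
  m <- toy_model(p_mem_inactive = 1, p_mem_active = 0, persist = 1)
  ## start inactive: memory declined with certainty at every slice
  ev <- list("0" = c(age_group = "55", ltpa = "inactive",
                     smoking = "never"))
  f <- forecast_risk(m, ev, 1)
  expect_equal(unname(f$outcome_probabilities[, "memory"]), c(1, 1))
  expect_identical(unname(f$slices[[2]]$map[["ltpa"]]), "inactive")
  ## full evidence on every slice is reproduced as MAP states
  ev_full <- list(
    "0" = c(age_group = "55", ltpa = "active", smoking = "never",
            memory = "good"),
    "1" = c(ltpa = "active", smoking = "never", memory = "good"))
  ff <- forecast_risk(m, ev_full, 1)
  expect_identical(unname(ff$slices[[2]]$map[c("ltpa", "smoking", "memory")]),
                   c("active", "never", "good"))
})

test_that("horizons beyond the top age group are truncated with a warning", {
  m <- toy_model()
  ev <- list("0" = c(age_group = "55"))
  expect_warning(f <- forecast_risk(m, ev, 5), "truncated")
  expect_identical(f$horizon, 1L)
  expect_error(forecast_risk(m, list("0" = c(ltpa = "active")), 1),
               "age_group")
})

test_that("forward sampling reproduces slice-0 marginals within 3 SE", {
  m <- random_small_model(n_nodes = 6, max_card = 3, max_parents = 2,
                          seed = 31)
  nodes <- names(m$registry$vars)
  ## independent ancestral sampler (oracle, no shared inference code)
  set.seed(7)
  n <- 1e5
  draws <- matrix(NA_integer_, n, length(nodes), dimnames = list(NULL, nodes))
  for (v in nodes) {
    fam <- m$initial[[v]]
    k <- length(m$registry$vars[[v]]$domain)
    pcfg <- rep(0L, n); mult <- 1L
    for (par in fam$parents) {
      pcfg <- pcfg + draws[, par] * mult
      mult <- mult * length(m$registry$vars[[par]]$domain)
    }
    u <- stats::runif(n)
    cum <- t(apply(fam$prob, 1, cumsum))
    draws[, v] <- rowSums(u > cum[pcfg + 1L, , drop = FALSE])
  }
  post <- slice_posteriors(m)
  for (v in nodes) {
    k <- length(post[[v]])
    freq <- tabulate(draws[, v] + 1L, nbins = k) / n
    se <- sqrt(pmax(post[[v]] * (1 - post[[v]]), 1e-12) / n)
    expect_true(all(abs(freq - post[[v]]) <= 3 * se + 1e-9), info = v)
  }
})

test_that("transition-slice posteriors match enumeration from fixed states", {
  m <- toy_model(persist = 0.85)
  prev <- c(age_group = "55", ltpa = "inactive", smoking = "current_smoker",
            memory = "declined")
  for (ev in list(NULL, c(smoking = "never"))) {
    post <- slice_posteriors(m, ev, prev_states = prev)
    for (q in setdiff(names(m$registry$vars), names(ev))) {
      oracle <- enum_posterior(m, ev, prev_states = prev, query = q)
      expect_equal(post[[q]], oracle, tolerance = 1e-12, info = q)
    }
  }
})
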