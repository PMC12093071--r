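#' Odds ratio of two probabilities
#'
#' `[p_target / (1 - p_target)] / [p_current / (1 - p_current)]`.
#'
#' @param p_target,p_current probabilities strictly inside (0, 1).
#' @return the odds ratio (> 0).
#' @examples
#' odds_ratio(0.339, 0.402)   # ~0.76
#' @export
odds_ratio <- function(p_target, p_current) {
  if (any(c(p_target, p_current) <= 0) || any(c(p_target, p_current) >= 1))
    stop("probabilities must lie strictly inside (0, 1)")
  (p_target / (1 - p_target)) / (p_current / (1 - p_current))
}

#' Compare a current and a target (intervention) scenario
#'
#' Runs [forecast_risk()] under both evidence sets and contrasts the
#' outcome probability at the requested slice: absolute risk reduction in
#' percentage points, odds ratio, and (optionally) an equal-tailed Bayesian
#' credible interval for the odds ratio obtained by resampling all CPT rows
#' from their Dirichlet posteriors.
#'
#' @param model a `dbn_model`.
#' @param current evidence set of the status-quo scenario (see
#'   [forecast_risk()]).
#' @param target evidence set of the intervention scenario; must agree with
#'   `current` at slice 0 (interventions are future-slice evidence).
#' @param horizon slice at which the outcome is read.
#' @param outcome an outcome or health node.
#' @param level credible level (default 0.95).
#' @param draws number of Dirichlet posterior draws for the interval;
#'   `draws = 0` skips the interval.
#' @param seed RNG seed for the interval draws.
#' @return an object of class `scenario_comparison` with elements
#'   `p_current`, `p_target`, `absolute_reduction_pp`, `odds_ratio` and
#'   `credible_interval`.
#' @export
compare_scenarios <- function(model, current, target, horizon = 1L, outcome,
                              level = 0.95, draws = 500L, seed = 1L) {
  check_outcome(model, outcome)
  current <- normalize_evidence(current)
  target <- normalize_evidence(target)
  if (!identical(current[["0"]][order(names(current[["0"]]))],
                 target[["0"]][order(names(target[["0"]]))]))
    stop("target may differ from current only in future-slice evidence")
  p_c <- forecast_risk(model, current, horizon)$outcome_probabilities[
    as.character(horizon), outcome]
  p_t <- forecast_risk(model, target, horizon)$outcome_probabilities[
    as.character(horizon), outcome]
  ci <- if (draws > 0)
    credible_interval(model, current, target, horizon, outcome,
                      level = level, draws = draws, seed = seed)
  structure(list(outcome = outcome, horizon = horizon,
                 p_current = unname(p_c), p_target = unname(p_t),
                 absolute_reduction_pp = 100 * (unname(p_c) - unname(p_t)),
                 odds_ratio = odds_ratio(p_t, p_c),
                 credible_interval = ci, level = level),
            class = "scenario_comparison")
}

check_outcome <- function(model, outcome) {
  role <- reg_role(model$registry, outcome)
  if (is.null(role) || !role %in% c("outcome", "health"))
    stop("'", outcome, "' is not an outcome or health node")
}

## draw one model with every estimated CPT row resampled from its
## Dirichlet(counts + alpha) posterior; deterministic families are kept
resample_model <- function(model) {
  draw_fam <- function(fam) {
    if (isTRUE(fam$deterministic)) return(fam)
    shape <- fam$counts + model$alpha
    g <- matrix(stats::rgamma(length(shape), shape = as.vector(shape)),
                nrow = nrow(shape))
    fam$prob <- g / rowSums(g)
    fam
  }
  model$initial <- lapply(model$initial, draw_fam)
  model$transition <- lapply(model$transition, draw_fam)
  model
}

#' Bayesian credible interval for a scenario odds ratio
#'
#' Parameter uncertainty is propagated by sampling every CPT row from its
#' Dirichlet posterior (observed counts plus the smoothing pseudo-counts),
#' recomputing both scenario forecasts under each sampled model, and taking
#' equal-tailed quantiles of the resulting odds ratios. Deterministic for a
#' fixed seed.
#'
#' @inheritParams compare_scenarios
#' @param draws number of posterior draws (>= 100 recommended).
#' @return named numeric `c(low, high)`.
#' @export
credible_interval <- function(model, current, target, horizon = 1L, outcome,
                              level = 0.95, draws = 500L, seed = 1L) {
  check_outcome(model, outcome)
  set.seed(seed)
  h <- as.character(horizon)
  ors <- vapply(seq_len(draws), function(i) {
    m <- resample_model(model)
    p_c <- suppressWarnings(
      forecast_risk(m, current, horizon))$outcome_probabilities[h, outcome]
    p_t <- suppressWarnings(
      forecast_risk(m, target, horizon))$outcome_probabilities[h, outcome]
    odds_ratio(p_t, p_c)
  }, numeric(1))
  a <- (1 - level) / 2
  stats::setNames(stats::quantile(ors, c(a, 1 - a), names = FALSE),
                  c("low", "high"))
}

#' Dynamic decision heatmap
#'
#' For each modifiable lifestyle factor and each attainable level, predicts
#' the outcome risk one slice (5 years) ahead when that factor is set to
#' that level, on top of any already committed choices, and reports the
#' change versus keeping the factor at its status-quo level (the committed
#' level if the factor was committed, otherwise its current slice-0
#' value). Committing a choice and re-rendering updates all cells, which
#' is what makes the heatmap dynamic.
#'
#' @param model a `dbn_model`.
#' @param current slice-0 evidence; must define every modifiable factor.
#' @param outcome an outcome or health node.
#' @param committed named character vector of already-chosen slice-1 target
#'   levels (at most one per factor).
#' @return an object of class `decision_matrix`: `cells` (data.frame with
#'   factor, level, risk, delta in percentage points, status-quo flag) and
#'   `baseline_risk`, the slice-1 risk under the committed evidence alone.
#' @export
decision_heatmap <- function(model, current, outcome, committed = character(0)) {
  check_outcome(model, outcome)
  current <- normalize_evidence(current)
  factors <- setdiff(reg_temporal(model$registry), "age_group")
  ev0 <- current[["0"]]
  missing_f <- setdiff(factors, names(ev0))
  if (length(missing_f))
    stop("current evidence must define all modifiable factors at slice 0; ",
         "missing: ", paste(missing_f, collapse = ", "))
  committed <- unlist(committed)
  if (length(committed) && anyDuplicated(names(committed)))
    stop("conflicting commitments: two levels given for one factor")

  risk_at_1 <- function(slice1) {
    ev <- current
    ev[["1"]] <- slice1
    forecast_risk(model, ev, horizon = 1L)$outcome_probabilities["1", outcome]
  }
  baseline_risk <- risk_at_1(committed)

  cells <- list()
  for (f in factors) {
    status <- if (f %in% names(committed)) committed[[f]] else ev0[[f]]
    base_sl <- committed
    base_sl[f] <- status
    row_base <- risk_at_1(base_sl)
    for (lev in reg_domain(model$registry, f)) {
      sl <- committed
      sl[f] <- lev
      r <- risk_at_1(sl)
      cells[[length(cells) + 1L]] <- data.frame(
        factor = f, level = lev, risk = unname(r),
        delta_pp = 100 * (unname(r) - unname(row_base)),
        status_quo = lev == status, stringsAsFactors = FALSE)
    }
  }
  structure(list(outcome = outcome, cells = do.call(rbind, cells),
                 baseline_risk = unname(baseline_risk),
                 committed = committed),
            class = "decision_matrix")
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat("Decision heatmap for '", x$outcome, "' 5 years ahead; baseline risk ",
      sprintf("%.1f%%", 100 * x$baseline_risk), "\n", sep = "")
  if (length(x$committed))
    cat("Committed:", paste(names(x$committed), x$committed, sep = "=",
                            collapse = ", "), "\n")
  bin <- function(d) {
    if (abs(d) < 1) " . "
    else if (d <= -5) "---"
    else if (d < 0) " - "
    else if (d >= 5) "+++"
    else " + "
  }
  for (f in unique(x$cells$factor)) {
    rows <- x$cells[x$cells$factor == f, ]
    cat(sprintf("  %-10s ", f))
    for (i in seq_len(nrow(rows))) {
      mark <- if (rows$status_quo[i]) "*" else " "
      cat(sprintf("%s%s %5.1f%% [%s]  ", mark, rows$level[i],
                  100 * rows$risk[i], bin(rows$delta_pp[i])))
    }
    cat("\n")
  }
  invisible(x)
}

#' Cross- and autocorrelations of the model's output variables
#'
#' Forward-samples trajectories from the DBN (ancestral sampling with
#' evidence variables fixed) and computes Pearson (phi) correlations
#' between the adverse-state indicators of outcome and health nodes within
#' each slice, and per-variable autocorrelations across lags 1..horizon.
#' Constant indicators yield `NA` rather than an error.
#'
#' @param model a `dbn_model`.
#' @param evidence evidence set (slice-0 evidence must include the age
#'   group).
#' @param horizon number of transition steps to sample.
#' @param n_samples number of sampled trajectories (>= 1000).
#' @param seed RNG seed.
#' @return list with `cross` (outcome/health correlation matrix per slice)
#'   and `auto` (matrix variable by lag).
#' @export
outcome_cross_correlations <- function(model, evidence, horizon = 3L,
                                       n_samples = 10000L, seed = 1L) {
  if (n_samples < 1000L) stop("n_samples must be >= 1000")
  set.seed(seed)
  evidence <- normalize_evidence(evidence)
  nodes <- reg_names(model$registry)
  karr <- lapply(model$registry$vars, function(v) length(v$domain))

  sample_slice <- function(prev, ev) {
    ## prev: NULL or matrix n x vars of 0-based codes
    out <- matrix(NA_integer_, n_samples, length(nodes),
                  dimnames = list(NULL, nodes))
    evc <- evidence_codes(model, as.list(ev))
    for (node in nodes) {
      if (node %in% names(evc)) { out[, node] <- evc[[node]]; next }
      if (!is.null(prev) && node %in% names(model$transition)) {
        fam <- model$transition[[node]]
        pcode <- prev[, node] +
          parent_config_code(out, fam$parents, karr) * karr[[node]]
      } else {
        fam <- model$initial[[node]]
        pcode <- parent_config_code(out, fam$parents, karr)
      }
      cp <- fam$prob %*% upper.tri(diag(ncol(fam$prob)), diag = TRUE)
      u <- stats::runif(n_samples)
      out[, node] <- ncol(cp) - as.integer(
        rowSums(u <= cp[pcode + 1L, , drop = FALSE]))
    }
    out
  }

  slices <- vector("list", horizon + 1L)
  slices[[1L]] <- sample_slice(NULL, evidence[["0"]])
  if (horizon >= 1L) for (t in seq_len(horizon))
    slices[[t + 1L]] <- sample_slice(slices[[t]],
                                     evidence[[as.character(t)]])

  outs <- reg_outcomes(model$registry)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  cross <- lapply(slices, function(s) {
    m <- matrix(NA_real_, length(outs), length(outs),
                dimnames = list(outs, outs))
    for (i in seq_along(outs)) for (j in seq_along(outs))
      m[i, j] <- if (i == j) 1 else safe_cor(s[, outs[i]], s[, outs[j]])
    m
  })
  auto <- matrix(NA_real_, length(nodes), horizon,
                 dimnames = list(nodes, paste0("lag", seq_len(horizon))))
  if (horizon >= 1L) for (v in nodes) for (lag in seq_len(horizon)) {
    xs <- ys <- integer(0)
    for (t in seq_len(horizon + 1L - lag)) {
      xs <- c(xs, slices[[t]][, v])
      ys <- c(ys, slices[[t + lag]][, v])
    }
    auto[v, lag] <- safe_cor(xs, ys)
  }
  list(cross = cross, auto = auto)
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf(
    "Scenario comparison for '%s' at slice %d:\n  current %.1f%%  target %.1f%%  reduction %.1f pp  OR %.2f",
    x$outcome, x$horizon, 100 * x$p_current, 100 * x$p_target,
    x$absolute_reduction_pp, x$odds_ratio))
  if (!is.null(x$credible_interval))
    cat(sprintf(" (%d%% CrI %.2f-%.2f)", round(100 * x$level),
                x$credible_interval["low"], x$credible_interval["high"]))
  cat("\n")
  invisible(x)
}
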