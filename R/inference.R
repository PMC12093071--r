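## Exact discrete inference by variable elimination.
##
## A factor is a list(vars, card, val): `val` is a numeric vector over the
## product space of `vars` with the FIRST variable varying fastest.

new_factor <- function(vars, card, val) list(vars = vars, card = card, val = val)

## factor from a fitted family: variable order c(parents, child); the count
## matrix layout (rows = parent configs, first parent fastest; cols = child)
## flattens to exactly that order
family_factor <- function(fam, karr) {
  vars <- c(fam$parents, fam$child)
  card <- vapply(vars, function(v) karr[[v]], integer(1))
  new_factor(vars, unname(card), as.vector(fam$prob))
}

factor_reduce <- function(f, var, idx0) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  stride <- prod(f$card[seq_len(pos - 1L)])
  cells <- seq_len(length(f$val)) - 1L
  keep <- ((cells %/% stride) %% f$card[pos]) == idx0
  new_factor(f$vars[-pos], f$card[-pos], f$val[keep])
}

factor_marginalize <- function(f, var) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  stride <- as.integer(prod(f$card[seq_len(pos - 1L)]))
  kv <- f$card[pos]
  high <- length(f$val) %/% (stride * kv)
  a <- array(f$val, dim = c(stride, kv, high))
  val <- if (stride == 1L && high == 1L) sum(a)
         else as.vector(apply(a, c(1, 3), sum))
  new_factor(f$vars[-pos], f$card[-pos], val)
}

factor_product <- function(a, b) {
  if (length(a$vars) == 0L) return(new_factor(b$vars, b$card, a$val * b$val))
  if (length(b$vars) == 0L) return(new_factor(a$vars, a$card, a$val * b$val))
  vars <- union(a$vars, b$vars)
  card <- integer(length(vars))
  card[match(a$vars, vars)] <- a$card
  card[match(b$vars, vars)] <- b$card
  n <- prod(card)
  cells <- seq_len(n) - 1L
  strides <- cumprod(c(1, card[-length(card)]))
  digit <- function(v) {
    i <- match(v, vars)
    (cells %/% strides[i]) %% card[i]
  }
  idx_in <- function(f) {
    if (length(f$vars) == 0L) return(rep.int(1L, n))
    s <- cumprod(c(1, f$card[-length(f$card)]))
    ix <- 0L
    for (j in seq_along(f$vars)) ix <- ix + digit(f$vars[j]) * s[j]
    ix + 1L
  }
  new_factor(vars, card, a$val[idx_in(a)] * b$val[idx_in(b)])
}

## posterior marginal of `query` given evidence (named 0-based integer
## vector), by variable elimination with a greedy min-size ordering
ve_marginal <- function(factors, query, evidence, card_of) {
  for (ev in names(evidence))
    factors <- lapply(factors, factor_reduce, var = ev, idx0 = evidence[[ev]])
  const <- 1
  keep <- vapply(factors, function(f) length(f$vars) > 0L, logical(1))
  if (any(!keep)) const <- prod(vapply(factors[!keep],
                                       function(f) f$val, numeric(1)))
  factors <- factors[keep]
  hidden <- setdiff(unique(unlist(lapply(factors, function(f) f$vars))), query)
  while (length(hidden)) {
    ## pick the variable whose elimination builds the smallest factor
    cost <- vapply(hidden, function(v) {
      involved <- factors[vapply(factors, function(f) v %in% f$vars, logical(1))]
      vs <- setdiff(unique(unlist(lapply(involved, function(f) f$vars))), v)
      prod(vapply(vs, card_of, numeric(1)))
    }, numeric(1))
    v <- hidden[which.min(cost)]
    inv <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prodf <- Reduce(factor_product, factors[inv])
    newf <- factor_marginalize(prodf, v)
    factors <- c(factors[!inv], if (length(newf$vars)) list(newf))
    if (length(newf$vars) == 0L) const <- const * newf$val
    hidden <- setdiff(hidden, v)
  }
  out <- Reduce(factor_product, factors,
                new_factor(character(0), integer(0), const))
  ## remaining vars are exactly the query (or none if query was evidence)
  if (!query %in% out$vars)
    stop("internal: query variable eliminated")
  if (length(out$vars) > 1L)
    for (v in setdiff(out$vars, query)) out <- factor_marginalize(out, v)
  z <- sum(out$val)
  if (z <= 0 || !is.finite(z))
    stop("impossible evidence: zero probability under the model")
  out$val / z
}

## factors of one slice network. prev_states: named 0-based codes of the
## previous slice (NULL for the initial slice). Temporal nodes then use
## their transition CPT with the previous-self dimension fixed; all other
## nodes use their initial CPT.
slice_factors <- function(model, prev_states = NULL) {
  karr <- lapply(model$registry$vars, function(v) length(v$domain))
  nodes <- reg_names(model$registry)
  lapply(stats::setNames(nodes, nodes), function(node) {
    if (!is.null(prev_states) && node %in% names(model$transition)) {
      fam <- model$transition[[node]]
      k_child <- karr[[node]]
      ## previous self is the fastest-varying parent dimension: rows of the
      ## count/prob matrix are (prev, intra...) configs
      prev <- prev_states[[node]]
      kp <- nrow(fam$prob)
      rows <- seq_len(kp)
      keep <- ((rows - 1L) %% k_child) == prev
      eff <- fam$prob[keep, , drop = FALSE]
      family_factor(list(child = node, parents = fam$parents, prob = eff), karr)
    } else {
      family_factor(model$initial[[node]], karr)
    }
  })
}

evidence_codes <- function(model, evidence) {
  if (length(evidence) == 0L) return(stats::setNames(integer(0), character(0)))
  out <- integer(length(evidence))
  names(out) <- names(evidence)
  for (v in names(evidence)) {
    dom <- reg_domain(model$registry, v)
    i <- match(evidence[[v]], dom)
    if (is.na(i))
      stop("evidence value '", evidence[[v]], "' not in domain of '", v, "'")
    out[v] <- i - 1L
  }
  out
}

#' Posterior marginals of one time slice
#'
#' Computes exact posterior marginals for every variable of a single slice
#' network given evidence, by variable elimination. For the initial slice
#' the network is built from the initial CPTs; when `prev_states` is given
#' (a full named vector of previous-slice category labels), temporal
#' variables instead use their transition CPTs conditioned on those states.
#'
#' @param model a `dbn_model`.
#' @param evidence named character vector or list, variable to observed
#'   category label (may be empty).
#' @param prev_states optional named character vector of previous-slice
#'   states for all variables (MAP propagation input).
#' @return named list: per variable, its posterior distribution (named
#'   numeric summing to 1); evidence variables get a degenerate
#'   distribution.
#' @export
slice_posteriors <- function(model, evidence = NULL, prev_states = NULL) {
  ev <- evidence_codes(model, as.list(evidence))
  prev <- if (!is.null(prev_states))
    lapply(evidence_codes(model, as.list(prev_states)), identity)
  factors <- slice_factors(model, prev)
  karr <- lapply(model$registry$vars, function(v) length(v$domain))
  card_of <- function(v) karr[[v]]
  nodes <- reg_names(model$registry)
  out <- vector("list", length(nodes))
  names(out) <- nodes
  for (node in nodes) {
    dom <- reg_domain(model$registry, node)
    if (node %in% names(ev)) {
      p <- numeric(length(dom))
      p[ev[[node]] + 1L] <- 1
    } else {
      p <- ve_marginal(factors, node, as.list(ev), card_of)
    }
    names(p) <- dom
    out[[node]] <- p
  }
  out
}

#' Per-variable maximum a posteriori states
#'
#' The marginal mode of each posterior; ties are broken toward the lower
#' category index.
#'
#' @param posteriors named list of named probability vectors, as returned
#'   by [slice_posteriors()].
#' @return named character vector of category labels.
#' @export
map_states <- function(posteriors) {
  vapply(posteriors, function(p) names(p)[which.max(p)], character(1))
}

#' Forecast forward with MAP slice propagation
#'
#' Slice 0 posteriors come from the initial CPTs conditioned on the slice-0
#' evidence. For each later slice, the per-variable MAP states of the
#' previous slice feed the transition CPTs (carrying each variable's modal
#' state forward rather than its full distribution, which keeps the
#' computation per-slice exact and prevents overpropagation of
#' uncertainty), the age group advances deterministically by one 5-year
#' category, and the slice's own posteriors are recomputed given any
#' user-supplied evidence at that slice -- this is how intervention targets
#' enter a what-if scenario.
#'
#' @param model a `dbn_model`.
#' @param evidence evidence set: a list whose names are slice indices
#'   (`"0"`, `"1"`, ...) and whose elements are named character vectors of
#'   variable = category label. Slice 0 must fix the age group (the
#'   initial parameter of the dynamic model).
#' @param horizon number of 5-year steps to forecast (`H >= 0`). A horizon
#'   that would push the age group beyond its top category is truncated
#'   with a warning.
#' @return an object of class `risk_forecast`: `slices` (per slice:
#'   posteriors and MAP states), and `outcome_probabilities`, a matrix
#'   (slice 0..H by outcome/health node) of the probability of the
#'   adverse category (declined / yes).
#' @export
forecast_risk <- function(model, evidence, horizon = 1L) {
  horizon <- as.integer(horizon)
  if (horizon < 0L) stop("horizon must be >= 0")
  evidence <- normalize_evidence(evidence)
  ev0 <- evidence[["0"]]
  if (is.null(ev0) || !"age_group" %in% names(ev0))
    stop("slice-0 evidence must include 'age_group'")
  k_age <- reg_k(model$registry, "age_group")
  age0 <- match(ev0[["age_group"]], reg_domain(model$registry, "age_group"))
  steps_left <- k_age - age0
  if (horizon > steps_left) {
    warning("horizon truncated to ", steps_left,
            " step(s): age group is absorbing at the top category")
    horizon <- steps_left
  }

  slices <- vector("list", horizon + 1L)
  post <- slice_posteriors(model, ev0)
  slices[[1L]] <- list(posteriors = post, map = map_states(post))
  if (horizon >= 1L) for (t in seq_len(horizon)) {
    prev <- slices[[t]]$map
    ev_t <- evidence[[as.character(t)]]
    post <- slice_posteriors(model, ev_t, prev_states = prev)
    slices[[t + 1L]] <- list(posteriors = post, map = map_states(post))
  }

  outs <- reg_outcomes(model$registry)
  probs <- matrix(NA_real_, nrow = horizon + 1L, ncol = length(outs),
                  dimnames = list(as.character(0:horizon), outs))
  for (t in seq_len(horizon + 1L))
    for (v in outs)
      probs[t, v] <- slices[[t]]$posteriors[[v]][2L]

  structure(list(slices = slices, outcome_probabilities = probs,
                 horizon = horizon, evidence = evidence),
            class = "risk_forecast")
}

normalize_evidence <- function(evidence) {
  if (is.null(evidence)) return(list())
  if (!is.list(evidence)) stop("evidence must be a list keyed by slice index")
  if (length(evidence) && is.null(names(evidence)))
    stop("evidence list must be named by slice index ('0', '1', ...)")
  out <- lapply(evidence, function(e) {
    e <- unlist(e)
    if (length(e) && anyDuplicated(names(e)))
      stop("at most one evidence value per (slice, variable)")
    e
  })
  names(out) <- names(evidence)
  out
}

#' @export
print.risk_forecast <- function(x, digits = 3, ...) {
  cat("Risk forecast over", x$horizon, "five-year step(s)\n")
  cat("P(adverse state) by slice:\n")
  print(round(x$outcome_probabilities, digits))
  invisible(x)
}
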