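## Independent oracles used to cross-check the package's implementations.

## Brute-force multinomial NML parametric complexity: direct sum over all
## compositions n_1 + ... + n_k = n (feasible for small n, k).
brute_regret <- function(n, k) {
  if (n == 0 || k == 1) return(0)
  total <- 0
  rec <- function(remaining, slots, acc) {
    if (slots == 1L) {
      ns <- c(acc, remaining)
      term <- exp(lfactorial(n) - sum(lfactorial(ns)))
      term <- term * prod(ifelse(ns == 0, 1, (ns / n)^ns))
      total <<- total + term
      return(invisible())
    }
    for (j in 0:remaining) rec(remaining - j, slots - 1L, c(acc, j))
  }
  rec(n, k, integer(0))
  log(total)
}

## Full-joint enumeration oracle for posterior marginals of one slice
## network: multiplies CPT entries over every complete assignment. Works on
## the model's family objects but shares no code with the elimination
## engine.
enum_posterior <- function(model, evidence = NULL, prev_states = NULL,
                           query) {
  reg <- model$registry
  nodes <- names(reg$vars)
  doms <- lapply(nodes, function(v) reg$vars[[v]]$domain)
  names(doms) <- nodes
  grid <- do.call(expand.grid,
                  c(lapply(doms, seq_along), KEEP.OUT.ATTRS = FALSE))
  names(grid) <- nodes
  p <- rep(1, nrow(grid))
  for (v in nodes) {
    if (!is.null(prev_states) && v %in% names(model$transition)) {
      fam <- model$transition[[v]]
      prev_idx <- match(prev_states[[v]], doms[[v]]) - 1L
      pcfg <- prev_idx
      mult <- length(doms[[v]])
      for (par in fam$parents) {
        pcfg <- pcfg + (grid[[par]] - 1L) * mult
        mult <- mult * length(doms[[par]])
      }
    } else {
      fam <- model$initial[[v]]
      pcfg <- 0L
      mult <- 1L
      for (par in fam$parents) {
        pcfg <- pcfg + (grid[[par]] - 1L) * mult
        mult <- mult * length(doms[[par]])
      }
    }
    p <- p * fam$prob[cbind(pcfg + 1L, grid[[v]])]
  }
  if (!is.null(evidence)) {
    for (v in names(evidence)) {
      idx <- match(evidence[[v]], doms[[v]])
      p[grid[[v]] != idx] <- 0
    }
  }
  stopifnot(sum(p) > 0)
  out <- tapply(p, grid[[query]], sum)
  out <- as.numeric(out) / sum(p)
  names(out) <- doms[[query]]
  out
}

## Hand-built model without touching the fitting code: CPT prob matrices
## are given directly (counts default to scaled probabilities so that
## Dirichlet resampling concentrates near them).
manual_model <- function(registry, parents, probs, temporal_probs = list(),
                         alpha = 0.5, count_scale = 1000) {
  nodes <- names(registry$vars)
  initial <- list()
  for (v in nodes) {
    pr <- probs[[v]]
    initial[[v]] <- list(child = v, parents = parents[[v]] %||% character(0),
                         counts = round(pr * count_scale), prob = pr,
                         deterministic = FALSE)
  }
  transition <- list()
  for (v in names(temporal_probs)) {
    pr <- temporal_probs[[v]]
    transition[[v]] <- list(child = v, parents = attr(pr, "intra") %||% character(0),
                            counts = round(pr * count_scale), prob = pr,
                            deterministic = isTRUE(attr(pr, "deterministic")))
  }
  st <- structure(list(
    intra_parents = lapply(stats::setNames(nodes, nodes),
                           function(v) parents[[v]] %||% character(0)),
    temporal = names(temporal_probs),
    scores = stats::setNames(rep(0, length(nodes)), nodes),
    margins = stats::setNames(rep(NA_real_, length(nodes)), nodes),
    n_used = stats::setNames(rep(0L, length(nodes)), nodes),
    total_score = 0, max_parents = 3L), class = "dbn_structure")
  structure(list(registry = registry, structure = st, alpha = alpha,
                 initial = initial, transition = transition,
                 meta = list(n_records = 0L, n_individuals = 0L,
                             format_version = "1")),
            class = "dbn_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Random slice network on a small custom registry: random parent sets
## respecting the ordering (<= max_parents) and random strictly positive
## CPTs. Used for the inference-vs-enumeration equivalence suite.
random_small_model <- function(n_nodes, max_card = 3, max_parents = 2,
                               seed) {
  set.seed(seed)
  cards <- sample(2:max_card, n_nodes, replace = TRUE)
  nodes <- paste0("V", seq_len(n_nodes))
  reg <- variable_registry(lapply(seq_len(n_nodes), function(i)
    list(name = nodes[i],
         domain = paste0("c", seq_len(cards[i])),
         role = if (i == n_nodes) "outcome" else "dynamic")))
  parents <- list()
  probs <- list()
  for (i in seq_len(n_nodes)) {
    cand <- nodes[seq_len(i - 1L)]
    np <- if (length(cand)) sample(0:min(max_parents, length(cand)), 1) else 0L
    ps <- if (np > 0) sort(sample(cand, np)) else character(0)
    parents[[nodes[i]]] <- ps
    kp <- prod(cards[match(ps, nodes)], 1)
    m <- matrix(stats::rgamma(kp * cards[i], shape = 1) + 0.05,
                nrow = kp)
    probs[[nodes[i]]] <- m / rowSums(m)
  }
  manual_model(reg, parents, probs)
}

## A tiny two-slice toy registry used across inference/risk tests:
## age (2 groups), two modifiable factors and one outcome.
toy_registry <- function() {
  variable_registry(list(
    list(name = "age_group", domain = c("55", "60"), role = "dynamic"),
    list(name = "ltpa", domain = c("inactive", "active"), role = "dynamic"),
    list(name = "smoking", domain = c("never", "current_smoker"),
         role = "dynamic"),
    list(name = "memory", domain = c("good", "declined"), role = "outcome")))
}

## Toy model where only LTPA affects memory; LTPA and smoking persist with
## probability `persist` between slices; age is deterministic.
toy_model <- function(p_mem_inactive = 0.8, p_mem_active = 0.2,
                      persist = 0.9) {
  reg <- toy_registry()
  probs <- list(
    age_group = matrix(c(1, 0), 1),
    ltpa = matrix(c(0.6, 0.4), 1),
    smoking = matrix(c(0.7, 0.3), 1),
    memory = matrix(c(1 - p_mem_inactive, p_mem_inactive,
                      1 - p_mem_active, p_mem_active),
                    nrow = 2, byrow = TRUE))
  parents <- list(memory = "ltpa")
  tp <- function(persist, k = 2) {
    m <- matrix((1 - persist) / (k - 1), k, k)
    diag(m) <- persist
    m
  }
  age_t <- matrix(c(0, 1, 0, 1), 2, byrow = TRUE)
  attr(age_t, "deterministic") <- TRUE
  temporal <- list(age_group = age_t, ltpa = tp(persist),
                   smoking = tp(persist))
  manual_model(reg, parents, probs, temporal)
}

## Brute-force re-enumeration of the per-node subset search, independent of
## learn_structure's bookkeeping (shares only the family-scoring primitive).
oracle_search <- function(tab, reg, max_parents = 3L) {
  codes <- scdforecast:::cohort_codes(tab, reg)
  karr <- lapply(reg$vars, function(v) length(v$domain))
  res <- list()
  for (node in names(reg$vars)) {
    cands <- candidate_parents(node, reg)
    all_sets <- list(character(0))
    for (s in seq_len(min(max_parents, length(cands))))
      all_sets <- c(all_sets, utils::combn(sort(cands), s, simplify = FALSE))
    scored <- lapply(all_sets, function(ps)
      scdforecast:::score_family_codes(codes, node, ps, karr))
    sc <- vapply(scored, function(x) if (is.null(x)) -Inf else x$score,
                 numeric(1))
    keys <- vapply(all_sets, function(ps)
      sprintf("%02d|%s", length(ps), paste(ps, collapse = ",")),
      character(1))
    best <- which(sc == max(sc))
    best <- best[order(keys[best])][1]   # tie-break: size, then lexicographic
    res[[node]] <- list(parents = all_sets[[best]], score = sc[best])
  }
  res
}
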