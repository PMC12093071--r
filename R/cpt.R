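## Conditional probability table estimation.
##
## A "family" is a child node plus an ordered parent list. Count tables are
## matrices with one row per parent configuration (the first listed parent
## varying fastest) and one column per child category. Transition families
## of temporal variables prepend the child's previous-slice copy as the
## first (fastest-varying) parent.

## 0-based parent-configuration code for given parent columns of a code
## matrix; karr is the named list of domain sizes
parent_config_code <- function(codes, parents, karr) {
  if (length(parents) == 0L) return(rep.int(0L, nrow(codes)))
  pcode <- 0L
  kp <- 1L
  for (p in parents) {
    pcode <- pcode + codes[, p] * kp
    kp <- kp * karr[[p]]
  }
  pcode
}

#' Count a family's observations on available cases
#'
#' In `initial` mode, counts every person-phase record complete for the
#' child and its parents, pooled across phases. In `transition` mode, the
#' unit is a pair of consecutive phases of one person (phase gaps are
#' excluded); the child and its intra-slice parents are taken from the
#' later phase and the child's previous value from the earlier phase, which
#' becomes the first (fastest-varying) parent dimension of the table.
#'
#' @param table a `cohort_table`.
#' @param child child variable name.
#' @param parents character vector of intra-slice parents (may be empty).
#' @param mode `"initial"` or `"transition"`.
#' @param registry a [variable_registry()].
#' @return an integer matrix, parent configurations by child categories.
#' @export
count_family <- function(table, child, parents, mode = c("initial", "transition"),
                         registry) {
  mode <- match.arg(mode)
  codes <- cohort_codes(table, registry)
  karr <- lapply(registry$vars, function(v) length(v$domain))
  k_child <- karr[[child]]
  if (mode == "initial") {
    x <- codes[, child]
    sub <- codes[, parents, drop = FALSE]
    ok <- !is.na(x)
    for (j in seq_along(parents)) ok <- ok & !is.na(sub[, j])
    pcode <- parent_config_code(codes[ok, , drop = FALSE], parents, karr)
    x <- x[ok]
    kp <- prod(vapply(parents, function(p) karr[[p]], numeric(1)), 1)
  } else {
    if (!child %in% reg_temporal(registry))
      stop("'", child, "' is not a temporal variable")
    pr <- consecutive_pairs(table)
    prev <- codes[pr[, "prev"], child]
    cur <- codes[pr[, "cur"], , drop = FALSE]
    x <- cur[, child]
    ok <- !is.na(prev) & !is.na(x)
    for (p in parents) ok <- ok & !is.na(cur[, p])
    intra_code <- parent_config_code(cur[ok, , drop = FALSE], parents, karr)
    pcode <- prev[ok] + intra_code * k_child
    x <- x[ok]
    kp <- k_child * prod(vapply(parents, function(p) karr[[p]], numeric(1)), 1)
  }
  cell <- pcode + x * kp
  counts <- tabulate(cell + 1L, nbins = kp * k_child)
  matrix(as.integer(counts), nrow = kp, ncol = k_child)
}

#' Dirichlet-smoothed conditional probabilities
#'
#' Posterior-mean estimate under a per-cell Dirichlet(alpha, ..., alpha)
#' prior: `p = (n_cell + alpha) / (n_row + alpha * k)`. With the default
#' Jeffreys-style `alpha = 1/2`, every probability is strictly positive, so
#' zero count cells never produce zero-probability inference paths. An
#' all-zero row falls back to the prior mean (uniform).
#'
#' @param counts count matrix (rows: parent configurations, columns: child
#'   categories).
#' @param alpha Dirichlet hyperparameter per cell, `> 0` (default 0.5).
#' @return a probability matrix of the same shape; rows sum to 1.
#' @export
smooth_cpt <- function(counts, alpha = 0.5) {
  if (alpha <= 0) stop("alpha must be > 0")
  counts <- as.matrix(counts)
  (counts + alpha) / (rowSums(counts) + alpha * ncol(counts))
}

## deterministic age transition: +1 category per 5-year slice, absorbing at
## the top group
age_transition_prob <- function(k) {
  p <- matrix(0, k, k)
  for (i in seq_len(k)) p[i, min(i + 1L, k)] <- 1
  p
}

#' Fit a dynamic Bayesian network model
#'
#' Estimates every node's initial-slice CPT (parents: the learned
#' intra-slice parents) and, for temporal variables, the transition CPT
#' (parents: the node's previous-slice copy plus its intra-slice parents),
#' each on family-wise available cases with Dirichlet smoothing. The
#' age-group transition is not estimated from data: ageing is exogenous
#' bookkeeping, fixed to a deterministic +1 category per slice, absorbing
#' in the top group.
#'
#' @param table a `cohort_table`.
#' @param structure a `dbn_structure` from [learn_structure()].
#' @param registry the registry used to learn the structure.
#' @param alpha Dirichlet smoothing hyperparameter (default 0.5).
#' @return an object of class `dbn_model`: the registry, structure, alpha,
#'   named family lists `initial` and `transition` (each family holding
#'   `child`, `parents`, `counts`, `prob` and for transitions a leading
#'   previous-self parent dimension), and training metadata.
#' @export
fit_dbn <- function(table, structure, registry, alpha = 0.5) {
  nodes <- reg_names(registry)
  if (!identical(sort(names(structure$intra_parents)), sort(nodes)))
    stop("structure and registry disagree on the node set")
  ord <- vapply(registry$vars, function(v) v$ordering_index, integer(1))
  for (node in nodes) {
    ps <- structure$intra_parents[[node]]
    if (length(ps) && any(ord[ps] >= ord[node]))
      stop("structure violates the ordering at node '", node, "'")
  }

  initial <- transition <- list()
  for (node in nodes) {
    ps <- structure$intra_parents[[node]]
    cnt <- count_family(table, node, ps, "initial", registry)
    initial[[node]] <- list(child = node, parents = ps, counts = cnt,
                            prob = smooth_cpt(cnt, alpha),
                            deterministic = FALSE)
  }
  for (node in intersect(structure$temporal, nodes)) {
    ps <- structure$intra_parents[[node]]
    if (node == "age_group") {
      k <- reg_k(registry, node)
      transition[[node]] <- list(child = node, parents = character(0),
                                 counts = matrix(0L, k, k),
                                 prob = age_transition_prob(k),
                                 deterministic = TRUE)
    } else {
      cnt <- count_family(table, node, ps, "transition", registry)
      transition[[node]] <- list(child = node, parents = ps, counts = cnt,
                                 prob = smooth_cpt(cnt, alpha),
                                 deterministic = FALSE)
    }
  }

  structure(list(registry = registry, structure = structure, alpha = alpha,
                 initial = initial, transition = transition,
                 meta = list(n_records = nrow(table),
                             n_individuals = length(unique(table$id)),
                             format_version = "1")),
            class = "dbn_model")
}

#' @export
print.dbn_model <- function(x, ...) {
  cat("Discrete DBN model:", length(x$initial), "nodes,",
      length(x$transition), "temporal;",
      "alpha =", x$alpha, "\n")
  cat("Trained on", x$meta$n_records, "person-phase records from",
      x$meta$n_individuals, "individuals\n")
  invisible(x)
}
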