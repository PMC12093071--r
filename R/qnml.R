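#' Maximized categorical log-likelihood
#'
#' The maximum-likelihood term of the normalized maximum likelihood (NML)
#' distribution of a k-category multinomial: `sum_j n_j * log(n_j / n)` in
#' nats, with the convention `0 * log(0) = 0`.
#'
#' @param counts nonnegative integer vector of category counts.
#' @return log-likelihood in nats (<= 0).
#' @export
categorical_log_ml <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- sum(counts)
  if (n < 1) stop("empty data: all counts are zero")
  nz <- counts[counts > 0]
  sum(nz * log(nz / n))
}

## per-session cache of log C(n, k) vectors, keyed by n
.regret_cache <- new.env(parent = emptyenv())

#' Multinomial NML parametric complexity (regret)
#'
#' Computes `log C(n, k)` in nats, where `C(n, k)` is the normalizing
#' constant of the NML distribution for a k-category multinomial over n
#' observations: the sum over all compositions `n_1 + ... + n_k = n` of
#' `n! / prod(n_j!) * prod((n_j / n)^(n_j))`. The computation is exact (to
#' floating point): `C(n, 1) = 1`, `C(n, 2)` by the explicit binomial sum,
#' and higher k via the linear recurrence
#' `C(n, k) = C(n, k-1) + n / (k - 2) * C(n, k-2)`, all carried in log
#' space so that large `n` and `k` cannot overflow.
#'
#' @param n number of observations (nonnegative integer).
#' @param k number of categories (positive integer).
#' @return `log C(n, k)` in nats; 0 when `k == 1` or `n == 0`.
#' @references Kontkanen & Myllymäki (2007) give the linear-time recurrence;
#'   Silander et al. introduced the quotient NML model-selection score built
#'   from these complexities.
#' @export
multinomial_regret <- function(n, k) {
  if (k < 1) stop("k must be >= 1")
  if (n < 0) stop("n must be >= 0")
  n <- as.integer(round(n)); k <- as.integer(round(k))
  if (n == 0L || k == 1L) return(0)
  key <- as.character(n)
  vec <- .regret_cache[[key]]
  if (!is.null(vec) && length(vec) >= k) return(vec[k])
  if (is.null(vec)) {
    ## log C(n, 1) and log C(n, 2)
    h <- 0:n
    terms <- lchoose(n, h) +
      ifelse(h == 0L, 0, h * log(h / n)) +
      ifelse(h == n, 0, (n - h) * log((n - h) / n))
    vec <- c(0, logsumexp(terms))
  }
  if (k > length(vec)) {
    from <- length(vec) + 1L
    vec <- c(vec, numeric(k - length(vec)))
    for (j in from:k)
      vec[j] <- logaddexp(vec[j - 1L], log(n) - log(j - 2) + vec[j - 2L])
  }
  .regret_cache[[key]] <- vec
  vec[k]
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

logaddexp <- function(a, b) {
  m <- max(a, b)
  m + log1p(exp(min(a, b) - m))
}

#' One-dimensional NML score of a count column
#'
#' `categorical_log_ml(counts) - multinomial_regret(n, k)` where `k` is the
#' full declared configuration-space size (unobserved configurations count
#' as structural zero cells but still enter the regret through `k`).
#'
#' @param counts nonnegative integer vector (may be shorter than `k`; the
#'   remaining cells are zeros).
#' @param k declared configuration-space size, `k >= length(nonzero cells)`.
#' @return NML score in nats.
#' @export
log_nml_column <- function(counts, k) {
  if (k < 1) stop("k must be >= 1")
  categorical_log_ml(counts) - multinomial_regret(sum(counts), k)
}

#' qNML family score
#'
#' The quotient NML score of one family (child plus ordered parent set):
#' the NML score of the joint child-parent column minus the NML score of the
#' parent column, each treated as a one-dimensional categorical over its
#' full product configuration space. For an empty parent set the parent
#' column is the trivial single-configuration column whose score is 0. The
#' score is decomposable: a network's score is the sum of its family
#' scores.
#'
#' @param joint_counts counts over the child-by-parent product configuration
#'   space.
#' @param parent_counts counts over the parent configuration space; for an
#'   empty parent set pass `sum(joint_counts)` (a single cell).
#' @param k_child child domain size.
#' @param k_parent parent configuration-space size (1 for no parents).
#' @return family score in nats.
#' @export
qnml_family_score <- function(joint_counts, parent_counts = sum(joint_counts),
                              k_child, k_parent = 1L) {
  n <- sum(joint_counts)
  if (n < 1) stop("family has no complete cases: score undefined")
  if (sum(parent_counts) != n)
    stop("joint and parent counts disagree on n")
  log_nml_column(joint_counts, k_child * k_parent) -
    log_nml_column(parent_counts, k_parent)
}

## ---- internal: score a candidate family on a code matrix -------------------

## Available-case scoring: rows complete for child + parents. Returns the
## qNML score and the n used, or NULL when no complete cases exist.
score_family_codes <- function(codes, child, parents, karr) {
  k_child <- karr[[child]]
  if (length(parents) == 0L) {
    x <- codes[, child]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0L) return(NULL)
    counts <- tabulate(x + 1L, nbins = k_child)
    return(list(score = qnml_family_score(counts, n, k_child, 1L), n = n))
  }
  sub <- codes[, c(child, parents), drop = FALSE]
  ok <- !is.na(sub[, 1L])
  for (j in 2:ncol(sub)) ok <- ok & !is.na(sub[, j])
  n <- sum(ok)
  if (n == 0L) return(NULL)
  sub <- sub[ok, , drop = FALSE]
  kp <- 1L
  pcode <- 0L
  for (j in seq_along(parents)) {
    pcode <- pcode + sub[, j + 1L] * kp
    kp <- kp * karr[[parents[j]]]
  }
  jcode <- sub[, 1L] + pcode * k_child
  joint <- tabulate(jcode + 1L, nbins = k_child * kp)
  par <- tabulate(pcode + 1L, nbins = kp)
  list(score = qnml_family_score(joint, par, k_child, kp), n = n)
}
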