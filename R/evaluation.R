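#' Area under the ROC curve (Mann-Whitney form)
#'
#' The fraction of (positive, negative) pairs in which the positive case is
#' scored higher, ties counted one half -- computed from midranks.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1, logical, or a 2-level factor).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Grouped k-fold cross-validated AUROC of the full pipeline
#'
#' Individuals (never person-phases) are shuffled with the given seed and
#' partitioned into `k` folds, so no person's repeated measures leak
#' between training and test. Per fold, the structure search and CPT
#' fitting are rerun on the training individuals only; each held-out
#' person-phase with an observed outcome is then scored with the posterior
#' probability of the adverse state given that record's observed same-slice
#' covariates (age, gender, education, lifestyle, health factors),
#' excluding the other cognitive outcomes. AUROC is computed per outcome
#' over the pooled held-out predictions, and per fold.
#'
#' @param table a `cohort_table`.
#' @param registry a [variable_registry()].
#' @param k number of folds (>= 2; default 5).
#' @param target_outcomes outcome nodes to evaluate (default all `outcome`
#'   role variables).
#' @param seed RNG seed for the fold shuffle.
#' @param max_parents,alpha passed to [learn_structure()] / [fit_dbn()].
#' @return an object of class `cv_result`: `summary` (data.frame with
#'   pooled AUROC, mean fold AUROC and counts per outcome) and `folds`
#'   (per-fold AUROCs; `NA` where a fold held only one class).
#' @export
cross_validate <- function(table, registry, k = 5L,
                           target_outcomes = NULL, seed = 1L,
                           max_parents = 3L, alpha = 0.5) {
  if (k < 2L) stop("k must be >= 2")
  roles <- reg_roles(registry)
  if (is.null(target_outcomes))
    target_outcomes <- reg_names(registry)[roles == "outcome"]
  scd_all <- reg_names(registry)[roles == "outcome"]

  ids <- unique(table$id)
  set.seed(seed)
  fold_of <- stats::setNames(rep_len(seq_len(k), length(ids)),
                             sample(ids))

  pooled <- stats::setNames(
    replicate(length(target_outcomes),
              list(score = numeric(0), label = integer(0)),
              simplify = FALSE), target_outcomes)
  folds <- matrix(NA_real_, nrow = k, ncol = length(target_outcomes),
                  dimnames = list(paste0("fold", seq_len(k)),
                                  target_outcomes))

  for (f in seq_len(k)) {
    test_ids <- names(fold_of)[fold_of == f]
    train <- table[!table$id %in% test_ids, , drop = FALSE]
    test <- table[table$id %in% test_ids, , drop = FALSE]
    st <- suppressWarnings(learn_structure(train, registry, max_parents))
    model <- fit_dbn(train, st, registry, alpha)
    karr <- lapply(registry$vars, function(v) length(v$domain))
    codes <- cohort_codes(test, registry)
    cache <- new.env(parent = emptyenv())

    for (outc in target_outcomes) {
      y <- codes[, outc]
      keep <- which(!is.na(y))
      if (!length(keep)) next
      covars <- setdiff(reg_names(registry), scd_all)
      pars <- model$initial[[outc]]$parents
      sc <- rep(NA_real_, length(keep))
      for (ii in seq_along(keep)) {
        r <- keep[ii]
        obs <- covars[!is.na(codes[r, covars])]
        if (length(pars) && all(pars %in% obs)) {
          ## all parents observed: the posterior is the CPT row (no
          ## evidence can lie downstream of the outcome here)
          pc <- parent_config_code(codes[r, , drop = FALSE], pars, karr)
          sc[ii] <- model$initial[[outc]]$prob[pc + 1L, 2L]
        } else if (length(pars) == 0L) {
          sc[ii] <- model$initial[[outc]]$prob[1L, 2L]
        } else {
          key <- paste(codes[r, obs], collapse = ",")
          key <- paste(outc, paste(obs, collapse = ","), key, sep = "|")
          p <- cache[[key]]
          if (is.null(p)) {
            ev <- stats::setNames(lapply(obs, function(v)
              reg_domain(registry, v)[codes[r, v] + 1L]), obs)
            p <- slice_posteriors(model, ev)[[outc]][2L]
            cache[[key]] <- p
          }
          sc[ii] <- p
        }
      }
      lab <- as.integer(y[keep] == 1L)  # adverse = second category
      pooled[[outc]]$score <- c(pooled[[outc]]$score, sc)
      pooled[[outc]]$label <- c(pooled[[outc]]$label, lab)
      if (length(unique(lab)) == 2L) {
        folds[f, outc] <- auroc(sc, lab)
      } else {
        warning("fold ", f, ": single-class outcome '", outc, "' skipped")
      }
    }
  }

  summary <- data.frame(
    outcome = target_outcomes,
    auroc = vapply(target_outcomes, function(o) {
      p <- pooled[[o]]
      if (length(unique(p$label)) < 2L) NA_real_ else auroc(p$score, p$label)
    }, numeric(1)),
    mean_fold_auroc = colMeans(folds, na.rm = TRUE),
    n = vapply(target_outcomes, function(o) length(pooled[[o]]$label),
               numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(summary = summary, folds = folds, fold_of = fold_of,
                 k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Grouped", x$k, "fold cross-validation (seed", paste0(x$seed, ")\n"))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
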