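#' Candidate parents of a node under the expert ordering
#'
#' Intra-slice edges are only allowed from variables earlier in the expert
#' ordering, which makes acyclicity hold by construction and turns the
#' structure search into an independent subset choice per node.
#'
#' @param node variable name.
#' @param registry a [variable_registry()].
#' @return character vector of candidate parent names, in ordering order.
#' @export
candidate_parents <- function(node, registry) {
  v <- registry$vars[[node]]
  if (is.null(v)) stop("unknown variable '", node, "'")
  ord <- vapply(registry$vars, function(x) x$ordering_index, integer(1))
  reg_names(registry)[ord < v$ordering_index][
    order(ord[ord < v$ordering_index])]
}

#' Learn the intra-slice structure by exhaustive qNML search
#'
#' For every node independently, evaluates every subset of its candidate
#' parents of size `0..max_parents` on the pooled person-phase records that
#' are complete for that candidate family (available-case scoring), and
#' selects the subset with the highest qNML score. Ties are broken toward
#' the smaller subset, then lexicographically by parent names. Dynamic
#' variables are additionally flagged with the hardwired self-edge from the
#' previous time slice; the temporal edge does not count against the parent
#' cap.
#'
#' @param table a `cohort_table`.
#' @param registry a [variable_registry()].
#' @param max_parents cap on the number of intra-slice parents (default 3).
#' @return an object of class `dbn_structure`: named list `intra_parents`
#'   (parents stored in ordering order), `temporal` (variables with the
#'   self-edge), per-node `scores`, `margins` (score lead over the
#'   runner-up subset), `n_used`, and `total_score`.
#' @export
learn_structure <- function(table, registry, max_parents = 3L) {
  if (nrow(table) == 0L) stop("empty cohort table")
  codes <- cohort_codes(table, registry)
  karr <- lapply(registry$vars, function(v) length(v$domain))
  nodes <- reg_names(registry)

  intra <- stats::setNames(vector("list", length(nodes)), nodes)
  scores <- margins <- stats::setNames(numeric(length(nodes)), nodes)
  n_used <- stats::setNames(integer(length(nodes)), nodes)
  n_skipped <- 0L

  for (node in nodes) {
    cands <- candidate_parents(node, registry)
    best <- NULL
    best_key <- NULL
    runner <- -Inf
    for (size in 0:min(max_parents, length(cands))) {
      subsets <- if (size == 0L) list(character(0)) else
        utils::combn(sort(cands), size, simplify = FALSE)
      for (ps in subsets) {
        res <- score_family_codes(codes, node, ps, karr)
        if (is.null(res)) { n_skipped <- n_skipped + 1L; next }
        ## enumeration order (size asc, lexicographic) realizes the
        ## tie-break: only a strictly larger score replaces the incumbent
        if (is.null(best) || res$score > best$score) {
          if (!is.null(best)) runner <- max(runner, best$score)
          best <- res
          best$parents <- ps
        } else {
          runner <- max(runner, res$score)
        }
      }
    }
    if (is.null(best))
      stop("node '", node, "' has zero complete cases; cannot be scored")
    ord <- vapply(registry$vars, function(x) x$ordering_index, integer(1))
    intra[[node]] <- best$parents[order(ord[best$parents])]
    scores[node] <- best$score
    margins[node] <- if (is.finite(runner)) best$score - runner else NA_real_
    n_used[node] <- best$n
  }
  if (n_skipped > 0L)
    warning(n_skipped, " candidate parent set(s) had no complete cases ",
            "and were skipped")

  structure(list(intra_parents = intra, temporal = reg_temporal(registry),
                 scores = scores, margins = margins, n_used = n_used,
                 total_score = sum(scores), max_parents = as.integer(max_parents)),
            class = "dbn_structure")
}

#' Report the selected structure
#'
#' @param structure a `dbn_structure`.
#' @return a data.frame with one row per node: selected parents, temporal
#'   flag, family score, score margin over the runner-up subset, and the
#'   number of complete cases used.
#' @export
structure_report <- function(structure) {
  nodes <- names(structure$intra_parents)
  data.frame(
    node = nodes,
    parents = vapply(structure$intra_parents,
                     function(p) paste(p, collapse = ","), character(1)),
    temporal = nodes %in% structure$temporal,
    score = unname(structure$scores),
    margin = unname(structure$margins),
    n = unname(structure$n_used),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.dbn_structure <- function(x, ...) {
  cat("DBN intra-slice structure (qNML), total score",
      format(x$total_score, digits = 8), "\n")
  rep <- structure_report(x)
  for (i in seq_len(nrow(rep))) {
    cat(sprintf("  %-17s <- {%s}%s\n", rep$node[i], rep$parents[i],
                if (rep$temporal[i]) " [+ self at t-1]" else ""))
  }
  invisible(x)
}
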