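MODEL_FORMAT_VERSION <- "1"

#' Serialize a fitted model to JSON
#'
#' Writes the registry, learned structure, smoothing hyperparameter and
#' all CPTs (counts and probabilities, full double precision) to a
#' versioned, diff-able JSON file. The round trip through [read_model()]
#' is lossless.
#'
#' @param model a `dbn_model`.
#' @param path output file path.
#' @export
write_model <- function(model, path) {
  fam_out <- function(fam) list(
    child = fam$child, parents = as.list(fam$parents),
    counts = fam$counts, prob = fam$prob,
    deterministic = isTRUE(fam$deterministic))
  payload <- list(
    format_version = MODEL_FORMAT_VERSION,
    registry = lapply(unname(model$registry$vars), function(v)
      list(name = v$name, domain = as.list(v$domain), role = v$role)),
    structure = list(
      intra_parents = lapply(model$structure$intra_parents, as.list),
      temporal = as.list(model$structure$temporal),
      scores = as.list(model$structure$scores),
      margins = as.list(model$structure$margins),
      n_used = as.list(model$structure$n_used),
      total_score = model$structure$total_score,
      max_parents = model$structure$max_parents),
    alpha = model$alpha,
    initial = lapply(model$initial, fam_out),
    transition = lapply(model$transition, fam_out),
    meta = model$meta)
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           pretty = TRUE, na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Deserialize a model written by [write_model()]
#'
#' @param path JSON file path.
#' @return a `dbn_model`.
#' @export
read_model <- function(path) {
  p <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE),
                error = function(e) stop("not a valid model file: ",
                                         conditionMessage(e)))
  if (is.null(p$format_version) ||
      !identical(as.character(p$format_version), MODEL_FORMAT_VERSION))
    stop("unsupported model format version: ",
         if (is.null(p$format_version)) "<missing>" else p$format_version)
  registry <- variable_registry(lapply(p$registry, function(v)
    list(name = v$name, domain = unlist(v$domain), role = v$role)))
  st <- p$structure
  structure_obj <- structure(list(
    intra_parents = lapply(st$intra_parents, function(x) as.character(unlist(x))),
    temporal = as.character(unlist(st$temporal)),
    scores = unlist(st$scores),
    margins = vapply(st$margins, function(m)
      if (is.null(m)) NA_real_ else as.numeric(m), numeric(1)),
    n_used = unlist(st$n_used),
    total_score = st$total_score,
    max_parents = as.integer(st$max_parents)), class = "dbn_structure")
  fam_in <- function(fam) list(
    child = fam$child, parents = as.character(unlist(fam$parents)),
    counts = as.matrix(fam$counts), prob = as.matrix(fam$prob),
    deterministic = isTRUE(fam$deterministic))
  structure(list(registry = registry, structure = structure_obj,
                 alpha = p$alpha,
                 initial = lapply(p$initial, fam_in),
                 transition = lapply(p$transition, fam_in),
                 meta = p$meta),
            class = "dbn_model")
}

#' Read a variable registry from a YAML config
#'
#' The config declares a `variables` list, each entry with `name`,
#' `domain` (list of category labels) and `role`; list order defines the
#' expert ordering.
#'
#' @param path YAML file path.
#' @return a `var_registry`.
#' @export
read_registry_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variables)) stop("config has no 'variables' section")
  variable_registry(lapply(cfg$variables, function(v)
    list(name = v$name, domain = as.character(unlist(v$domain)),
         role = v$role)))
}
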