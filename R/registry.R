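#' Variable registry for a discrete dynamic Bayesian network
#'
#' A registry declares, for every node of the network, its categorical
#' domain, its role and its position in the expert node ordering used by the
#' structure search. Roles are:
#' \describe{
#'   \item{static}{measured once per person (e.g. gender, education);}
#'   \item{dynamic}{time-dependent lifestyle/demographic factors that carry a
#'     hardwired self-edge between consecutive time slices;}
#'   \item{health}{time-varying health factors regenerated each slice from
#'     their intra-slice parents;}
#'   \item{outcome}{the binary subjective cognitive decline indicators
#'     (good vs declined).}
#' }
#'
#' @param specs a list of variable specifications, each a list with elements
#'   `name`, `domain` (character vector of at least two unique labels) and
#'   `role`. The list order defines the expert ordering (index 0-based).
#' @return an object of class `var_registry`.
#' @seealso [default_registry()]
#' @export
variable_registry <- function(specs) {
  stopifnot(is.list(specs), length(specs) >= 1)
  nms <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate variable names in registry")
  roles <- c("static", "dynamic", "outcome", "health")
  vars <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (!is.character(s$domain) || length(s$domain) < 2)
      stop("variable '", s$name, "': domain must have at least 2 labels")
    if (anyDuplicated(s$domain))
      stop("variable '", s$name, "': domain labels must be unique")
    if (!s$role %in% roles)
      stop("variable '", s$name, "': unknown role '", s$role, "'")
    vars[[i]] <- list(name = s$name, domain = s$domain, role = s$role,
                      ordering_index = i - 1L)
  }
  names(vars) <- nms
  structure(list(vars = vars), class = "var_registry")
}

#' Default 17-variable registry of the cognitive-decline risk model
#'
#' Builds the study schema: nine 5-year age groups (40--80), gender,
#' education, daily fruit/vegetable consumption, smoking, 4-level alcohol
#' consumption, binary leisure-time physical activity (LTPA, MET cut at 14),
#' insomnia symptom frequency, 3-level BMI (underweight merged with healthy
#' weight, as tabulated), five physician-diagnosed/health factors and the
#' three binary subjective cognitive decline outcomes (concentration,
#' memory, learning; good vs declined). The list order is the expert
#' ordering under which intra-slice parents are searched: putative causes
#' precede effects.
#'
#' @return a `var_registry` with 17 variables.
#' @examples
#' reg <- default_registry()
#' length(reg$vars)              # 17
#' reg$vars$alcohol$domain      # 4 consumption levels
#' @export
default_registry <- function() {
  variable_registry(list(
    list(name = "age_group",
         domain = as.character(seq(40L, 80L, by = 5L)), role = "dynamic"),
    list(name = "gender", domain = c("woman", "man"), role = "static"),
    list(name = "education",
         domain = c("basic", "secondary", "higher"), role = "static"),
    list(name = "fruit_veg",
         domain = c("both_daily", "either_daily", "nondaily"),
         role = "dynamic"),
    list(name = "smoking",
         domain = c("never", "ex_smoker", "current_smoker"),
         role = "dynamic"),
    list(name = "alcohol",
         domain = c("none", "moderate", "high", "very_high"),
         role = "dynamic"),
    list(name = "ltpa", domain = c("inactive", "active"), role = "dynamic"),
    list(name = "insomnia",
         domain = c("lt4_nights", "n4_14_nights", "gt14_nights"),
         role = "dynamic"),
    list(name = "bmi",
         domain = c("under_or_healthy", "overweight", "obesity"),
         role = "dynamic"),
    list(name = "hypertension", domain = c("no", "yes"), role = "health"),
    list(name = "high_cholesterol", domain = c("no", "yes"), role = "health"),
    list(name = "diabetes", domain = c("no", "yes"), role = "health"),
    list(name = "mental_disorders", domain = c("no", "yes"), role = "health"),
    list(name = "pain", domain = c("no", "yes"), role = "health"),
    list(name = "concentration", domain = c("good", "declined"),
         role = "outcome"),
    list(name = "memory", domain = c("good", "declined"), role = "outcome"),
    list(name = "learning", domain = c("good", "declined"), role = "outcome")
  ))
}

## ---- internal accessors ----------------------------------------------------

reg_names <- function(registry) names(registry$vars)

reg_domain <- function(registry, var) {
  v <- registry$vars[[var]]
  if (is.null(v)) stop("unknown variable '", var, "'")
  v$domain
}

reg_k <- function(registry, var) length(reg_domain(registry, var))

reg_role <- function(registry, var) registry$vars[[var]]$role

#' @keywords internal
reg_roles <- function(registry) {
  vapply(registry$vars, function(v) v$role, character(1))
}

## variables carrying the hardwired temporal self-edge
reg_temporal <- function(registry) {
  reg_names(registry)[reg_roles(registry) == "dynamic"]
}

reg_outcomes <- function(registry) {
  reg_names(registry)[reg_roles(registry) %in% c("outcome", "health")]
}

#' @export
print.var_registry <- function(x, ...) {
  cat("Variable registry:", length(x$vars), "variables\n")
  for (v in x$vars) {
    cat(sprintf("  %2d %-17s [%-7s] {%s}\n", v$ordering_index, v$name,
                v$role, paste(v$domain, collapse = ", ")))
  }
  invisible(x)
}
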