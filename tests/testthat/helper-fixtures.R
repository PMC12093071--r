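## Shared fixtures, generated once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memoize <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

## Fully observed covariates; cognitive outcomes observed in the last two
## phases only, as in the emulated study design. Keeps every candidate
## parent set of an outcome node on a common available-case n.
covariate_missingness <- function() {
  m <- default_missingness_rates()
  m[, ] <- 0
  m[c("concentration", "memory", "learning"), 1:3] <- 1
  m
}

## Cohort with strong planted gender/alcohol/LTPA outcome effects, used for
## structure- and effect-recovery checks at moderate n.
planted_cohort_5k <- function() memoize("planted5k", function() {
  cfg <- generator_config(
    n_individuals = 5000, seed = 20260901,
    effects = list(gender = c(0, 0.5), ltpa = c(0, log(0.5)),
                   alcohol = c(0.6, 0, 0.2, 0.8)),
    missingness = covariate_missingness(), dropout = rep(0, 5))
  generate_cohort(cfg)
})

## Small complete toy cohort on the toy registry, handy for IO/CLI tests.
toy_cohort_df <- function(n = 40, seed = 1) {
  set.seed(seed)
  reg <- toy_registry()
  df <- expand.grid(id = sprintf("p%02d", seq_len(n)), phase = 1:2,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[order(df$id, df$phase), ]
  df$age_group <- "55"
  df$age_group[df$phase == 2] <- "60"
  df$ltpa <- sample(c("inactive", "active"), nrow(df), TRUE)
  df$smoking <- sample(c("never", "current_smoker"), nrow(df), TRUE)
  df$memory <- ifelse(stats::runif(nrow(df)) <
                        ifelse(df$ltpa == "inactive", 0.8, 0.2),
                      "declined", "good")
  rownames(df) <- NULL
  df
}
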