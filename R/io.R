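# Flat key-value parameter files (JSON or YAML) with explicit units in the
# key names, so that per-kGy table values cannot be silently confused with
# per-Gy internal units.

readKeyValue <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

writeKeyValue <- function(x, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

modelParamKeys <- c("kg_per_day", "kk_per_day", "v0_mm3",
                    "alpha_per_gy", "alpha_per_kgy",
                    "gamma_per_gy", "gamma_per_kgy",
                    "a_ml_per_ug", "b_ml_per_ug",
                    "alpha_beta_ratio_gy", "lq_quadratic", "tse_potency")

parseModelParameters <- function(x) {
  unknown <- setdiff(names(x), modelParamKeys)
  if (length(unknown))
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "))
  pick <- function(perGy, perKGy, default) {
    if (!is.null(x[[perGy]])) x[[perGy]]
    else if (!is.null(x[[perKGy]])) x[[perKGy]] / 1000
    else default
  }
  orDefault <- function(key, default) {
    if (is.null(x[[key]])) default else x[[key]]
  }
  modelParameters(
    kg = orDefault("kg_per_day", 0.40),
    kk = orDefault("kk_per_day", 0.26),
    v0 = orDefault("v0_mm3", 27.0),
    alpha = pick("alpha_per_gy", "alpha_per_kgy", 0.082),
    gamma = pick("gamma_per_gy", "gamma_per_kgy", 0.004),
    a = orDefault("a_ml_per_ug", 0.42),
    b = orDefault("b_ml_per_ug", 0.15),
    alphaBetaRatio = orDefault("alpha_beta_ratio_gy", 10),
    lqQuadratic = orDefault("lq_quadratic", TRUE),
    tsePotency = orDefault("tse_potency", "b"))
}

#' Read / write model parameters (JSON or YAML)
#'
#' Keys carry explicit units: `kg_per_day`, `kk_per_day`, `v0_mm3`,
#' `alpha_per_gy` (or `alpha_per_kgy`, converted on read), `gamma_per_gy`
#' (or `gamma_per_kgy`), `a_ml_per_ug`, `b_ml_per_ug`,
#' `alpha_beta_ratio_gy`, `lq_quadratic`, `tse_potency`. Unknown keys are
#' rejected; missing keys fall back to the packaged defaults.
#'
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @return `readModelParameters` returns a [ModelParameters-class].
#' @export
readModelParameters <- function(path) {
  parseModelParameters(readKeyValue(path))
}

#' @rdname readModelParameters
#' @param params a [ModelParameters-class] object.
#' @export
writeModelParameters <- function(params, path) {
  stopifnot(is(params, "ModelParameters"))
  writeKeyValue(list(
    kg_per_day = params@kg, kk_per_day = params@kk, v0_mm3 = params@v0,
    alpha_per_gy = params@alpha, gamma_per_gy = params@gamma,
    a_ml_per_ug = params@a, b_ml_per_ug = params@b,
    alpha_beta_ratio_gy = params@alphaBetaRatio,
    lq_quadratic = params@lqQuadratic, tse_potency = params@tsePotency),
    path)
}

#' Read / write population parameters (JSON or YAML)
#'
#' Structure: a `model` block (see [readModelParameters()]), a `bsv_cv_pct`
#' block with entries `v0`, `gamma`, `alpha` (CV percent, converted to
#' log-scale SDs as `sqrt(log(1 + cv^2))` unless `cv_approx` is true), and
#' `sigma_prop` / `sigma_add_mm3` residual errors.
#'
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @return `readPopulationParameters` returns a
#'   [PopulationParameters-class].
#' @export
readPopulationParameters <- function(path) {
  x <- readKeyValue(path)
  known <- c("model", "bsv_cv_pct", "sigma_prop", "sigma_add_mm3",
             "cv_approx")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown population keys: ", paste(unknown, collapse = ", "))
  fixed <- parseModelParameters(if (is.null(x$model)) list() else x$model)
  cv <- unlist(x$bsv_cv_pct)
  if (is.null(cv)) cv <- c(v0 = 50, gamma = 46, alpha = 42)
  populationParameters(fixed = fixed, bsvCV = cv,
                       sigmaProp = if (is.null(x$sigma_prop)) 0.24
                                   else x$sigma_prop,
                       sigmaAdd = if (is.null(x$sigma_add_mm3)) 6.9
                                  else x$sigma_add_mm3,
                       cvApprox = isTRUE(x$cv_approx))
}

#' @rdname readPopulationParameters
#' @param pop a [PopulationParameters-class] object.
#' @export
writePopulationParameters <- function(pop, path) {
  stopifnot(is(pop, "PopulationParameters"))
  f <- pop@fixed
  writeKeyValue(list(
    model = list(kg_per_day = f@kg, kk_per_day = f@kk, v0_mm3 = f@v0,
                 alpha_per_gy = f@alpha, gamma_per_gy = f@gamma,
                 a_ml_per_ug = f@a, b_ml_per_ug = f@b,
                 alpha_beta_ratio_gy = f@alphaBetaRatio,
                 lq_quadratic = f@lqQuadratic, tse_potency = f@tsePotency),
    bsv_cv_pct = as.list(round(100 * sqrt(exp(pop@omega^2) - 1), 6)),
    sigma_prop = pop@sigmaProp, sigma_add_mm3 = pop@sigmaAdd), path)
}

#' Read / write observation CSVs
#'
#' Long format, one row per caliper measurement:
#' `animal_id, arm, time_days, volume_mm3` plus any extra columns (e.g.
#' `below_limit`).
#'
#' @param path CSV file path.
#' @return `readObservations` returns the `data.frame`.
#' @export
readObservations <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "arm", "time_days", "volume_mm3")
  if (!all(need %in% names(x)))
    stop("observation file must have columns ", paste(need, collapse = ", "))
  x
}

#' @rdname readObservations
#' @param observations `data.frame` in the same schema.
#' @export
writeObservations <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE)
  invisible(path)
}
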