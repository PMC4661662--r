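#' Distance-decay specification
#'
#' Describes how interaction between a population and a facility fades
#' with travel time inside a catchment of size `C` minutes.  Three
#' families are supported:
#'
#' * `"gaussian"`: a catchment-normalised truncated Gaussian,
#'   \deqn{\omega(d, C) = \left[\frac{e^{-d^2/(2C^2)} - e^{-1/2}}
#'   {1 - e^{-1/2}}\right]^{\beta},}
#'   which equals 1 at `d = 0`, falls continuously to 0 at `d = C`, and
#'   is 0 beyond.  `beta` is a shape exponent (default 1); larger values
#'   steepen the decay.  Setting `form = "raw"` swaps in the unnormalised
#'   kernel \eqn{e^{-d^2/\beta}} (still truncated at `C`) for
#'   experimentation with impedance-coefficient parameterisations.
#' * `"stepwise"`: the catchment is split into `length(zone_weights)`
#'   equal travel-time zones and each zone carries a fixed weight
#'   (default `c(1.00, 0.42, 0.03)`, the classic three-zone scheme).
#'   Zone intervals are half-open `(lo, hi]` with zone 1 closed at 0, so
#'   a boundary time belongs to the inner (higher-weight) zone.
#' * `"none"`: weight 1 everywhere inside the catchment, 0 beyond.
#'
#' @param family One of `"gaussian"`, `"stepwise"`, `"none"`.
#' @param beta Positive shape exponent for the Gaussian family.
#' @param zone_weights Strictly decreasing weights in `(0, 1]` with first
#'   element 1, one per zone (stepwise family).
#' @param form `"normalized"` (default) or `"raw"` Gaussian form.
#' @return An object of class `decay_spec`.
#' @seealso [gaussian_weight()], [stepwise_weight()], [make_decay()]
#' @export
#' @examples
#' decay_spec("gaussian", beta = 1)
#' decay_spec("stepwise")
decay_spec <- function(family = c("gaussian", "stepwise", "none"),
                       beta = 1,
                       zone_weights = c(1.00, 0.42, 0.03),
                       form = c("normalized", "raw")) {
  family <- match.arg(family)
  form <- match.arg(form)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("`beta` must be a single positive number", call. = FALSE)
  if (family == "stepwise") {
    if (length(zone_weights) == 0L)
      stop("`zone_weights` must be non-empty", call. = FALSE)
    if (any(!is.finite(zone_weights)) ||
        any(zone_weights <= 0) || any(zone_weights > 1))
      stop("`zone_weights` must lie in (0, 1]", call. = FALSE)
    if (zone_weights[1L] != 1)
      stop("first zone weight must be 1.0", call. = FALSE)
    if (length(zone_weights) > 1L && any(diff(zone_weights) >= 0))
      stop("`zone_weights` must be strictly decreasing", call. = FALSE)
  }
  structure(
    list(family = family, beta = beta,
         zone_weights = as.numeric(zone_weights), form = form),
    class = "decay_spec"
  )
}

#' @export
print.decay_spec <- function(x, ...) {
  cat("<decay_spec>", x$family)
  if (x$family == "gaussian")
    cat(sprintf(" (beta = %g, %s form)", x$beta, x$form))
  if (x$family == "stepwise")
    cat(" weights:", paste(x$zone_weights, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' EV2SFCA run configuration
#'
#' Parameters of the enhanced variable two-step floating catchment area
#' method.  The catchment search walks the travel-time grid
#' `t0, t0 + dt, ...` up to `t_max`.  A facility catchment stops growing
#' once its facility-to-population ratio (capacity over unweighted
#' reachable population) falls to `fprt1`; a population catchment stops
#' once the summed facility ratios reach `fprt2`.  Defaults are the
#' published run parameters of the method: `t0 = 5` min, `dt = 1` min,
#' `t_max = 120` min (two-hour travel cap), `fprt1 = 135/50000`
#' (135 beds per 50,000 persons), `fprt2 = 30/1000` (30 beds per 1,000
#' persons).
#'
#' @param t0 Initial travel time in minutes.
#' @param dt Grid increment in minutes.
#' @param t_max Maximum travel time (cap) in minutes; searches that never
#'   meet their threshold stop here and are flagged `capped`.
#' @param fprt1 Facility-side stopping threshold (beds per person).
#' @param fprt2 Population-side target ratio (beds per person).
#' @param decay A [decay_spec()]; default continuous Gaussian.
#' @param constraint_mode Which facility-population pairs enter the
#'   scoring steps: `"mutual"` (both catchments must contain the other
#'   site; the method's defining constraint), `"facility_side"` (only
#'   `d <= C_i`), or `"population_side"` (only `d <= C_j`).
#' @param weight_param Catchment used inside the decay weight:
#'   `"own_catchment"` (facility equation uses `C_i`, population equation
#'   uses `C_j`; the conventional 2SFCA reading) or `"symmetric_min"`
#'   (both use `min(C_i, C_j)`, the only choice under which the
#'   supply-conservation identity holds exactly for any decay family).
#' @param strict_thresholds If `TRUE`, threshold attainment requires a
#'   strict inequality instead of the default inclusive comparison
#'   (stop at ratio `<=` `fprt1`, sum `>=` `fprt2`).
#' @return An object of class `ev_config`.
#' @export
#' @examples
#' ev_config()
#' ev_config(dt = 5, decay = decay_spec("none"))
ev_config <- function(t0 = 5, dt = 1, t_max = 120,
                      fprt1 = 135 / 50000, fprt2 = 30 / 1000,
                      decay = decay_spec("gaussian"),
                      constraint_mode = c("mutual", "facility_side",
                                          "population_side"),
                      weight_param = c("own_catchment", "symmetric_min"),
                      strict_thresholds = FALSE) {
  constraint_mode <- match.arg(constraint_mode)
  weight_param <- match.arg(weight_param)
  check_grid_params(t0, dt, t_max)
  if (!is.numeric(fprt1) || length(fprt1) != 1L || fprt1 <= 0)
    stop("`fprt1` must be a single positive number", call. = FALSE)
  if (!is.numeric(fprt2) || length(fprt2) != 1L || fprt2 <= 0)
    stop("`fprt2` must be a single positive number", call. = FALSE)
  if (!inherits(decay, "decay_spec"))
    stop("`decay` must be a decay_spec object", call. = FALSE)
  structure(
    list(t0 = t0, dt = dt, t_max = t_max, fprt1 = fprt1, fprt2 = fprt2,
         decay = decay, constraint_mode = constraint_mode,
         weight_param = weight_param,
         strict_thresholds = isTRUE(strict_thresholds)),
    class = "ev_config"
  )
}

#' V2SFCA run configuration
#'
#' Parameters of the variable two-step floating catchment area baseline.
#' The supply catchment grows until the unweighted reachable population
#' reaches `base_population` (BP); the demand catchment grows until the
#' summed supply ratios reach the provider-to-population target `ppr`.
#' Defaults follow the published baseline run: `BP = 50000`,
#' `ppr = 30/1000`, grid `t0 = 5`, `dt = 1`, `t_max = 120` minutes, and
#' the three-zone stepwise decay.
#'
#' @param base_population Supply-side base population threshold (BP).
#' @param ppr Demand-side provider-to-population target ratio.
#' @inheritParams ev_config
#' @return An object of class `v2_config`.
#' @export
v2_config <- function(base_population = 50000, ppr = 30 / 1000,
                      t0 = 5, dt = 1, t_max = 120,
                      decay = decay_spec("stepwise"),
                      strict_thresholds = FALSE) {
  check_grid_params(t0, dt, t_max)
  if (!is.numeric(base_population) || length(base_population) != 1L ||
      base_population <= 0)
    stop("`base_population` must be a single positive number", call. = FALSE)
  if (!is.numeric(ppr) || length(ppr) != 1L || ppr <= 0)
    stop("`ppr` must be a single positive number", call. = FALSE)
  if (!inherits(decay, "decay_spec"))
    stop("`decay` must be a decay_spec object", call. = FALSE)
  structure(
    list(base_population = base_population, ppr = ppr,
         t0 = t0, dt = dt, t_max = t_max, decay = decay,
         strict_thresholds = isTRUE(strict_thresholds)),
    class = "v2_config"
  )
}

check_grid_params <- function(t0, dt, t_max) {
  if (!is.numeric(t0) || length(t0) != 1L || t0 <= 0)
    stop("`t0` must be a single positive number", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  if (!is.numeric(t_max) || length(t_max) != 1L || t_max < t0)
    stop("`t_max` must be >= `t0`", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.ev_config <- function(x, ...) {
  cat("<ev_config>\n")
  cat(sprintf("  grid: t0 = %g, dt = %g, t_max = %g min\n",
              x$t0, x$dt, x$t_max))
  cat(sprintf("  thresholds: fprt1 = %g, fprt2 = %g (beds/person)\n",
              x$fprt1, x$fprt2))
  cat(sprintf("  decay: %s | constraint: %s | weights: %s\n",
              x$decay$family, x$constraint_mode, x$weight_param))
  invisible(x)
}

#' @export
print.v2_config <- function(x, ...) {
  cat("<v2_config>\n")
  cat(sprintf("  grid: t0 = %g, dt = %g, t_max = %g min\n",
              x$t0, x$dt, x$t_max))
  cat(sprintf("  thresholds: BP = %g, PPR = %g\n", x$base_population, x$ppr))
  cat(sprintf("  decay: %s\n", x$decay$family))
  invisible(x)
}

#' Read a run configuration from a YAML or JSON file
#'
#' Keys mirror the [ev_config()] / [v2_config()] argument names; the
#' `decay` key is a mapping with `family`, `beta`, `zone_weights`,
#' `form`.  Unknown keys are rejected so typos cannot silently fall back
#' to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param method `"ev2sfca"` or `"v2sfca"`: which configuration class to
#'   build.
#' @return An `ev_config` or `v2_config`.
#' @export
read_config <- function(path, method = c("ev2sfca", "v2sfca")) {
  method <- match.arg(method)
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("config file must contain a mapping", call. = FALSE)
  if (!is.null(raw$decay)) {
    d <- raw$decay
    allowed <- c("family", "beta", "zone_weights", "form")
    bad <- setdiff(names(d), allowed)
    if (length(bad))
      stop("unknown decay key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    raw$decay <- do.call(decay_spec, d)
  }
  ctor <- if (method == "ev2sfca") ev_config else v2_config
  allowed <- names(formals(ctor))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(ctor, raw)
}
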