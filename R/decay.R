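#' Gaussian distance-decay weight
#'
#' Catchment-normalised truncated Gaussian: weight 1 at the origin,
#' continuous and strictly decreasing to 0 at the catchment edge `C`,
#' and 0 beyond it.  With `form = "normalized"` (default),
#' \deqn{\omega(d, C) = \left[\frac{e^{-d^2/(2C^2)} - e^{-1/2}}
#' {1 - e^{-1/2}}\right]^{\beta};}
#' `form = "raw"` gives the unnormalised kernel \eqn{e^{-d^2/\beta}}
#' truncated at `C`.  Vectorised over `d` and `C` (recycled).
#'
#' @param d Travel time in minutes, `>= 0`.
#' @param C Catchment size in minutes, `> 0`.
#' @param beta Positive shape exponent.
#' @param form `"normalized"` or `"raw"`.
#' @return Weight(s) in `[0, 1]`.
#' @export
#' @examples
#' gaussian_weight(0, 30)            # 1
#' gaussian_weight(30, 30)           # 0 at the edge
#' gaussian_weight(15, 30)           # ~0.70136
gaussian_weight <- function(d, C, beta = 1, form = c("normalized", "raw")) {
  form <- match.arg(form)
  if (any(!is.finite(C)) || any(C <= 0))
    stop("catchment `C` must be positive and finite", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("`beta` must be a single positive number", call. = FALSE)
  if (any(d < 0))
    stop("travel time `d` must be non-negative", call. = FALSE)
  w <- if (form == "normalized") {
    base <- (exp(-d^2 / (2 * C^2)) - exp(-0.5)) / (1 - exp(-0.5))
    pmax(base, 0)^beta
  } else {
    exp(-d^2 / beta)
  }
  ifelse(d > C, 0, w)
}

#' Stepwise (zonal) distance-decay weight
#'
#' The catchment `[0, C]` is split into `length(zone_weights)` equal
#' travel-time zones; the weight of the zone containing `d` is
#' returned, and 0 beyond `C`.  Zone intervals are half-open `(lo, hi]`
#' with zone 1 = `[0, C/K]`, so a time exactly on a boundary takes the
#' inner zone's (higher) weight.  With the default three-zone weights
#' `(1.00, 0.42, 0.03)` and a 45-minute catchment, zone 1 covers 0-15
#' min, zone 2 covers 15-30 min and zone 3 covers 30-45 min.
#' Vectorised over `d` and `C` (recycled).
#'
#' @param d Travel time in minutes, `>= 0`.
#' @param C Catchment size in minutes, `> 0`.
#' @param zone_weights Strictly decreasing weights, one per zone.
#' @return Weight(s) in `[0, 1]`.
#' @export
#' @examples
#' stepwise_weight(20, 45)  # zone 2 -> 0.42
#' stepwise_weight(35, 45)  # zone 3 -> 0.03
stepwise_weight <- function(d, C, zone_weights = c(1.00, 0.42, 0.03)) {
  if (length(zone_weights) == 0L)
    stop("`zone_weights` must be non-empty", call. = FALSE)
  if (any(!is.finite(C)) || any(C <= 0))
    stop("catchment `C` must be positive and finite", call. = FALSE)
  if (any(d < 0))
    stop("travel time `d` must be non-negative", call. = FALSE)
  K <- length(zone_weights)
  n <- max(length(d), length(C))
  d <- rep_len(d, n)
  C <- rep_len(C, n)
  zone <- ceiling(d * K / C)
  zone[d == 0] <- 1L
  out <- numeric(n)
  inside <- d <= C
  out[inside] <- zone_weights[pmin(zone[inside], K)]
  out
}

#' Build a decay weight function from a specification
#'
#' Dispatches on the family of a [decay_spec()] and returns a function
#' `f(d, C)` mapping travel time and catchment size to a weight in
#' `[0, 1]`; every returned function gives 0 beyond the catchment.
#'
#' @param spec A [decay_spec()].
#' @return A vectorised function of `(d, C)`.
#' @export
#' @examples
#' w <- make_decay(decay_spec("stepwise"))
#' w(20, 45)  # 0.42
make_decay <- function(spec) {
  if (!inherits(spec, "decay_spec"))
    stop("`spec` must be a decay_spec object", call. = FALSE)
  switch(spec$family,
    gaussian = function(d, C)
      gaussian_weight(d, C, beta = spec$beta, form = spec$form),
    stepwise = function(d, C)
      stepwise_weight(d, C, zone_weights = spec$zone_weights),
    none = function(d, C) {
      if (any(!is.finite(C)) || any(C <= 0))
        stop("catchment `C` must be positive and finite", call. = FALSE)
      as.numeric(d <= C)
    },
    stop("unknown decay family: ", spec$family, call. = FALSE)
  )
}
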