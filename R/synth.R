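#' Parameters of a synthetic monocentric city
#'
#' Describes an idealised city used to exercise the accessibility
#' methods without real data: population density decays exponentially
#' with distance from the center, facilities are preferentially placed
#' centrally, bed capacities are drawn from a heavy-tailed law
#' *independently of location* (so capacity-catchment correlations
#' reflect the algorithm, not the generator), and travel runs on a
#' square grid of roads whose class (hence speed) improves toward the
#' center.
#'
#' Defaults describe a mid-sized city scaled to the conditions under
#' which the default thresholds are meaningful: 200 demand points and
#' 20 facilities within a 20 km radius; center density 2,700 elders per
#' demand point with an 8 km decay scale, giving roughly 125,000 elders
#' in total and an average elderly population of about 50,000 within 20
#' minutes of a facility (the population base from which the default
#' `fprt1 = 135/50000` is derived); capacities between 30 and 1,000
#' beds with Pareto shape 0.7, mean about 140 beds (residential care
#' stock averages near 135 beds per facility); and a 2 km road grid.
#'
#' @param n_populations,n_facilities Site counts, `> 0`.
#' @param radius_m City radius in meters.
#' @param density_scale Persons per demand point at the center.
#' @param density_decay_m Exponential length scale of the density fall.
#' @param facility_central_bias In `[0, 1)`: 0 places facilities
#'   uniformly over the disk, values toward 1 concentrate them at the
#'   center.
#' @param capacity_min,capacity_max,capacity_shape Truncated-Pareto
#'   capacity law (beds).
#' @param road_spacing_m Grid spacing of the road network in meters.
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return An object of class `city_params`.
#' @export
city_params <- function(n_populations = 200, n_facilities = 20,
                        radius_m = 20000,
                        density_scale = 2700, density_decay_m = 8000,
                        facility_central_bias = 0.5,
                        capacity_min = 30, capacity_max = 1000,
                        capacity_shape = 0.7,
                        road_spacing_m = 2000,
                        seed) {
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory: the generator has no implicit randomness",
         call. = FALSE)
  if (n_populations <= 0 || n_facilities <= 0)
    stop("site counts must be positive", call. = FALSE)
  if (radius_m <= 0 || density_scale <= 0 || density_decay_m <= 0 ||
      road_spacing_m <= 0)
    stop("lengths and densities must be positive", call. = FALSE)
  if (facility_central_bias < 0 || facility_central_bias >= 1)
    stop("`facility_central_bias` must lie in [0, 1)", call. = FALSE)
  if (capacity_min <= 0 || capacity_max < capacity_min ||
      capacity_shape <= 0)
    stop("invalid capacity law", call. = FALSE)
  structure(
    list(n_populations = as.integer(n_populations),
         n_facilities = as.integer(n_facilities),
         radius_m = radius_m, density_scale = density_scale,
         density_decay_m = density_decay_m,
         facility_central_bias = facility_central_bias,
         capacity_min = capacity_min, capacity_max = capacity_max,
         capacity_shape = capacity_shape,
         road_spacing_m = road_spacing_m,
         seed = as.integer(seed)),
    class = "city_params"
  )
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

rtrunc_pareto <- function(n, xmin, xmax, shape) {
  if (xmin == xmax) return(rep(xmin, n))
  u <- runif(n)
  f <- 1 - (xmin / xmax)^shape          # mass inside the truncation
  xmin / (1 - u * f)^(1 / shape)
}

#' Generate a synthetic monocentric city
#'
#' Demand points sit on a jittered square grid clipped to the city
#' disk, with population counts `round(density_scale *
#' exp(-r / density_decay_m))` at radius `r`.  Facilities are placed by
#' a center-biased radial draw; capacities come from the truncated
#' Pareto law, independent of location.  The road network is a square
#' grid whose edge class improves toward the center (outer ring
#' `other`, then `secondary`, `main`, and `expressway` innermost).
#' Identical parameters (including the seed) give byte-identical
#' outputs when written with [write_city()].
#'
#' @param params A [city_params()].
#' @return A list with `facilities`, `populations` (site tables) and
#'   `network` (a [road_network()]).
#' @export
generate_city <- function(params) {
  stopifnot(inherits(params, "city_params"))
  with_seed(params$seed, {
    R <- params$radius_m
    n <- params$n_populations

    # --- demand points: jittered grid clipped to the disk
    s <- sqrt(pi * R^2 / n)
    repeat {
      ax <- seq(-R, R, by = s)
      grid <- expand.grid(x = ax, y = ax)
      grid <- grid[grid$x^2 + grid$y^2 <= R^2, , drop = FALSE]
      if (nrow(grid) >= n) break
      s <- s * 0.95
    }
    keep <- sort(sample.int(nrow(grid), n))
    px <- grid$x[keep] + runif(n, -0.3 * s, 0.3 * s)
    py <- grid$y[keep] + runif(n, -0.3 * s, 0.3 * s)
    pr <- sqrt(px^2 + py^2)
    pop <- round(params$density_scale * exp(-pr / params$density_decay_m))
    populations <- data.frame(
      id = sprintf("p%04d", seq_len(n)),
      x = px, y = py, population = pop,
      stringsAsFactors = FALSE
    )

    # --- facilities: center-biased radial placement, independent capacity
    nf <- params$n_facilities
    expo <- 1 / (2 * (1 - params$facility_central_bias))
    fr <- R * runif(nf)^expo
    th <- runif(nf, 0, 2 * pi)
    cap <- round(rtrunc_pareto(nf, params$capacity_min,
                               params$capacity_max,
                               params$capacity_shape))
    facilities <- data.frame(
      id = sprintf("f%03d", seq_len(nf)),
      x = fr * cos(th), y = fr * sin(th), capacity = cap,
      stringsAsFactors = FALSE
    )

    # --- road grid with faster classes toward the center
    g <- params$road_spacing_m
    ax <- seq(-R, R, by = g)
    nodes <- expand.grid(col = seq_along(ax), row = seq_along(ax))
    nodes <- data.frame(
      id = sprintf("n%03d_%03d", nodes$row, nodes$col),
      x = ax[nodes$col], y = ax[nodes$row],
      stringsAsFactors = FALSE
    )
    m <- length(ax)
    node_id <- function(row, col) sprintf("n%03d_%03d", row, col)
    h <- expand.grid(row = seq_len(m), col = seq_len(m - 1))
    v <- expand.grid(row = seq_len(m - 1), col = seq_len(m))
    edges <- rbind(
      data.frame(from = node_id(h$row, h$col),
                 to = node_id(h$row, h$col + 1),
                 mx = (ax[h$col] + ax[h$col + 1]) / 2, my = ax[h$row],
                 stringsAsFactors = FALSE),
      data.frame(from = node_id(v$row, v$col),
                 to = node_id(v$row + 1, v$col),
                 mx = ax[v$col], my = (ax[v$row] + ax[v$row + 1]) / 2,
                 stringsAsFactors = FALSE)
    )
    ring <- sqrt(edges$mx^2 + edges$my^2) / R
    edges$class <- cut(ring, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
                       labels = c("expressway", "main", "secondary",
                                  "other"))
    edges <- data.frame(from = edges$from, to = edges$to,
                        length_m = g, class = as.character(edges$class),
                        stringsAsFactors = FALSE)
    list(facilities = facilities, populations = populations,
         network = road_network(nodes, edges))
  })
}

#' Write a synthetic city to CSV files
#'
#' Writes `facilities.csv`, `populations.csv`, `nodes.csv` and
#' `edges.csv` into `dir`.
#'
#' @param city A list as returned by [generate_city()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_city <- function(city, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sites(city$facilities, file.path(dir, "facilities.csv"))
  write_sites(city$populations, file.path(dir, "populations.csv"))
  utils::write.csv(city$network$nodes, file.path(dir, "nodes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(city$network$edges, file.path(dir, "edges.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Two-facility, two-population micro-systems
#'
#' Small fixtures illustrating why one-sided catchment containment
#' over-counts interaction.  In `system1` the facility catchments
#' (20 min) contain population `A`, but `A`'s own 5-minute catchment
#' excludes the farther facility `a` (12 min away): people choose the
#' closer facility `b` (3 min).  In `system2` the population catchments
#' (20 min) contain facility `a`, but `a`'s 12-minute catchment
#' excludes population `B` 15 minutes away, so `a` can rarely serve it.
#' Travel times not pinned down by the narrative are documented
#' stand-ins chosen to satisfy its inequalities; capacities and
#' populations are nominal.
#'
#' @param which `"system1"` or `"system2"`.
#' @return A list with `facilities`, `populations`, `od` and preset
#'   `catchments` (a `catchment_table`).
#' @export
generate_figure1_system <- function(which = c("system1", "system2")) {
  which <- match.arg(which)
  facilities <- data.frame(
    id = c("a", "b"), x = c(0, 4000), y = c(0, 0),
    capacity = c(100, 100), stringsAsFactors = FALSE
  )
  populations <- data.frame(
    id = c("A", "B"), x = c(2000, 6000), y = c(3000, 1000),
    population = c(1000, 1000), stringsAsFactors = FALSE
  )
  if (which == "system1") {
    minutes <- data.frame(
      facility_id = c("a", "a", "b", "b"),
      population_id = c("A", "B", "A", "B"),
      minutes = c(12, 8, 3, 10),
      stringsAsFactors = FALSE
    )
    catch <- data.frame(
      id = c("a", "b", "A", "B"),
      type = c("facility", "facility", "population", "population"),
      catchment_min = c(20, 20, 5, 20),
      fpr = c(NA_real_, NA_real_, NA_real_, NA_real_),
      capped = FALSE, stringsAsFactors = FALSE
    )
  } else {
    minutes <- data.frame(
      facility_id = c("a", "a", "b", "b"),
      population_id = c("A", "B", "A", "B"),
      minutes = c(8, 15, 5, 6),
      stringsAsFactors = FALSE
    )
    catch <- data.frame(
      id = c("a", "b", "A", "B"),
      type = c("facility", "facility", "population", "population"),
      catchment_min = c(12, 20, 20, 20),
      fpr = c(NA_real_, NA_real_, NA_real_, NA_real_),
      capped = FALSE, stringsAsFactors = FALSE
    )
  }
  class(catch) <- c("catchment_table", "data.frame")
  list(
    facilities = facilities,
    populations = populations,
    od = od_matrix(minutes, facilities$id, populations$id, t_max = 120),
    catchments = catch
  )
}
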