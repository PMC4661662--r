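# Shared fixtures, all built in code.

# Two-facility / two-population instance whose four steps can be (and were)
# enumerated by hand: grid {5, 10, ..., 120}, fprt1 = 0.0027 stops facility
# `a` at 20 min (25/10000 = 0.0025) and `b` at 5 min (10/6000), both
# population searches cap at 120 min, and with decay "none" under the
# mutual constraint D_a = 0.0025, D_b = 1/600, A_A = 0.0025,
# A_B = 0.0025 + 1/600.
toy_instance <- function(decay = decay_spec("none")) {
  facilities <- data.frame(id = c("a", "b"), x = c(0, 5000), y = 0,
                           capacity = c(25, 10), stringsAsFactors = FALSE)
  populations <- data.frame(id = c("A", "B"), x = c(1000, 6000), y = 0,
                            population = c(4000, 6000),
                            stringsAsFactors = FALSE)
  od <- od_matrix(
    data.frame(facility_id = c("a", "a", "b", "b"),
               population_id = c("A", "B", "A", "B"),
               minutes = c(5, 20, 15, 5)),
    facilities$id, populations$id, t_max = 120)
  cfg <- ev_config(t0 = 5, dt = 5, t_max = 120, fprt1 = 0.0027,
                   fprt2 = 0.03, decay = decay)
  list(facilities = facilities, populations = populations, od = od,
       cfg = cfg)
}

# Random small instance on a travel-time grid; distances include
# unreachable pairs, populations include zeros, thresholds vary.
random_instance <- function(nf = sample(1:5, 1), np = sample(1:5, 1),
                            t_max = 60) {
  facilities <- data.frame(
    id = sprintf("f%02d", seq_len(nf)),
    x = runif(nf, 0, 1e4), y = runif(nf, 0, 1e4),
    capacity = sample(5:200, nf, replace = TRUE),
    stringsAsFactors = FALSE)
  populations <- data.frame(
    id = sprintf("p%02d", seq_len(np)),
    x = runif(np, 0, 1e4), y = runif(np, 0, 1e4),
    population = sample(c(0, 50:5000), np, replace = TRUE),
    stringsAsFactors = FALSE)
  m <- matrix(runif(nf * np, 0, t_max * 1.3), nf, np,
              dimnames = list(facilities$id, populations$id))
  m[runif(nf * np) < 0.15] <- Inf
  od <- as_od_matrix(m, t_max = t_max)
  cfg <- ev_config(t0 = 5, dt = sample(c(1, 2, 5), 1), t_max = t_max,
                   fprt1 = 10^runif(1, -3.3, -1.5),
                   fprt2 = 10^runif(1, -2.5, -1),
                   decay = decay_spec("none"))
  list(facilities = facilities, populations = populations, od = od,
       cfg = cfg)
}

default_city_cache <- new.env(parent = emptyenv())

# Default synthetic city (seed 1) plus its network travel times; cached so
# the accessibility, synthesis and acceptance tests share one build.
default_city <- function() {
  if (is.null(default_city_cache$city)) {
    city <- generate_city(city_params(seed = 1))
    od <- od_from_network(city$network, city$facilities,
                          city$populations, t_max = 120)
    default_city_cache$city <- c(city, list(od = od))
  }
  default_city_cache$city
}
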