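#' Facility-population pairs admitted to the scoring steps
#'
#' A reachable pair (travel time `d` finite, i.e. within the travel cap)
#' enters the accessibility calculation only if the mode's containment
#' predicate holds: under `"mutual"` the facility catchment must contain
#' the population location *and* the population catchment must contain
#' the facility location (`d <= C_i` and `d <= C_j`); the one-sided
#' modes check only their own side, as the classic 2SFCA steps do.
#' Boundary distances `d == C` are eligible (inclusive comparison).
#'
#' @param od An [od_matrix()].
#' @param catchments A `catchment_table` from
#'   [compute_all_catchments()] covering every site in `od`.
#' @param mode `"mutual"`, `"facility_side"` or `"population_side"`.
#' @return A `data.frame` with columns `facility_id`, `population_id`,
#'   `minutes`, `c_facility`, `c_population`, sorted by facility then
#'   population id.  The attribute `"rejected"` counts, among reachable
#'   pairs, how many fail only the facility-side test, only the
#'   population-side test, or both (independent of `mode`).
#' @export
eligible_pairs <- function(od, catchments,
                           mode = c("mutual", "facility_side",
                                    "population_side")) {
  mode <- match.arg(mode)
  M <- od$times
  fc <- catchments[catchments$type == "facility", , drop = FALSE]
  pc <- catchments[catchments$type == "population", , drop = FALSE]
  idx <- which(is.finite(M), arr.ind = TRUE)
  fid <- if (nrow(idx)) rownames(M)[idx[, 1L]] else character(0)
  pid <- if (nrow(idx)) colnames(M)[idx[, 2L]] else character(0)
  d <- M[idx]
  ci <- fc$catchment_min[match(fid, fc$id)]
  cj <- pc$catchment_min[match(pid, pc$id)]
  if (anyNA(ci) || anyNA(cj))
    stop("catchment table does not cover every site in the OD matrix",
         call. = FALSE)
  ok_f <- d <= ci
  ok_p <- d <= cj
  keep <- switch(mode,
    mutual = ok_f & ok_p,
    facility_side = ok_f,
    population_side = ok_p
  )
  out <- data.frame(
    facility_id = fid[keep], population_id = pid[keep],
    minutes = d[keep], c_facility = ci[keep], c_population = cj[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$facility_id, out$population_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- c(
    facility_side_only = sum(!ok_f & ok_p),
    population_side_only = sum(ok_f & !ok_p),
    both_sides = sum(!ok_f & !ok_p)
  )
  out
}

#' Discounted facility-to-population ratio (step 3)
#'
#' Capacity divided by the decay-weighted population of the facility's
#' eligible demand, \eqn{D_i = S_i / \sum_j P_j \omega_{ji}}.  An empty
#' eligible set, or one whose weights all vanish, yields 0 (the facility
#' serves no one).
#'
#' @param capacity Facility capacity (beds), a single positive number.
#' @param population Populations of the eligible demand sites.
#' @param weight Decay weights for the same sites.
#' @return Beds per weighted person, `>= 0`.
#' @export
discounted_fpr <- function(capacity, population, weight) {
  stopifnot(length(population) == length(weight))
  denom <- sum(population * weight)
  if (length(population) == 0L || denom <= 0) return(0)
  capacity / denom
}

#' Accessibility score of a population site (step 4)
#'
#' Decay-weighted sum of the discounted ratios of the site's eligible
#' facilities, \eqn{A_j = \sum_i D_i \omega_{ij}}; 0 when no facility is
#' eligible.  Units: beds per person.
#'
#' @param d_fpr Discounted ratios `D_i` of the eligible facilities.
#' @param weight Decay weights for the same facilities.
#' @return Beds per person, `>= 0`.
#' @export
accessibility_score <- function(d_fpr, weight) {
  stopifnot(length(d_fpr) == length(weight))
  if (length(d_fpr) == 0L) return(0)
  sum(d_fpr * weight)
}

score_pairs <- function(facilities, populations, pairs_eq1, pairs_eq2,
                        wfun, weight_param) {
  pick_c <- function(pairs, side) {
    if (weight_param == "symmetric_min")
      pmin(pairs$c_facility, pairs$c_population)
    else if (side == "facility") pairs$c_facility else pairs$c_population
  }
  d_fpr <- setNames(numeric(nrow(facilities)), facilities$id)
  n_elig_f <- setNames(integer(nrow(facilities)), facilities$id)
  if (nrow(pairs_eq1)) {
    w1 <- wfun(pairs_eq1$minutes, pick_c(pairs_eq1, "facility"))
    pw <- populations$population[match(pairs_eq1$population_id,
                                       populations$id)] * w1
    denom <- rowsum(pw, pairs_eq1$facility_id)
    d_fpr[rownames(denom)] <- ifelse(
      denom[, 1L] > 0,
      facilities$capacity[match(rownames(denom), facilities$id)] /
        denom[, 1L],
      0)
    cnt <- table(pairs_eq1$facility_id)
    n_elig_f[names(cnt)] <- as.integer(cnt)
  }
  acc <- setNames(numeric(nrow(populations)), populations$id)
  n_elig_p <- setNames(integer(nrow(populations)), populations$id)
  if (nrow(pairs_eq2)) {
    w2 <- wfun(pairs_eq2$minutes, pick_c(pairs_eq2, "population"))
    contrib <- d_fpr[pairs_eq2$facility_id] * w2
    sums <- rowsum(contrib, pairs_eq2$population_id)
    acc[rownames(sums)] <- sums[, 1L]
    cnt <- table(pairs_eq2$population_id)
    n_elig_p[names(cnt)] <- as.integer(cnt)
  }
  list(d_fpr = d_fpr, acc = acc,
       n_elig_f = n_elig_f, n_elig_p = n_elig_p)
}

new_accessibility_result <- function(method, facilities, populations,
                                     catchments, scores, config, rejected) {
  structure(
    list(
      method = method,
      facility = data.frame(
        facility_id = facilities$id,
        discounted_fpr = unname(scores$d_fpr),
        n_eligible = unname(scores$n_elig_f),
        stringsAsFactors = FALSE
      ),
      population = data.frame(
        population_id = populations$id,
        accessibility = unname(scores$acc),
        n_eligible = unname(scores$n_elig_p),
        stringsAsFactors = FALSE
      ),
      catchments = catchments,
      config = config,
      rejected_pairs = rejected
    ),
    class = "accessibility_result"
  )
}

#' @export
print.accessibility_result <- function(x, ...) {
  cat(sprintf("<accessibility_result> method: %s\n", x$method))
  cat(sprintf("  %d facilities, %d populations\n",
              nrow(x$facility), nrow(x$population)))
  cat(sprintf("  accessibility (beds/person): mean %.6g, range [%.6g, %.6g]\n",
              mean(x$population$accessibility),
              min(x$population$accessibility),
              max(x$population$accessibility)))
  capped <- sum(x$catchments$capped)
  cat(sprintf("  capped catchments: %d of %d\n", capped,
              nrow(x$catchments)))
  invisible(x)
}

#' Run the enhanced variable 2SFCA method
#'
#' Executes the four steps in order: (1) grow each facility catchment
#' until its facility-to-population ratio falls to `fprt1`; (2) grow
#' each population catchment until the summed saved ratios reach
#' `fprt2`; (3) compute each facility's discounted ratio
#' \eqn{D_i = S_i / \sum P_j \omega_{ji}} over the pairs admitted by the
#' containment constraint; (4) sum \eqn{A_j = \sum D_i \omega_{ij}} over
#' the same constraint.  Under the default `"mutual"` constraint the
#' same pair set backs both equations.
#'
#' @param facilities,populations Site tables ([read_sites()]).
#' @param od An [od_matrix()].
#' @param cfg An [ev_config()].
#' @return An `accessibility_result`: per-facility discounted ratios,
#'   per-population accessibility scores (beds/person), the catchment
#'   table, the configuration, and counts of reachable pairs rejected by
#'   each side of the containment test.
#' @export
run_ev2sfca <- function(facilities, populations, od, cfg = ev_config()) {
  stopifnot(inherits(cfg, "ev_config"))
  facilities <- facilities[order(facilities$id), , drop = FALSE]
  populations <- populations[order(populations$id), , drop = FALSE]
  ct <- compute_all_catchments(facilities, populations, od, cfg,
                               method = "ev2sfca")
  pairs <- eligible_pairs(od, ct, mode = cfg$constraint_mode)
  wfun <- make_decay(cfg$decay)
  scores <- score_pairs(facilities, populations, pairs, pairs, wfun,
                        cfg$weight_param)
  new_accessibility_result("ev2sfca", facilities, populations, ct,
                           scores, cfg, attr(pairs, "rejected"))
}

#' Run the variable 2SFCA baseline
#'
#' Supply catchments grow until the base population `BP` is reached
#' (capacity plays no role); demand catchments grow until the summed
#' supply ratios reach `ppr`.  The scoring steps use the one-sided
#' containment of the classic method: the discounted-ratio equation
#' admits every reachable population inside the facility catchment
#' (`d <= C_i`), and the accessibility equation admits every reachable
#' facility inside the population catchment (`d <= C_j`), with no
#' requirement that the other catchment contain the site.
#'
#' @param facilities,populations Site tables.
#' @param od An [od_matrix()].
#' @param cfg A [v2_config()].
#' @return An `accessibility_result` (see [run_ev2sfca()]).
#' @export
run_v2sfca <- function(facilities, populations, od, cfg = v2_config()) {
  stopifnot(inherits(cfg, "v2_config"))
  facilities <- facilities[order(facilities$id), , drop = FALSE]
  populations <- populations[order(populations$id), , drop = FALSE]
  ct <- compute_all_catchments(facilities, populations, od, cfg,
                               method = "v2sfca")
  pairs1 <- eligible_pairs(od, ct, mode = "facility_side")
  pairs2 <- eligible_pairs(od, ct, mode = "population_side")
  wfun <- make_decay(cfg$decay)
  scores <- score_pairs(facilities, populations, pairs1, pairs2, wfun,
                        weight_param = "own_catchment")
  new_accessibility_result("v2sfca", facilities, populations, ct,
                           scores, cfg, attr(pairs1, "rejected"))
}

#' Supply-conservation diagnostic
#'
#' Ratio of the population-weighted accessibility total to the capacity
#' of the served facilities, \eqn{\sum_j P_j A_j / \sum_{i: served}
#' S_i}, where a facility is served when it has at least one eligible
#' pair.  When the same weight value backs a pair in both scoring
#' equations (pair-symmetric weights: `weight_param = "symmetric_min"`,
#' or `decay = "none"` under the mutual constraint) the double sum
#' telescopes and the ratio is exactly 1; with own-catchment weights and
#' unequal catchments it generally is not, and is reported as a
#' diagnostic only.
#'
#' @param result An `accessibility_result`.
#' @param facilities,populations The site tables of the run.
#' @return A list with `ratio` (`NA` when no facility is served),
#'   `served_count`, `served_supply` and `weighted_demand`.
#' @export
conservation_check <- function(result, facilities, populations) {
  stopifnot(inherits(result, "accessibility_result"))
  P <- populations$population[match(result$population$population_id,
                                    populations$id)]
  S <- facilities$capacity[match(result$facility$facility_id,
                                 facilities$id)]
  served <- result$facility$n_eligible > 0
  demand <- sum(P * result$population$accessibility)
  supply <- sum(S[served])
  list(
    ratio = if (any(served)) demand / supply else NA_real_,
    served_count = sum(served),
    served_supply = supply,
    weighted_demand = demand
  )
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

summary_row <- function(x) {
  c(min = min(x), max = max(x), mean = mean(x), sd = pop_sd(x))
}

#' Compare two accessibility results
#'
#' Per-site differences (result 1 minus result 2) of catchment sizes,
#' discounted ratios and accessibility scores, plus summary statistics
#' (min, max, mean, and population standard deviation) of each quantity
#' under both runs.
#'
#' @param r1,r2 `accessibility_result` objects over the same sites.
#' @return A list with `facility` and `population` difference tables and
#'   a long `summary` table.
#' @export
compare_results <- function(r1, r2) {
  stopifnot(inherits(r1, "accessibility_result"),
            inherits(r2, "accessibility_result"))
  if (!identical(r1$facility$facility_id, r2$facility$facility_id) ||
      !identical(r1$population$population_id, r2$population$population_id))
    stop("results cover different site sets", call. = FALSE)
  fc1 <- r1$catchments[r1$catchments$type == "facility", ]
  fc2 <- r2$catchments[r2$catchments$type == "facility", ]
  pc1 <- r1$catchments[r1$catchments$type == "population", ]
  pc2 <- r2$catchments[r2$catchments$type == "population", ]
  facility <- data.frame(
    facility_id = r1$facility$facility_id,
    catchment_1 = fc1$catchment_min, catchment_2 = fc2$catchment_min,
    catchment_diff = fc1$catchment_min - fc2$catchment_min,
    discounted_fpr_1 = r1$facility$discounted_fpr,
    discounted_fpr_2 = r2$facility$discounted_fpr,
    discounted_fpr_diff = r1$facility$discounted_fpr -
      r2$facility$discounted_fpr,
    stringsAsFactors = FALSE
  )
  population <- data.frame(
    population_id = r1$population$population_id,
    catchment_1 = pc1$catchment_min, catchment_2 = pc2$catchment_min,
    catchment_diff = pc1$catchment_min - pc2$catchment_min,
    accessibility_1 = r1$population$accessibility,
    accessibility_2 = r2$population$accessibility,
    accessibility_diff = r1$population$accessibility -
      r2$population$accessibility,
    stringsAsFactors = FALSE
  )
  quantities <- list(
    c("facility", "catchment_min", "1"), c("facility", "catchment_min", "2"),
    c("population", "catchment_min", "1"),
    c("population", "catchment_min", "2"),
    c("facility", "discounted_fpr", "1"), c("facility", "discounted_fpr", "2"),
    c("population", "accessibility", "1"),
    c("population", "accessibility", "2")
  )
  values <- list(
    fc1$catchment_min, fc2$catchment_min,
    pc1$catchment_min, pc2$catchment_min,
    r1$facility$discounted_fpr, r2$facility$discounted_fpr,
    r1$population$accessibility, r2$population$accessibility
  )
  summary <- do.call(rbind, lapply(seq_along(quantities), function(k) {
    q <- quantities[[k]]
    stats <- summary_row(values[[k]])
    data.frame(object_type = q[1], quantity = q[2], result = q[3],
               min = stats["min"], max = stats["max"],
               mean = stats["mean"], sd = stats["sd"],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(facility = facility, population = population, summary = summary)
}

#' Threshold sensitivity sweep
#'
#' Re-runs the EV2SFCA method over a grid of facility-side (`fprt1`)
#' and/or population-side (`fprt2`) thresholds and summarises each run.
#' Smaller `fprt1` values force facility catchments to grow further
#' (lower ratios take longer to reach) and depress accessibility;
#' larger `fprt2` values grow population catchments.
#'
#' @param facilities,populations Site tables.
#' @param od An [od_matrix()].
#' @param cfg Base [ev_config()]; each grid point overrides its
#'   threshold(s).
#' @param fprt1,fprt2 Numeric vectors of threshold values (default: the
#'   base configuration's single value).
#' @return A `data.frame`, one row per grid point, with the thresholds
#'   and summary statistics of catchments and accessibility.
#' @export
sensitivity_sweep <- function(facilities, populations, od,
                              cfg = ev_config(),
                              fprt1 = NULL, fprt2 = NULL) {
  stopifnot(inherits(cfg, "ev_config"))
  grid <- expand.grid(fprt1 = fprt1 %||% cfg$fprt1,
                      fprt2 = fprt2 %||% cfg$fprt2)
  if (nrow(grid) == 0L)
    stop("threshold grid is empty", call. = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    cfg_k <- cfg
    cfg_k$fprt1 <- grid$fprt1[k]
    cfg_k$fprt2 <- grid$fprt2[k]
    res <- run_ev2sfca(facilities, populations, od, cfg_k)
    fc <- res$catchments[res$catchments$type == "facility", ]
    pc <- res$catchments[res$catchments$type == "population", ]
    data.frame(
      fprt1 = grid$fprt1[k], fprt2 = grid$fprt2[k],
      mean_facility_catchment = mean(fc$catchment_min),
      max_facility_catchment = if (nrow(fc)) max(fc$catchment_min) else NA,
      mean_population_catchment = mean(pc$catchment_min),
      mean_accessibility = mean(res$population$accessibility),
      max_accessibility = if (nrow(pc))
        max(res$population$accessibility) else NA,
      n_capped = sum(res$catchments$capped),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
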