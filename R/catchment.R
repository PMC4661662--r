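time_grid <- function(cfg) seq(cfg$t0, cfg$t_max, by = cfg$dt)

met_le <- function(value, threshold, strict) {
  if (strict) value < threshold else value <= threshold
}

met_ge <- function(value, threshold, strict) {
  if (strict) value > threshold else value >= threshold
}

od_row <- function(od, facility_id, population_ids) {
  if (!facility_id %in% rownames(od$times))
    stop("facility id not in OD matrix: ", facility_id, call. = FALSE)
  missing_p <- setdiff(population_ids, colnames(od$times))
  if (length(missing_p))
    stop("population id(s) not in OD matrix: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  od$times[facility_id, population_ids]
}

od_col <- function(od, population_id, facility_ids) {
  if (!population_id %in% colnames(od$times))
    stop("population id not in OD matrix: ", population_id, call. = FALSE)
  missing_f <- setdiff(facility_ids, rownames(od$times))
  if (length(missing_f))
    stop("facility id(s) not in OD matrix: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  od$times[facility_ids, population_id]
}

#' Facility-to-population ratio within a travel-time window
#'
#' Capacity of the facility divided by the total (unweighted) population
#' whose travel time to it is at most `t`.  When no population is
#' reachable the ratio is undefined and [SENTINEL_INF] is returned.
#'
#' @param facility One-row facility table (`id`, `capacity`).
#' @param populations Population site table.
#' @param od An [od_matrix()].
#' @param t Travel-time window in minutes.
#' @return Beds per person, or `Inf` when the window is empty.
#' @export
facility_fpr <- function(facility, populations, od, t) {
  d <- od_row(od, facility$id[1L], populations$id)
  psum <- sum(populations$population[d <= t])
  if (psum > 0) facility$capacity[1L] / psum else SENTINEL_INF
}

#' Facility catchment size (EV2SFCA step 1)
#'
#' Grows the facility's travel-time window along the grid
#' `t0, t0 + dt, ...` until the facility-to-population ratio falls to
#' the threshold `fprt1`; a dense surrounding population (small ratio)
#' stops the search early, a large capacity keeps it growing.  If the
#' threshold is never met by `t_max` the catchment is capped there and
#' flagged.
#'
#' @inheritParams facility_fpr
#' @param cfg An [ev_config()].
#' @return A list with `catchment` (minutes), `fpr` (the ratio at the
#'   stopping time; `Inf` when no population is reachable at the cap)
#'   and `capped`.
#' @export
facility_catchment <- function(facility, populations, od, cfg) {
  for (t in time_grid(cfg)) {
    fpr <- facility_fpr(facility, populations, od, t)
    if (met_le(fpr, cfg$fprt1, cfg$strict_thresholds))
      return(list(catchment = t, fpr = fpr, capped = FALSE))
  }
  list(catchment = cfg$t_max,
       fpr = facility_fpr(facility, populations, od, cfg$t_max),
       capped = TRUE)
}

#' Population catchment size (EV2SFCA step 2)
#'
#' Grows the population's travel-time window along the grid until the
#' sum of the step-1 facility ratios reachable within the window reaches
#' the target `fprt2`.  A facility whose saved ratio is the empty-window
#' sentinel `Inf` satisfies the target the moment it enters the window
#' (degenerate; a warning is emitted upstream when such facilities are
#' produced).  Capped at `t_max` when the target is never reached.
#'
#' @param population One-row population table (`id`).
#' @param facility_fprs `data.frame` with columns `facility_id`, `fpr`
#'   (step-1 ratios for every facility).
#' @param od An [od_matrix()].
#' @param cfg An [ev_config()].
#' @return A list with `catchment` (minutes) and `capped`.
#' @export
population_catchment <- function(population, facility_fprs, od, cfg) {
  d <- od_col(od, population$id[1L], facility_fprs$facility_id)
  fpr <- facility_fprs$fpr
  for (t in time_grid(cfg)) {
    within <- d <= t
    total <- if (any(within & is.infinite(fpr))) Inf else sum(fpr[within])
    if (met_ge(total, cfg$fprt2, cfg$strict_thresholds))
      return(list(catchment = t, capped = FALSE))
  }
  list(catchment = cfg$t_max, capped = TRUE)
}

#' V2SFCA supply catchment
#'
#' Baseline rule: the facility window grows until the unweighted
#' reachable population reaches the base population `BP`, independent of
#' the facility's capacity.  The supply ratio `R_i` is capacity over the
#' reachable population at the stopping time.
#'
#' @inheritParams facility_fpr
#' @param cfg A [v2_config()].
#' @return A list with `catchment`, `ratio` and `capped`.
#' @export
v2sfca_supply_catchment <- function(facility, populations, od, cfg) {
  d <- od_row(od, facility$id[1L], populations$id)
  S <- facility$capacity[1L]
  for (t in time_grid(cfg)) {
    psum <- sum(populations$population[d <= t])
    if (met_ge(psum, cfg$base_population, cfg$strict_thresholds))
      return(list(catchment = t, ratio = S / psum, capped = FALSE))
  }
  psum <- sum(populations$population[d <= cfg$t_max])
  list(catchment = cfg$t_max,
       ratio = if (psum > 0) S / psum else SENTINEL_INF,
       capped = TRUE)
}

#' V2SFCA demand catchment
#'
#' The population window grows until the summed supply ratios of
#' reachable facilities meet the provider-to-population target `ppr`.
#'
#' @param population One-row population table (`id`).
#' @param supply_ratios `data.frame` with columns `facility_id`,
#'   `ratio`.
#' @param od An [od_matrix()].
#' @param cfg A [v2_config()].
#' @return A list with `catchment` and `capped`.
#' @export
v2sfca_demand_catchment <- function(population, supply_ratios, od, cfg) {
  d <- od_col(od, population$id[1L], supply_ratios$facility_id)
  r <- supply_ratios$ratio
  for (t in time_grid(cfg)) {
    within <- d <= t
    total <- if (any(within & is.infinite(r))) Inf else sum(r[within])
    if (met_ge(total, cfg$ppr, cfg$strict_thresholds))
      return(list(catchment = t, capped = FALSE))
  }
  list(catchment = cfg$t_max, capped = TRUE)
}

#' Compute all facility and population catchments
#'
#' Batch form of the step-1/step-2 catchment searches for either method.
#' Sites are processed in lexicographic id order and each site's
#' catchment is independent of the others (facility searches depend only
#' on the populations; population searches depend on the saved step-1
#' ratios), so the batch result equals the per-site operations applied
#' one at a time.
#'
#' @param facilities,populations Site tables ([read_sites()]).
#' @param od An [od_matrix()] covering exactly the sites.
#' @param cfg An [ev_config()] (`method = "ev2sfca"`) or [v2_config()]
#'   (`method = "v2sfca"`).
#' @param method `"ev2sfca"` or `"v2sfca"`.
#' @return A `catchment_table`: a `data.frame` with one row per site and
#'   columns `id`, `type` (`"facility"`/`"population"`), `catchment_min`,
#'   `fpr` (facility rows: the saved step-1 ratio, `Inf` when the window
#'   is empty at the cap; population rows: `NA`) and `capped`.
#' @export
compute_all_catchments <- function(facilities, populations, od, cfg,
                                   method = c("ev2sfca", "v2sfca")) {
  method <- match.arg(method)
  if (method == "ev2sfca" && !inherits(cfg, "ev_config"))
    stop("method 'ev2sfca' needs an ev_config", call. = FALSE)
  if (method == "v2sfca" && !inherits(cfg, "v2_config"))
    stop("method 'v2sfca' needs a v2_config", call. = FALSE)
  facilities <- facilities[order(facilities$id), , drop = FALSE]
  populations <- populations[order(populations$id), , drop = FALSE]
  check_od_ids(od, facilities, populations)
  M <- od$times[facilities$id, populations$id, drop = FALSE]
  grid <- time_grid(cfg)
  nf <- nrow(facilities)
  np <- nrow(populations)
  S <- facilities$capacity
  P <- populations$population
  strict <- cfg$strict_thresholds

  f_catch <- rep(cfg$t_max, nf)
  f_fpr <- rep(NA_real_, nf)
  f_done <- logical(nf)
  p_catch <- rep(cfg$t_max, np)
  p_done <- logical(np)

  # facility side
  for (t in grid) {
    if (all(f_done)) break
    reach <- M <= t                      # Inf entries are FALSE
    psum <- as.vector(reach %*% P)
    if (method == "ev2sfca") {
      fpr <- ifelse(psum > 0, S / psum, SENTINEL_INF)
      met <- if (strict) fpr < cfg$fprt1 else fpr <= cfg$fprt1
    } else {
      met <- if (strict) psum > cfg$base_population else
        psum >= cfg$base_population
      fpr <- ifelse(psum > 0, S / psum, SENTINEL_INF)
    }
    newly <- met & !f_done
    f_catch[newly] <- t
    f_fpr[newly] <- fpr[newly]
    f_done <- f_done | met
  }
  f_capped <- !f_done
  if (any(f_capped)) {
    reach <- M <= cfg$t_max
    psum <- as.vector(reach %*% P)
    f_fpr[f_capped] <- ifelse(psum[f_capped] > 0,
                              S[f_capped] / psum[f_capped], SENTINEL_INF)
  }
  if (any(is.infinite(f_fpr)))
    warning(sum(is.infinite(f_fpr)),
            " facility catchment(s) contain no population; ",
            "their saved ratio is the Inf sentinel", call. = FALSE)

  # population side: cumulative sum of saved facility ratios
  fpr_finite <- ifelse(is.finite(f_fpr), f_fpr, 0)
  fpr_inf <- is.infinite(f_fpr)
  thr <- if (method == "ev2sfca") cfg$fprt2 else cfg$ppr
  for (t in grid) {
    if (all(p_done)) break
    reach <- M <= t
    total <- as.vector(crossprod(reach, fpr_finite))
    has_inf <- as.vector(crossprod(reach, as.numeric(fpr_inf))) > 0
    total[has_inf] <- Inf
    met <- if (strict) total > thr else total >= thr
    newly <- met & !p_done
    p_catch[newly] <- t
    p_done <- p_done | met
  }
  p_capped <- !p_done

  out <- data.frame(
    id = c(facilities$id, populations$id),
    type = rep(c("facility", "population"), c(nf, np)),
    catchment_min = c(f_catch, p_catch),
    fpr = c(f_fpr, rep(NA_real_, np)),
    capped = c(f_capped, p_capped),
    stringsAsFactors = FALSE
  )
  class(out) <- c("catchment_table", "data.frame")
  out
}

check_od_ids <- function(od, facilities, populations) {
  miss_f <- setdiff(facilities$id, rownames(od$times))
  extra_f <- setdiff(rownames(od$times), facilities$id)
  miss_p <- setdiff(populations$id, colnames(od$times))
  extra_p <- setdiff(colnames(od$times), populations$id)
  problems <- c(
    if (length(miss_f)) paste("facility id(s) missing from OD:",
                              paste(miss_f, collapse = ", ")),
    if (length(extra_f)) paste("OD facility id(s) not in site list:",
                               paste(extra_f, collapse = ", ")),
    if (length(miss_p)) paste("population id(s) missing from OD:",
                              paste(miss_p, collapse = ", ")),
    if (length(extra_p)) paste("OD population id(s) not in site list:",
                               paste(extra_p, collapse = ", "))
  )
  if (length(problems))
    stop("id mismatch between OD matrix and site lists: ",
         paste(problems, collapse = "; "), call. = FALSE)
  invisible(TRUE)
}

#' Write a catchment table to CSV
#'
#' Columns `id,type,catchment_min,fpr,capped`; `fpr` is empty for
#' population rows and `Inf` for empty-window facilities.
#'
#' @param catchments A `catchment_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_catchments <- function(catchments, path) {
  df <- as.data.frame(catchments)
  df$fpr <- ifelse(is.na(df$fpr), "",
                   formatC(df$fpr, digits = 10, format = "g"))
  df$capped <- ifelse(df$capped, "true", "false")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
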