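#' Read facility or population sites
#'
#' Sites are points in a projected planar coordinate system (meters).
#' CSV input needs columns `id,x,y` plus `capacity` (facilities, beds,
#' must be positive) or `population` (non-negative count).  GeoJSON
#' Point FeatureCollections with the same property names are accepted;
#' they parse to the identical table.  Row order is preserved.
#'
#' @param path CSV or GeoJSON file.
#' @param kind `"facility"` or `"population"`.
#' @return A `data.frame` with columns `id` (character), `x`, `y`, and
#'   `capacity` or `population`.
#' @export
read_sites <- function(path, kind = c("facility", "population")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  value_col <- if (kind == "facility") "capacity" else "population"
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("geojson", "json")) {
    read_sites_geojson(path, value_col)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("id", "x", "y", value_col)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[required]
  df$id <- as.character(df$id)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup))
    stop("duplicate id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  for (col in c("x", "y", value_col)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric `", col, "` at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    df[[col]] <- v
  }
  if (kind == "facility") {
    bad <- which(df$capacity <= 0)
    if (length(bad))
      stop("non-positive capacity at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  } else {
    bad <- which(df$population < 0)
    if (length(bad))
      stop("negative population at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

read_sites_geojson <- function(path, value_col) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("GeoJSON input must be a FeatureCollection", call. = FALSE)
  rows <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Point"))
      stop("GeoJSON features must be Points", call. = FALSE)
    coords <- f$geometry$coordinates
    props <- f$properties
    out <- data.frame(
      id = as.character(props$id %||% NA_character_),
      x = as.numeric(coords[[1]]),
      y = as.numeric(coords[[2]]),
      stringsAsFactors = FALSE
    )
    out[[value_col]] <- if (is.null(props[[value_col]])) NA_real_ else
      as.numeric(props[[value_col]])
    out
  })
  do.call(rbind, rows)
}

#' Write sites to CSV
#'
#' @param sites A site table as returned by [read_sites()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Origin-destination travel-time matrix
#'
#' Holds one undirected travel time in minutes per facility-population
#' pair.  Pairs that are absent, disconnected, or beyond the travel cap
#' `t_max` are unreachable and stored as `Inf`; they are excluded from
#' every reachable-set sum downstream.  Internally the object is a dense
#' facility-by-population matrix with ids sorted lexicographically so
#' that processing order is deterministic.
#'
#' @param pairs Long-format `data.frame` with columns `facility_id`,
#'   `population_id`, `minutes` (each pair at most once).
#' @param facility_ids,population_ids Optional full id vectors; ids in
#'   `pairs` must be drawn from them.  Defaults to the ids present in
#'   `pairs`.
#' @param t_max Travel cap in minutes; entries above it become
#'   unreachable.
#' @return An object of class `od_matrix`.
#' @export
od_matrix <- function(pairs, facility_ids = NULL, population_ids = NULL,
                      t_max = 120) {
  required <- c("facility_id", "population_id", "minutes")
  missing_cols <- setdiff(required, names(pairs))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  fid <- as.character(pairs$facility_id)
  pid <- as.character(pairs$population_id)
  minutes <- suppressWarnings(as.numeric(pairs$minutes))
  bad <- which(is.na(minutes) | minutes < 0)
  if (length(bad))
    stop("negative or non-numeric minutes at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  key <- paste(fid, pid, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate facility/population pair(s): ",
         paste(unique(sub("\r", " / ", key[duplicated(key)])),
               collapse = ", "), call. = FALSE)
  facility_ids <- sort(as.character(facility_ids %||% unique(fid)))
  population_ids <- sort(as.character(population_ids %||% unique(pid)))
  unknown_f <- setdiff(fid, facility_ids)
  if (length(unknown_f))
    stop("unknown facility id(s): ",
         paste(unique(unknown_f), collapse = ", "), call. = FALSE)
  unknown_p <- setdiff(pid, population_ids)
  if (length(unknown_p))
    stop("unknown population id(s): ",
         paste(unique(unknown_p), collapse = ", "), call. = FALSE)
  times <- matrix(Inf, nrow = length(facility_ids),
                  ncol = length(population_ids),
                  dimnames = list(facility_ids, population_ids))
  times[cbind(match(fid, facility_ids), match(pid, population_ids))] <- minutes
  times[times > t_max] <- Inf
  new_od_matrix(times, t_max)
}

new_od_matrix <- function(times, t_max) {
  structure(list(times = times, t_max = t_max), class = "od_matrix")
}

#' Build an od_matrix from a dense travel-time matrix
#'
#' @param times Numeric matrix, facilities in rows and populations in
#'   columns, with `dimnames` giving the ids; `Inf` marks unreachable
#'   pairs.
#' @param t_max Travel cap in minutes.
#' @return An `od_matrix`.
#' @export
as_od_matrix <- function(times, t_max = 120) {
  if ((nrow(times) > 0 && is.null(rownames(times))) ||
      (ncol(times) > 0 && is.null(colnames(times))))
    stop("`times` must have facility row names and population column names",
         call. = FALSE)
  if (any(times < 0, na.rm = TRUE))
    stop("travel times must be non-negative", call. = FALSE)
  ro <- if (nrow(times)) order(rownames(times)) else integer(0)
  co <- if (ncol(times)) order(colnames(times)) else integer(0)
  times <- times[ro, co, drop = FALSE]
  dimnames(times) <- list(rownames(times) %||% character(0),
                          colnames(times) %||% character(0))
  times[is.na(times) | times > t_max] <- Inf
  new_od_matrix(times, t_max)
}

#' @export
print.od_matrix <- function(x, ...) {
  finite <- sum(is.finite(x$times))
  cat(sprintf(
    "<od_matrix> %d facilities x %d populations, %d reachable pair(s), t_max = %g min\n",
    nrow(x$times), ncol(x$times), finite, x$t_max))
  invisible(x)
}

#' @export
dim.od_matrix <- function(x) dim(x$times)

#' Travel times of an od_matrix
#'
#' @param od An `od_matrix`.
#' @return The dense minutes matrix (`Inf` = unreachable), facilities in
#'   rows, populations in columns, both sorted by id.
#' @export
od_times <- function(od) {
  stopifnot(inherits(od, "od_matrix"))
  od$times
}

#' Read / write an origin-destination matrix
#'
#' Long-format CSV with header `facility_id,population_id,minutes`.
#' Only reachable pairs are stored; any pair absent from the file is
#' unreachable.  Minutes are written with 17 significant digits so that
#' a write-then-read round trip reproduces the binary values exactly.
#'
#' @param path CSV path.
#' @param t_max Travel cap in minutes; entries above it are stored as
#'   unreachable.
#' @param facilities,populations Optional site tables; when given, every
#'   id in the file must occur in them (unknown ids are an error) and
#'   the matrix covers all their sites.
#' @return `read_od()`: an `od_matrix`.  `write_od()`: `path`,
#'   invisibly.
#' @export
read_od <- function(path, t_max = 120, facilities = NULL,
                    populations = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  od_matrix(df,
            facility_ids = if (!is.null(facilities)) facilities$id,
            population_ids = if (!is.null(populations)) populations$id,
            t_max = t_max)
}

#' @param od An `od_matrix`.
#' @rdname read_od
#' @export
write_od <- function(od, path) {
  stopifnot(inherits(od, "od_matrix"))
  m <- od$times
  idx <- which(is.finite(m), arr.ind = TRUE)
  df <- data.frame(
    facility_id = rownames(m)[idx[, 1L]],
    population_id = colnames(m)[idx[, 2L]],
    minutes = formatC(m[idx], digits = 17, format = "g"),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$facility_id, df$population_id), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
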