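#' Road speeds by class, km/h
#'
#' Standard speeds used to convert edge length to travel time:
#' expressways 60 km/h, main roads 50 km/h, secondary roads 40 km/h,
#' other roads 30 km/h.
#' @format Named numeric vector.
#' @export
ROAD_SPEEDS_KMH <- c(expressway = 60, main = 50, secondary = 40, other = 30)

#' Classed road network
#'
#' An undirected planar road graph.  `nodes` needs columns `id,x,y`
#' (projected meters); `edges` needs `from,to,length_m,class` with
#' positive lengths, endpoints present in `nodes`, and classes drawn
#' from `names(ROAD_SPEEDS_KMH)`.
#'
#' @param nodes,edges Data frames as described.
#' @return An object of class `road_network`.
#' @export
road_network <- function(nodes, edges) {
  req_n <- c("id", "x", "y")
  req_e <- c("from", "to", "length_m", "class")
  if (length(setdiff(req_n, names(nodes))))
    stop("nodes need columns ", paste(req_n, collapse = ","), call. = FALSE)
  if (length(setdiff(req_e, names(edges))))
    stop("edges need columns ", paste(req_e, collapse = ","), call. = FALSE)
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s)", call. = FALSE)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  missing_ep <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing_ep))
    stop("edge endpoint(s) not in nodes: ",
         paste(unique(missing_ep), collapse = ", "), call. = FALSE)
  if (any(!is.finite(edges$length_m) | edges$length_m <= 0))
    stop("edge lengths must be positive", call. = FALSE)
  bad_class <- setdiff(unique(edges$class), names(ROAD_SPEEDS_KMH))
  if (length(bad_class))
    stop("unknown road class(es): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a road network from node and edge CSV files
#'
#' @param nodes_path CSV with header `id,x,y`.
#' @param edges_path CSV with header `from,to,length_m,class`.
#' @return A [road_network()].
#' @export
read_network <- function(nodes_path, edges_path) {
  for (p in c(nodes_path, edges_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  road_network(utils::read.csv(nodes_path, stringsAsFactors = FALSE),
               utils::read.csv(edges_path, stringsAsFactors = FALSE))
}

#' Travel time along a road edge
#'
#' Converts edge length to minutes at the standard class speed:
#' `minutes = length_m / 1000 / speed_kmh * 60`.  A 1 km main-road
#' (50 km/h) edge takes 1.2 minutes.
#'
#' @param length_m Edge length in meters, `> 0`.
#' @param road_class One of `names(ROAD_SPEEDS_KMH)`; recycled against
#'   `length_m`.
#' @return Minutes.
#' @export
edge_time <- function(length_m, road_class) {
  if (any(!is.finite(length_m) | length_m <= 0))
    stop("edge length must be positive", call. = FALSE)
  speed <- ROAD_SPEEDS_KMH[road_class]
  if (anyNA(speed))
    stop("unknown road class(es): ",
         paste(unique(road_class[is.na(speed)]), collapse = ", "),
         call. = FALSE)
  unname(length_m / 1000 / speed * 60)
}

snap_to_nodes <- function(sites, nodes) {
  vapply(seq_len(nrow(sites)), function(k) {
    which.min((nodes$x - sites$x[k])^2 + (nodes$y - sites$y[k])^2)
  }, integer(1))
}

#' Travel-time matrix from a road network
#'
#' Snaps every facility and population site to its nearest network node
#' (Euclidean distance, zero access time) and computes shortest-path
#' travel times between the snapped nodes with Dijkstra's algorithm,
#' edge weights being the class-speed travel times of [edge_time()].
#' Pairs that are disconnected or slower than `t_max` are unreachable.
#'
#' @param network A [road_network()].
#' @param facilities,populations Site tables ([read_sites()]).
#' @param t_max Travel cap in minutes.
#' @return An [od_matrix()].
#' @export
od_from_network <- function(network, facilities, populations,
                            t_max = 120) {
  stopifnot(inherits(network, "road_network"))
  if (nrow(network$nodes) == 0L || nrow(network$edges) == 0L)
    stop("road network is empty", call. = FALSE)
  nodes <- network$nodes
  bbox <- c(range(nodes$x), range(nodes$y))
  sites <- rbind(facilities[c("id", "x", "y")],
                 populations[c("id", "x", "y")])
  outside <- sites$x < bbox[1] | sites$x > bbox[2] |
    sites$y < bbox[3] | sites$y > bbox[4]
  if (any(outside))
    warning("site(s) outside the network bounding box: ",
            paste(sites$id[outside], collapse = ", "), call. = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = network$edges$from, to = network$edges$to,
               weight = edge_time(network$edges$length_m,
                                  network$edges$class)),
    directed = FALSE, vertices = nodes$id)
  f_node <- snap_to_nodes(facilities, nodes)
  p_node <- snap_to_nodes(populations, nodes)
  uf <- unique(f_node)
  up <- unique(p_node)
  dm <- igraph::distances(g, v = nodes$id[uf], to = nodes$id[up],
                          algorithm = "dijkstra")
  dmat <- dm[match(f_node, uf), match(p_node, up), drop = FALSE]
  dimnames(dmat) <- list(facilities$id, populations$id)
  as_od_matrix(dmat, t_max = t_max)
}
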