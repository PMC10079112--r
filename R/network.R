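#' Immune signaling networks
#'
#' An `immune_network` is a signed, directed protein-interaction graph with
#' three node roles: one *detector* (parasite sensing), any number of
#' *signaling* proteins (relays), and one *effector* (parasite killing).
#' Edge weights lie in `[-1, 1]`: a positive weight is an upregulatory
#' coefficient from source to target, a negative weight a downregulatory
#' one (its magnitude enters the inhibition sum of the dynamics).  A stored
#' weight of exactly zero means "no edge".  The detector may never connect
#' directly to the effector.  Networks optionally carry a pleiotropy record
#' (one focal signaling protein whose constraint mode and locked edges are
#' fixed across evolutionary time) and a `lineage_id` naming their
#' generation-0 ancestor.
#'
#' @param ids Integer node identifiers (stable labels inherited by
#'   descendants; duplicated proteins receive fresh ids).
#' @param roles Character vector, one of `"detector"`, `"signaling"`,
#'   `"effector"` per node.
#' @param W Square numeric weight matrix, `W[s, t]` the signed weight of
#'   edge `s -> t` (0 = absent), rows/columns in the order of `ids`.
#' @param locked Logical matrix of the same shape flagging pleiotropically
#'   locked edges, or `NULL` for none.
#' @param pleio `NULL`, or a list with elements `node` (the pleiotropic
#'   protein's id) and `mode` (one of `"fixed-random"`, `"fixed-up"`,
#'   `"fixed-down"`, `"slow"`).
#' @param lineage_id Integer identifier of the generation-0 ancestor.
#'
#' @return An object of class `immune_network`.
#' @seealso [init_random_network()], [apply_pleiotropy()],
#'   [network_to_json()]
#' @export
immune_network <- function(ids, roles, W, locked = NULL, pleio = NULL,
                           lineage_id = 1L) {
  ids <- as.integer(ids)
  n <- length(ids)
  W <- as.matrix(W)
  if (is.null(locked)) locked <- matrix(FALSE, n, n)
  net <- structure(
    list(ids = ids, roles = roles, W = W, locked = locked,
         pleio = pleio, lineage_id = as.integer(lineage_id),
         gid = new_gid()),
    class = "immune_network")
  validate_network(net)
  net
}

#' @export
print.immune_network <- function(x, ...) {
  cat(sprintf(
    "<immune_network> %d proteins (%d signaling), %d edges, lineage %d\n",
    length(x$ids), sum(x$roles == "signaling"), sum(x$W != 0),
    x$lineage_id))
  if (!is.null(x$pleio))
    cat(sprintf("  pleiotropy: node %d, mode '%s', %d locked edge(s)\n",
                x$pleio$node, x$pleio$mode, sum(x$locked)))
  invisible(x)
}

validate_network <- function(net) {
  n <- length(net$ids)
  stopifnot(length(net$roles) == n, all(dim(net$W) == c(n, n)),
            all(dim(net$locked) == c(n, n)))
  if (anyDuplicated(net$ids)) stop("duplicated node ids")
  if (sum(net$roles == "detector") != 1L)
    stop("network must have exactly one detector")
  if (sum(net$roles == "effector") != 1L)
    stop("network must have exactly one effector")
  d <- which(net$roles == "detector"); e <- which(net$roles == "effector")
  if (net$W[d, e] != 0)
    stop("the detector may not connect directly to the effector")
  if (any(abs(net$W) > 1)) stop("edge weights must lie in [-1, 1]")
  if (any(net$locked & net$W == 0))
    stop("locked edges must exist")
  if (!is.null(net$pleio)) {
    if (!net$pleio$node %in% net$ids[net$roles == "signaling"])
      stop("pleiotropic node must be a signaling protein")
    if (any(net$locked)) {
      p <- match(net$pleio$node, net$ids)
      inc <- which(net$locked, arr.ind = TRUE)
      if (!all(inc[, 1] == p | inc[, 2] == p))
        stop("locked edges must be incident to the pleiotropic node")
    }
  }
  invisible(net)
}

detector_id <- function(net) net$ids[net$roles == "detector"]
effector_id <- function(net) net$ids[net$roles == "effector"]

#' Identifiers of a network's signaling proteins
#' @param net An [immune_network()].
#' @return Integer vector of node ids with role `"signaling"`.
#' @export
signaling_ids <- function(net) net$ids[net$roles == "signaling"]

node_index <- function(net, id) match(id, net$ids)

#' Generate a random initial immune network
#'
#' Builds the ancestral network used at generation 0: one detector,
#' `n_signaling` signaling proteins, one effector.  Every ordered node pair
#' (self-edges included) receives an edge independently with probability
#' 1/2, except the forbidden detector-to-effector pair; each realized edge
#' gets a weight drawn uniformly on `[-1, 1]`.
#'
#' @param n_signaling Number of signaling proteins (default 3).
#' @param lineage_id Lineage label recorded on the network.
#' @return An [immune_network()].
#' @examples
#' set.seed(1)
#' net <- init_random_network()
#' length(net$ids)  # 5 proteins
#' @export
init_random_network <- function(n_signaling = 3, lineage_id = 1L) {
  stopifnot(n_signaling >= 1)
  n <- n_signaling + 2L
  roles <- c("detector", rep("signaling", n_signaling), "effector")
  present <- matrix(runif(n * n) < 0.5, n, n)
  weights <- matrix(runif(n * n, -1, 1), n, n)
  present[1, n] <- FALSE                       # no detector -> effector
  W <- ifelse(present, weights, 0)
  immune_network(seq_len(n), roles, W, lineage_id = lineage_id)
}

#' Fraction of possible connections a network uses
#'
#' The number of realized edges divided by the number a network of its size
#' could legally hold: all ordered pairs including self-edges
#' (`n^2`) minus the one forbidden detector-to-effector pair.
#'
#' @param net An [immune_network()].
#' @return A scalar in `[0, 1]`.
#' @export
connectivity <- function(net) {
  n <- length(net$ids)
  sum(net$W != 0) / (n^2 - 1)
}

#' Number of proteins in a network
#' @param net An [immune_network()].
#' @return Integer node count.
#' @export
network_size <- function(net) length(net$ids)

# ---- serialization ---------------------------------------------------------

#' Serialize an immune network to JSON (and back)
#'
#' The JSON form lists nodes (id, role, pleiotropic flag), edges (src, dst,
#' weight at full double precision, locked flag), the lineage id and, when
#' present, the pleiotropy mode.  The round trip is lossless.
#'
#' @param net An [immune_network()].
#' @return `network_to_json()`: a JSON string. `network_from_json()`: an
#'   [immune_network()].
#' @export
network_to_json <- function(net) {
  jsonlite::toJSON(network_to_list(net), auto_unbox = TRUE,
                   digits = I(17), null = "null")
}

network_to_list <- function(net) {
  e <- which(net$W != 0, arr.ind = TRUE)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  edges <- lapply(seq_len(nrow(e)), function(k) {
    i <- e[k, 1]; j <- e[k, 2]
    list(src = net$ids[i], dst = net$ids[j], w = net$W[i, j],
         locked = net$locked[i, j])
  })
  pnode <- if (is.null(net$pleio)) NA_integer_ else net$pleio$node
  nodes <- lapply(seq_along(net$ids), function(i) {
    list(id = net$ids[i], role = net$roles[i],
         pleiotropic = identical(net$ids[i], as.integer(pnode)))
  })
  list(nodes = nodes, edges = edges, lineage_id = net$lineage_id,
       pleiotropy_mode = if (is.null(net$pleio)) NULL else net$pleio$mode)
}

network_from_list <- function(x) {
  ids <- vapply(x$nodes, function(nd) as.integer(nd$id), integer(1))
  roles <- vapply(x$nodes, function(nd) nd$role, character(1))
  n <- length(ids)
  W <- matrix(0, n, n)
  L <- matrix(FALSE, n, n)
  for (ed in x$edges) {
    i <- match(as.integer(ed$src), ids); j <- match(as.integer(ed$dst), ids)
    W[i, j] <- ed$w
    L[i, j] <- isTRUE(ed$locked)
  }
  ple <- vapply(x$nodes, function(nd) isTRUE(nd$pleiotropic), logical(1))
  pleio <- NULL
  if (any(ple) && !is.null(x$pleiotropy_mode))
    pleio <- list(node = ids[which(ple)[1]], mode = x$pleiotropy_mode)
  immune_network(ids, roles, W, L, pleio, lineage_id = x$lineage_id)
}

#' @rdname network_to_json
#' @param json A JSON string produced by `network_to_json()`.
#' @export
network_from_json <- function(json) {
  network_from_list(jsonlite::fromJSON(json, simplifyVector = FALSE))
}

#' Convert an immune network to an igraph object
#'
#' Vertices carry `role` and `pleiotropic` attributes, edges carry `weight`
#' and `locked`; useful for GraphML export via [igraph::write_graph()].
#'
#' @param net An [immune_network()].
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  e <- which(net$W != 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(net$ids), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(net$ids))
  g <- igraph::set_vertex_attr(g, "role", value = net$roles)
  pnode <- if (is.null(net$pleio)) NA_integer_ else net$pleio$node
  g <- igraph::set_vertex_attr(g, "pleiotropic", value = net$ids == pnode &
                                 !is.na(pnode))
  if (nrow(e) > 0) {
    g <- igraph::add_edges(g, rbind(e[, 1], e[, 2]),
                           weight = net$W[e], locked = net$locked[e])
  }
  g
}

#' Write an immune network to GraphML
#' @param net An [immune_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

# canonical key for exact-match network equality: ordered roles with stable
# node labels plus the sorted edge list at full float precision
network_key <- function(net) {
  ord <- order(net$ids)
  ids <- net$ids[ord]
  e <- which(net$W != 0, arr.ind = TRUE)
  edge_str <- if (nrow(e) == 0) "" else {
    src <- net$ids[e[, 1]]; dst <- net$ids[e[, 2]]
    o <- order(src, dst)
    paste(sprintf("%d>%d=%.17g", src[o], dst[o], net$W[e][o]),
          collapse = ";")
  }
  paste(paste(ids, substr(net$roles[ord], 1, 1), sep = ":", collapse = ","),
        edge_str, sep = "|")
}
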