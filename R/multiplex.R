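#' Build a multiplex network from edge lists
#'
#' A multiplex network is a shared, ordered node set together with two or more
#' undirected edge layers defined on it. Layers may be supplied as a single
#' long edge list with a `layer` column, or as a named list of per-layer edge
#' lists. Nodes present in only some layers are padded as isolated nodes in
#' the others; nodes isolated in the union of all layers are dropped at
#' construction, so downstream code can assume every node is reachable from
#' at least one edge.
#'
#' @param x A data frame of edges with columns `from`, `to` (aliases
#'   `source`, `target` are accepted), optionally `weight` and `layer`; or a
#'   named list of such data frames (one per layer).
#' @param layer_names Optional character vector of layer names; defaults to
#'   the `layer` column values (in order of first appearance) or list names.
#' @param nodes Optional character vector fixing the node set and its order;
#'   nodes isolated in the union are still dropped.
#' @return An object of class `multiplex`: a list with elements `nodes`
#'   (character vector, the canonical node order), `layers` (named list of
#'   igraph objects on the common node set) and `layer_names`.
#' @examples
#' edges <- tibble::tibble(
#'   from  = c("1", "2", "3", "1", "2"),
#'   to    = c("2", "3", "4", "3", "4"),
#'   layer = c("A", "A", "A", "B", "B")
#' )
#' m <- as_multiplex(edges)
#' m
#' @export
as_multiplex <- function(x, layer_names = NULL, nodes = NULL) {
  if (inherits(x, "multiplex")) {
    return(x)
  }
  if (is.data.frame(x)) {
    x <- normalize_edge_cols(x)
    if (!"layer" %in% names(x)) {
      stop("edge data frame must have a `layer` column (or pass a list of layers)",
           call. = FALSE)
    }
    lv <- unique(as.character(x$layer))
    layers <- lapply(lv, function(l) x[as.character(x$layer) == l, , drop = FALSE])
    names(layers) <- lv
  } else if (is.list(x)) {
    layers <- lapply(x, function(el) {
      if (igraph::is_igraph(el)) el else normalize_edge_cols(el)
    })
    if (is.null(names(layers)) || any(names(layers) == "")) {
      names(layers) <- paste0("L", seq_along(layers))
    }
  } else {
    stop("`x` must be an edge data frame with a layer column or a list of layers",
         call. = FALSE)
  }
  if (!is.null(layer_names)) {
    stopifnot(length(layer_names) == length(layers))
    names(layers) <- layer_names
  }
  if (length(layers) < 2) {
    stop("a multiplex network needs at least 2 layers", call. = FALSE)
  }

  edge_tbls <- lapply(layers, function(l) {
    if (igraph::is_igraph(l)) {
      el <- igraph::as_data_frame(l, what = "edges")
      names(el)[1:2] <- c("from", "to")
      tibble::as_tibble(el)
    } else {
      tibble::as_tibble(l)
    }
  })
  for (el in edge_tbls) {
    if (any(as.character(el$from) == as.character(el$to))) {
      stop("self-loops are not allowed", call. = FALSE)
    }
  }

  seen <- unique(unlist(lapply(edge_tbls, function(el) {
    c(as.character(el$from), as.character(el$to))
  })))
  if (length(seen) == 0) {
    stop("the union of all layers has no edges", call. = FALSE)
  }
  all_nodes <- if (is.null(nodes)) {
    sort_nodes(seen)
  } else {
    as.character(nodes)
  }
  # drop nodes isolated in the union of all layers
  keep <- all_nodes %in% seen
  all_nodes <- all_nodes[keep]
  if (!is.null(nodes)) {
    bad <- setdiff(seen, all_nodes)
    if (length(bad)) {
      stop("edges reference nodes not in `nodes`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }

  gs <- lapply(edge_tbls, function(el) edges_to_igraph(el, all_nodes))
  structure(
    list(nodes = all_nodes, layers = gs, layer_names = names(gs)),
    class = "multiplex"
  )
}

#' @rdname as_multiplex
#' @param networks A list of edge data frames or igraph objects, one per layer.
#' @param names Layer names for `networks`.
#' @export
build_multiplex <- function(networks, names = NULL) {
  as_multiplex(networks, layer_names = names)
}

#' @export
print.multiplex <- function(x, ...) {
  cat("<multiplex network>\n")
  cat("  nodes:", length(x$nodes), "\n")
  for (nm in x$layer_names) {
    cat(sprintf("  layer %-12s %d edges\n", nm, igraph::gsize(x$layers[[nm]])))
  }
  invisible(x)
}

#' Number of layers of a multiplex network
#' @param m A `multiplex` object.
#' @return Integer count of layers.
#' @export
n_layers <- function(m) length(m$layers)

# ---- internal helpers -------------------------------------------------------

# accept source/target aliases, coerce endpoints to character
normalize_edge_cols <- function(el) {
  el <- tibble::as_tibble(el)
  nm <- names(el)
  if (!"from" %in% nm && "source" %in% nm) nm[nm == "source"] <- "from"
  if (!"to" %in% nm && "target" %in% nm) nm[nm == "target"] <- "to"
  names(el) <- nm
  if (!all(c("from", "to") %in% names(el))) {
    stop("edge data needs `from`/`to` (or `source`/`target`) columns", call. = FALSE)
  }
  el$from <- as.character(el$from)
  el$to <- as.character(el$to)
  if ("weight" %in% names(el) && any(el$weight <= 0)) {
    stop("edge weights must be strictly positive", call. = FALSE)
  }
  el
}

# numeric-looking labels sort numerically, otherwise lexicographically
sort_nodes <- function(v) {
  num <- suppressWarnings(as.numeric(v))
  if (!anyNA(num)) v[order(num)] else sort(v)
}

edges_to_igraph <- function(el, nodes) {
  keep <- intersect(c("from", "to", "weight"), names(el))
  g <- igraph::graph_from_data_frame(
    as.data.frame(el[, keep, drop = FALSE]),
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "first")
}

# coerce an edge tibble / igraph / multiplex layer to igraph
as_network_graph <- function(x, nodes = NULL) {
  if (igraph::is_igraph(x)) {
    return(x)
  }
  if (is.data.frame(x)) {
    el <- normalize_edge_cols(x)
    if (is.null(nodes)) {
      nodes <- attr(x, "nodes")
    }
    if (is.null(nodes)) {
      nodes <- sort_nodes(unique(c(el$from, el$to)))
    }
    return(edges_to_igraph(el, as.character(nodes)))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a network", call. = FALSE)
}

# ---- joint network and efficiency machinery --------------------------------

#' Joint (union) network of a subset of layers
#'
#' The joint network places an edge between two nodes whenever they are
#' directly connected in any of the selected layers.
#'
#' @param m A `multiplex` object.
#' @param layers Layer indices or names to combine; defaults to all layers.
#' @return An igraph object on the multiplex node set.
#' @export
joint_network <- function(m, layers = NULL) {
  m <- as_multiplex(m)
  idx <- resolve_layers(m, layers)
  if (length(idx) == 0) stop("`layers` must select at least one layer", call. = FALSE)
  if (length(idx) == 1) {
    return(m$layers[[idx]])
  }
  els <- lapply(m$layers[idx], igraph::as_edgelist, names = TRUE)
  el <- do.call(rbind, els)
  edges_to_igraph(tibble::tibble(from = el[, 1], to = el[, 2]), m$nodes)
}

resolve_layers <- function(m, layers) {
  if (is.null(layers)) {
    return(seq_along(m$layers))
  }
  if (is.character(layers)) {
    idx <- match(layers, m$layer_names)
    if (anyNA(idx)) stop("unknown layer name(s): ",
                         paste(layers[is.na(idx)], collapse = ", "), call. = FALSE)
    return(idx)
  }
  layers <- as.integer(layers)
  if (any(layers < 1 | layers > length(m$layers))) {
    stop("layer index out of range", call. = FALSE)
  }
  layers
}

#' Shortest-path length matrix
#'
#' Breadth-first search for binary networks, Dijkstra for weighted ones
#' (path length = sum of edge weights). Disconnected pairs have length `Inf`;
#' the diagonal is 0.
#'
#' @param x An edge data frame, igraph object, or `multiplex` layer.
#' @param nodes Optional node order (for edge data frames).
#' @return A symmetric numeric matrix indexed by node label.
#' @export
shortest_path_lengths <- function(x, nodes = NULL) {
  g <- as_network_graph(x, nodes)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) NULL else NA
  igraph::distances(g, weights = w)
}

#' Pairwise efficiency matrix
#'
#' Efficiency of a node pair is the inverse of its shortest-path length;
#' 0 for disconnected pairs, 1 for a direct edge in a binary network.
#'
#' @inheritParams shortest_path_lengths
#' @return A symmetric numeric matrix in `[0, 1]` (binary case), 0 diagonal.
#' @export
pairwise_efficiency <- function(x, nodes = NULL) {
  d <- shortest_path_lengths(x, nodes)
  eff <- 1 / d
  eff[is.infinite(d)] <- 0
  diag(eff) <- 0
  eff
}

# validate / default the pair weighting; returns an upper-triangle weight
# matrix summing to 1 over unordered distinct pairs
pair_weight_matrix <- function(n, weights = NULL, nodes = NULL) {
  if (is.null(weights)) {
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- 1 / (n * (n - 1) / 2)
    return(w)
  }
  if (!is.matrix(weights) || !all(dim(weights) == c(n, n))) {
    stop("`weights` must be an n x n matrix over the multiplex node set",
         call. = FALSE)
  }
  if (any(weights < 0)) stop("pair weights must be non-negative", call. = FALSE)
  w <- (weights + t(weights)) / 2   # symmetrize; unordered pairs
  diag(w) <- 0
  tot <- sum(w[upper.tri(w)])
  if (tot <= 0) stop("pair weights sum to zero", call. = FALSE)
  out <- matrix(0, n, n)
  out[upper.tri(out)] <- w[upper.tri(w)] / tot
  out
}

#' Global utility (global efficiency) of a network
#'
#' The expectation of pairwise efficiency under a probability weighting over
#' unordered distinct node pairs. With the default uniform weighting this is
#' the network's global efficiency.
#'
#' @inheritParams shortest_path_lengths
#' @param weights Optional symmetric matrix of pair weights (normalized
#'   internally); `NULL` for uniform.
#' @return A single number in `[0, 1]` for binary networks.
#' @export
global_efficiency <- function(x, weights = NULL, nodes = NULL) {
  eff <- pairwise_efficiency(x, nodes)
  w <- pair_weight_matrix(nrow(eff), weights)
  sum(eff * w)
}

#' Utility gain of adding one layer set to another
#'
#' The increase in global efficiency from adding the layers in `e1` on top of
#' the layers in `e2`: `F(joint(e1 + e2)) - F(joint(e2))`. Non-negative for
#' the efficiency utility, since taking unions can only shorten paths.
#'
#' @param m A `multiplex` object.
#' @param e1,e2 Layer indices or names.
#' @inheritParams global_efficiency
#' @return A single non-negative number.
#' @export
utility_gain <- function(m, e1, e2, weights = NULL) {
  m <- as_multiplex(m)
  i1 <- resolve_layers(m, e1)
  i2 <- resolve_layers(m, e2)
  f12 <- global_efficiency(joint_network(m, union(i1, i2)), weights)
  f2 <- global_efficiency(joint_network(m, i2), weights)
  f12 - f2
}
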