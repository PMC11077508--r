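#' Surrogate-network generators
#'
#' Three null models for significance testing of decomposition terms:
#' degree-preserving edge-swap randomization (Maslov-Sneppen), a stricter
#' geometry-preserving variant that additionally preserves the binned
#' distribution of edge Euclidean lengths, and density-matched random
#' graphs.
#'
#' @name nullmodels
NULL

# one double-edge-swap engine serves both rewiring models: edges (a,b),(c,d)
# -> (a,d),(c,b), rejected if it would create a self-loop or duplicate edge,
# and -- when a bin constraint is given -- unless the two new edges occupy
# the same multiset of length bins as the two removed ones (so the per-bin
# edge-length histogram is preserved exactly).
swap_engine <- function(el, n, n_swaps, max_attempts, bin_of = NULL) {
  adj <- matrix(FALSE, n, n)
  adj[el] <- TRUE
  adj[el[, c(2, 1), drop = FALSE]] <- TRUE
  m <- nrow(el)
  done <- 0L
  att <- 0L
  while (done < n_swaps && att < max_attempts) {
    att <- att + 1L
    ij <- sample.int(m, 2L)
    a <- el[ij[1], 1]; b <- el[ij[1], 2]
    c <- el[ij[2], 1]; d <- el[ij[2], 2]
    if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
    # propose (a,d), (c,b)
    if (a == d || c == b) next
    if (adj[a, d] || adj[c, b]) next
    if ((a == c && d == b) || (a == b && d == c)) next
    if (!is.null(bin_of)) {
      old_bins <- sort(c(bin_of(a, b), bin_of(c, d)))
      new_bins <- sort(c(bin_of(a, d), bin_of(c, b)))
      if (!identical(old_bins, new_bins)) next
    }
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c, d] <- adj[d, c] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c, b] <- adj[b, c] <- TRUE
    el[ij[1], ] <- c(a, d)
    el[ij[2], ] <- c(c, b)
    done <- done + 1L
  }
  list(el = el, swaps_done = done, attempts = att)
}

graph_to_index_edgelist <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  el
}

index_edgelist_to_graph <- function(el, nodes) {
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::set_vertex_attr(g, "name", value = nodes)
}

#' Degree-preserving (Maslov-Sneppen) rewiring
#'
#' Randomizes a binary network by repeated double-edge swaps, preserving the
#' exact degree of every node (and hence the density). Swap proposals that
#' would create a self-loop or duplicate edge are rejected and retried, up
#' to `100 * n_swaps` attempts; if the target number of successful swaps is
#' not reached (degenerate graphs such as stars), the partially rewired
#' network is returned with a warning.
#'
#' @param x A network (edge data frame or igraph object).
#' @param swaps_per_edge Target successful swaps per edge (default 10).
#' @param n_swaps Override the total successful-swap target.
#' @param seed Optional integer seed; same seed, same output.
#' @param nodes Optional node order for edge data frames.
#' @return An igraph object with the same node set and degree sequence.
#' @export
rewire_degree_preserving <- function(x, swaps_per_edge = 10, n_swaps = NULL,
                                     seed = NULL, nodes = NULL) {
  g <- as_network_graph(x, nodes)
  if (!is.null(seed)) set.seed(seed)
  el <- graph_to_index_edgelist(g)
  m <- nrow(el)
  if (is.null(n_swaps)) n_swaps <- ceiling(swaps_per_edge * m)
  out <- swap_engine(el, igraph::vcount(g), n_swaps, 100L * n_swaps)
  if (out$swaps_done < n_swaps) {
    warning(sprintf("reached attempt cap after %d of %d swaps (degenerate graph?)",
                    out$swaps_done, n_swaps))
  }
  index_edgelist_to_graph(out$el, igraph::V(g)$name)
}

#' Geometry-preserving rewiring
#'
#' Degree-preserving rewiring additionally constrained to preserve the
#' histogram of edge Euclidean lengths: the edge-length range is divided
#' into `n_bins` equal-width bins, and a swap is accepted only if the two
#' new edges fall into the same bins as the two removed ones. With
#' `n_bins = 1` this reduces to unconstrained Maslov-Sneppen rewiring.
#'
#' @inheritParams rewire_degree_preserving
#' @param coords A data frame with columns `node`, `x`, `y` and optionally
#'   `z`, covering every node of the network.
#' @param n_bins Number of equal-width distance bins (default 10).
#' @return An igraph object with the original degree sequence and per-bin
#'   edge-length counts.
#' @export
rewire_geometry_preserving <- function(x, coords, n_bins = 10,
                                       swaps_per_edge = 10, n_swaps = NULL,
                                       seed = NULL, nodes = NULL) {
  g <- as_network_graph(x, nodes)
  nd <- node_distance_matrix(g, coords)
  if (!is.null(seed)) set.seed(seed)
  el <- graph_to_index_edgelist(g)
  m <- nrow(el)
  if (is.null(n_swaps)) n_swaps <- ceiling(swaps_per_edge * m)

  dmax <- max(nd) + 1e-9
  dmin <- min(nd[nd > 0])
  brk <- seq(dmin - 1e-9, dmax, length.out = n_bins + 1)
  bin_of <- function(i, j) {
    findInterval(nd[i, j], brk, rightmost.closed = TRUE, all.inside = TRUE)
  }
  out <- swap_engine(el, igraph::vcount(g), n_swaps, 100L * n_swaps, bin_of)
  if (out$swaps_done < n_swaps) {
    warning(sprintf("reached attempt cap after %d of %d swaps", out$swaps_done,
                    n_swaps))
  }
  index_edgelist_to_graph(out$el, igraph::V(g)$name)
}

node_distance_matrix <- function(g, coords) {
  coords <- tibble::as_tibble(coords)
  if (!all(c("node", "x", "y") %in% names(coords))) {
    stop("`coords` needs columns node, x, y (and optionally z)", call. = FALSE)
  }
  nodes <- igraph::V(g)$name
  idx <- match(nodes, as.character(coords$node))
  if (anyNA(idx)) {
    stop("missing coordinates for node(s): ",
         paste(nodes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  xyz <- cbind(coords$x[idx], coords$y[idx],
               if ("z" %in% names(coords)) coords$z[idx] else 0)
  as.matrix(stats::dist(xyz))
}

#' Density-matched random graph
#'
#' An Erdos-Renyi graph with exactly the same node set and edge count as the
#' input (G(n, m) convention). Degrees are generally not preserved.
#'
#' @inheritParams rewire_degree_preserving
#' @return An igraph object.
#' @export
sample_density_matched <- function(x, seed = NULL, nodes = NULL) {
  g <- as_network_graph(x, nodes)
  if (!is.null(seed)) set.seed(seed)
  out <- igraph::sample_gnm(igraph::vcount(g), igraph::gsize(g))
  igraph::set_vertex_attr(out, "name", value = igraph::V(g)$name)
}

#' Null ensemble of decompositions from rewired surrogates
#'
#' Generates `n_surrogates` surrogate multiplexes by rewiring every layer
#' independently (each with its own deterministically derived child seed),
#' decomposes each, and collects the null distribution of every
#' decomposition term. Two-layer multiplexes only.
#'
#' @param x A two-layer `multiplex` object (or anything `as_multiplex()`
#'   accepts).
#' @param model `"degree_preserving"`, `"geometry_preserving"` or
#'   `"density_random"`.
#' @param n_surrogates Number of surrogates (the transport-network analyses
#'   in the literature use 1,000).
#' @param swaps_per_edge Swap budget per edge for the rewiring models.
#' @param n_bins Distance bins for the geometry model.
#' @param coords Node coordinates (geometry model only).
#' @param seed Master seed; child seeds are drawn from it so the ensemble is
#'   reproducible.
#' @return An object of class `pnd_null_ensemble`: the observed `glance()`
#'   row, a tibble `nulls` with one row per surrogate (atoms and reachable
#'   class proportions), and the model metadata. Use `tidy()` for the
#'   surrogate table and [test_against_null()] for significance.
#' @export
null_ensemble <- function(x, model = c("degree_preserving",
                                       "geometry_preserving",
                                       "density_random"),
                          n_surrogates = 100, swaps_per_edge = 10,
                          n_bins = 10, coords = NULL, seed = NULL) {
  model <- match.arg(model)
  m <- as_multiplex(x)
  if (n_layers(m) != 2) {
    stop("null_ensemble() currently supports two-layer multiplexes",
         call. = FALSE)
  }
  if (model == "geometry_preserving" && is.null(coords)) {
    stop("geometry_preserving model needs `coords`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  child <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_surrogates),
                  ncol = 2)

  observed <- decompose_efficiency(m, per_pair = FALSE)
  one <- function(i) {
    layers <- lapply(1:2, function(j) {
      g <- m$layers[[j]]
      switch(model,
        degree_preserving = rewire_degree_preserving(
          g, swaps_per_edge = swaps_per_edge, seed = child[i, j]),
        geometry_preserving = rewire_geometry_preserving(
          g, coords = coords, n_bins = n_bins,
          swaps_per_edge = swaps_per_edge, seed = child[i, j]),
        density_random = sample_density_matched(g, seed = child[i, j])
      )
    })
    names(layers) <- m$layer_names
    ms <- structure(list(nodes = m$nodes, layers = layers,
                         layer_names = m$layer_names), class = "multiplex")
    res <- decompose_efficiency(ms, per_pair = FALSE)
    props <- class_proportions(res)
    row <- c(res$atoms, F_joint = res$F_joint)
    prop <- stats::setNames(props$proportion, paste0("prop_", props$class))
    tibble::as_tibble(as.list(c(surrogate = i, row, prop)))
  }
  nulls <- dplyr::bind_rows(lapply(seq_len(n_surrogates), one))

  structure(
    list(
      observed = glance(observed),
      observed_proportions = class_proportions(observed),
      nulls = nulls,
      model = model,
      n_surrogates = n_surrogates,
      swaps_per_edge = swaps_per_edge,
      n_bins = if (model == "geometry_preserving") n_bins else NA_integer_,
      seed = seed,
      layer_names = m$layer_names
    ),
    class = "pnd_null_ensemble"
  )
}

#' @export
print.pnd_null_ensemble <- function(x, ...) {
  cat(sprintf("<null ensemble: %s, %d surrogates>\n", x$model, x$n_surrogates))
  print(test_against_null(x))
  invisible(x)
}

#' @export
tidy.pnd_null_ensemble <- function(x, ...) x$nulls

#' Test observed decomposition terms against a null ensemble
#'
#' Add-one-corrected empirical p-values of the observed atoms against the
#' surrogate distributions, with a z-style standardized effect
#' (observed minus null mean, over null SD).
#'
#' @param x A `pnd_null_ensemble` object.
#' @param direction `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A tibble: `term`, `observed`, `null_mean`, `null_sd`, `p`, `z`,
#'   `direction`, `n_null`.
#' @export
test_against_null <- function(x, direction = "two.sided") {
  terms <- c("R", "U_A", "U_B", "S")
  obs <- unlist(x$observed[terms])
  rows <- lapply(terms, function(tm) {
    nv <- x$nulls[[tm]]
    tibble::tibble(
      term = tm,
      observed = obs[[tm]],
      null_mean = mean(nv),
      null_sd = stats::sd(nv),
      p = empirical_p(obs[[tm]], nv, direction),
      z = if (stats::sd(nv) > 0) (obs[[tm]] - mean(nv)) / stats::sd(nv) else NA_real_,
      direction = direction,
      n_null = length(nv)
    )
  })
  dplyr::bind_rows(rows)
}
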