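#' Synthetic network generators and simulation experiments
#'
#' Generators emulating the study designs used to characterize the
#' decomposition: pairs of Erdos-Renyi layers across a density grid, ring
#' lattices with progressive degree-preserving rewiring, and the
#' connectome-style preprocessing steps (Euclidean distance split, consensus
#' matrix, density matching).
#'
#' @name netgen
NULL

#' Pair of Erdos-Renyi layers
#'
#' Two independent G(n, m) layers on a shared node set, with
#' `m = round(f * n * (n - 1) / 2)` edges each ("selecting a fraction f of
#' all possible edges"). Nodes isolated in the union are dropped by the
#' multiplex constructor.
#'
#' @param n Number of nodes.
#' @param f_a,f_b Edge densities of the two layers, in `(0, 1]`.
#' @param seed Optional seed.
#' @param layer_names Names for the two layers.
#' @return A two-layer `multiplex` object.
#' @export
er_multiplex <- function(n, f_a, f_b, seed = NULL, layer_names = c("A", "B")) {
  stopifnot(f_a > 0, f_a <= 1, f_b > 0, f_b <= 1)
  if (!is.null(seed)) set.seed(seed)
  npairs <- n * (n - 1) / 2
  ma <- round(f_a * npairs)
  mb <- round(f_b * npairs)
  if (ma + mb < 1) stop("both layers would be empty at these densities",
                        call. = FALSE)
  nodes <- as.character(seq_len(n))
  ga <- igraph::set_vertex_attr(igraph::sample_gnm(n, ma), "name", value = nodes)
  gb <- igraph::set_vertex_attr(igraph::sample_gnm(n, mb), "name", value = nodes)
  ml <- list(ga, gb)
  names(ml) <- layer_names
  as_multiplex(ml)
}

#' Density sweep of Erdos-Renyi layer pairs
#'
#' Decomposes independent ER layer pairs over a grid of density
#' combinations, recording the reachable-pair class proportions per cell and
#' replicate. Three regimes emerge: synergy dominates when both layers are
#' sparse (about 5% density or less), redundancy on the dense diagonal
#' (similar densities above about 15%), and the denser layer's unique
#' contribution off-diagonal.
#'
#' The synergy regime is a property of sparse *mean degree*, not of density
#' alone: at a fixed density the mean degree grows linearly with `n`, and
#' once each layer is internally well connected (mean degree around 10,
#' e.g. 200 nodes at 5% density) within-layer shortcuts erase most synergy.
#' The default of 50 nodes keeps the 5%-density cell in the sparse regime
#' where the three-regime structure is expressed, while still allowing a
#' 1%-density grid cell.
#'
#' @param n Nodes per layer (default 50; see Details).
#' @param densities Numeric vector of densities in `(0, 1]`; the grid is
#'   their Cartesian square.
#' @param replicates Independent replicates per cell (default 10).
#' @param seed Master seed.
#' @return A tibble of class `pnd_sweep`: `f_a`, `f_b`, `replicate`,
#'   proportions `prop_redundant`, `prop_unique_a`, `prop_unique_b`,
#'   `prop_synergistic`, and the cell's `dominant` class.
#' @export
density_sweep <- function(n = 50, densities = c(0.05, 0.1, 0.15, 0.2, 0.3),
                          replicates = 10, seed = NULL) {
  stopifnot(all(densities > 0), all(densities <= 1))
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(f_a = densities, f_b = densities,
                      replicate = seq_len(replicates))
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- er_multiplex(n, grid$f_a[i], grid$f_b[i], seed = seeds[i])
    res <- decompose_efficiency(m, per_pair = FALSE)
    pr <- sweep_proportions(res)
    tibble::tibble(
      f_a = grid$f_a[i], f_b = grid$f_b[i], replicate = grid$replicate[i],
      prop_redundant = pr[["redundant"]],
      prop_unique_a = pr[["unique_a"]],
      prop_unique_b = pr[["unique_b"]],
      prop_synergistic = pr[["synergistic"]],
      dominant = names(pr)[which.max(pr)]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pnd_sweep", class(out))
  out
}

# reachable-pair proportions keyed by generic class names
sweep_proportions <- function(res) {
  cp <- class_proportions(res)
  key <- c("redundant",
           paste0("unique:", res$layer_names[1]),
           paste0("unique:", res$layer_names[2]),
           "synergistic")
  pr <- cp$proportion[match(key, cp$class)]
  pr[is.na(pr)] <- 0
  stats::setNames(pr, c("redundant", "unique_a", "unique_b", "synergistic"))
}

#' Mean class proportions per density cell
#'
#' @param x A `pnd_sweep` tibble.
#' @return A tibble with one row per `(f_a, f_b)` cell: mean proportions,
#'   their SDs, and the dominant (largest mean) class.
#' @export
sweep_summary <- function(x) {
  x |>
    dplyr::group_by(.data$f_a, .data$f_b) |>
    dplyr::summarise(
      dplyr::across(dplyr::starts_with("prop_"),
                    list(mean = mean, sd = stats::sd)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      dominant = c("redundant", "unique_a", "unique_b", "synergistic")[
        max.col(cbind(.data$prop_redundant_mean, .data$prop_unique_a_mean,
                      .data$prop_unique_b_mean, .data$prop_synergistic_mean))
      ]
    )
}

#' @export
autoplot.pnd_sweep <- function(object, ...) {
  sm <- sweep_summary(object)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$f_a, y = .data$f_b,
                                   fill = .data$dominant)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "density of layer A", y = "density of layer B",
                  fill = "dominant class") +
    ggplot2::theme_minimal()
}

#' Ring lattice at a target density
#'
#' A regular ring lattice in which every node is linked to its `k` nearest
#' neighbors per side, with `k` chosen so the edge count `k * n` is closest
#' to `density * n * (n - 1) / 2`. At 200 nodes and 5% density this gives
#' `k = 5` (1000 edges against a target of 995).
#'
#' @param n Number of nodes.
#' @param density Target edge density.
#' @return An igraph ring lattice with constant degree `2k`.
#' @export
ring_lattice <- function(n, density) {
  target <- density * n * (n - 1) / 2
  kmax <- floor((n - 1) / 2)
  k <- which.min(abs(seq_len(kmax) * n - target))
  if (target < n / 2) stop("density below the minimum ring lattice (k = 1)",
                           call. = FALSE)
  ring_lattice_nm(n, k * n)
}

#' Lattice rewiring trajectory
#'
#' The small-world experiment: two copies of the same ring lattice; one copy
#' is cumulatively rewired in steps of `step_frac` of its edges (each step
#' performs `round(step_frac * m / 2)` successful degree-preserving
#' double-edge swaps, each swap rewiring two edges), and at every step the
#' two-layer decomposition of (fixed lattice, rewired copy) and the
#' small-world propensity of their joint network are recorded. At step 0 the
#' layers are identical, so the redundancy proportion is exactly 1. The
#' rewired layer's unique contribution peaks at around 9% rewiring,
#' coinciding with the peak of the joint network's small-world propensity.
#'
#' @param n Nodes (default 200).
#' @param density Lattice density (default 0.05).
#' @param step_frac Fraction of edges rewired per step (default 0.01).
#' @param n_steps Number of rewiring steps (default 100, i.e. up to 100%).
#' @param seeds Integer vector of seeds, one trajectory each (or a single
#'   count, expanded to `1:seeds`).
#' @param swp Also compute the joint network's small-world propensity per
#'   step?
#' @param n_rand_swp Random-reference realizations for the SWP.
#' @return A tibble of class `pnd_trajectory`: `seed`, `step` (integer,
#'   in units of `step_frac`, i.e. percent rewired for the default),
#'   `prop_redundant`, `prop_unique_lattice`, `prop_unique_rewired`,
#'   `prop_synergistic`, `R`, `U_lattice`, `U_rewired`, `S`, `F_joint`,
#'   `swp`.
#' @export
rewiring_experiment <- function(n = 200, density = 0.05, step_frac = 0.01,
                                n_steps = round(1 / step_frac), seeds = 1L,
                                swp = TRUE, n_rand_swp = 10) {
  if (length(seeds) == 1 && seeds >= 1 && seeds == round(seeds)) {
    if (seeds > 1) seeds <- seq_len(seeds)
  }
  latt <- ring_lattice(n, density)
  nodes <- igraph::V(latt)$name
  el0 <- graph_to_index_edgelist(latt)
  m <- nrow(el0)
  swaps_per_step <- max(1L, round(step_frac * m / 2))

  one_seed <- function(sd) {
    set.seed(sd)
    swp_seeds <- sample.int(.Machine$integer.max - 1L, n_steps + 1)
    el <- el0
    d_latt <- shortest_path_lengths(latt)
    rows <- vector("list", n_steps + 1)
    for (stp in 0:n_steps) {
      if (stp > 0) {
        out <- swap_engine(el, n, swaps_per_step, 100L * swaps_per_step)
        el <- out$el
      }
      g_rew <- index_edgelist_to_graph(el, nodes)
      ml <- structure(list(nodes = nodes,
                           layers = list(lattice = latt, rewired = g_rew),
                           layer_names = c("lattice", "rewired")),
                      class = "multiplex")
      d_rew <- shortest_path_lengths(g_rew)
      gj <- joint_network(ml)
      d_joint <- shortest_path_lengths(gj)
      res <- decompose_from_lengths(d_latt, d_rew, d_joint, ml,
                                    per_pair = FALSE)
      pr <- sweep_proportions(res)
      swp_val <- if (swp) {
        small_world_propensity(gj, n_rand = n_rand_swp,
                               seed = swp_seeds[stp + 1])$swp
      } else NA_real_
      rows[[stp + 1]] <- tibble::tibble(
        seed = sd, step = stp,
        prop_redundant = pr[["redundant"]],
        prop_unique_lattice = pr[["unique_a"]],
        prop_unique_rewired = pr[["unique_b"]],
        prop_synergistic = pr[["synergistic"]],
        R = res$atoms[["R"]], U_lattice = res$atoms[["U_A"]],
        U_rewired = res$atoms[["U_B"]], S = res$atoms[["S"]],
        F_joint = res$F_joint, swp = swp_val
      )
    }
    dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(lapply(seeds, one_seed))
  attr(out, "step_frac") <- step_frac
  class(out) <- c("pnd_trajectory", class(out))
  out
}

#' Peak locations of a rewiring trajectory
#'
#' Locates the peak of the rewired layer's unique-contribution proportion
#' and of the joint network's small-world propensity. The headline estimate
#' (`peak_unique_rewired`, `peak_swp`) is the argmax of the seed-averaged
#' curve — the peak one reads off the mean trajectory. Both curves have
#' broad, flat tops, so the argmax of an individual noisy trajectory is
#' biased towards wherever its noise happens to spike; averaging the curves
#' across seeds before taking the argmax removes most of that bias. The
#' per-seed argmaxes and their mean are also reported for reference.
#'
#' @param x A `pnd_trajectory` tibble.
#' @return A list with `peak_unique_rewired` and `peak_swp` (argmax of the
#'   seed-averaged curves, in step units, i.e. percent rewired at the
#'   default step size), `per_seed` (tibble of per-seed argmaxes) and
#'   `mean_peak_unique_rewired`, `mean_peak_swp` (their means).
#' @export
trajectory_peaks <- function(x) {
  avg <- x |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(
      u = mean(.data$prop_unique_rewired),
      s = mean(.data$swp),
      .groups = "drop"
    )
  per_seed <- x |>
    dplyr::group_by(.data$seed) |>
    dplyr::summarise(
      peak_unique_rewired = .data$step[which.max(.data$prop_unique_rewired)],
      peak_swp = if (all(is.na(.data$swp))) NA_real_
                 else .data$step[which.max(.data$swp)],
      .groups = "drop"
    )
  list(
    peak_unique_rewired = avg$step[which.max(avg$u)],
    peak_swp = if (all(is.na(avg$s))) NA_real_ else avg$step[which.max(avg$s)],
    per_seed = per_seed,
    mean_peak_unique_rewired = mean(per_seed$peak_unique_rewired),
    mean_peak_swp = mean(per_seed$peak_swp)
  )
}

#' @export
autoplot.pnd_trajectory <- function(object, ...) {
  long <- object |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(dplyr::across(c(dplyr::starts_with("prop_"), "swp"),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    tidyr::pivot_longer(-"step", names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "% of edges rewired", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Split a spatial network into short- and long-range layers
#'
#' Sorts edges by the Euclidean distance between their endpoints (ties
#' broken by canonical edge order, so the split is reproducible) and
#' assigns the shortest 50% to a `"short"` layer and the longest 50% to a
#' `"long"` layer; for an odd edge count the extra edge goes to the short
#' layer. The two layers partition the edge set and have equal density.
#'
#' @param x A network (edge data frame or igraph object).
#' @param coords Node coordinates (`node`, `x`, `y`, optionally `z`).
#' @param nodes Optional node order for edge data frames.
#' @return A two-layer `multiplex` with layers `short` and `long`.
#' @export
split_by_distance <- function(x, coords, nodes = NULL) {
  g <- as_network_graph(x, nodes)
  if (igraph::gsize(g) < 2) stop("need at least 2 edges to split", call. = FALSE)
  nd <- node_distance_matrix(g, coords)
  el <- igraph::as_edgelist(g, names = FALSE)
  d <- nd[el]
  nm <- igraph::V(g)$name
  ef <- pmin(el[, 1], el[, 2])
  et <- pmax(el[, 1], el[, 2])
  ord <- order(d, ef, et)
  m <- length(ord)
  n_short <- ceiling(m / 2)
  short_idx <- ord[seq_len(n_short)]
  long_idx <- ord[seq(n_short + 1, m)]
  mk <- function(idx) tibble::tibble(from = nm[ef[idx]], to = nm[et[idx]])
  as_multiplex(list(short = mk(short_idx), long = mk(long_idx)),
               nodes = nm)
}

#' Group-consensus connectome
#'
#' For each node pair, if strictly more than half of the subjects have a
#' non-zero connection, the consensus weight is the mean over the subjects
#' with a non-zero connection; otherwise 0.
#'
#' @param subject_matrices A list of same-shaped non-negative weighted
#'   adjacency matrices with identical node order.
#' @return A weighted edge tibble (`from`, `to`, `weight`) over the upper
#'   triangle, with the node order kept in the `nodes` attribute.
#' @export
consensus_connectome <- function(subject_matrices) {
  dims <- unique(lapply(subject_matrices, dim))
  if (length(dims) != 1) stop("subject matrices differ in shape", call. = FALSE)
  if (any(vapply(subject_matrices, function(a) any(a < 0), TRUE))) {
    stop("weights must be non-negative", call. = FALSE)
  }
  n <- dims[[1]][1]
  ns <- length(subject_matrices)
  nz <- Reduce(`+`, lapply(subject_matrices, function(a) (a != 0) * 1))
  tot <- Reduce(`+`, subject_matrices)
  cons <- ifelse(nz > ns / 2, tot / pmax(nz, 1), 0)
  nodes <- rownames(subject_matrices[[1]])
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  ut <- which(upper.tri(cons) & cons > 0, arr.ind = TRUE)
  out <- tibble::tibble(from = nodes[ut[, 1]], to = nodes[ut[, 2]],
                        weight = cons[ut])
  attr(out, "nodes") <- nodes
  out
}

#' Threshold a weighted matrix to a target edge count
#'
#' "Structural density matching": keep exactly the `target_edge_count`
#' strongest edges of a weighted (e.g. functional-correlation) matrix, so
#' the binarized network has the same density as a reference structural
#' network. Weights are ranked by absolute value by default (set
#' `absolute = FALSE` to rank signed values); ties at the cutoff are broken
#' by canonical (row, column) order.
#'
#' @param w A symmetric weighted matrix.
#' @param target_edge_count Number of edges to keep.
#' @param absolute Rank by `|w|` (default) or signed `w`.
#' @return A binary edge tibble (`from`, `to`) with the node order in the
#'   `nodes` attribute.
#' @export
match_density <- function(w, target_edge_count, absolute = TRUE) {
  n <- nrow(w)
  nodes <- rownames(w)
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  ut <- which(upper.tri(w), arr.ind = TRUE)
  val <- w[upper.tri(w)]
  score <- if (absolute) abs(val) else val
  nonzero <- sum(score != 0)
  if (target_edge_count > nonzero) {
    stop("target_edge_count exceeds available non-zero entries", call. = FALSE)
  }
  ord <- order(-score, ut[, 1], ut[, 2])
  keep <- ord[seq_len(target_edge_count)]
  out <- tibble::tibble(from = nodes[ut[keep, 1]], to = nodes[ut[keep, 2]])
  attr(out, "nodes") <- nodes
  out
}
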