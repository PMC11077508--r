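#' Two-layer partial network decomposition of global efficiency
#'
#' Decomposes the global efficiency of the joint network of a two-layer
#' multiplex into redundant, unique and synergistic contributions. For each
#' unordered node pair with per-layer efficiencies `f_A`, `f_B` and joint
#' efficiency `f_AB`, the atoms are
#' \deqn{r = \min(f_A, f_B), \quad u_j = f_j - r, \quad
#'       s = f_{AB} - \max(f_A, f_B),}
#' which are non-negative and sum exactly to `f_AB`. Averaging under the pair
#' weighting yields the global atoms `R + U_A + U_B + S = F(joint)`.
#'
#' Each pair is also classified by its dominant character from the layer and
#' joint shortest-path lengths: synergistic if `min(l_A, l_B) > l_joint`,
#' unique to the layer achieving the minimum if `min = l_joint < max`,
#' redundant if `max(l_A, l_B) = l_joint`, and unreachable if the pair is
#' disconnected even in the joint network. Direct edges (length-1 pairs) can
#' only be redundant or unique.
#'
#' @param x A two-layer `multiplex` object, or anything `as_multiplex()`
#'   accepts (long edge list with a `layer` column, list of edge lists).
#' @param weights Optional symmetric pair-weight matrix (normalized
#'   internally); `NULL` for the uniform weighting over unordered distinct
#'   pairs, which makes `F` the global efficiency.
#' @param per_pair Keep the per-pair table? Set `FALSE` for a fast summary
#'   (used by the simulation experiments).
#' @return An object of class `pnd_decomposition` with fields
#'   `atoms` (named: `R`, `U_A`, `U_B`, `S`), `F_joint`, `class_counts`,
#'   `layer_names`, `n_nodes`, `n_pairs`, `n_unreachable` and (optionally)
#'   `per_pair`, a tibble with one row per unordered node pair. Use `tidy()`,
#'   `glance()`, `by_length_profile()`, `edgewise_networks()` and
#'   `autoplot()` on it.
#' @examples
#' edges <- tibble::tibble(
#'   from  = c("1", "2", "3", "1", "2"),
#'   to    = c("2", "3", "4", "3", "4"),
#'   layer = c("A", "A", "A", "B", "B")
#' )
#' res <- decompose_efficiency(edges)
#' glance(res)   # R = 1/6, U_A = 5/9, U_B = 1/6, S = 1/36
#' @export
decompose_efficiency <- function(x, weights = NULL, per_pair = TRUE) {
  m <- as_multiplex(x)
  if (n_layers(m) != 2) {
    stop("decompose_efficiency() is for exactly 2 layers; ",
         "use pnd_lattice() for N > 2", call. = FALSE)
  }
  n <- length(m$nodes)
  dA <- shortest_path_lengths(m$layers[[1]])
  dB <- shortest_path_lengths(m$layers[[2]])
  dJ <- shortest_path_lengths(joint_network(m))
  decompose_from_lengths(dA, dB, dJ, m, weights, per_pair)
}

# core arithmetic, shared with the fast simulation paths
decompose_from_lengths <- function(dA, dB, dJ, m, weights = NULL,
                                   per_pair = TRUE) {
  n <- nrow(dA)
  ut <- upper.tri(dA)
  w <- pair_weight_matrix(n, weights)

  eA <- ifelse(is.finite(dA), 1 / dA, 0); diag(eA) <- 0
  eB <- ifelse(is.finite(dB), 1 / dB, 0); diag(eB) <- 0
  eJ <- ifelse(is.finite(dJ), 1 / dJ, 0); diag(eJ) <- 0

  r <- pmin(eA, eB)
  uA <- eA - r
  uB <- eB - r
  s <- eJ - pmax(eA, eB)

  atoms <- c(
    R = sum(r * w),
    U_A = sum(uA * w),
    U_B = sum(uB * w),
    S = sum(s * w)
  )
  f_joint <- sum(eJ * w)

  lA <- dA[ut]; lB <- dB[ut]; lJ <- dJ[ut]
  cls <- classify_pair(lA, lB, lJ)
  lab <- class_label(cls, m$layer_names)
  cc <- table(factor(lab, levels = class_levels(m$layer_names)))
  class_counts <- tibble::tibble(class = names(cc), n = as.integer(cc))

  res <- structure(
    list(
      atoms = atoms,
      F_joint = f_joint,
      class_counts = class_counts,
      layer_names = m$layer_names,
      n_nodes = n,
      n_pairs = n * (n - 1) / 2,
      n_unreachable = sum(cls == "unreachable"),
      per_pair = NULL
    ),
    class = "pnd_decomposition"
  )

  if (per_pair) {
    iu <- which(ut, arr.ind = TRUE)
    gain <- pair_gain_values(lA, lB, lJ, cls)
    res$per_pair <- tibble::tibble(
      node_u = m$nodes[iu[, 1]],
      node_v = m$nodes[iu[, 2]],
      l_A = lA, l_B = lB, l_joint = lJ,
      f_A = eA[ut], f_B = eB[ut], f_joint = eJ[ut],
      r = r[ut], u_A = uA[ut], u_B = uB[ut], s = s[ut],
      class = lab,
      gain = gain
    )
  }
  res
}

#' Classify a node pair from its shortest-path lengths
#'
#' Vectorized over the three length arguments. The three classification
#' conditions are mutually exclusive and exhaustive for reachable pairs:
#' synergistic if `min(l_A, l_B) > l_joint`; unique (to the layer achieving
#' the minimum) if `min(l_A, l_B) = l_joint < max(l_A, l_B)`; redundant if
#' `max(l_A, l_B) = l_joint`. A pair disconnected in the joint network is
#' `"unreachable"`.
#'
#' @param l_A,l_B,l_joint Shortest-path lengths in layer A, layer B, and the
#'   joint network (`Inf` for disconnected pairs).
#' @param tol Tolerance for length comparisons (only relevant for weighted
#'   path lengths; binary lengths are exact integers).
#' @return Character vector over
#'   `{"synergistic", "unique_A", "unique_B", "redundant", "unreachable"}`.
#' @export
classify_pair <- function(l_A, l_B, l_joint, tol = 1e-9) {
  lmin <- pmin(l_A, l_B)
  lmax <- pmax(l_A, l_B)
  bad <- (is.finite(l_joint) & lmin < l_joint - tol) |
    (is.infinite(l_joint) & is.finite(lmin))
  if (any(bad)) {
    stop("l_joint exceeds min(l_A, l_B): shortest paths cannot lengthen ",
         "under edge union", call. = FALSE)
  }
  out <- rep("redundant", length(l_joint))
  out[is.infinite(l_joint)] <- "unreachable"
  syn <- is.finite(l_joint) & lmin > l_joint + tol
  out[syn] <- "synergistic"
  unq <- is.finite(l_joint) & !syn & lmax > l_joint + tol
  out[unq & l_A <= l_B] <- "unique_A"
  out[unq & l_B < l_A] <- "unique_B"
  out
}

class_levels <- function(layer_names) {
  c("redundant", paste0("unique:", layer_names), "synergistic", "unreachable")
}

class_label <- function(cls, layer_names) {
  lab <- cls
  lab[cls == "unique_A"] <- paste0("unique:", layer_names[1])
  lab[cls == "unique_B"] <- paste0("unique:", layer_names[2])
  lab
}

# gain in path length against the next-best alternative (steps);
# Inf when the alternative is disconnected; NA for unreachable pairs
pair_gain_values <- function(l_A, l_B, l_joint, cls) {
  gain <- numeric(length(cls))
  syn <- cls == "synergistic"
  gain[syn] <- pmin(l_A, l_B)[syn] - l_joint[syn]
  unq <- cls %in% c("unique_A", "unique_B")
  gain[unq] <- pmax(l_A, l_B)[unq] - l_joint[unq]
  gain[cls == "unreachable"] <- NA_real_
  gain
}

#' Per-pair atoms of the two-layer decomposition
#'
#' Applies the atom formulas to given pair efficiencies: `r = min(f_A, f_B)`,
#' `u_j = f_j - r`, `s = f_AB - max(f_A, f_B)`. Vectorized.
#'
#' @param f_A,f_B,f_AB Pair efficiencies in each layer and the joint network;
#'   `f_AB >= max(f_A, f_B)` is required (unions cannot lower efficiency).
#' @return A tibble with columns `r`, `u_A`, `u_B`, `s`.
#' @export
pair_atoms <- function(f_A, f_B, f_AB) {
  if (any(f_AB < pmax(f_A, f_B) - 1e-12)) {
    stop("f_AB < max(f_A, f_B): joint efficiency cannot be below a layer's",
         call. = FALSE)
  }
  r <- pmin(f_A, f_B)
  tibble::tibble(r = r, u_A = f_A - r, u_B = f_B - r,
                 s = f_AB - pmax(f_A, f_B))
}

# ---- methods ---------------------------------------------------------------

#' @export
print.pnd_decomposition <- function(x, ...) {
  cat("<partial network decomposition (efficiency, 2 layers)>\n")
  cat(sprintf("  layers : %s\n", paste(x$layer_names, collapse = " + ")))
  cat(sprintf("  nodes  : %d   pairs: %d (%d unreachable)\n",
              x$n_nodes, x$n_pairs, x$n_unreachable))
  cat(sprintf("  F(joint) = %.6f\n", x$F_joint))
  a <- x$atoms
  cat(sprintf("  R = %.6f   U_%s = %.6f   U_%s = %.6f   S = %.6f\n",
              a[["R"]], x$layer_names[1], a[["U_A"]],
              x$layer_names[2], a[["U_B"]], a[["S"]]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-pair table of a decomposition
#'
#' @param x A `pnd_decomposition` object (built with `per_pair = TRUE`).
#' @param ... Unused.
#' @return A tibble with one row per unordered node pair: lengths,
#'   efficiencies, atoms, class label and gain.
#' @export
tidy.pnd_decomposition <- function(x, ...) {
  if (is.null(x$per_pair)) {
    stop("decomposition was computed with per_pair = FALSE", call. = FALSE)
  }
  x$per_pair
}

#' One-row summary of a decomposition
#'
#' @param x A `pnd_decomposition` object.
#' @param ... Unused.
#' @return A one-row tibble: `F_joint`, the four global atoms, node/pair
#'   counts.
#' @export
glance.pnd_decomposition <- function(x, ...) {
  tibble::tibble(
    F_joint = x$F_joint,
    R = x$atoms[["R"]],
    U_A = x$atoms[["U_A"]],
    U_B = x$atoms[["U_B"]],
    S = x$atoms[["S"]],
    n_nodes = x$n_nodes,
    n_pairs = x$n_pairs,
    n_unreachable = x$n_unreachable
  )
}

#' Class proportions of a decomposition
#'
#' Proportion of node pairs per dominant class. By default proportions are
#' over reachable pairs (pairs disconnected even in the joint network are
#' excluded from the denominator); set `include_unreachable = TRUE` to report
#' over all pairs instead.
#'
#' @param x A `pnd_decomposition` object.
#' @param include_unreachable Count unreachable pairs in the denominator?
#' @return A tibble with columns `class`, `n`, `proportion`.
#' @export
class_proportions <- function(x, include_unreachable = FALSE) {
  cc <- x$class_counts
  if (!include_unreachable) {
    cc <- cc[cc$class != "unreachable", , drop = FALSE]
  }
  denom <- sum(cc$n)
  cc$proportion <- if (denom > 0) cc$n / denom else NA_real_
  cc
}

#' Length-stratified class profile
#'
#' Groups reachable pairs by their joint shortest-path length and reports the
#' proportion of each dominant class among pairs of that length. Rows for a
#' given length sum to 1; the length-1 row can contain no synergistic pairs
#' (a direct edge is already maximally efficient).
#'
#' @param x A `pnd_decomposition` object with a per-pair table.
#' @param wide Return one column per class (`TRUE`) or a long tibble
#'   (`FALSE`, default).
#' @return A tibble with columns `l_joint`, `class`, `n`, `proportion`
#'   (long), or `l_joint` plus one proportion column per class (wide).
#' @export
by_length_profile <- function(x, wide = FALSE) {
  pp <- tidy(x)
  pp <- pp[pp$class != "unreachable", , drop = FALSE]
  out <- pp |>
    dplyr::count(.data$l_joint, .data$class, name = "n") |>
    tidyr::complete(
      l_joint = unique(pp$l_joint),
      class = class_levels(x$layer_names)[1:4],
      fill = list(n = 0L)
    ) |>
    dplyr::group_by(.data$l_joint) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$l_joint, .data$class)
  if (wide) {
    out <- tidyr::pivot_wider(
      out[, c("l_joint", "class", "proportion")],
      names_from = "class", values_from = "proportion"
    )
  }
  out
}

#' Gain of a single pair against the next-best alternative
#'
#' For a synergistic pair, the number of steps saved by the joint network
#' relative to the better single layer; for a unique pair, the steps saved by
#' the better layer relative to the worse one (`Inf` when the other layer
#' disconnects the pair); 0 for redundant pairs.
#'
#' @param x A `pnd_decomposition` object with a per-pair table.
#' @param node_u,node_v Node labels of the pair.
#' @return A single number (possibly `Inf`; `NA` for unreachable pairs).
#' @export
pair_gain <- function(x, node_u, node_v) {
  pp <- tidy(x)
  hit <- (pp$node_u == node_u & pp$node_v == node_v) |
    (pp$node_u == node_v & pp$node_v == node_u)
  if (!any(hit)) {
    stop("pair (", node_u, ", ", node_v, ") not found", call. = FALSE)
  }
  pp$gain[hit][1]
}

#' Edge-wise mode networks
#'
#' Assigns every reachable node pair to exactly one of four networks —
#' redundant, unique to each layer, synergistic — weighted by the pair's
#' gain. Redundant pairs are carried with weight 0 (present, as opposed to
#' absent); unreachable pairs are omitted.
#'
#' @param x A `pnd_decomposition` object with a per-pair table.
#' @return A named list of four edge tibbles (`from`, `to`, `weight`), one
#'   per mode, whose pair sets partition the reachable pairs.
#' @export
edgewise_networks <- function(x) {
  pp <- tidy(x)
  pp <- pp[pp$class != "unreachable", , drop = FALSE]
  modes <- class_levels(x$layer_names)[1:4]
  out <- lapply(modes, function(md) {
    sub <- pp[pp$class == md, , drop = FALSE]
    tibble::tibble(from = sub$node_u, to = sub$node_v, weight = sub$gain)
  })
  names(out) <- modes
  out
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a two-layer decomposition
#'
#' Bar chart of the four global atoms next to the dominant-class proportions.
#'
#' @param object A `pnd_decomposition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pnd_decomposition <- function(object, ...) {
  a <- object$atoms
  atom_tbl <- tibble::tibble(
    term = factor(c("R", paste0("U:", object$layer_names), "S"),
                  levels = c("R", paste0("U:", object$layer_names), "S")),
    value = as.numeric(a),
    panel = "global atoms"
  )
  prop_tbl <- class_proportions(object)
  prop_tbl <- tibble::tibble(
    term = factor(prop_tbl$class, levels = prop_tbl$class),
    value = prop_tbl$proportion,
    panel = "class proportions"
  )
  df <- dplyr::bind_rows(atom_tbl, prop_tbl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$value,
                                   fill = .data$term)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the length-stratified class profile
#'
#' Stacked proportions of dominant classes as a function of joint
#' shortest-path length.
#'
#' @param x A `pnd_decomposition` object with a per-pair table.
#' @return A ggplot object.
#' @export
plot_by_length <- function(x) {
  prof <- by_length_profile(x)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$l_joint, y = .data$proportion,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "joint shortest-path length", y = "proportion of pairs",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
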