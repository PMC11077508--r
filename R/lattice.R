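#' General N-layer decomposition on the antichain lattice
#'
#' The general decomposition evaluates a redundancy function on every
#' antichain of nonempty layer subsets and Moebius-inverts it over the
#' lattice to obtain the atoms. An antichain `a = {a_1, ..., a_L}` is a
#' collection of layer subsets none of which contains another; the
#' redundancy function used here is
#' \deqn{F_\cap(\alpha) = E\left[\min_{a \in \alpha} f(\Omega; E_a)\right],}
#' the expected minimum, across the antichain's elements, of the pair
#' efficiency in the joint network of that element. Atoms follow by
#' \deqn{F_\partial(\alpha) = F_\cap(\alpha) -
#'       \sum_{\beta \prec \alpha} F_\partial(\beta),}
#' and sum to the global efficiency of the full joint network. For two
#' layers the four atoms are exactly the R, U_A, U_B, S of
#' [decompose_efficiency()].
#'
#' The partial order is the redundancy-lattice order used in partial
#' information decomposition: `alpha <= beta` iff every element of `beta`
#' contains some element of `alpha`.
#'
#' @name pnd_lattice
NULL

# antichains are represented internally as integer vectors of bitmasks,
# one bit per layer; element {1,3} of a 3-layer multiplex is mask 0b101 = 5

mask_subset <- function(a, b) bitwAnd(a, b) == a

mask_to_set <- function(mask, n) which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)

set_to_mask <- function(set) sum(bitwShiftL(1L, as.integer(set) - 1L))

antichain_label <- function(masks, n) {
  sets <- lapply(sort(masks), mask_to_set, n = n)
  sets <- sets[order(lengths(sets), vapply(sets, paste, "", collapse = ","))]
  paste0("{", paste(vapply(sets, function(s) {
    paste0("{", paste(s, collapse = ","), "}")
  }, ""), collapse = ""), "}")
}

#' Enumerate all antichains of nonempty layer subsets
#'
#' Returns every collection of pairwise-incomparable nonempty subsets of
#' `{1, ..., n_layers}` (excluding the empty collection) in a canonical
#' order: by lattice rank (bottom first), then lexicographically by label.
#' Counts are 1, 4, 18, 166 for 1-4 layers; larger `n_layers` is refused
#' (antichain counts grow as the Dedekind numbers).
#'
#' @param n_layers Number of layers (1 to 4).
#' @return A tibble with columns `id`, `label`, `rank` and a list-column
#'   `antichain` whose entries are lists of integer vectors (the layer
#'   subsets).
#' @export
enumerate_antichains <- function(n_layers) {
  lat <- antichain_lattice(n_layers)
  tibble::tibble(
    id = seq_along(lat$chains),
    label = lat$labels,
    rank = lat$rank,
    antichain = lapply(lat$chains, function(masks) {
      lapply(sort(masks), mask_to_set, n = n_layers)
    })
  )
}

# full lattice structure: chains (list of mask vectors, canonical order),
# labels, leq matrix, rank
antichain_lattice <- function(n_layers) {
  if (n_layers < 1 || n_layers > 4) {
    stop("antichain lattice supported for 1 to 4 layers ",
         "(antichain counts grow as the Dedekind numbers)", call. = FALSE)
  }
  subsets <- seq_len(2^n_layers - 1)           # all nonempty subset masks
  ns <- length(subsets)
  # comparability between subset masks
  comp <- outer(subsets, subsets, function(a, b) {
    mapply(function(x, y) mask_subset(x, y) || mask_subset(y, x), a, b)
  })
  chains <- list()
  for (pick in seq_len(2^ns - 1)) {            # nonempty collections
    idx <- which(bitwAnd(pick, bitwShiftL(1L, 0:(ns - 1))) != 0L)
    if (length(idx) > 1) {
      sub <- comp[idx, idx, drop = FALSE]
      diag(sub) <- FALSE
      if (any(sub)) next                       # some pair comparable
    }
    chains[[length(chains) + 1L]] <- subsets[idx]
  }
  nn <- length(chains)
  leq <- matrix(FALSE, nn, nn)
  for (i in seq_len(nn)) {
    for (j in seq_len(nn)) {
      leq[i, j] <- all(vapply(chains[[j]], function(b) {
        any(vapply(chains[[i]], function(a) mask_subset(a, b), TRUE))
      }, TRUE))
    }
  }
  # rank = longest chain from the bottom
  rank <- rep(NA_integer_, nn)
  remaining <- seq_len(nn)
  level <- 0L
  while (length(remaining)) {
    minimal <- remaining[vapply(remaining, function(j) {
      !any(leq[remaining, j] & remaining != j)
    }, TRUE)]
    rank[minimal] <- level
    remaining <- setdiff(remaining, minimal)
    level <- level + 1L
  }
  labels <- vapply(chains, antichain_label, "", n = n_layers)
  ord <- order(rank, labels)
  list(
    chains = chains[ord],
    labels = labels[ord],
    rank = rank[ord],
    leq = leq[ord, ord, drop = FALSE]
  )
}

#' Partial order on antichains
#'
#' `alpha` precedes `beta` iff every element of `beta` contains some element
#' of `alpha` (the redundancy-lattice order).
#'
#' @param alpha,beta Antichains: lists of integer vectors (layer subsets).
#' @param n_layers Number of layers both antichains live over.
#' @return `TRUE` or `FALSE`.
#' @export
antichain_leq <- function(alpha, beta, n_layers) {
  am <- vapply(alpha, set_to_mask, 0)
  bm <- vapply(beta, set_to_mask, 0)
  lim <- 2^n_layers - 1
  if (any(c(am, bm) > lim) || any(c(am, bm) < 1)) {
    stop("antichain elements must be nonempty subsets of 1..n_layers",
         call. = FALSE)
  }
  all(vapply(bm, function(b) any(vapply(am, function(a) {
    mask_subset(as.integer(a), as.integer(b))
  }, TRUE)), TRUE))
}

#' Redundancy function of an antichain
#'
#' The expectation over node pairs of the minimum, across the antichain's
#' elements, of the pair efficiency in the joint network of that element.
#' Satisfies self-intersection (`F_cap({a}) = F(E_a)`), symmetry,
#' deterministic equality and monotonicity.
#'
#' @param m A `multiplex` object (or anything `as_multiplex()` accepts).
#' @param alpha An antichain: list of integer vectors of layer indices
#'   (a single vector is taken as a one-element antichain).
#' @param weights Optional pair-weight matrix; `NULL` for uniform.
#' @return A single number.
#' @export
redundancy_fn <- function(m, alpha, weights = NULL) {
  m <- as_multiplex(m)
  if (!is.list(alpha)) alpha <- list(alpha)
  n <- length(m$nodes)
  w <- pair_weight_matrix(n, weights)
  effs <- lapply(alpha, function(a) pairwise_efficiency(joint_network(m, a)))
  emin <- Reduce(pmin, effs)
  sum(emin * w)
}

#' N-layer decomposition over the antichain lattice
#'
#' Computes the redundancy function on every antichain and Moebius-inverts
#' it bottom-up to obtain the atoms. All atoms are non-negative and sum to
#' the global efficiency of the full joint network.
#'
#' @param x A `multiplex` object with 2-4 layers.
#' @param weights Optional pair-weight matrix; `NULL` for uniform.
#' @param per_pair Also keep per-pair atom matrices (needed by
#'   [dominant_character()])?
#' @return An object of class `pnd_lattice`: list with `table` (tibble of
#'   `id`, `label`, `rank`, `antichain`, `f_cap`, `f_atom`), `F_joint`,
#'   `layer_names`, `nodes`, and internal per-pair state when requested.
#' @examples
#' edges <- tibble::tibble(
#'   from  = c("1", "2", "3", "1", "2"),
#'   to    = c("2", "3", "4", "3", "4"),
#'   layer = c("A", "A", "A", "B", "B")
#' )
#' lat <- pnd_lattice(edges)
#' lat$table[, c("label", "f_cap", "f_atom")]
#' @export
pnd_lattice <- function(x, weights = NULL, per_pair = FALSE) {
  m <- as_multiplex(x)
  N <- n_layers(m)
  lat <- antichain_lattice(N)
  n <- length(m$nodes)
  ut <- upper.tri(matrix(0, n, n))
  w <- pair_weight_matrix(n, weights)
  wv <- w[ut]

  # efficiency matrices for every distinct nonempty layer subset
  subset_eff <- vector("list", 2^N - 1)
  for (mask in seq_len(2^N - 1)) {
    subset_eff[[mask]] <- pairwise_efficiency(
      joint_network(m, mask_to_set(mask, N))
    )[ut]
  }

  nn <- length(lat$chains)
  fcap_pair <- matrix(0, nrow = sum(ut), ncol = nn)
  for (i in seq_len(nn)) {
    fcap_pair[, i] <- Reduce(pmin, subset_eff[lat$chains[[i]]])
  }
  f_cap <- as.numeric(crossprod(fcap_pair, wv))

  # Moebius inversion in rank order (strict lower sets already computed)
  fatom_pair <- matrix(0, nrow = nrow(fcap_pair), ncol = nn)
  ord <- order(lat$rank)
  for (i in ord) {
    below <- which(lat$leq[, i] & seq_len(nn) != i)
    fatom_pair[, i] <- fcap_pair[, i] -
      if (length(below)) rowSums(fatom_pair[, below, drop = FALSE]) else 0
  }
  f_atom <- as.numeric(crossprod(fatom_pair, wv))

  top <- which(lat$rank == max(lat$rank))
  res <- structure(
    list(
      table = tibble::tibble(
        id = seq_len(nn),
        label = lat$labels,
        rank = lat$rank,
        antichain = lapply(lat$chains, function(masks) {
          lapply(sort(masks), mask_to_set, n = N)
        }),
        f_cap = f_cap,
        f_atom = f_atom
      ),
      F_joint = f_cap[top],
      layer_names = m$layer_names,
      nodes = m$nodes,
      leq = lat$leq
    ),
    class = "pnd_lattice"
  )
  if (per_pair) {
    iu <- which(ut, arr.ind = TRUE)
    res$pair_index <- tibble::tibble(node_u = m$nodes[iu[, 1]],
                                     node_v = m$nodes[iu[, 2]])
    res$fcap_pair <- fcap_pair
    res$fatom_pair <- fatom_pair
  }
  res
}

#' @export
print.pnd_lattice <- function(x, ...) {
  cat(sprintf("<antichain-lattice decomposition: %d layers, %d atoms>\n",
              length(x$layer_names), nrow(x$table)))
  cat(sprintf("  F(joint) = %.6f   sum of atoms = %.6f\n",
              x$F_joint, sum(x$table$f_atom)))
  print(x$table[, c("label", "rank", "f_cap", "f_atom")], n = nrow(x$table))
  invisible(x)
}

#' @export
tidy.pnd_lattice <- function(x, ...) x$table

#' @export
glance.pnd_lattice <- function(x, ...) {
  tibble::tibble(
    F_joint = x$F_joint,
    n_layers = length(x$layer_names),
    n_atoms = nrow(x$table),
    atom_sum = sum(x$table$f_atom),
    min_atom = min(x$table$f_atom)
  )
}

#' Dominant character of each node pair
#'
#' The dominant character of a pair is the antichain with a strictly
#' positive per-pair atom such that every strictly greater antichain has a
#' zero atom. For two layers this is unique; for more layers uniqueness is
#' an open conjecture, so multiple qualifying antichains are reported with
#' `ambiguous = TRUE` rather than silently resolved. Pairs disconnected in
#' the full joint network get the sentinel `"none"`.
#'
#' @param x A `pnd_lattice` object built with `per_pair = TRUE`.
#' @param tol Atoms below `tol` count as zero.
#' @return A tibble: `node_u`, `node_v`, `dominant` (antichain label or
#'   `"none"`), `ambiguous`.
#' @export
dominant_character <- function(x, tol = 1e-12) {
  if (is.null(x$fatom_pair)) {
    stop("run pnd_lattice(..., per_pair = TRUE) first", call. = FALSE)
  }
  nn <- ncol(x$fatom_pair)
  leq <- x$leq
  res <- apply(x$fatom_pair, 1, function(atoms) {
    pos <- which(atoms > tol)
    if (!length(pos)) {
      return(c(NA_integer_, 0L))
    }
    # qualifying: positive atom, and no strictly greater antichain positive
    qual <- pos[vapply(pos, function(i) {
      above <- which(leq[i, ] & seq_len(nn) != i)
      !any(atoms[above] > tol)
    }, TRUE)]
    c(if (length(qual)) qual[1] else NA_integer_, length(qual))
  })
  tibble::tibble(
    node_u = x$pair_index$node_u,
    node_v = x$pair_index$node_v,
    dominant = ifelse(is.na(res[1, ]), "none", x$table$label[res[1, ]]),
    ambiguous = res[2, ] > 1
  )
}

#' Numerically verify the redundancy-function axioms
#'
#' Checks symmetry, self-intersection, deterministic equality and
#' monotonicity of the redundancy function on a multiplex network, over all
#' applicable antichain tuples (exhaustive for up to 3 layers).
#'
#' @param x A `multiplex` object (2-3 layers for exhaustive checks).
#' @param weights Optional pair-weight matrix.
#' @param tol Numerical tolerance for a violation.
#' @return A tibble: `axiom`, `n_checks`, `max_violation`, `pass`.
#' @export
verify_axioms <- function(x, weights = NULL, tol = 1e-12) {
  m <- as_multiplex(x)
  N <- n_layers(m)
  if (N > 3) stop("exhaustive axiom checks supported for up to 3 layers",
                  call. = FALSE)
  subsets <- lapply(seq_len(2^N - 1), mask_to_set, n = N)

  viol_sym <- 0; n_sym <- 0L
  viol_self <- 0; n_self <- 0L
  viol_det <- 0; n_det <- 0L
  viol_mono <- 0; n_mono <- 0L

  # self-intersection: F_cap({a}) = F(E_a)
  for (a in subsets) {
    v1 <- redundancy_fn(m, list(a), weights)
    v2 <- global_efficiency(joint_network(m, a), weights)
    viol_self <- max(viol_self, abs(v1 - v2)); n_self <- n_self + 1L
  }
  # pairs of subsets: symmetry, deterministic equality, monotonicity
  for (i in seq_along(subsets)) {
    for (j in seq_along(subsets)) {
      if (i == j) next
      a <- subsets[[i]]; b <- subsets[[j]]
      vab <- redundancy_fn(m, list(a, b), weights)
      vba <- redundancy_fn(m, list(b, a), weights)
      viol_sym <- max(viol_sym, abs(vab - vba)); n_sym <- n_sym + 1L
      va <- redundancy_fn(m, list(a), weights)
      viol_mono <- max(viol_mono, vab - va); n_mono <- n_mono + 1L
      if (all(a %in% b)) {
        # E_a subset of E_b: adding the superset argument changes nothing
        viol_det <- max(viol_det, abs(vab - va)); n_det <- n_det + 1L
      }
    }
  }
  tibble::tibble(
    axiom = c("symmetry", "self_intersection", "deterministic_equality",
              "monotonicity"),
    n_checks = c(n_sym, n_self, n_det, n_mono),
    max_violation = c(viol_sym, viol_self, viol_det, viol_mono),
    pass = c(viol_sym, viol_self, viol_det, viol_mono) <= tol
  )
}

#' Serialize a lattice decomposition to JSON
#'
#' @param x A `pnd_lattice` object.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_lattice_json <- function(x, path) {
  out <- lapply(seq_len(nrow(x$table)), function(i) {
    list(
      antichain = x$table$antichain[[i]],
      label = x$table$label[i],
      f_cap = x$table$f_cap[i],
      f_atom = x$table$f_atom[i]
    )
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
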