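# Independent oracles, kept deliberately naive: Floyd-Warshall distances,
# literal per-pair atom formulas, and a set-based antichain Moebius
# inversion. None of them share code with the package internals.

fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj != 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

adj_of_layer <- function(m, idx) {
  gs <- m$layers[idx]
  a <- matrix(0, length(m$nodes), length(m$nodes))
  for (g in gs) {
    el <- igraph::as_edgelist(g, names = TRUE)
    if (nrow(el)) {
      i <- match(el[, 1], m$nodes); j <- match(el[, 2], m$nodes)
      a[cbind(i, j)] <- 1
      a[cbind(j, i)] <- 1
    }
  }
  a
}

eff_of <- function(d) {
  e <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  diag(e) <- 0
  e
}

# literal two-layer decomposition: fresh Floyd-Warshall on each layer and the
# union, atom formulas applied pair by pair, uniform average
brute_decompose <- function(m) {
  aA <- adj_of_layer(m, 1)
  aB <- adj_of_layer(m, 2)
  aJ <- pmax(aA, aB)
  eA <- eff_of(fw_distances(aA))
  eB <- eff_of(fw_distances(aB))
  eJ <- eff_of(fw_distances(aJ))
  n <- nrow(aA)
  R <- UA <- UB <- S <- 0
  np <- n * (n - 1) / 2
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      r <- min(eA[i, j], eB[i, j])
      R <- R + r / np
      UA <- UA + (eA[i, j] - r) / np
      UB <- UB + (eB[i, j] - r) / np
      S <- S + (eJ[i, j] - max(eA[i, j], eB[i, j])) / np
    }
  }
  list(R = R, U_A = UA, U_B = UB, S = S,
       F_joint = sum(eJ[upper.tri(eJ)]) / np)
}

# set-based antichain machinery, independent of the bitmask implementation
oracle_antichains <- function(N) {
  subsets <- unlist(lapply(seq_len(N), function(k) {
    utils::combn(N, k, simplify = FALSE)
  }), recursive = FALSE)
  is_sub <- function(a, b) all(a %in% b)
  out <- list()
  ns <- length(subsets)
  for (sel in seq_len(2^ns - 1)) {
    take <- which(bitwAnd(sel, bitwShiftL(1L, 0:(ns - 1))) != 0L)
    col <- subsets[take]
    ok <- TRUE
    if (length(col) > 1) {
      for (i in seq_along(col)) {
        for (j in seq_along(col)) {
          if (i != j && is_sub(col[[i]], col[[j]])) ok <- FALSE
        }
      }
    }
    if (ok) out[[length(out) + 1]] <- col
  }
  out
}

oracle_leq <- function(alpha, beta) {
  all(vapply(beta, function(b) {
    any(vapply(alpha, function(a) all(a %in% b), TRUE))
  }, TRUE))
}

# naive Moebius inversion by recursive definition with memoisation on labels
oracle_moebius <- function(chains, f_cap) {
  lbl <- vapply(chains, function(ch) {
    paste(sort(vapply(ch, paste, "", collapse = ",")), collapse = "|")
  }, "")
  memo <- new.env()
  atom <- function(i) {
    key <- lbl[i]
    if (!is.null(memo[[key]])) return(memo[[key]])
    below <- setdiff(which(vapply(seq_along(chains), function(j) {
      oracle_leq(chains[[j]], chains[[i]])
    }, TRUE)), i)
    v <- f_cap[i] - sum(vapply(below, atom, 0))
    memo[[key]] <- v
    v
  }
  vapply(seq_along(chains), atom, 0)
}

# random multiplex on n nodes: each layer is an independent G(n, p) layer;
# resampled until the union has at least one edge
rand_multiplex <- function(n, p = 0.3, n_layers = 2,
                           layer_names = LETTERS[seq_len(n_layers)]) {
  repeat {
    layers <- lapply(seq_len(n_layers), function(k) {
      pairs <- t(utils::combn(n, 2))
      keep <- stats::runif(nrow(pairs)) < p
      tibble::tibble(from = as.character(pairs[keep, 1]),
                     to = as.character(pairs[keep, 2]))
    })
    if (sum(vapply(layers, nrow, 0L)) > 0) break
  }
  names(layers) <- layer_names
  as_multiplex(layers)
}

worked_example <- function() {
  tibble::tibble(
    from  = c("1", "2", "3", "1", "2"),
    to    = c("2", "3", "4", "3", "4"),
    layer = c("A", "A", "A", "B", "B")
  )
}
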