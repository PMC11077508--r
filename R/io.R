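#' Readers and writers for network files
#'
#' Plain-text formats: delimited edge lists (columns `source, target`,
#' optionally `weight` and `layer`; `from`/`to` headers also accepted),
#' dense adjacency matrices with node labels as header row and first
#' column, and node coordinate tables (`node, x, y[, z]`).
#'
#' @name io
NULL

guess_delim <- function(path) {
  if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a delimited edge list
#'
#' @param path File path (`.csv` comma-delimited, `.tsv` tab-delimited;
#'   override with `delim`).
#' @param delim Field delimiter; guessed from the extension by default.
#' @return An edge tibble with columns `from`, `to` and any of `weight`,
#'   `layer` present in the file.
#' @export
read_edgelist <- function(path, delim = guess_delim(path)) {
  el <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          trim_ws = TRUE)
  normalize_edge_cols(el)
}

#' Write an edge list
#'
#' Columns are written as `source, target[, weight][, layer]`.
#'
#' @param edges An edge tibble (`from`/`to` or `source`/`target`).
#' @param path Output path; delimiter guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(edges, path) {
  el <- normalize_edge_cols(edges)
  out <- dplyr::rename(el, source = "from", target = "to")
  readr::write_delim(out, path, delim = guess_delim(path))
  invisible(path)
}

#' Read a dense adjacency matrix
#'
#' Expects node labels in the header row and in the first column.
#'
#' @inheritParams read_edgelist
#' @return A symmetric numeric matrix with node labels as dimnames.
#' @export
read_adjacency <- function(path, delim = guess_delim(path)) {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  nodes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(mat), nodes)) {
    stop("adjacency header labels do not match the first column", call. = FALSE)
  }
  storage.mode(mat) <- "double"
  rownames(mat) <- nodes
  if (max(abs(mat - t(mat))) > 1e-12) {
    stop("adjacency matrix is not symmetric", call. = FALSE)
  }
  mat
}

#' Read node coordinates
#'
#' @inheritParams read_edgelist
#' @return A tibble `node`, `x`, `y`, `z` (z filled with 0 when absent).
#' @export
read_coords <- function(path, delim = guess_delim(path)) {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if (!all(c("node", "x", "y") %in% names(df))) {
    stop("coordinate file needs columns node, x, y", call. = FALSE)
  }
  df$node <- as.character(df$node)
  if (!"z" %in% names(df)) df$z <- 0
  tibble::as_tibble(df[, c("node", "x", "y", "z")])
}

#' Read a multilayer transport edge list (London dialect)
#'
#' Ingests a multilayer edge list whose `layer` column distinguishes train
#' system layers, e.g. the London rail multiplex with layers
#' `underground`, `overground` and `dlr`. The overground and DLR layers are
#' merged into a single `"overground"` layer (they form one interoperating
#' surface-rail system), yielding a two-layer underground-vs-overground
#' multiplex. Layers named `1`, `2`, `3` are interpreted in that
#' (underground, overground, DLR) order.
#'
#' @param path Path to a delimited edge list with a `layer` column.
#' @param delim Field delimiter; guessed from the extension.
#' @return A two-layer `multiplex` object.
#' @export
read_london_multiplex <- function(path, delim = guess_delim(path)) {
  if (!file.exists(path)) {
    stop("London transport file not found at '", path,
         "'. This dataset is an optional external input ",
         "(netzschleuder 'london_transport'); download it separately.",
         call. = FALSE)
  }
  el <- read_edgelist(path, delim)
  if (!"layer" %in% names(el)) {
    stop("multilayer edge list needs a `layer` column", call. = FALSE)
  }
  lay <- tolower(as.character(el$layer))
  lay[lay == "1"] <- "underground"
  lay[lay == "2"] <- "overground"
  lay[lay == "3"] <- "dlr"
  known <- c("underground", "overground", "dlr")
  if (!all(lay %in% known)) {
    stop("unrecognized layer label(s): ",
         paste(unique(lay[!lay %in% known]), collapse = ", "), call. = FALSE)
  }
  lay[lay == "dlr"] <- "overground"
  el$layer <- factor(lay, levels = c("underground", "overground"))
  as_multiplex(el[order(el$layer), ])
}

#' Write the per-pair table of a decomposition
#'
#' CSV with columns `node_u, node_v, l_A, l_B, l_joint, f_A, f_B, f_joint,
#' r, u_<layerA>, u_<layerB>, s, class, gain`; an infinite gain is
#' serialized as the string `"inf"`.
#'
#' @param x A `pnd_decomposition` with a per-pair table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(x, path) {
  pp <- tidy(x)
  names(pp)[names(pp) == "u_A"] <- paste0("u_", x$layer_names[1])
  names(pp)[names(pp) == "u_B"] <- paste0("u_", x$layer_names[2])
  pp$gain <- ifelse(is.infinite(pp$gain), "inf", as.character(pp$gain))
  readr::write_csv(pp, path)
  invisible(path)
}

#' Write the summary of a decomposition as JSON
#'
#' JSON object with the global atoms, joint efficiency, class counts and
#' length-stratified profile.
#'
#' @param x A `pnd_decomposition` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  u <- list(x$atoms[["U_A"]], x$atoms[["U_B"]])
  names(u) <- x$layer_names
  out <- list(
    R = x$atoms[["R"]],
    U = u,
    S = x$atoms[["S"]],
    F_joint = x$F_joint,
    class_counts = stats::setNames(as.list(x$class_counts$n),
                                   x$class_counts$class)
  )
  if (!is.null(x$per_pair)) {
    prof <- by_length_profile(x)
    out$by_length <- lapply(split(prof, prof$l_joint), function(df) {
      list(l = df$l_joint[1],
           proportions = stats::setNames(as.list(df$proportion), df$class))
    })
    names(out$by_length) <- NULL
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a null ensemble to CSV + JSON summary
#'
#' @param x A `pnd_null_ensemble` object.
#' @param csv_path Per-surrogate CSV (`surrogate`, atoms, proportions).
#' @param json_path JSON with observed values, null means/SDs and p-values.
#' @return `csv_path`, invisibly.
#' @export
write_ensemble <- function(x, csv_path, json_path = NULL) {
  readr::write_csv(x$nulls, csv_path)
  if (!is.null(json_path)) {
    tt <- test_against_null(x)
    out <- list(
      model = x$model, n_surrogates = x$n_surrogates, seed = x$seed,
      observed = as.list(x$observed),
      terms = lapply(split(tt, tt$term), as.list)
    )
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
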