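#' Read a network from a TSV edge list or a Pajek .net file
#'
#' TSV: one edge per line, two whitespace/tab-separated vertex ids (a third
#' numeric column, e.g. a weight, is ignored). The first line is treated as
#' a header iff its first two fields, lowercased, are one of the usual pairs
#' (`from`/`to`, `source`/`target`, `v1`/`v2`, `node1`/`node2`). Pajek: a
#' `*Vertices n` section with optional quoted labels, then `*Edges` with
#' 1-based vertex indices; vertex indices outside `1..n` are an error naming
#' the offending line.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension: `.net` is Pajek, anything else TSV),
#'   `"tsv"`, or `"pajek"`.
#' @param class_path Optional TSV (id, 0/1) assigning the binary display
#'   class of each vertex; unknown ids are an error.
#' @return An undirected simple igraph object.
#' @export
read_network <- function(path, format = c("auto", "tsv", "pajek"),
                         class_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.net$", path, ignore.case = TRUE)) "pajek" else "tsv"
  }
  g <- if (format == "pajek") read_pajek(path) else read_edge_tsv(path)
  if (!is.null(class_path)) {
    cls <- read.delim(class_path, header = FALSE, stringsAsFactors = FALSE)
    unknown <- setdiff(as.character(cls[[1]]), vertex_names(g))
    if (length(unknown)) {
      abort(paste0(
        "class file mentions unknown vertices: ",
        paste(head(unknown, 5), collapse = ", ")
      ))
    }
    flag <- setNames(as.integer(cls[[2]]), as.character(cls[[1]]))
    igraph::V(g)$class <- unname(flag[vertex_names(g)])
  }
  g
}

read_edge_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) abort("empty file")
  rows <- strsplit(trimws(lines[keep]), "[\t ]+")
  lineno <- which(keep)
  short <- lengths(rows) < 2
  if (any(short)) {
    abort(paste0("line ", lineno[short][1], ": expected two vertex ids"))
  }
  first <- tolower(rows[[1]][1:2])
  header_pairs <- list(
    c("from", "to"), c("source", "target"), c("v1", "v2"), c("node1", "node2")
  )
  if (any(vapply(header_pairs, identical, TRUE, y = first))) {
    rows <- rows[-1]
    if (!length(rows)) abort("empty file")
  }
  el <- t(vapply(rows, function(r) r[1:2], character(2)))
  network_from_edges(data.frame(from = el[, 1], to = el[, 2]))
}

read_pajek <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vhead <- grep("^\\*vertices", tolower(lines))
  if (!length(vhead)) abort("not a Pajek file: missing *Vertices")
  n <- as.integer(strsplit(trimws(lines[vhead[1]]), "\\s+")[[1]][2])
  if (is.na(n) || n < 1) abort("invalid *Vertices count")
  ehead <- grep("^\\*(edges|arcs)", tolower(lines))
  if (!length(ehead)) abort("not a Pajek file: missing *Edges")
  labels <- as.character(seq_len(n))
  for (i in seq((vhead[1] + 1), ehead[1] - 1)) {
    if (i > length(lines)) break
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    idx <- as.integer(sub("^(\\d+).*", "\\1", ln))
    if (is.na(idx) || idx < 1 || idx > n) {
      abort(paste0("line ", i, ": vertex index out of range"))
    }
    lab <- sub("^\\d+\\s*", "", ln)
    if (grepl('^"', lab)) lab <- sub('^"([^"]*)".*$', "\\1", lab)
    lab <- trimws(lab)
    if (nzchar(lab)) labels[idx] <- lab
  }
  el <- NULL
  for (i in seq(ehead[1] + 1, length(lines))) {
    if (i > length(lines)) break
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^\\*", ln)) next
    parts <- strsplit(ln, "\\s+")[[1]]
    ij <- suppressWarnings(as.integer(parts[1:2]))
    if (any(is.na(ij)) || any(ij < 1) || any(ij > n)) {
      abort(paste0("line ", i, ": vertex index out of range"))
    }
    el <- rbind(el, ij)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- labels
  if (!is.null(el)) g <- igraph::add_edges(g, t(el))
  igraph::simplify(g)
}

#' Write a network to TSV or Pajek
#'
#' @param network An undirected simple igraph object.
#' @param path Output file.
#' @param format `"tsv"` (edge list with a `from`/`to` header; isolated
#'   vertices are not representable and trigger a warning) or `"pajek"`
#'   (full vertex list with quoted labels, so isolated vertices survive a
#'   round trip).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "pajek")) {
  format <- match.arg(format)
  check_network(network)
  nm <- vertex_names(network)
  if (format == "tsv") {
    if (any(igraph::degree(network) == 0)) {
      warn("isolated vertices are dropped by the TSV edge-list format")
    }
    el <- igraph::as_edgelist(network)
    writeLines(
      c("from\tto", sprintf("%s\t%s", el[, 1], el[, 2])),
      path
    )
  } else {
    el <- igraph::as_edgelist(network, names = FALSE)
    writeLines(
      c(
        sprintf("*Vertices %d", length(nm)),
        sprintf('%d "%s"', seq_along(nm), nm),
        "*Edges",
        if (nrow(el)) sprintf("%d %d", el[, 1], el[, 2])
      ),
      path
    )
  }
  invisible(path)
}

#' Read a labeled square matrix from TSV/CSV
#'
#' The first row holds the column labels and the first column the row
#' labels; the separator is sniffed (tab unless the header contains commas
#' and no tabs). The matrix must be square with matching row/column labels
#' and symmetric within `tol`; the error message names the worst offending
#' pair.
#'
#' @param path Input file.
#' @param tol Symmetry tolerance (default 1e-9).
#' @return A labeled numeric matrix.
#' @export
read_matrix <- function(path, tol = 1e-9) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1)
  sep <- if (grepl(",", header) && !grepl("\t", header)) "," else "\t"
  df <- read.delim(path,
    sep = sep, header = TRUE, row.names = 1,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  m <- check_square_labeled(m, "matrix")
  check_symmetric(m, tol = tol, what = basename(path))
  m
}

#' Write a labeled square matrix to TSV at full precision
#'
#' Numbers are written with 17 significant digits, enough for a bit-exact
#' round trip through [read_matrix()].
#'
#' @param m Labeled numeric matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  m <- check_square_labeled(m, "matrix")
  body <- apply(m, 1, function(row) {
    paste(sprintf("%.17g", row), collapse = "\t")
  })
  writeLines(
    c(
      paste(c("", colnames(m)), collapse = "\t"),
      paste(rownames(m), body, sep = "\t")
    ),
    path
  )
  invisible(path)
}

#' Write a layout to TSV
#'
#' Columns `vertex_id`, `component_index`, `x`, `y`, with a header line and
#' full float precision (17 significant digits).
#'
#' @param layout A layout tibble with columns `vertex`, `component`, `x`,
#'   `y` (e.g. from [fragviz_layout()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(all(c("vertex", "component", "x", "y") %in% names(layout)))
  writeLines(
    c(
      "vertex_id\tcomponent_index\tx\ty",
      sprintf(
        "%s\t%d\t%.17g\t%.17g",
        layout$vertex, as.integer(layout$component), layout$x, layout$y
      )
    ),
    path
  )
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  expected <- c("vertex_id", "component_index", "x", "y")
  if (!all(expected %in% names(df))) {
    abort("layout file must have columns vertex_id, component_index, x, y")
  }
  tibble(
    vertex = as.character(df$vertex_id),
    component = as.integer(df$component_index),
    x = as.numeric(df$x), y = as.numeric(df$y)
  )
}

#' Rendering options for [render_svg()]
#'
#' @param vertex_radius Circle radius in pixels.
#' @param link_color Color of the background component-similarity lines.
#' @param link_width_scale Maximum similarity-line width in pixels; each
#'   line's width is `weight * link_width_scale`.
#' @param label_components Draw the component index at each component
#'   centroid.
#' @param size Canvas side length in pixels.
#' @return A list of class `render_spec`.
#' @export
render_spec <- function(vertex_radius = 4, link_color = "steelblue",
                        link_width_scale = 4, label_components = TRUE,
                        size = 600) {
  stopifnot(vertex_radius > 0, link_width_scale > 0, size > 0)
  structure(
    list(
      vertex_radius = vertex_radius, link_color = link_color,
      link_width_scale = link_width_scale,
      label_components = label_components, size = size
    ),
    class = "render_spec"
  )
}

#' Render a layout to a standalone SVG file
#'
#' Vertices are circles — solid when the vertex `class` attribute is 1,
#' hollow otherwise — intra-component edges are line segments, and optional
#' component-similarity links ([nearest_component_links()]) are drawn behind
#' the network as colored lines whose widths scale with similarity.
#' Component index labels sit at the component centroids. The output is
#' plain deterministic markup: identical inputs give identical bytes.
#'
#' @param layout A layout tibble (`vertex`, `component`, `x`, `y`).
#' @param network The igraph object the layout belongs to.
#' @param path Output file.
#' @param spec A [render_spec()].
#' @param links Optional tibble from [nearest_component_links()].
#' @return `path`, invisibly.
#' @export
render_svg <- function(layout, network, path, spec = render_spec(),
                       links = NULL) {
  check_network(network)
  stopifnot(all(c("vertex", "component", "x", "y") %in% names(layout)))
  S <- spec$size
  margin <- 0.05 * S
  rngx <- range(layout$x)
  rngy <- range(layout$y)
  span <- max(diff(rngx), diff(rngy), 1e-12)
  px <- function(x) margin + (S - 2 * margin) * (x - rngx[1]) / span
  py <- function(y) S - margin - (S - 2 * margin) * (y - rngy[1]) / span
  X <- px(layout$x)
  Y <- py(layout$y)
  at <- setNames(seq_len(nrow(layout)), layout$vertex)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
      S, S, S, S
    ),
    sprintf('<rect width="%d" height="%d" fill="white"/>', S, S)
  )
  cx <- tapply(X, layout$component, mean)
  cy <- tapply(Y, layout$component, mean)
  if (!is.null(links) && nrow(links)) {
    out <- c(out, sprintf(
      '<line class="component-link" x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="%s" stroke-width="%.3f" stroke-opacity="0.5"/>',
      cx[as.character(links$comp_a)], cy[as.character(links$comp_a)],
      cx[as.character(links$comp_b)], cy[as.character(links$comp_b)],
      spec$link_color, pmax(links$weight * spec$link_width_scale, 0.3)
    ))
  }
  el <- igraph::as_edgelist(network)
  if (nrow(el)) {
    i <- at[el[, 1]]
    j <- at[el[, 2]]
    out <- c(out, sprintf(
      '<line class="edge" x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="grey" stroke-width="1"/>',
      X[i], Y[i], X[j], Y[j]
    ))
  }
  cls <- igraph::vertex_attr(network, "class")
  solid <- if (is.null(cls)) {
    rep(FALSE, nrow(layout))
  } else {
    cls[match(layout$vertex, vertex_names(network))] == 1
  }
  solid[is.na(solid)] <- FALSE
  out <- c(out, sprintf(
    '<circle class="vertex" cx="%.3f" cy="%.3f" r="%.3f" fill="%s" stroke="black"><title>%s</title></circle>',
    X, Y, spec$vertex_radius, ifelse(solid, "black", "white"), layout$vertex
  ))
  if (spec$label_components) {
    out <- c(out, sprintf(
      '<text class="component-label" x="%.3f" y="%.3f" font-size="10" fill="grey">%s</text>',
      cx, cy - 2 * spec$vertex_radius, names(cx)
    ))
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}
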