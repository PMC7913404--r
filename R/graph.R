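## Areal adjacency structures: construction, validation, I/O, ICAR precision
## matrices, and BYM2 scaling.

#' Areal adjacency graph
#'
#' An undirected region-neighbourhood structure: the set of region labels and
#' the unordered pairs of regions that share a border. This is the object from
#' which the ICAR structure matrix \eqn{Q = M - A} is built.
#'
#' @param edges two-column matrix or data frame of region-label pairs, one row
#'   per undirected edge. Duplicate and reversed pairs are deduplicated.
#' @param region_ids optional character vector of region labels fixing the
#'   region order; defaults to the sorted labels appearing in `edges`. Labels
#'   listed here but absent from `edges` become isolated regions.
#' @return an object of class `adjacency_graph` with fields `region_ids`,
#'   `edges` (two-column character matrix, each pair stored once with the
#'   lexicographically smaller label first), `n_regions` and `neighbor_counts`
#'   (per-region degree \eqn{m_i}).
#' @examples
#' g <- adjacency_graph(rbind(c("a", "b"), c("b", "c")))
#' g$neighbor_counts
#' @export
adjacency_graph <- function(edges, region_ids = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  }
  stop_if_not(is.matrix(edges) && ncol(edges) == 2,
              "`edges` must be a two-column matrix or data frame")
  mode(edges) <- "character"
  if (any(edges[, 1] == edges[, 2])) {
    bad <- edges[edges[, 1] == edges[, 2], 1]
    stop(sprintf("self-loop on region '%s' is not allowed", bad[1]),
         call. = FALSE)
  }
  ## canonical order within each pair, then dedupe
  swap <- edges[, 1] > edges[, 2]
  edges[swap, ] <- edges[swap, 2:1]
  edges <- unique(edges)
  if (is.null(region_ids)) {
    region_ids <- sort(unique(as.vector(edges)))
  } else {
    region_ids <- as.character(region_ids)
    stop_if_not(!anyDuplicated(region_ids), "duplicated labels in `region_ids`")
    missing <- setdiff(unique(as.vector(edges)), region_ids)
    stop_if_not(length(missing) == 0,
                "edge endpoint(s) not in `region_ids`: %s",
                paste(utils::head(missing, 5), collapse = ", "))
  }
  deg <- stats::setNames(integer(length(region_ids)), region_ids)
  if (nrow(edges) > 0) {
    tab <- table(factor(as.vector(edges), levels = region_ids))
    deg[] <- as.integer(tab)
  }
  structure(
    list(region_ids = region_ids, edges = edges,
         n_regions = length(region_ids), n_edges = nrow(edges),
         neighbor_counts = deg),
    class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency_graph: %d regions, %d undirected edges, %d component(s)\n",
              x$n_regions, x$n_edges, graph_n_components(x)))
  cat(sprintf("degrees: min %d / mean %.2f / max %d\n",
              min(x$neighbor_counts), mean(x$neighbor_counts),
              max(x$neighbor_counts)))
  invisible(x)
}

## Per-region connected-component membership (integer labels 1..k) by BFS.
graph_components <- function(graph) {
  n <- graph$n_regions
  idx <- stats::setNames(seq_len(n), graph$region_ids)
  adj <- vector("list", n)
  if (nrow(graph$edges) > 0) {
    e1 <- idx[graph$edges[, 1]]
    e2 <- idx[graph$edges[, 2]]
    adj <- split(c(e2, e1), factor(c(e1, e2), levels = seq_len(n)))
  }
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[v]]
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

graph_n_components <- function(graph) max(graph_components(graph))

#' Read an areal adjacency edge list
#'
#' Reads a delimited text file with two region-ID columns into an
#' [adjacency_graph()]. Lines starting with `#` are comments; duplicate and
#' reversed pairs are deduplicated; self-pairs are rejected.
#'
#' @param path path to the edge-list file.
#' @param sep field separator; `NULL` (default) auto-detects comma, tab, or
#'   whitespace from the first data line.
#' @param header logical; does the file start with a header line?
#' @param cols integer pair giving the two ID columns (default first two).
#' @param region_ids optional full region-label vector (to carry isolated
#'   regions).
#' @return an [adjacency_graph()].
#' @export
read_edge_list <- function(path, sep = NULL, header = FALSE, cols = c(1, 2),
                           region_ids = NULL) {
  stop_if_not(file.exists(path), "edge-list file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  stop_if_not(length(lines) > 0, "no data lines in %s", path)
  if (is.null(sep)) {
    probe <- lines[[if (header) min(2, length(lines)) else 1]]
    sep <- if (grepl(",", probe)) "," else if (grepl("\t", probe)) "\t" else ""
  }
  if (header) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  split_fields <- function(x) {
    if (sep == "") strsplit(trimws(x), "\\s+") else strsplit(x, sep, fixed = TRUE)
  }
  fields <- split_fields(lines)
  nf <- lengths(fields)
  if (any(nf < max(cols))) {
    bad <- which(nf < max(cols))[1]
    stop(sprintf("malformed edge-list row at line %d of %s: %s",
                 lineno[bad], path, lines[bad]), call. = FALSE)
  }
  edges <- cbind(trimws(vapply(fields, `[[`, "", cols[1])),
                 trimws(vapply(fields, `[[`, "", cols[2])))
  adjacency_graph(edges, region_ids = region_ids)
}

#' Write an areal adjacency edge list
#'
#' Emits the same dialect [read_edge_list()] consumes: one undirected edge per
#' line, two delimited columns.
#'
#' @param graph an [adjacency_graph()].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @param header logical; write a `from<sep>to` header line?
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path, sep = ",", header = FALSE) {
  out <- paste(graph$edges[, 1], graph$edges[, 2], sep = sep)
  if (header) out <- c(paste("from", "to", sep = sep), out)
  writeLines(out, path)
  invisible(path)
}

#' Summarize an adjacency graph as JSON
#'
#' @param graph an [adjacency_graph()].
#' @param path optional file to write the JSON to.
#' @return a list with `n_regions`, `n_edges`, `n_components`, and a degree
#'   histogram; written as JSON when `path` is given.
#' @export
graph_summary <- function(graph, path = NULL) {
  hist <- table(graph$neighbor_counts)
  out <- list(
    n_regions = graph$n_regions,
    n_edges = graph$n_edges,
    n_components = graph_n_components(graph),
    degree_histogram = stats::setNames(as.integer(hist), names(hist)))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Build the ICAR structure matrix from an adjacency graph
#'
#' Constructs the intrinsic CAR structure matrix \eqn{Q = M - A}, where
#' \eqn{M = diag(m_1, \ldots, m_n)} holds the neighbour counts and \eqn{A} is
#' the 0/1 adjacency indicator. \eqn{Q} is symmetric positive semi-definite
#' with zero row sums and rank \eqn{n - } (number of connected components).
#'
#' @param graph an [adjacency_graph()].
#' @return an object of class `icar_structure` with fields `graph`, `Q`, `A`
#'   (sparse, `Matrix`), `M` (degree vector), `n_components`, `components`
#'   (membership), and unset scaling fields `Q_star`, `scaling_factor` (see
#'   [compute_bym2_scaling()]).
#' @export
build_icar_precision <- function(graph) {
  stop_if_not(inherits(graph, "adjacency_graph"), "`graph` must be an adjacency_graph")
  stop_if_not(graph$n_regions > 0, "empty graph")
  n <- graph$n_regions
  idx <- stats::setNames(seq_len(n), graph$region_ids)
  if (nrow(graph$edges) > 0) {
    i <- idx[graph$edges[, 1]]
    j <- idx[graph$edges[, 2]]
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n),
                              dimnames = list(graph$region_ids, graph$region_ids))
  } else {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n),
                              dimnames = list(graph$region_ids, graph$region_ids))
  }
  M <- as.numeric(graph$neighbor_counts)
  Q <- Matrix::Diagonal(n, M) - A
  comp <- graph_components(graph)
  structure(
    list(graph = graph, Q = Q, A = A, M = M,
         components = comp, n_components = max(comp),
         Q_star = NULL, scaling_factor = NULL, eigen = NULL),
    class = "icar_structure")
}

#' @export
print.icar_structure <- function(x, ...) {
  cat(sprintf("icar_structure: n = %d, rank %d (%d component(s))%s\n",
              length(x$M), length(x$M) - x$n_components, x$n_components,
              if (is.null(x$Q_star)) "" else
                sprintf(", BYM2-scaled (factor %s)",
                        paste(signif(x$scaling_factor, 4), collapse = "/"))))
  invisible(x)
}

## Eigendecomposition of a symmetric PSD matrix with zero-eigenvalue
## truncation at relative tolerance 1e-10. Returns values (descending),
## vectors, and the indices of the (numerically) null directions.
psd_eigen <- function(Qd, rel_tol = 1e-10) {
  e <- eigen(Qd, symmetric = TRUE)
  thresh <- rel_tol * max(e$values, 0)
  null <- which(e$values <= thresh)
  e$values[null] <- 0
  list(values = e$values, vectors = e$vectors, null = null)
}

#' Scale an ICAR structure matrix (BYM2 scaling)
#'
#' Computes the scaling factor making the structured spatial field's marginal
#' variances graph-invariant: \eqn{Q_\star = s Q} with \eqn{s} chosen so that
#' the geometric mean of the marginal variances
#' \eqn{diag(Q_\star^-)} — the generalized inverse under the per-component
#' sum-to-zero constraint — equals 1. This makes the BYM2 variance parameter
#' \eqn{\sigma^2} interpretable across neighbourhood structures.
#'
#' Scaling is applied per connected component; an isolated (degree-0) region
#' is an error because its structured variance is undefined.
#'
#' @param structure an `icar_structure` from [build_icar_precision()].
#' @return the structure with `Q_star`, `scaling_factor` (one factor per
#'   connected component), and a cached eigendecomposition of `Q_star` filled
#'   in.
#' @export
compute_bym2_scaling <- function(structure) {
  stop_if_not(inherits(structure, "icar_structure"),
              "`structure` must come from build_icar_precision()")
  if (any(structure$M == 0)) {
    bad <- structure$graph$region_ids[structure$M == 0][1]
    stop(sprintf(
      "region '%s' has no neighbours: structured spatial variance undefined",
      bad), call. = FALSE)
  }
  n <- length(structure$M)
  comp <- structure$components
  Qd <- as.matrix(structure$Q)
  vals <- numeric(n)
  vecs <- matrix(0, n, n)
  factors <- numeric(structure$n_components)
  col0 <- 0L
  for (k in seq_len(structure$n_components)) {
    rows <- which(comp == k)
    ek <- psd_eigen(Qd[rows, rows, drop = FALSE])
    pos <- setdiff(seq_along(rows), ek$null)
    ## marginal variances of the sum-to-zero-constrained field: diag of the
    ## Moore-Penrose generalized inverse
    mvar <- rowSums(sweep(ek$vectors[, pos, drop = FALSE]^2, 2,
                          1 / ek$values[pos], `*`))
    s <- exp(mean(log(mvar)))        # gmean(diag(Q^-)); (sQ)^- has gmean 1
    factors[k] <- s
    cols <- col0 + seq_along(rows)
    vals[cols] <- s * ek$values
    vecs[rows, cols] <- ek$vectors
    col0 <- col0 + length(rows)
  }
  ## assemble Q_star = per-component s_k * Q_kk, kept sparse
  sv <- factors[comp]
  Qs <- Matrix::Diagonal(n, sqrt(sv)) %*% structure$Q %*% Matrix::Diagonal(n, sqrt(sv))
  ## (per-component scaling: sqrt(s_i) Q_ij sqrt(s_j) = s Q_ij within a
  ## component and Q_ij = 0 across components)
  structure$Q_star <- methods::as(Qs, "symmetricMatrix")
  structure$scaling_factor <- factors
  ord <- order(vals)      # ascending, null directions first
  structure$eigen <- list(values = vals[ord], vectors = vecs[, ord],
                          n_null = structure$n_components)
  structure
}

## Scaled-structure memo: spatial fits on the same graph (e.g. across
## simulation replicates) reuse the eigendecomposition instead of repeating
## a dense solve per fit. Keyed by the full edge list; bounded size.
.structure_cache <- new.env(parent = emptyenv())
.structure_cache$entries <- list()

scaled_structure_for <- function(graph) {
  key <- paste(graph$n_regions, graph$n_edges,
               paste(graph$edges[, 1], graph$edges[, 2], sep = "-",
                     collapse = "|"),
               sep = "#")
  hit <- .structure_cache$entries[[key]]
  if (!is.null(hit)) return(hit)
  st <- compute_bym2_scaling(build_icar_precision(graph))
  if (length(.structure_cache$entries) >= 8) .structure_cache$entries <- list()
  .structure_cache$entries[[key]] <- st
  st
}

## ---- synthetic county-like graphs -------------------------------------

## Bowyer-Watson Delaunay triangulation of points (x, y).
## Returns a two-column integer matrix of unique undirected edges.
## O(n^2); intended for the few-hundred-region graphs used here.
delaunay_edges <- function(x, y) {
  n <- length(x)
  stop_if_not(n >= 3, "need at least 3 points for a triangulation")
  ## super-triangle enclosing all points
  cx <- mean(range(x)); cy <- mean(range(y))
  d <- max(diff(range(x)), diff(range(y))) * 20 + 1
  px <- c(x, cx - 2 * d, cx + 2 * d, cx)
  py <- c(y, cy - d, cy - d, cy + 2 * d)
  sup <- n + 1:3
  tris <- matrix(sup, nrow = 1)           # vertex triples
  circ <- matrix(0, nrow = 1, ncol = 3)   # (ccx, ccy, r^2)
  circum <- function(t) {
    ax <- px[t[1]]; ay <- py[t[1]]
    bx <- px[t[2]]; by <- py[t[2]]
    cx2 <- px[t[3]]; cy2 <- py[t[3]]
    dd <- 2 * (ax * (by - cy2) + bx * (cy2 - ay) + cx2 * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy2) + (bx^2 + by^2) * (cy2 - ay) +
             (cx2^2 + cy2^2) * (ay - by)) / dd
    uy <- ((ax^2 + ay^2) * (cx2 - bx) + (bx^2 + by^2) * (ax - cx2) +
             (cx2^2 + cy2^2) * (bx - ax)) / dd
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  circ[1, ] <- circum(tris[1, ])
  for (p in seq_len(n)) {
    inside <- (px[p] - circ[, 1])^2 + (py[p] - circ[, 2])^2 <= circ[, 3] * (1 + 1e-12)
    bad <- which(inside)
    ## boundary polygon: edges of bad triangles that appear exactly once
    be <- rbind(tris[bad, c(1, 2), drop = FALSE],
                tris[bad, c(2, 3), drop = FALSE],
                tris[bad, c(1, 3), drop = FALSE])
    be <- t(apply(be, 1, sort))
    key <- paste(be[, 1], be[, 2])
    once <- names(which(table(key) == 1))
    poly <- be[match(once, key), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    circ <- circ[-bad, , drop = FALSE]
    newt <- cbind(poly, p)
    newc <- t(apply(newt, 1, circum))
    tris <- rbind(tris, newt)
    circ <- rbind(circ, newc)
  }
  keep <- rowSums(matrix(tris %in% sup, nrow = nrow(tris))) == 0
  tris <- tris[keep, , drop = FALSE]
  ed <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(1, 3)])
  ed <- t(apply(ed, 1, sort))
  unique(ed)
}

#' Generate a synthetic county-like adjacency graph
#'
#' Synthesizes a connected, planar areal neighbourhood structure with a target
#' size and density, standing in for a census county adjacency file: random
#' points are Delaunay-triangulated and edges are pruned uniformly at random
#' (never disconnecting the graph) down to the requested count. The default
#' target of 272 regions with 1528 ordered adjacencies (764 undirected edges)
#' mirrors a three-state US county adjacency structure.
#'
#' @param n_regions number of regions.
#' @param n_adjacencies target adjacency count; interpreted per `ordered`.
#' @param seed RNG seed (a given seed always yields the same edge set).
#' @param ordered if `TRUE` (default), `n_adjacencies` counts ordered pairs as
#'   census adjacency files do, so the graph gets `n_adjacencies / 2`
#'   undirected edges; if `FALSE` it counts undirected edges directly.
#' @return an [adjacency_graph()] with region labels `r001`, `r002`, ...
#' @export
synthetic_county_graph <- function(n_regions = 272, n_adjacencies = 1528,
                                   seed = 1, ordered = TRUE) {
  if (ordered) {
    stop_if_not(n_adjacencies %% 2 == 0,
                "an ordered adjacency count must be even")
    m_target <- n_adjacencies / 2
  } else {
    m_target <- n_adjacencies
  }
  stop_if_not(m_target >= n_regions - 1,
              "target edge count %d is below the spanning-tree minimum %d",
              m_target, n_regions - 1)
  labels <- sprintf("r%0*d", max(3, nchar(n_regions)), seq_len(n_regions))
  with_seed(seed, {
    x <- stats::runif(n_regions)
    y <- stats::runif(n_regions)
    if (n_regions >= 3) {
      ed <- delaunay_edges(x, y)
    } else {
      ed <- cbind(1, 2)[seq_len(n_regions - 1), , drop = FALSE]
    }
    stop_if_not(nrow(ed) >= m_target,
                "triangulation has only %d edges; cannot reach target %d",
                nrow(ed), m_target)
    ## prune random edges, preserving connectivity
    order_try <- sample.int(nrow(ed))
    alive <- rep(TRUE, nrow(ed))
    n_alive <- nrow(ed)
    connected_without <- function(drop_i) {
      es <- ed[alive & seq_len(nrow(ed)) != drop_i, , drop = FALSE]
      adj <- split(c(es[, 2], es[, 1]),
                   factor(c(es[, 1], es[, 2]), levels = seq_len(n_regions)))
      seen <- logical(n_regions)
      queue <- 1L
      seen[1] <- TRUE
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        nb <- adj[[v]]
        nb <- nb[!seen[nb]]
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
      all(seen)
    }
    for (i in order_try) {
      if (n_alive <= m_target) break
      if (connected_without(i)) {
        alive[i] <- FALSE
        n_alive <- n_alive - 1
      }
    }
    stop_if_not(n_alive == m_target,
                "could not prune to %d edges without disconnecting", m_target)
    ed <- ed[alive, , drop = FALSE]
    adjacency_graph(cbind(labels[ed[, 1]], labels[ed[, 2]]),
                    region_ids = labels)
  })
}
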