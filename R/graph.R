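#' Project a reaction system onto its substance graph
#'
#' The substance graph is a simple undirected graph whose vertices are the
#' metabolites; two metabolites are joined by an edge when they take part in
#' the same reaction, as substrate or product. A reaction with participants
#' \{H2, O2, H2O\} therefore contributes three edges. Self-loops are excluded
#' and repeated co-participation collapses to a single edge.
#'
#' @param system A `reaction_system`.
#' @return An [igraph::graph] with vertex names equal to molecule ids.
#' @examples
#' comp <- rbind(H2 = c(2, 0), O2 = c(0, 2), H2O = c(2, 1))
#' water <- reaction_system(comp, tibble::tibble(
#'   substrates = list(c("H2", "O2")), sub_mult = list(c(2L, 1L)),
#'   products = list("H2O"), prod_mult = list(2L)
#' ))
#' igraph::ecount(substance_graph(water))  # 3
#' @export
substance_graph <- function(system) {
  stopifnot(inherits(system, "reaction_system"))
  if (nrow(system$molecules) == 0L) stop("empty system", call. = FALSE)
  edges <- lapply(seq_len(nrow(system$reactions)), function(i) {
    parts <- unique(c(system$reactions$substrates[[i]],
                      system$reactions$products[[i]]))
    if (length(parts) < 2L) return(NULL)
    t(utils::combn(sort(parts), 2L))
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(system$molecules),
                            name = system$molecules$id)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(edges))
    g <- igraph::simplify(g)
  }
  g
}

#' Network modularity of a vertex partition
#'
#' Computes Newman's modularity \eqn{Q = \sum_i (e_{ii} - a_i^2)}, where
#' \eqn{e_{ii}} is the fraction of edges inside group \eqn{i} and
#' \eqn{a_i} the fraction of edge ends attached to group \eqn{i}
#' (\eqn{a_i^2} being the expected within-group edge fraction in a random
#' graph with the same group degrees).
#'
#' @param graph An undirected simple igraph graph with at least one edge.
#' @param membership Group assignment: an integer vector over the vertices
#'   (in vertex order, or named by vertex name), or a `module_partition`.
#' @return The modularity Q, a number in \eqn{[-1, 1]}.
#' @export
compute_modularity <- function(graph, membership) {
  m <- igraph::ecount(graph)
  if (m == 0L) stop("modularity is undefined for an edgeless graph", call. = FALSE)
  memb <- normalize_membership(graph, membership)
  el <- igraph::as_edgelist(graph, names = FALSE)
  within <- sum(memb[el[, 1L]] == memb[el[, 2L]]) / m
  deg <- igraph::degree(graph)
  a <- rowsum(deg, memb)[, 1L] / (2 * m)
  within - sum(a^2)
}

normalize_membership <- function(graph, membership) {
  if (inherits(membership, "module_partition")) {
    membership <- membership$membership
  }
  n <- igraph::vcount(graph)
  if (!is.null(names(membership))) {
    vn <- igraph::V(graph)$name
    if (is.null(vn) || !all(vn %in% names(membership))) {
      stop("membership names do not cover the vertex set", call. = FALSE)
    }
    membership <- membership[vn]
  }
  if (length(membership) != n || anyNA(membership)) {
    stop("membership must assign every vertex to a group", call. = FALSE)
  }
  as.integer(factor(membership))
}

#' Detect modules by greedy modularity maximization
#'
#' Agglomerative heuristic: start from singleton groups and repeatedly merge
#' the pair of groups with the largest modularity gain (ties broken towards
#' the lowest group-index pair), keeping the best partition seen on the way
#' to a single group. Deterministic given the graph. The resulting maximized
#' Q is the modularity measure of the graph, and the groups define the
#' modules used by local perturbations.
#'
#' @param graph An undirected simple igraph graph with at least one edge.
#' @return A `module_partition`: list with `membership` (named integer vector,
#'   groups relabeled `1..k`), `n_modules`, and `Q` (its modularity).
#' @export
detect_modules <- function(graph) {
  m <- igraph::ecount(graph)
  if (m == 0L) stop("modularity is undefined for an edgeless graph", call. = FALSE)
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)

  # e[i, j]: half the fraction of edges between groups i and j (i != j);
  # e[i, i]: fraction of edges inside group i. Then a = rowSums(e) sums to 1.
  e <- matrix(0, n, n)
  for (k in seq_len(m)) {
    i <- el[k, 1L]; j <- el[k, 2L]
    e[i, j] <- e[i, j] + 1 / (2 * m)
    e[j, i] <- e[j, i] + 1 / (2 * m)
  }
  a <- rowSums(e)
  memb <- seq_len(n)
  alive <- rep(TRUE, n)
  q <- 0 - sum(a^2)
  best_q <- q
  best_memb <- memb

  for (step in seq_len(n - 1L)) {
    idx <- which(alive)
    k <- length(idx)
    if (k < 2L) break
    ea <- e[idx, idx, drop = FALSE]
    dq <- 2 * (ea - outer(a[idx], a[idx]))
    diag(dq) <- -Inf
    mx <- max(dq)
    hit <- which(dq == mx, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    gi <- idx[hit[1L, 1L]]; gj <- idx[hit[1L, 2L]]

    # merge gj into gi
    e[gi, ] <- e[gi, ] + e[gj, ]
    e[, gi] <- e[, gi] + e[, gj]
    a[gi] <- a[gi] + a[gj]
    alive[gj] <- FALSE
    memb[memb == gj] <- gi
    q <- q + mx
    if (q > best_q + 1e-12) {
      best_q <- q
      best_memb <- memb
    }
  }

  membership <- as.integer(factor(best_memb, levels = unique(best_memb)))
  vn <- igraph::V(graph)$name
  if (!is.null(vn)) names(membership) <- vn
  new_partition(membership, compute_modularity(graph, membership))
}

new_partition <- function(membership, q) {
  structure(list(
    membership = membership,
    n_modules = length(unique(membership)),
    Q = q
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d vertices in %d modules, Q = %.4f\n",
              length(x$membership), x$n_modules, x$Q))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.module_partition <- function(x, ...) {
  tibble::tibble(
    id = if (is.null(names(x$membership))) {
      as.character(seq_along(x$membership))
    } else names(x$membership),
    module = unname(x$membership)
  )
}

#' Exact maximum-modularity partition by exhaustive enumeration
#'
#' Enumerates every set partition of the vertex set and returns one with
#' maximal modularity. Serves as the independent oracle for
#' [detect_modules()]; guarded to at most 12 vertices (Bell numbers explode).
#'
#' @param graph An undirected simple igraph graph with 1..12 vertices and at
#'   least one edge.
#' @return A `module_partition` attaining the exact maximum Q.
#' @export
brute_force_max_modularity <- function(graph) {
  n <- igraph::vcount(graph)
  if (n > 12L) stop("brute force is limited to 12 vertices", call. = FALSE)
  m <- igraph::ecount(graph)
  if (m == 0L) stop("modularity is undefined for an edgeless graph", call. = FALSE)
  parts <- set_partitions(n)
  el <- igraph::as_edgelist(graph, names = FALSE)
  deg <- igraph::degree(graph)

  within <- rowSums(parts[, el[, 1L], drop = FALSE] ==
                    parts[, el[, 2L], drop = FALSE]) / m
  # sum over groups of (degree mass)^2 via pairwise same-group indicators
  sum_a2 <- numeric(nrow(parts))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sum_a2 <- sum_a2 + deg[i] * deg[j] * (parts[, i] == parts[, j])
    }
  }
  q <- within - sum_a2 / (4 * m^2)
  bi <- which.max(q)
  membership <- as.integer(parts[bi, ])
  vn <- igraph::V(graph)$name
  if (!is.null(vn)) names(membership) <- vn
  new_partition(membership, q[bi])
}

# All set partitions of n elements as restricted-growth strings (rows),
# cached per n (Bell(12) = 4,213,597 rows is the guard limit).
partition_cache <- new.env(parent = emptyenv())

set_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(partition_cache[[key]])) return(partition_cache[[key]])
  p <- matrix(1L, 1L, 1L)
  maxg <- 1L
  for (i in seq_len(n - 1L)) {
    reps <- maxg + 1L
    idx <- rep.int(seq_len(nrow(p)), reps)
    newcol <- sequence(reps)
    p <- cbind(p[idx, , drop = FALSE], newcol)
    maxg <- pmax(maxg[idx], newcol)
  }
  dimnames(p) <- NULL
  partition_cache[[key]] <- p
  p
}

#' Associate a reaction with a module
#'
#' A reaction belongs to the module holding the majority of its participant
#' metabolites; ties are broken uniformly at random among the tied modules.
#'
#' @param reaction One row of a system's `reactions` tibble (or a list with
#'   `substrates` and `products`).
#' @param partition A `module_partition` covering the participants.
#' @return The integer module index.
#' @export
assign_reaction_module <- function(reaction, partition) {
  reaction <- as_reaction_parts(reaction)
  parts <- unique(c(reaction$substrates, reaction$products))
  missing <- setdiff(parts, names(partition$membership))
  if (length(missing) > 0L) {
    stop("participant(s) absent from partition: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mods <- partition$membership[parts]
  tab <- table(mods)
  winners <- as.integer(names(tab)[tab == max(tab)])
  if (length(winners) == 1L) winners else winners[sample.int(length(winners), 1L)]
}

#' Export a substance graph
#'
#' Writes the graph as a tab-separated edge list or as GraphML; with a
#' partition, a `module` vertex attribute is attached (GraphML) or a
#' companion `(id, module)` TSV can be written via [tidy()].
#'
#' @param graph An igraph graph.
#' @param path Output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @param partition Optional `module_partition` used to attach module labels.
#' @return `path`, invisibly.
#' @export
export_substance_graph <- function(graph, path,
                                   format = c("edgelist", "graphml"),
                                   partition = NULL) {
  format <- match.arg(format)
  if (!is.null(partition)) {
    igraph::V(graph)$module <- unname(
      partition$membership[igraph::V(graph)$name])
  }
  if (format == "edgelist") {
    el <- igraph::as_edgelist(graph)
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    igraph::write_graph(graph, path, format = "graphml")
  }
  invisible(path)
}
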