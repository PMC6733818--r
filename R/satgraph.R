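#' Percent similarity between two cluster representatives
#'
#' Best local alignment (Smith-Waterman: match +1, mismatch -1, linear
#' gap -2) of the two representatives over both strands; similarity is
#' `100 * matches / alignment columns` of that local alignment.
#'
#' @param a,b clusters (lists with a `representative`) or sequences as
#'   character scalars / single-row [seq_set]s.
#' @return Similarity percent in `[0, 100]`.
#' @export
cluster_similarity <- function(a, b) {
  get_bases <- function(x) {
    if (is.list(x) && !is.null(x$representative)) x <- x$representative
    if (is.list(x) || is.data.frame(x)) as.character(x$bases) else as.character(x)
  }
  a <- get_bases(a)
  b <- get_bases(b)
  res <- .local_align_set(c(b, revcomp(b)), a)
  top <- which.max(res$score)
  if (res$columns[top] == 0L) return(0)
  100 * res$matches[top] / res$columns[top]
}

#' Minimum spanning tree over a cluster similarity graph
#'
#' Kruskal's algorithm on distance `100 - similarity`, with the
#' deterministic tie-break (smaller distance, then smaller first node
#' id, then smaller second node id) so the tree is reproducible under
#' relabeling up to ties.
#'
#' @param nodes vector of node ids.
#' @param edges data frame with columns `from`, `to`, `similarity`.
#' @return The subset of `edges` rows forming the MST.
#' @export
build_mst <- function(nodes, edges) {
  n <- length(nodes)
  if (n == 1L) return(edges[0L, , drop = FALSE])
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  dist <- 100 - edges$similarity
  ord <- order(dist, a, b)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  take <- integer(0)
  for (k in ord) {
    ra <- find(match(a[k], nodes))
    rb <- find(match(b[k], nodes))
    if (ra != rb) {
      parent[ra] <- rb
      take <- c(take, k)
      if (length(take) == n - 1L) break
    }
  }
  if (length(take) < n - 1L) {
    roots <- vapply(seq_len(n), find, 0L)
    comps <- split(nodes, roots)
    stop("similarity graph is disconnected; components: ",
         paste(vapply(comps, function(cc) paste(cc, collapse = ","), ""),
               collapse = " | "))
  }
  edges[sort(take), , drop = FALSE]
}

#' Build the cluster graph: pairwise similarities plus MST
#'
#' Computes [cluster_similarity()] between every pair of cluster
#' representatives (a complete graph, so the MST always exists), runs
#' [build_mst()], and attaches the per-cluster composition needed for
#' the species-mixing summary.
#'
#' @param clusters a `sat_clusters` summary from [summarize_clusters()].
#' @return Object of class `cluster_graph`: list with `nodes` (the
#'   `sat_clusters` data frame), `edges` (`from`, `to`, `similarity`,
#'   `in_mst`), and `mst_edges`.
#' @export
cluster_graph <- function(clusters) {
  stopifnot(inherits(clusters, "sat_clusters"))
  clustering <- attr(clusters, "clustering")
  ids <- clusters$cluster_id
  reps <- vapply(clustering, function(cl) cl$representative$bases, "")
  n <- length(ids)
  edges <- if (n >= 2L) {
    pairs <- utils::combn(n, 2L)
    sim <- vapply(seq_len(ncol(pairs)), function(k) {
      cluster_similarity(reps[pairs[1L, k]], reps[pairs[2L, k]])
    }, 0)
    data.frame(from = ids[pairs[1L, ]], to = ids[pairs[2L, ]],
               similarity = sim)
  } else {
    data.frame(from = integer(0), to = integer(0), similarity = numeric(0))
  }
  mst <- if (n >= 2L) build_mst(ids, edges) else edges
  key <- paste(edges$from, edges$to)
  edges$in_mst <- key %in% paste(mst$from, mst$to)
  structure(list(nodes = clusters, edges = edges, mst_edges = mst),
            class = "cluster_graph")
}

#' @export
print.cluster_graph <- function(x, ...) {
  mix <- mixing_summary(x)
  cat(sprintf(paste0("cluster_graph: %d node(s), %d edge(s), %d MST edge(s)\n",
                     "  multi-source node fraction %.3f; ",
                     "size-weighted mean Shannon H %.4f nats\n"),
              nrow(x$nodes), nrow(x$edges), nrow(x$mst_edges),
              mix["multi_source_fraction"], mix["weighted_mean_shannon_h"]))
  invisible(x)
}

#' Species-mixing summary of a cluster graph
#'
#' The computational restatement of "are clusters species-specific or
#' intermingled": the fraction of cluster nodes drawing members from
#' two or more source libraries, and the raw-count-weighted mean of the
#' per-cluster Shannon's H.
#'
#' @param graph a `cluster_graph` (or a `sat_clusters` summary).
#' @return Named numeric vector `c(multi_source_fraction,
#'   weighted_mean_shannon_h)`.
#' @export
mixing_summary <- function(graph) {
  nodes <- if (inherits(graph, "cluster_graph")) graph$nodes else graph
  stopifnot(inherits(nodes, "sat_clusters"), nrow(nodes) > 0L)
  comp <- attr(nodes, "composition")
  multi <- vapply(comp, function(cc) sum(cc > 0) >= 2L, logical(1))
  w <- nodes$raw_count
  c(multi_source_fraction = mean(multi),
    weighted_mean_shannon_h = sum(nodes$shannon_h * w) / sum(w))
}

#' Export a cluster graph as GraphML or DOT
#'
#' Node attributes: `size` (raw count), one count attribute per source
#' library (pie data), `shannon_h`. Edge attributes: `similarity`,
#' `in_mst`. Attribute ordering is fixed so output is bit-stable.
#'
#' @param graph a `cluster_graph`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @param min_similarity edges below this similarity are omitted from
#'   the written file (display pruning only; the MST is always kept
#'   complete). Default 0 keeps everything.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "dot"),
                         min_similarity = 0) {
  stopifnot(inherits(graph, "cluster_graph"))
  format <- match.arg(format)
  nodes <- graph$nodes
  comp <- attr(nodes, "composition")
  libs <- attr(nodes, "libraries")
  edges <- graph$edges[graph$edges$similarity >= min_similarity |
                         graph$edges$in_mst, , drop = FALSE]
  num <- function(x) formatC(x, format = "g", digits = 10)
  if (format == "graphml") {
    keys <- c(
      '  <key id="size" for="node" attr.name="size" attr.type="int"/>',
      sprintf('  <key id="src_%s" for="node" attr.name="count_%s" attr.type="int"/>',
              libs, libs),
      '  <key id="shannon_h" for="node" attr.name="shannon_h" attr.type="double"/>',
      '  <key id="similarity" for="edge" attr.name="similarity" attr.type="double"/>',
      '  <key id="in_mst" for="edge" attr.name="in_mst" attr.type="boolean"/>')
    node_xml <- vapply(seq_len(nrow(nodes)), function(i) {
      cc <- comp[[i]]
      paste0('    <node id="n', nodes$cluster_id[i], '">\n',
             '      <data key="size">', nodes$raw_count[i], '</data>\n',
             paste0('      <data key="src_', libs, '">', cc[libs],
                    '</data>\n', collapse = ""),
             '      <data key="shannon_h">', num(nodes$shannon_h[i]),
             '</data>\n    </node>')
    }, "")
    edge_xml <- vapply(seq_len(nrow(edges)), function(k) {
      paste0('    <edge source="n', edges$from[k], '" target="n',
             edges$to[k], '">\n',
             '      <data key="similarity">', num(edges$similarity[k]),
             '</data>\n',
             '      <data key="in_mst">',
             tolower(as.character(edges$in_mst[k])), '</data>\n',
             '    </edge>')
    }, "")
    out <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
             keys,
             '  <graph id="satellite_clusters" edgedefault="undirected">',
             node_xml, edge_xml,
             '  </graph>', '</graphml>')
  } else {
    node_dot <- sprintf('  n%d [size=%d, shannon_h=%s];',
                        nodes$cluster_id, nodes$raw_count,
                        num(nodes$shannon_h))
    edge_dot <- sprintf('  n%d -- n%d [similarity=%s, in_mst=%s];',
                        edges$from, edges$to, num(edges$similarity),
                        tolower(as.character(edges$in_mst)))
    out <- c("graph satellite_clusters {", node_dot, edge_dot, "}")
  }
  writeLines(out, path)
  invisible(path)
}
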