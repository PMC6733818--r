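#' Pairwise identity between two sequences
#'
#' Ends-free global alignment (free terminal gaps; match +1, mismatch -1,
#' gap open -2, gap extend -1). Identity is matched columns over
#' alignment columns with terminal-gap columns excluded, maximised over
#' the forward and reverse-complement orientation of `b`. With
#' `ambiguity = TRUE` IUPAC codes count as a match when their base sets
#' intersect, which is the right rule for consensus-vs-consensus
#' comparisons.
#'
#' @param a,b sequences as character scalars or single-row [seq_set]s.
#' @param ambiguity treat IUPAC ambiguity codes as matches when
#'   compatible (default `FALSE`).
#' @return Identity as a fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGTACGTAC", "ACGAACGTAC")  # 0.9
#' @export
pairwise_identity <- function(a, b, ambiguity = FALSE) {
  a <- if (is.list(a) || is.data.frame(a)) as.character(a$bases) else as.character(a)
  b <- if (is.list(b) || is.data.frame(b)) as.character(b$bases) else as.character(b)
  res <- .overlap_identity_set(c(b, revcomp(b)), a, ambiguity = ambiguity)
  max(res$identity)
}

#' Greedy incremental identity clustering
#'
#' Reimplements the cd-hit-est strategy without its word-filter
#' heuristics: sequences are sorted by length (descending, ties by id)
#' and scanned once; each sequence is compared by [pairwise_identity()]
#' to the representatives of existing clusters whose length ratio
#' (shorter/longer) is at least `length_diff_cutoff`. With
#' `assignment = "best"` it joins the cluster of highest identity
#' >= `threshold` (ties to the lowest cluster id); with `"first"` the
#' first qualifying cluster in id order. Otherwise it founds a new
#' cluster with itself as representative.
#'
#' @param seqs [seq_set] of sequences to cluster.
#' @param threshold identity threshold, typically 0.95, 0.97 or 0.99.
#' @param length_diff_cutoff minimum shorter/longer length ratio for a
#'   sequence to be eligible for a cluster, default 0.8.
#' @param assignment `"best"` (default) or `"first"`.
#' @return Object of class `sat_clustering`: list of clusters, each with
#'   `id` (0-based), `representative` (single-row [seq_set]) and
#'   `members` (character vector of sequence ids, representative first).
#'   Attributes record the threshold and parameters.
#' @export
cluster_greedy <- function(seqs, threshold, length_diff_cutoff = 0.8,
                           assignment = c("best", "first")) {
  stopifnot(nrow(seqs) > 0L, threshold > 0, threshold <= 1)
  assignment <- match.arg(assignment)
  ord <- order(-nchar(seqs$bases), seqs$id)
  seqs <- seqs[ord, , drop = FALSE]
  rep_bases <- character(0)
  rep_rc <- character(0)
  rep_len <- integer(0)
  rep_row <- integer(0)
  members <- list()
  for (i in seq_len(nrow(seqs))) {
    len <- nchar(seqs$bases[i])
    assigned <- FALSE
    if (length(rep_bases)) {
      # representatives are never shorter than the query (length-sorted scan)
      eligible <- which(len / rep_len >= length_diff_cutoff)
      if (length(eligible)) {
        res <- .overlap_identity_set(
          c(rep_bases[eligible], rep_rc[eligible]), seqs$bases[i])
        ident <- pmax(res$identity[seq_along(eligible)],
                      res$identity[seq_along(eligible) + length(eligible)])
        hit <- ident >= threshold
        if (any(hit)) {
          j <- if (assignment == "best") {
            eligible[which.max(ident)]          # first max = lowest cluster id
          } else {
            eligible[which(hit)[1L]]
          }
          members[[j]] <- c(members[[j]], seqs$id[i])
          assigned <- TRUE
        }
      }
    }
    if (!assigned) {
      rep_bases <- c(rep_bases, seqs$bases[i])
      rep_rc <- c(rep_rc, revcomp(seqs$bases[i]))
      rep_len <- c(rep_len, len)
      rep_row <- c(rep_row, i)
      members[[length(rep_bases)]] <- seqs$id[i]
    }
  }
  clusters <- lapply(seq_along(rep_row), function(k) {
    rep_rec <- seqs[rep_row[k], , drop = FALSE]
    class(rep_rec) <- c("seq_set", "data.frame")
    list(id = k - 1L, representative = rep_rec, members = members[[k]])
  })
  structure(clusters, class = "sat_clustering",
            threshold = threshold,
            length_diff_cutoff = length_diff_cutoff,
            assignment = assignment)
}

#' @export
print.sat_clustering <- function(x, ...) {
  sizes <- vapply(x, function(cl) length(cl$members), 0L)
  cat(sprintf("sat_clustering: %d cluster(s) at threshold %.2f; sizes: %s\n",
              length(x), attr(x, "threshold"),
              paste(sort(sizes, decreasing = TRUE), collapse = " ")))
  invisible(x)
}

#' Shannon diversity of a composition vector
#'
#' `H = -sum(p_i * log(p_i))` in natural log units (nats), with
#' `p_i = n_i / sum(n)`; zero counts are dropped.
#'
#' @param counts non-negative numeric vector of per-source counts.
#' @return Shannon's H in nats.
#' @examples
#' shannon_index(c(4, 4))      # log(2)
#' shannon_index(c(2, 1, 1))   # ~1.0397
#' @export
shannon_index <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) <= 1L) return(0)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Assign each read a source label by best hit against a library
#'
#' For reads whose originating run is unknown, the most similar library
#' sequence (by [pairwise_identity()]) lends its `source` label (or its
#' id when the library carries no source labels).
#'
#' @param reads [seq_set] of reads.
#' @param library [seq_set] of library sequences.
#' @return Named character vector: read id -> label.
#' @export
assign_source_by_best_hit <- function(reads, library) {
  labels <- ifelse(is.na(library$source), library$id, library$source)
  lib2 <- c(library$bases, revcomp(library$bases))
  lab2 <- rep(labels, 2L)
  out <- vapply(seq_len(nrow(reads)), function(i) {
    res <- .overlap_identity_set(lib2, reads$bases[i])
    lab2[which.max(res$identity)]
  }, "")
  setNames(out, reads$id)
}

#' Complete clusters with composition, normalized counts and Shannon's H
#'
#' Tallies each cluster's members by source library, computes raw counts,
#' counts normalized to each library's initial read number and to its
#' post-filter read number (summed over the libraries present in the
#' cluster), and Shannon's H (nats) of the composition.
#'
#' @param clustering a `sat_clustering` from [cluster_greedy()].
#' @param source_of named character vector mapping read id -> library
#'   label (e.g. the run of origin, or [assign_source_by_best_hit()]).
#' @param initial_totals,filtered_totals named numeric vectors: per-library
#'   read totals before any processing and after the repeat filter.
#' @return Object of class `sat_clusters`: a data frame with one row per
#'   cluster (`cluster_id`, `representative_id`, `raw_count`,
#'   `norm_initial`, `norm_filtered`, `shannon_h`, then one count column
#'   per library), with the clustering attached as attribute
#'   `clustering` and the per-cluster composition as attribute
#'   `composition` (list of named vectors).
#' @export
summarize_clusters <- function(clustering, source_of,
                               initial_totals, filtered_totals) {
  stopifnot(inherits(clustering, "sat_clustering"))
  libs <- sort(unique(as.character(source_of)))
  rows <- lapply(clustering, function(cl) {
    miss <- setdiff(cl$members, names(source_of))
    if (length(miss))
      stop("no source label for read id(s): ", paste(miss, collapse = ", "))
    comp <- table(factor(source_of[cl$members], levels = libs))
    comp <- setNames(as.numeric(comp), libs)
    raw <- length(cl$members)
    present <- names(comp)[comp > 0]
    ni <- sum(comp[present] / initial_totals[present])
    nf <- sum(comp[present] / filtered_totals[present])
    c(list(cluster_id = cl$id,
           representative_id = cl$representative$id,
           raw_count = raw,
           norm_initial = ni, norm_filtered = nf,
           shannon_h = shannon_index(comp)),
      as.list(comp))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  rownames(df) <- NULL
  comp_list <- lapply(rows, function(r) unlist(r[-(1:6)]))
  structure(df, class = c("sat_clusters", "data.frame"),
            clustering = clustering,
            composition = comp_list,
            libraries = libs)
}

#' @export
print.sat_clusters <- function(x, ...) {
  cat(sprintf("sat_clusters: %d cluster(s), %d read(s); Shannon's H in nats\n",
              nrow(x), sum(x$raw_count)))
  print.data.frame(head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
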