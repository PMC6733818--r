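#' Read a pipeline run configuration from YAML
#'
#' Flat YAML with a `runs` section (label -> `fastq1`/`fastq2` paths), a
#' `library` FASTA path, and optional stage parameters mirroring the
#' defaults of [run_pipeline()]. Values given in `override` replace file
#' values, so command-line flags can win over the file.
#'
#' @param path YAML file.
#' @param override named list of overrides.
#' @return Configuration list.
#' @export
read_run_config <- function(path, override = list()) {
  cfg <- yaml::read_yaml(path)
  for (nm in names(override)) cfg[[nm]] <- override[[nm]]
  cfg
}

#' Run the satellite comparison pipeline end to end
#'
#' Stage order: pair and merge each run's mates; screen merged reads for
#' repeat content against the satellite library; pool retained reads
#' (labelled by run) and cluster at each threshold; summarize cluster
#' composition, normalized counts and Shannon's H; build the similarity
#' graph and MST at each threshold and summarize species mixing.
#'
#' @param runs named list: label -> either `list(fastq1=, fastq2=)`
#'   file paths or in-memory `list(fwd=, rev=)` [seq_set]s.
#' @param library satellite clone library: FASTA path or [seq_set].
#' @param thresholds clustering identity thresholds.
#' @param min_overlap,max_mismatch_rate merge parameters
#'   ([merge_pair()]).
#' @param screen_threshold repeat-content retention threshold
#'   ([filter_reads()]).
#' @param min_local_identity masking identity floor ([mask_read()]).
#' @param outdir optional directory; when given, per-threshold cluster
#'   TSVs, representative FASTAs and GraphML files are written there.
#' @return Object of class `sat_run_report`: list with `counts` (per-run
#'   data frame: initial pairs, merged, retained), `clusters` and
#'   `graphs` (named by threshold), `mixing` (per-threshold matrix) and
#'   `params`.
#' @export
run_pipeline <- function(runs, library,
                         thresholds = c(0.95, 0.97, 0.99),
                         min_overlap = 10L, max_mismatch_rate = 0.1,
                         screen_threshold = 0.99,
                         min_local_identity = 0.7,
                         outdir = NULL) {
  if (is.character(library)) library <- read_sequences(library, "fasta")
  if (is.null(names(runs)) || any(!nzchar(names(runs))))
    stop("every run needs a label")
  counts <- data.frame(run = names(runs), initial_pairs = NA_integer_,
                       merged = NA_integer_, retained = NA_integer_)
  retained_all <- NULL
  source_of <- character(0)
  for (i in seq_along(runs)) {
    lab <- names(runs)[i]
    r <- runs[[i]]
    if (!is.null(r$fastq1)) {
      fwd <- read_sequences(r$fastq1, "fastq", source = lab)
      rev <- read_sequences(r$fastq2, "fastq", source = lab)
    } else {
      fwd <- r$fwd
      rev <- r$rev
    }
    if (nrow(fwd) == 0L)
      stop("merge stage failed for run '", lab, "': no input reads")
    pairs <- pair_reads(fwd, rev)
    mg <- merge_pairs(pairs, min_overlap, max_mismatch_rate)
    sc <- filter_reads(mg$merged, library, threshold = screen_threshold,
                       min_local_identity = min_local_identity)
    counts$initial_pairs[i] <- length(pairs)
    counts$merged[i] <- mg$stats$merged
    counts$retained[i] <- sc$stats$retained
    kept <- sc$retained
    if (nrow(kept)) {
      kept$source <- lab
      retained_all <- if (is.null(retained_all)) kept else {
        out <- rbind(as.data.frame(retained_all)[, 1:4],
                     as.data.frame(kept)[, 1:4])
        seq_set(out$id, out$bases, out$quals, out$source)
      }
      source_of <- c(source_of, setNames(rep(lab, nrow(kept)), kept$id))
    }
  }
  if (is.null(retained_all) || nrow(retained_all) == 0L)
    stop("screen stage retained no reads")
  initial_totals <- setNames(counts$initial_pairs, counts$run)
  filtered_totals <- setNames(counts$retained, counts$run)
  clusters <- list()
  graphs <- list()
  mixing <- NULL
  for (th in thresholds) {
    cl <- cluster_greedy(retained_all, threshold = th)
    cs <- summarize_clusters(cl, source_of, initial_totals, filtered_totals)
    gr <- cluster_graph(cs)
    key <- sprintf("%.2f", th)
    clusters[[key]] <- cs
    graphs[[key]] <- gr
    mixing <- rbind(mixing, c(threshold = th, mixing_summary(gr),
                              n_clusters = nrow(cs)))
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      write.table(as.data.frame(cs),
                  file.path(outdir, paste0("clusters_", key, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      reps <- do.call(rbind, lapply(attr(cs, "clustering"),
                                    function(x) as.data.frame(x$representative)))
      write_sequences(seq_set(reps$id, reps$bases),
                      file.path(outdir, paste0("representatives_", key, ".fasta")))
      export_graph(gr, file.path(outdir, paste0("graph_", key, ".graphml")),
                   "graphml")
    }
  }
  structure(list(counts = counts, clusters = clusters, graphs = graphs,
                 mixing = as.data.frame(mixing),
                 params = list(thresholds = thresholds,
                               min_overlap = min_overlap,
                               max_mismatch_rate = max_mismatch_rate,
                               screen_threshold = screen_threshold,
                               min_local_identity = min_local_identity)),
            class = "sat_run_report")
}

#' @export
print.sat_run_report <- function(x, ...) {
  cat("satellite pipeline run\n")
  cat("  per-run counts (pairs -> merged -> retained):\n")
  print.data.frame(x$counts, row.names = FALSE)
  cat("  per-threshold clusters and species mixing:\n")
  print.data.frame(x$mixing, row.names = FALSE, digits = 4)
  invisible(x)
}
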