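#' Estimate a read's repeat content against a satellite library
#'
#' Every library monomer is aligned locally (Smith-Waterman, match +1,
#' mismatch -1, linear gap -2) to the read on both strands. Qualifying
#' alignments (identity >= `min_local_identity` over >= `min_length`
#' alignment columns) contribute their read interval; found intervals are
#' hard-masked and the search repeats until no further hit qualifies, so
#' several monomer copies along one read are all recovered. Intervals are
#' unioned; the repeat fraction is the union length over the read length.
#' Masking runs on a canonical orientation of the read (the
#' lexicographically smaller of read and reverse complement) so the
#' repeat fraction is exactly strand-invariant; reported intervals are in
#' input-read coordinates.
#'
#' @param read single-row [seq_set] (or list with `id`, `bases`).
#' @param library [seq_set] of satellite monomers; `source` labels, when
#'   present, identify the originating species/library.
#' @param min_local_identity minimum alignment identity, default 0.7.
#' @param min_length minimum alignment length in columns, default 25.
#' @return Object of class `mask_annotation`: list with `read_id`,
#'   `intervals` (matrix of 0-based half-open `start`,`end`), `best_hit`
#'   (library id of the highest-scoring alignment, `NA` if none),
#'   `repeat_fraction`.
#' @export
mask_read <- function(read, library, min_local_identity = 0.7,
                      min_length = 25L) {
  bases <- as.character(read$bases)
  if (!nzchar(bases)) stop("empty read: ", read$id)
  if (nrow(library) == 0L) stop("empty satellite library")
  # mask on a canonical orientation so the repeat fraction is exactly
  # strand-invariant (traceback ties would otherwise let co-optimal
  # alignments qualify on one strand but not the other); intervals are
  # mirrored back onto the input read afterwards
  rc_bases <- revcomp(bases)
  flipped <- rc_bases < bases
  if (flipped) bases <- rc_bases
  lib2 <- c(library$bases, revcomp(library$bases))
  lib_ids <- rep(library$id, 2L)
  cur <- bases
  ivs <- NULL
  best_hit <- NA_character_
  best_score <- -Inf
  for (iter in seq_len(50L)) {
    hits <- .local_align_set(lib2, cur)
    ok <- hits$identity >= min_local_identity & hits$columns >= min_length
    if (!any(ok)) break
    top <- which(ok)[which.max(hits$score[ok])]
    if (hits$score[top] > best_score) {
      best_score <- hits$score[top]
      best_hit <- lib_ids[top]
    }
    s <- hits$sub_start[top]
    e <- hits$sub_end[top]
    ivs <- rbind(ivs, c(s, e))
    # hard-mask so the next round finds the next-best region
    substr(cur, s + 1L, e) <- strrep("N", e - s)
    if (sum(strsplit(cur, "")[[1]] != "N") < min_length) break
  }
  if (is.null(ivs)) {
    ivs <- matrix(integer(0), ncol = 2L)
    frac <- 0
  } else {
    if (flipped) {
      L <- nchar(bases)
      ivs <- cbind(L - ivs[, 2L], L - ivs[, 1L])
    }
    r <- IRanges::reduce(IRanges::IRanges(start = ivs[, 1L] + 1L,
                                          end = ivs[, 2L]))
    ivs <- cbind(start = IRanges::start(r) - 1L, end = IRanges::end(r))
    frac <- sum(IRanges::width(r)) / nchar(bases)
  }
  colnames(ivs) <- c("start", "end")
  structure(list(read_id = as.character(read$id), intervals = ivs,
                 best_hit = best_hit, repeat_fraction = frac),
            class = "mask_annotation")
}

#' @export
print.mask_annotation <- function(x, ...) {
  cat(sprintf("mask_annotation for '%s': repeat fraction %.3f, best hit %s, %d interval(s)\n",
              x$read_id, x$repeat_fraction, x$best_hit, nrow(x$intervals)))
  invisible(x)
}

#' Retain reads that are (nearly) pure satellite
#'
#' Reads are masked with [mask_read()] and kept when their repeat
#' fraction reaches `threshold`. The default 0.99 focuses the downstream
#' clustering on tandemly arrayed repeats rather than solo, degenerate
#' monomers.
#'
#' @param reads [seq_set] of merged reads.
#' @param library satellite clone library as a [seq_set].
#' @param threshold retention threshold on the repeat fraction, in (0, 1].
#' @inheritParams mask_read
#' @return List with `retained` (a [seq_set]) and `stats`: `initial`,
#'   `retained`, `best_hit_tally` (per-library-id counts over retained
#'   reads) and `report`, a data frame with columns `read_id`,
#'   `best_hit`, `repeat_fraction`, `kept`.
#' @export
filter_reads <- function(reads, library, threshold = 0.99,
                         min_local_identity = 0.7, min_length = 25L) {
  stopifnot(threshold > 0, threshold <= 1)
  anns <- lapply(seq_len(nrow(reads)), function(i)
    mask_read(reads[i, ], library, min_local_identity, min_length))
  frac <- vapply(anns, `[[`, 0, "repeat_fraction")
  best <- vapply(anns, `[[`, "", "best_hit")
  kept <- frac >= threshold
  report <- data.frame(read_id = reads$id, best_hit = best,
                       repeat_fraction = frac, kept = kept,
                       stringsAsFactors = FALSE)
  retained <- reads[kept, , drop = FALSE]
  class(retained) <- c("seq_set", "data.frame")
  list(retained = retained,
       stats = list(initial = nrow(reads), retained = sum(kept),
                    best_hit_tally = table(best[kept]),
                    report = report))
}

#' Locate the modal read-start window on a reference
#'
#' Each read is aligned locally to the reference (both read strands); its
#' start coordinate is the leftmost reference position of the best
#' alignment. The half-open window `[s, s + window)` containing the most
#' start coordinates is returned; ties break toward the smallest `s`.
#'
#' @param reads [seq_set] of retained reads.
#' @param reference single-row [seq_set]: the clone to anchor on.
#' @param window window width in bp, default 25.
#' @param min_score minimum local alignment score for a read to count.
#' @return Named integer vector `c(start, end)`, 0-based half-open, plus
#'   attribute `count`: number of starts inside the window.
#' @export
anchor_window <- function(reads, reference, window = 25L, min_score = 15) {
  stopifnot(window >= 1L)
  ref <- as.character(reference$bases)
  if (nchar(ref) < window) stop("reference shorter than window")
  starts <- integer(0)
  for (i in seq_len(nrow(reads))) {
    # pattern = read (both strands), subject = reference: sub_start is the
    # leftmost reference coordinate of the alignment, strand-symmetric
    hits <- .local_align_set(c(reads$bases[i], revcomp(reads$bases[i])), ref)
    top <- which.max(hits$score)
    if (hits$score[top] < min_score || hits$columns[top] == 0L) next
    starts <- c(starts, hits$sub_start[top])
  }
  if (length(starts) == 0L) stop("no anchors: no read aligns to the reference")
  L <- nchar(ref)
  cand <- 0:(L - window)
  counts <- vapply(cand, function(s) sum(starts >= s & starts < s + window), 0L)
  s <- cand[which.max(counts)]  # which.max takes the first maximum: smallest s
  structure(c(start = s, end = s + window), count = max(counts))
}
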