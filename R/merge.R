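#' Merge one read pair over its best 3' overlap
#'
#' The reverse mate is reverse-complemented, then every ungapped overlap
#' of length >= `min_overlap` between the forward read's 3' end and the
#' reverse-complemented mate's 5' end is scored as `matches - mismatches`.
#' The highest-scoring overlap whose mismatch rate is <=
#' `max_mismatch_rate` is chosen; score ties go to the longer overlap.
#' Within the overlap the base with the higher Phred quality is emitted
#' (ties keep the forward base) along with its quality. When no overlap
#' qualifies the pair is not merged and `NULL` is returned.
#'
#' @param fwd,rev single-row [seq_set]s (or lists with `id`, `bases`,
#'   `quals`): the forward mate and the reverse mate as sequenced.
#' @param min_overlap smallest admissible overlap, >= 10.
#' @param max_mismatch_rate largest admissible mismatch fraction in the
#'   overlap, in `[0, 0.5)`.
#' @return A list with `id`, `bases`, `quals`, `overlap_len`,
#'   `mismatches_in_overlap`, or `NULL` when the pair does not merge.
#' @examples
#' s <- "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC"
#' m <- merge_pair(list(id = "r", bases = s, quals = NA),
#'                 list(id = "r", bases = revcomp(s), quals = NA))
#' m$overlap_len  # 50: the mates span the same fragment
#' @export
merge_pair <- function(fwd, rev, min_overlap = 10L, max_mismatch_rate = 0.1) {
  stopifnot(min_overlap >= 10L, max_mismatch_rate >= 0, max_mismatch_rate < 0.5)
  f <- as.character(fwd$bases)
  r <- revcomp(as.character(rev$bases))
  fq <- if (is.null(fwd$quals) || is.na(fwd$quals)) rep(30L, nchar(f)) else
    phred_decode(fwd$quals)[[1]]
  rq <- if (is.null(rev$quals) || is.na(rev$quals)) rep(30L, nchar(r)) else
    rev(phred_decode(rev$quals)[[1]])  # reversed to track the revcomp
  fi <- utf8ToInt(f)
  ri <- utf8ToInt(r)
  m <- length(fi)
  n <- length(ri)
  max_ov <- min(m, n)
  if (max_ov < min_overlap) return(NULL)
  best <- NULL
  for (ov in seq.int(min_overlap, max_ov)) {
    fseg <- fi[(m - ov + 1L):m]
    rseg <- ri[1L:ov]
    mism <- sum(fseg != rseg)
    if (mism / ov > max_mismatch_rate) next
    sc <- (ov - mism) - mism
    # strict '>' plus ascending ov scan: ties resolved toward longer overlap
    if (is.null(best) || sc >= best$score) {
      if (is.null(best) || sc > best$score || ov > best$ov)
        best <- list(score = sc, ov = ov, mism = mism)
    }
  }
  if (is.null(best)) return(NULL)
  ov <- best$ov
  fo <- (m - ov + 1L):m
  ro <- 1L:ov
  take_rev <- rq[ro] > fq[fo]
  cons <- fi[fo]
  cons[take_rev] <- ri[ro][take_rev]
  consq <- pmax(fq[fo], rq[ro])
  bases <- intToUtf8(c(fi[seq_len(m - ov)], cons, ri[seq.int(ov + 1L, length.out = n - ov)]))
  quals <- c(fq[seq_len(m - ov)], consq, rq[seq.int(ov + 1L, length.out = n - ov)])
  list(id = as.character(fwd$id), bases = bases,
       quals = phred_encode(quals),
       overlap_len = ov, mismatches_in_overlap = best$mism)
}

#' Merge a collection of read pairs
#'
#' Applies [merge_pair()] to every pair; unmergeable pairs are dropped
#' and counted.
#'
#' @param pairs a `read_pairs` object from [pair_reads()].
#' @inheritParams merge_pair
#' @return List with `merged` (a [seq_set] with extra columns
#'   `overlap_len`, `mismatches_in_overlap`) and `stats`
#'   (`total`, `merged`, `unmerged`).
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_mismatch_rate = 0.1) {
  stopifnot(inherits(pairs, "read_pairs"))
  res <- lapply(seq_along(pairs$id), function(i) {
    merge_pair(pairs$fwd[i, ], pairs$rev[i, ],
               min_overlap = min_overlap,
               max_mismatch_rate = max_mismatch_rate)
  })
  ok <- !vapply(res, is.null, logical(1))
  res <- res[ok]
  merged <- if (length(res)) {
    out <- seq_set(id = pairs$id[ok],
                   bases = vapply(res, `[[`, "", "bases"),
                   quals = vapply(res, `[[`, "", "quals"),
                   source = pairs$fwd$source[ok])
    out$overlap_len <- vapply(res, `[[`, 0L, "overlap_len")
    out$mismatches_in_overlap <- vapply(res, `[[`, 0L, "mismatches_in_overlap")
    out
  } else {
    seq_set(character(0), character(0))
  }
  list(merged = merged,
       stats = list(total = length(ok), merged = sum(ok),
                    unmerged = sum(!ok)))
}
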