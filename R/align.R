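# Internal alignment kernels shared by the screening, clustering and
# graph modules. All are thin wrappers over Biostrings::pairwiseAlignment
# with the toolkit's declared scoring schemes:
#   * ends-free global ("overlap"): match +1, mismatch -1,
#     gap open -2, gap extend -1 (a gap of length L costs 2 + L)
#   * local (Smith-Waterman):       match +1, mismatch -1, linear gap -2
# Identity is matched columns / alignment columns, terminal-gap columns
# excluded (the "overlap" type clips the unaligned overhangs).

ALN_BASES <- c("A", "C", "G", "T", "N")

# substitution matrix over A/C/G/T/N; N mismatches everything incl. itself,
# so hard-masked stretches can never re-align
.submat_acgtn <- local({
  m <- matrix(-1, 5L, 5L, dimnames = list(ALN_BASES, ALN_BASES))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
})

# substitution matrix over the full IUPAC alphabet: +1 when the two codes'
# base sets intersect ("ambiguity counts as match iff it contains the other
# base"), -1 otherwise
.submat_iupac <- local({
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  n <- length(codes)
  m <- matrix(-1, n, n, dimnames = list(codes, codes))
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (length(intersect(sets[[i]], sets[[j]]))) m[i, j] <- 1
  m["N", "N"] <- 1
  m
})

# per-column match indicator under the IUPAC intersection rule
.iupac_cols_match <- function(a_chars, b_chars) {
  sets <- Biostrings::IUPAC_CODE_MAP
  av <- sets[a_chars]
  bv <- sets[b_chars]
  ok <- !is.na(av) & !is.na(bv)
  out <- logical(length(a_chars))
  out[ok] <- mapply(function(x, y) {
    any(strsplit(x, "")[[1]] %in% strsplit(y, "")[[1]])
  }, av[ok], bv[ok])
  out
}

# Identity of one subject vs a set of patterns under ends-free global
# alignment over the span of the shorter sequence: the shorter sequence
# of each pair is aligned end to end, terminal gaps on the longer one are
# free (the cd-hit-est notion of identity; a plain ends-free alignment
# would collapse to a short, spuriously perfect overlap on divergent
# pairs). Returns data.frame(identity, columns, matches, score).
.overlap_identity_set <- function(patterns, subject, ambiguity = FALSE) {
  submat <- if (ambiguity) .submat_iupac else .submat_acgtn
  pl <- nchar(patterns)
  sl <- nchar(subject)
  n <- length(patterns)
  out <- data.frame(identity = numeric(n), columns = integer(n),
                    matches = integer(n), score = numeric(n))
  run <- function(idx, type) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(patterns[idx]), Biostrings::DNAString(subject),
      type = type, substitutionMatrix = submat,
      gapOpening = 2, gapExtension = 1)
    p <- as.character(Biostrings::pattern(aln))
    s <- as.character(Biostrings::subject(aln))
    cols <- nchar(p)
    matches <- mapply(function(pp, ss) {
      if (nchar(pp) == 0L) return(0L)
      pc <- strsplit(pp, "")[[1]]
      sc <- strsplit(ss, "")[[1]]
      if (ambiguity) sum(.iupac_cols_match(pc, sc)) else sum(pc == sc)
    }, p, s, USE.NAMES = FALSE)
    out$identity[idx] <<- ifelse(cols > 0L, matches / cols, 0)
    out$columns[idx] <<- cols
    out$matches[idx] <<- as.integer(matches)
    out$score[idx] <<- Biostrings::score(aln)
  }
  # pattern longer or equal: subject is the shorter -> global in subject
  long <- which(pl >= sl)
  short <- which(pl < sl)
  if (length(long)) run(long, "local-global")
  if (length(short)) run(short, "global-local")
  out
}

# best local (Smith-Waterman) alignment of each pattern vs one subject.
# Coordinates returned 0-based half-open on the subject (the read) and
# the pattern. Returns a data.frame; rows with score <= 0 have columns 0.
.local_align_set <- function(patterns, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = .submat_acgtn,
    gapOpening = 0, gapExtension = 2)
  p <- as.character(Biostrings::pattern(aln))
  s <- as.character(Biostrings::subject(aln))
  cols <- nchar(p)
  matches <- mapply(function(pp, ss) {
    if (nchar(pp) == 0L) return(0L)
    sum(strsplit(pp, "")[[1]] == strsplit(ss, "")[[1]])
  }, p, s, USE.NAMES = FALSE)
  sub_start <- Biostrings::start(Biostrings::subject(aln)) - 1L
  sub_end <- Biostrings::end(Biostrings::subject(aln))
  data.frame(score = Biostrings::score(aln),
             identity = ifelse(cols > 0L, matches / cols, 0),
             columns = cols, matches = matches,
             sub_start = sub_start, sub_end = sub_end)
}
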