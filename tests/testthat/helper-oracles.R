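# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package internals (except
# revcomp / pairwise_identity where the oracle's target is a different
# layer, e.g. the greedy assignment logic).

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# substitute exactly k distinct positions, each to a different base
mutate_at <- function(s, k, positions = NULL) {
  chars <- strsplit(s, "")[[1]]
  pos <- if (is.null(positions)) sample(length(chars), k) else positions
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# --- exhaustive-offset merge oracle ---------------------------------------
# scores every ungapped overlap >= min_overlap of fwd's 3' end with the
# reverse-complemented mate's 5' end; ties toward the longer overlap
merge_oracle <- function(fwd, rev, min_overlap = 10, max_rate = 0.1) {
  rc <- satconnect::revcomp(rev)
  f <- strsplit(fwd, "")[[1]]
  r <- strsplit(rc, "")[[1]]
  m <- length(f); n <- length(r)
  best <- NULL
  for (ov in seq_len(min(m, n))) {
    if (ov < min_overlap) next
    mism <- sum(f[(m - ov + 1):m] != r[1:ov])
    if (mism / ov > max_rate) next
    sc <- ov - 2 * mism
    if (is.null(best) || sc > best$score ||
        (sc == best$score && ov > best$ov))
      best <- list(score = sc, ov = ov, mism = mism)
  }
  best
}

# --- plain-R Smith-Waterman oracle ----------------------------------------
# match +1, mismatch -1, linear gap -2; returns the best local alignment's
# score, matched/total columns and 0-based half-open interval on b
sw_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  ptr <- matrix(0L, n + 1, m + 1)  # 1 diag, 2 up, 3 left
  best <- c(0, 1, 1)
  for (i in 1:n) for (j in 1:m) {
    d <- H[i, j] + if (A[i] == B[j]) 1 else -1
    u <- H[i, j + 1] - 2
    l <- H[i + 1, j] - 2
    v <- max(0, d, u, l)
    H[i + 1, j + 1] <- v
    ptr[i + 1, j + 1] <- if (v == 0) 0L else if (v == d) 1L else if (v == u) 2L else 3L
    if (v > best[1]) best <- c(v, i + 1, j + 1)
  }
  if (best[1] == 0) return(list(score = 0, matches = 0, columns = 0))
  i <- best[2]; j <- best[3]
  matches <- 0L; cols <- 0L
  while (i > 1 && j > 1 && ptr[i, j] != 0L) {
    cols <- cols + 1L
    if (ptr[i, j] == 1L) {
      if (A[i - 1] == B[j - 1]) matches <- matches + 1L
      i <- i - 1; j <- j - 1
    } else if (ptr[i, j] == 2L) i <- i - 1 else j <- j - 1
  }
  list(score = best[1], matches = matches, columns = cols,
       b_start = j - 1, b_end = best[3] - 1)
}

# both-strand SW similarity percent, the oracle for cluster_similarity
sw_similarity_oracle <- function(a, b) {
  h1 <- sw_oracle(b, a)
  h2 <- sw_oracle(satconnect::revcomp(b), a)
  h <- if (h1$score >= h2$score) h1 else h2
  if (h$columns == 0) 0 else 100 * h$matches / h$columns
}

# --- brute-force greedy clustering oracle ---------------------------------
# recomputes the full scan over an explicit identity matrix; shares only
# pairwise_identity with the implementation (the oracle's target is the
# assignment logic, not the aligner)
greedy_oracle <- function(seqs, threshold, cutoff = 0.8,
                          assignment = "best") {
  ord <- order(-nchar(seqs$bases), seqs$id)
  seqs <- seqs[ord, ]
  reps <- integer(0)
  members <- list()
  for (i in seq_len(nrow(seqs))) {
    assigned <- FALSE
    if (length(reps)) {
      ratio <- nchar(seqs$bases[i]) / nchar(seqs$bases[reps])
      elig <- which(pmin(ratio, 1 / ratio) >= cutoff)
      if (length(elig)) {
        ident <- vapply(elig, function(k)
          satconnect::pairwise_identity(seqs$bases[reps[k]], seqs$bases[i]), 0)
        hit <- ident >= threshold
        if (any(hit)) {
          k <- if (assignment == "best") elig[which.max(ident)] else elig[which(hit)[1]]
          members[[k]] <- c(members[[k]], seqs$id[i])
          assigned <- TRUE
        }
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      members[[length(reps)]] <- seqs$id[i]
    }
  }
  members
}

# --- spanning-tree enumeration via Pruefer sequences ----------------------
# minimum total distance over all n^(n-2) labelled spanning trees
min_spanning_cost_oracle <- function(dist) {
  n <- nrow(dist)
  if (n == 2) return(dist[1, 2])
  decode <- function(prf) {
    degree <- rep(1L, n)
    for (v in prf) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1, 2)
    for (k in seq_along(prf)) {
      leaf <- which(degree == 1L)[1]
      edges[k, ] <- c(leaf, prf[k])
      degree[leaf] <- degree[leaf] - 1L
      degree[prf[k]] <- degree[prf[k]] - 1L
    }
    last <- which(degree == 1L)
    edges[n - 1, ] <- last
    edges
  }
  grid <- do.call(expand.grid, rep(list(seq_len(n)), n - 2))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    e <- decode(as.integer(grid[r, ]))
    best <- min(best, sum(dist[e]))
  }
  best
}

# --- exhaustive motif window scan oracle ----------------------------------
scan_oracle <- function(seq, motif, critical) {
  w <- nchar(motif)
  mot <- strsplit(motif, "")[[1]]
  informative <- which(mot != "N")
  iupac <- Biostrings::IUPAC_CODE_MAP
  match1 <- function(a, b) {
    any(strsplit(iupac[[a]], "")[[1]] %in% strsplit(iupac[[b]], "")[[1]])
  }
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else satconnect::revcomp(seq)
    chars <- strsplit(s, "")[[1]]
    for (st in seq_len(nchar(s) - w + 1)) {
      win <- chars[st:(st + w - 1)]
      m <- vapply(seq_len(w), function(k) match1(win[k], mot[k]), logical(1))
      offset <- if (strand == "+") st - 1 else nchar(seq) - w - (st - 1)
      cand <- list(offset = offset, strand = strand,
                   crit = sum(m[critical]), total = sum(m[informative]))
      if (is.null(best) ||
          cand$crit > best$crit ||
          (cand$crit == best$crit && cand$total > best$total) ||
          (cand$crit == best$crit && cand$total == best$total &&
           cand$offset < best$offset) ||
          (cand$crit == best$crit && cand$total == best$total &&
           cand$offset == best$offset && cand$strand == "+" &&
           best$strand == "-"))
        best <- cand
    }
  }
  best
}

# --- exhaustive anchor-window scan ----------------------------------------
anchor_oracle <- function(starts, ref_len, window) {
  cand <- 0:(ref_len - window)
  counts <- vapply(cand, function(s) sum(starts >= s & starts < s + window), 0L)
  s <- cand[which.max(counts)]
  c(start = s, end = s + window)
}
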