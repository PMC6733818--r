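#' Consensus monomer from a set of clones
#'
#' Progressive multiple alignment: clones are ordered by mean pairwise
#' identity (most central first) and added one at a time by global
#' alignment against the running majority-rule consensus of the profile.
#' Per column the majority base is called; ties become the IUPAC code of
#' the tied base set; columns with more than 50% gaps are dropped.
#'
#' @param clones [seq_set] with at least 2 records.
#' @param species label stored on the consensus (defaults to the clones'
#'   common `source`, if any).
#' @return Object of class `consensus_monomer`: list with `species`,
#'   `bases` (may contain IUPAC codes), `depth` (clone count) and the
#'   alignment matrix as attribute `alignment`.
#' @export
build_consensus <- function(clones, species = NULL) {
  if (nrow(clones) < 2L) stop("need >= 2 clones for a consensus")
  if (is.null(species)) {
    src <- unique(clones$source[!is.na(clones$source)])
    species <- if (length(src) == 1L) src else NA_character_
  }
  n <- nrow(clones)
  # guide order: decreasing mean pairwise identity to all other clones
  idm <- matrix(1, n, n)
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n)) {
      idm[i, j] <- idm[j, i] <- pairwise_identity(clones$bases[i], clones$bases[j])
    }
  ord <- order(-rowMeans(idm), clones$id)
  aln <- matrix(strsplit(clones$bases[ord[1L]], "")[[1]], nrow = 1L)
  for (i in ord[-1L]) {
    cons <- .profile_consensus(aln)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(clones$bases[i]), Biostrings::DNAString(cons),
      type = "global", substitutionMatrix = .submat_iupac,
      gapOpening = 2, gapExtension = 1)
    new_chars <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
    cons_chars <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
    # map profile columns onto the alignment columns; cons gap = insertion
    out <- matrix("-", nrow(aln) + 1L, length(cons_chars))
    prof_col <- 0L
    for (k in seq_along(cons_chars)) {
      if (cons_chars[k] != "-") {
        prof_col <- prof_col + 1L
        out[seq_len(nrow(aln)), k] <- aln[, prof_col]
      }
      out[nrow(aln) + 1L, k] <- new_chars[k]
    }
    aln <- out
  }
  # undo the guide reordering so rows match input order
  aln <- aln[order(ord), , drop = FALSE]
  gap_frac <- colMeans(aln == "-")
  keep <- gap_frac <= 0.5
  cons <- .profile_consensus(aln[, keep, drop = FALSE])
  structure(list(species = species, bases = cons, depth = n),
            alignment = aln, class = "consensus_monomer")
}

# majority-rule consensus of a character alignment matrix; ties -> IUPAC
.profile_consensus <- function(aln) {
  rev_iupac <- setNames(names(Biostrings::IUPAC_CODE_MAP),
                        Biostrings::IUPAC_CODE_MAP)
  cols <- vapply(seq_len(ncol(aln)), function(k) {
    v <- aln[, k]
    v <- v[v != "-" & v != "N"]
    if (length(v) == 0L) return("N")
    # expand ambiguity codes already present into their base sets
    tab <- table(unlist(strsplit(Biostrings::IUPAC_CODE_MAP[v], "")))
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else rev_iupac[paste(sort(top), collapse = "")]
  }, "")
  paste(cols, collapse = "")
}

#' @export
print.consensus_monomer <- function(x, ...) {
  cat(sprintf("consensus_monomer (%s): %d bp from %d clones\n",
              x$species, nchar(x$bases), x$depth))
  invisible(x)
}

#' Intra- or inter-specific identity of satellite groups
#'
#' `mode = "intra"`: per group, the mean [pairwise_identity()] over all
#' unordered clone pairs, in percent, plus the group's consensus monomer
#' length. `mode = "inter"`: the symmetric matrix of percent identities
#' between the groups' consensus monomers ([build_consensus()]), with
#' IUPAC ambiguity codes counting as matches when compatible.
#'
#' @param groups named list: label -> [seq_set] of clones.
#' @param mode `"intra"` or `"inter"`.
#' @return For `"intra"`, a data frame (`label`, `identity`,
#'   `monomer_length`, `n_clones`); for `"inter"`, a square percent
#'   matrix with the labels on both dimensions and diagonal 100.
#' @export
identity_matrix <- function(groups, mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  labels <- names(groups)
  if (mode == "intra") {
    rows <- lapply(labels, function(lab) {
      cl <- groups[[lab]]
      if (nrow(cl) < 2L) stop("group '", lab, "' has < 2 clones")
      pairs <- utils::combn(nrow(cl), 2L)
      ids <- vapply(seq_len(ncol(pairs)), function(k)
        pairwise_identity(cl$bases[pairs[1L, k]], cl$bases[pairs[2L, k]]), 0)
      cons <- build_consensus(cl, species = lab)
      data.frame(label = lab, identity = 100 * mean(ids),
                 monomer_length = nchar(cons$bases), n_clones = nrow(cl))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  } else {
    cons <- lapply(labels, function(lab)
      build_consensus(groups[[lab]], species = lab)$bases)
    n <- length(labels)
    m <- matrix(100, n, n, dimnames = list(labels, labels))
    if (n >= 2L)
      for (i in seq_len(n - 1L))
        for (j in seq.int(i + 1L, n)) {
          m[i, j] <- m[j, i] <-
            100 * pairwise_identity(cons[[i]], cons[[j]], ambiguity = TRUE)
        }
    m
  }
}

#' Flag pairs where interspecific identity exceeds intraspecific identity
#'
#' The asterisk rule of the identity-matrix display: every ordered pair
#' `(i, j)` with `inter(i, j) > intra(i)` is flagged. Flags are evidence
#' against unchecked concerted evolution: the repeat is more similar
#' across species `j` than it is within species `i`.
#'
#' @param intra data frame from `identity_matrix(..., "intra")` (or a
#'   named numeric vector of percent identities).
#' @param inter square percent matrix from `identity_matrix(..., "inter")`.
#' @return Data frame of flagged pairs: `species`, `versus`,
#'   `intra_identity`, `inter_identity`.
#' @export
concerted_evolution_test <- function(intra, inter) {
  iv <- if (is.data.frame(intra)) setNames(intra$identity, intra$label) else intra
  labs <- rownames(inter)
  stopifnot(setequal(labs, names(iv)))
  out <- data.frame(species = character(0), versus = character(0),
                    intra_identity = numeric(0), inter_identity = numeric(0))
  for (i in labs)
    for (j in setdiff(labs, i))
      if (inter[i, j] > iv[[i]])
        out <- rbind(out, data.frame(species = i, versus = j,
                                     intra_identity = iv[[i]],
                                     inter_identity = inter[i, j]))
  out
}

#' The human 17-bp CENP-B box motif and its critical positions
#'
#' Loads the motif configuration shipped with the package: the 17-bp
#' consensus CENP-B DNA-binding motif from human alpha satellite and the
#' nine positions critical for CENP-B binding. The motif is data, not a
#' constant: pass your own file to score a different motif.
#'
#' @param path motif file: line 1 the 17-bp motif, line 2 the
#'   space-separated 1-based critical positions.
#' @return List with `motif` (character) and `critical` (integer vector).
#' @export
cenpb_motif <- function(path = system.file("extdata", "cenpb_motif.txt",
                                           package = "satconnect")) {
  lines <- readLines(path)
  list(motif = toupper(trimws(lines[1L])),
       critical = as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1]]))
}

#' Scan a consensus monomer for the CENP-B box
#'
#' Every window of motif length on both strands is scored by the number
#' of critical motif positions matched (IUPAC codes on the consensus
#' count as a match when they contain the motif base). Ties break toward
#' more total motif matches, then the smaller offset, then the + strand.
#'
#' @param consensus a `consensus_monomer` (or character sequence).
#' @param motif list as returned by [cenpb_motif()].
#' @return Object of class `motif_hit`: list with `offset` (0-based, on
#'   the forward consensus), `strand`, `critical_matches`,
#'   `matched_positions` (1-based motif positions, subset of critical),
#'   `total_matches`, `window` (the matched consensus sequence).
#' @export
scan_cenpb <- function(consensus, motif = cenpb_motif()) {
  seq <- if (is.list(consensus)) consensus$bases else as.character(consensus)
  w <- nchar(motif$motif)
  if (nchar(seq) < w) stop("consensus shorter than the motif")
  mot <- strsplit(motif$motif, "")[[1]]
  informative <- which(mot != "N")
  score_windows <- function(s) {
    L <- nchar(s)
    starts <- seq_len(L - w + 1L)
    chars <- strsplit(s, "")[[1]]
    t(vapply(starts, function(st) {
      win <- chars[st:(st + w - 1L)]
      m <- .iupac_cols_match(win, mot)
      c(crit = sum(m[motif$critical]), total = sum(m[informative]))
    }, c(crit = 0, total = 0)))
  }
  fwd <- score_windows(seq)
  rc <- score_windows(revcomp(seq))
  L <- nchar(seq)
  cand <- rbind(
    data.frame(offset = seq_len(nrow(fwd)) - 1L, strand = "+",
               crit = fwd[, "crit"], total = fwd[, "total"]),
    # offset of a - strand window, mapped back to forward coordinates
    data.frame(offset = L - w - (seq_len(nrow(rc)) - 1L), strand = "-",
               crit = rc[, "crit"], total = rc[, "total"]))
  ord <- order(-cand$crit, -cand$total, cand$offset,
               match(cand$strand, c("+", "-")))
  best <- cand[ord[1L], ]
  win_fwd <- substr(seq, best$offset + 1L, best$offset + w)
  win <- if (best$strand == "+") win_fwd else revcomp(win_fwd)
  matched <- motif$critical[.iupac_cols_match(strsplit(win, "")[[1]], mot)[motif$critical]]
  structure(list(offset = best$offset, strand = best$strand,
                 critical_matches = as.integer(best$crit),
                 matched_positions = matched,
                 total_matches = as.integer(best$total),
                 window = win),
            class = "motif_hit")
}

#' @export
print.motif_hit <- function(x, ...) {
  cat(sprintf("motif_hit: offset %d (%s), %d/9 critical positions matched (%s)\n",
              x$offset, x$strand, x$critical_matches,
              paste(x$matched_positions, collapse = ",")))
  invisible(x)
}

#' In-silico complete restriction digestion of a tandem array
#'
#' Cuts at every exact occurrence of the recognition site. For MspI
#' (C^CGG, the default) the cut falls after the first base of the site
#' (`cut_offset = 1`). A homogeneous tandem array whose monomer carries
#' one site yields the monomer-periodic fragment ladder seen on a
#' Southern blot of satellite DNA.
#'
#' @param array single-row [seq_set] or character sequence.
#' @param site recognition sequence, default `"CCGG"` (MspI).
#' @param cut_offset cut position within the site, default 1 (C^CGG).
#' @param monomer_length monomer length used to bin the ladder.
#' @return Object of class `digest_profile`: list with
#'   `fragment_lengths` (integer multiset, 5' to 3') and
#'   `monomer_length`.
#' @export
digest_array <- function(array, site = "CCGG", cut_offset = 1L,
                         monomer_length = 345L) {
  seq <- if (is.list(array) || is.data.frame(array)) as.character(array$bases)
         else as.character(array)
  stopifnot(nzchar(seq), nzchar(site))
  L <- nchar(seq)
  hits <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(site), Biostrings::DNAString(seq)))
  cuts <- hits - 1L + cut_offset          # 0-based cut coordinates
  cuts <- cuts[cuts > 0L & cuts < L]
  frags <- diff(c(0L, sort(cuts), L))
  structure(list(fragment_lengths = as.integer(frags),
                 monomer_length = as.integer(monomer_length)),
            class = "digest_profile")
}

#' Ladder summary of a digest profile
#'
#' Bins fragment lengths by `round(length / monomer_length)`: rung `k`
#' collects fragments of about `k` monomers.
#'
#' @param profile a `digest_profile`.
#' @return Data frame with `rung` (k) and `count`.
#' @export
ladder_summary <- function(profile) {
  stopifnot(inherits(profile, "digest_profile"))
  k <- round(profile$fragment_lengths / profile$monomer_length)
  tab <- table(k)
  data.frame(rung = as.integer(names(tab)), count = as.integer(tab))
}

#' @export
print.digest_profile <- function(x, ...) {
  cat(sprintf("digest_profile: %d fragment(s), total %d bp (monomer %d bp)\n",
              length(x$fragment_lengths), sum(x$fragment_lengths),
              x$monomer_length))
  print(ladder_summary(x))
  invisible(x)
}
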