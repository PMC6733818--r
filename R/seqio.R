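#' Sequence record collections
#'
#' A `seq_set` is the container every stage of the toolkit consumes and
#' produces: a data frame with one row per sequence record and columns
#' `id` (unique label), `bases` (uppercase string over A/C/G/T/N, IUPAC
#' ambiguity codes tolerated for consensus sequences), `quals` (Phred+33
#' encoded quality string of the same length, or `NA` for FASTA-derived
#' records) and `source` (originating library/run label, or `NA`).
#'
#' @param id character vector of record identifiers.
#' @param bases character vector of sequences.
#' @param quals optional character vector of Phred+33 quality strings.
#' @param source optional character vector of library labels.
#' @return A data frame of class `seq_set`.
#' @examples
#' seq_set(c("r1", "r2"), c("ACGT", "GGGTTT"))
#' @export
seq_set <- function(id, bases, quals = NA_character_, source = NA_character_) {
  id <- as.character(id)
  bases <- toupper(as.character(bases))
  x <- data.frame(id = id, bases = bases,
                  quals = rep_len(as.character(quals), length(id)),
                  source = rep_len(as.character(source), length(id)),
                  stringsAsFactors = FALSE)
  validate_seq_set(x)
  class(x) <- c("seq_set", "data.frame")
  x
}

validate_seq_set <- function(x) {
  if (any(nchar(x$bases) == 0L))
    stop("empty sequence for record(s): ",
         paste(x$id[nchar(x$bases) == 0L], collapse = ", "))
  if (anyDuplicated(x$id))
    stop("duplicate record id(s): ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  bad <- grepl("[^ACGTNRYSWKMBDHV-]", x$bases)
  if (any(bad))
    stop("invalid characters in bases of: ",
         paste(x$id[bad], collapse = ", "))
  has_q <- !is.na(x$quals)
  if (any(has_q & nchar(x$quals) != nchar(x$bases)))
    stop("quality/sequence length mismatch for: ",
         paste(x$id[has_q & nchar(x$quals) != nchar(x$bases)], collapse = ", "))
  invisible(x)
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set with %d record(s); lengths %d-%d bp\n",
              nrow(x), if (nrow(x)) min(nchar(x$bases)) else 0L,
              if (nrow(x)) max(nchar(x$bases)) else 0L))
  print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param quals character vector of quality strings.
#' @return List of integer vectors.
#' @export
phred_decode <- function(quals) {
  lapply(quals, function(q) {
    if (is.na(q)) return(integer(0))
    utf8ToInt(q) - 33L
  })
}

#' Encode integer Phred scores as a Phred+33 string
#' @param scores integer vector.
#' @return character scalar.
#' @export
phred_encode <- function(scores) {
  if (length(scores) == 0L) return("")
  intToUtf8(as.integer(scores) + 33L)
}

#' Reverse complement of nucleotide strings
#'
#' IUPAC ambiguity codes are complemented correctly (delegates to
#' Biostrings).
#'
#' @param x character vector of sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read sequences from FASTA or FASTQ
#'
#' FASTA may be wrapped or single-line; FASTQ must be canonical 4-line
#' records with Phred+33 qualities. Bases are uppercased; record order is
#' preserved. Malformed records raise an error naming the offending line.
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"`; default guessed from the
#'   extension (`.fq`/`.fastq` means FASTQ).
#' @param source optional library label stored on every record.
#' @return A [seq_set].
#' @export
read_sequences <- function(path, format = NULL, source = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  format <- match.arg(format, c("fasta", "fastq"))
  lines <- readLines(path)
  if (format == "fasta") parse_fasta(lines, source) else parse_fastq(lines, source)
}

parse_fasta <- function(lines, source) {
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty FASTA input")
  hdr <- startsWith(lines, ">")
  if (!hdr[1L])
    stop("FASTA parse error at line ", lineno[1L], ": expected '>' header")
  grp <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  bases <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  # headers with no sequence line at all
  n_seq <- tabulate(grp[!hdr], nbins = sum(hdr))
  if (any(n_seq == 0L)) {
    bad <- which(n_seq == 0L)[1L]
    stop("FASTA parse error at line ", lineno[hdr][bad],
         ": header '", ids[bad], "' has no sequence")
  }
  seq_set(ids, bases, source = source)
}

parse_fastq <- function(lines, source) {
  keep <- nzchar(lines)
  if (!all(keep)) lines <- lines[keep]
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("FASTQ parse error: ", n, " non-empty lines is not a multiple of 4")
  if (n == 0L)
    return(seq_set(character(0), character(0)))
  i <- seq(1L, n, by = 4L)
  if (!all(startsWith(lines[i], "@"))) {
    bad <- i[!startsWith(lines[i], "@")][1L]
    stop("FASTQ parse error at line ", bad, ": expected '@' header")
  }
  if (!all(startsWith(lines[i + 2L], "+"))) {
    bad <- (i + 2L)[!startsWith(lines[i + 2L], "+")][1L]
    stop("FASTQ parse error at line ", bad, ": expected '+' separator")
  }
  ids <- sub("\\s.*$", "", sub("^@", "", lines[i]))
  bases <- lines[i + 1L]
  quals <- lines[i + 3L]
  mism <- nchar(bases) != nchar(quals)
  if (any(mism)) {
    bad <- which(mism)[1L]
    stop("FASTQ format error at line ", i[bad] + 3L,
         ": quality length != sequence length for '", ids[bad], "'")
  }
  seq_set(ids, bases, quals = quals, source = source)
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTA is written single-line; FASTQ canonical 4-line. FASTQ records
#' lacking qualities get constant Q30.
#'
#' @param x a [seq_set].
#' @param path output file path.
#' @param format `"fasta"` or `"fastq"`; default guessed from extension.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  format <- match.arg(format, c("fasta", "fastq"))
  if (nrow(x) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (format == "fasta") {
    out <- as.vector(rbind(paste0(">", x$id), x$bases))
  } else {
    quals <- x$quals
    fallback <- strrep(rawToChar(as.raw(33L + 30L)), nchar(x$bases))
    quals[is.na(quals)] <- fallback[is.na(quals)]
    out <- as.vector(rbind(paste0("@", x$id), x$bases, "+", quals))
  }
  writeLines(out, path)
  invisible(path)
}

#' Pair forward and reverse mate collections
#'
#' Mates must come in matching order; ids are compared after stripping a
#' trailing `/1`, `/2`, `_1`, `_2` or `.1`/`.2` mate suffix. The reverse
#' mate is stored exactly as given (not reverse-complemented).
#'
#' @param fwd,rev [seq_set]s of equal length.
#' @return Object of class `read_pairs`: list with elements `id`
#'   (stripped pair ids), `fwd` and `rev`.
#' @export
pair_reads <- function(fwd, rev) {
  if (nrow(fwd) != nrow(rev))
    stop("pairing error: ", nrow(fwd), " forward vs ", nrow(rev),
         " reverse reads")
  strip <- function(id) sub("([/._][12])$", "", id)
  fid <- strip(fwd$id)
  rid <- strip(rev$id)
  bad <- which(fid != rid)
  if (length(bad))
    stop("pairing error at rank ", bad[1L], ": '", fwd$id[bad[1L]],
         "' vs '", rev$id[bad[1L]], "'")
  structure(list(id = fid, fwd = fwd, rev = rev), class = "read_pairs")
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("read_pairs with %d pair(s)\n", length(x$id)))
  invisible(x)
}

#' @export
length.read_pairs <- function(x) length(x$id)
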