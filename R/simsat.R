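#' Simulation configuration for satellite evolution
#'
#' Bundles every knob of the synthetic-data generator. The defaults
#' describe a four-species rodent-like clade with a ~345-bp centromeric
#' satellite monomer, branch lengths in substitutions per site, and two
#' contrasting regimes:
#'
#' * `mode = "drive"` — molecular drive / concerted evolution: every
#'   site is free to mutate and gene-conversion-like homogenization
#'   events (`homogenization_rate` events per monomer per branch-unit)
#'   repeatedly copy one monomer over another within a lineage, keeping
#'   intraspecific identity high while species drift apart.
#' * `mode = "frozen"` — a conserved satellite: no homogenization and a
#'   large constrained fraction of sites that cannot mutate, so both
#'   intra- and inter-specific identity stay high and roughly equal.
#'
#' @param mode `"drive"` or `"frozen"`.
#' @param seed integer seed; fixes all generator output.
#' @param tree Newick string or `ape::phylo`, branch lengths in
#'   substitutions/site.
#' @param n_monomers monomers per species library.
#' @param monomer_length ancestral monomer length (bp).
#' @param rate substitution-rate multiplier on branch lengths.
#' @param homogenization_rate homogenization events per monomer per
#'   branch-unit (drive mode; must be > 0 there).
#' @param constrained_fraction fraction of immutable sites in frozen
#'   mode.
#' @param site restriction recognition site carried once per ancestral
#'   monomer (MspI `CCGG` by default).
#' @param copies_per_array monomer copies per simulated tandem array.
#' @param site_ablation_prob probability that a copy's restriction site
#'   is destroyed by a single substitution when building an array.
#' @param read_length,insert_size,error_rate,n_pairs paired-end read
#'   model: read and insert lengths (bp), per-base substitution error
#'   rate, pairs per species.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(mode = c("drive", "frozen"),
                       seed = 1L,
                       tree = "((maniculatus:0.04,polionotus:0.03):0.06,((californicus:0.05,eremicus:0.05):0.04,leucopus:0.09):0.01);",
                       n_monomers = 8L,
                       monomer_length = 345L,
                       rate = 1.0,
                       homogenization_rate = 400,
                       constrained_fraction = 0.95,
                       site = "CCGG",
                       copies_per_array = 40L,
                       site_ablation_prob = 0.3,
                       read_length = 150L,
                       insert_size = 260L,
                       error_rate = 0.005,
                       n_pairs = 240L) {
  mode <- match.arg(mode)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            rate >= 0, homogenization_rate >= 0,
            constrained_fraction >= 0, constrained_fraction < 1,
            insert_size >= read_length, error_rate >= 0,
            site_ablation_prob >= 0, site_ablation_prob <= 1)
  if (mode == "drive" && homogenization_rate <= 0)
    stop("drive mode requires homogenization_rate > 0")
  structure(list(mode = mode, seed = as.integer(seed), tree = tree,
                 n_monomers = as.integer(n_monomers),
                 monomer_length = as.integer(monomer_length),
                 rate = rate,
                 homogenization_rate = if (mode == "drive") homogenization_rate else 0,
                 constrained_fraction = if (mode == "frozen") constrained_fraction else 0,
                 site = site,
                 copies_per_array = as.integer(copies_per_array),
                 site_ablation_prob = site_ablation_prob,
                 read_length = as.integer(read_length),
                 insert_size = as.integer(insert_size),
                 error_rate = error_rate,
                 n_pairs = as.integer(n_pairs)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: mode %s, %d species, %d monomers/species of %d bp, seed %d\n",
              x$mode, length(x$tree$tip.label), x$n_monomers,
              x$monomer_length, x$seed))
  invisible(x)
}

BASES <- c("A", "C", "G", "T")

#' Random satellite monomer with one planted restriction site
#'
#' Uniform random bases, regenerated until the recognition site occurs
#' exactly once, at the planted position.
#'
#' @param length monomer length (bp).
#' @param site recognition site to plant.
#' @param site_pos 0-based position of the planted site.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return Character monomer sequence.
#' @export
random_monomer <- function(length = 345L, site = "CCGG", site_pos = 100L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(site_pos + nchar(site) <= length)
  repeat {
    s <- paste(sample(BASES, length, replace = TRUE), collapse = "")
    substr(s, site_pos + 1L, site_pos + nchar(site)) <- site
    if (length(gregexpr(site, s, fixed = TRUE)[[1]]) == 1L) return(s)
  }
}

# substitute k uniform positions (from `free`) of a monomer, each to one
# of the three alternative bases (Jukes-Cantor-like, no indels)
.mutate <- function(bases, p_sub, free) {
  chars <- strsplit(bases, "")[[1]]
  n_mut <- rbinom(1L, length(free), p_sub)
  if (n_mut == 0L) return(bases)
  pos <- if (length(free) == 1L) free else sample(free, n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# evolve one species library along one branch; monomers is a character
# vector. Homogenization events are placed uniformly along the branch and
# interleaved with substitution accumulation.
.evolve_branch <- function(monomers, blen, config, free) {
  n <- length(monomers)
  n_events <- if (config$homogenization_rate > 0)
    rpois(1L, config$homogenization_rate * blen * n) else 0L
  times <- sort(runif(n_events)) * blen
  bounds <- c(0, times, blen)
  for (seg in seq_len(length(bounds) - 1L)) {
    dt <- bounds[seg + 1L] - bounds[seg]
    if (dt > 0) {
      p <- dt * config$rate
      monomers <- vapply(monomers, .mutate, "", p_sub = p, free = free,
                         USE.NAMES = FALSE)
    }
    if (seg <= n_events) {
      donor <- sample(n, 1L)
      recipient <- sample(n, 1L)
      monomers[recipient] <- monomers[donor]  # gene-conversion analog
    }
  }
  monomers
}

#' Evolve satellite monomer libraries along a species tree
#'
#' Starting from `n_monomers` identical copies of the ancestral monomer
#' at the root, each branch accumulates substitutions at
#' `rate * branch length` per free site; in drive mode homogenization
#' events copy a random donor monomer over a random recipient at
#' `homogenization_rate` events per monomer per branch-unit; in frozen
#' mode a `constrained_fraction` of sites (drawn once at the root) never
#' mutates and there is no homogenization.
#'
#' @param config a [sim_config()].
#' @param ancestral optional ancestral monomer sequence; by default a
#'   [random_monomer()] drawn from the config seed.
#' @return Named list (one entry per tree tip): [seq_set] of that
#'   species' monomers, `source` set to the species label.
#' @export
evolve_library <- function(config, ancestral = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(ancestral))
    ancestral <- random_monomer(config$monomer_length, config$site)
  L <- nchar(ancestral)
  free <- if (config$constrained_fraction > 0) {
    sort(sample(L, round(L * (1 - config$constrained_fraction))))
  } else seq_len(L)
  tree <- ape::reorder.phylo(config$tree, "postorder")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  libs <- vector("list", max(tree$edge))
  libs[[root]] <- rep(ancestral, config$n_monomers)
  # preorder: parents before children
  for (k in rev(seq_len(nrow(tree$edge)))) {
    parent <- tree$edge[k, 1L]
    child <- tree$edge[k, 2L]
    libs[[child]] <- .evolve_branch(libs[[parent]], tree$edge.length[k],
                                    config, free)
  }
  out <- lapply(seq_len(n_tip), function(i) {
    sp <- tree$tip.label[i]
    seq_set(id = sprintf("%s_m%02d", sp, seq_len(config$n_monomers)),
            bases = libs[[i]], source = sp)
  })
  setNames(out, tree$tip.label)
}

#' Assemble a tandem array from a monomer library
#'
#' Head-to-tail concatenation of `copies` monomers drawn with
#' replacement; each copy's restriction site (first occurrence) is
#' destroyed with probability `site_ablation_prob` by a single
#' substitution inside the site.
#'
#' @param monomers [seq_set] (or character vector) of monomers.
#' @param copies number of copies in the array.
#' @param site_ablation_prob per-copy ablation probability.
#' @param seed integer seed.
#' @param site recognition site, default `"CCGG"`.
#' @param id,source labels for the returned record.
#' @return Single-row [seq_set] holding the array.
#' @export
build_array <- function(monomers, copies, site_ablation_prob = 0,
                        seed = 1L, site = "CCGG", id = "array",
                        source = NA_character_) {
  stopifnot(copies >= 1L)
  set.seed(seed)
  pool <- if (is.data.frame(monomers)) monomers$bases else as.character(monomers)
  if (is.data.frame(monomers) && is.na(source)) {
    src <- unique(monomers$source[!is.na(monomers$source)])
    if (length(src) == 1L) source <- src
  }
  picks <- pool[sample(length(pool), copies, replace = TRUE)]
  ablate <- runif(copies) < site_ablation_prob
  for (i in which(ablate)) {
    hit <- regexpr(site, picks[i], fixed = TRUE)
    if (hit > 0L) {
      # redraw until the substitution really removes the site: a flanking
      # context like CCCGG can otherwise recreate a shifted copy
      repeat {
        s <- picks[i]
        pos <- as.integer(hit) + sample(nchar(site), 1L) - 1L
        old <- substr(s, pos, pos)
        substr(s, pos, pos) <- sample(setdiff(BASES, old), 1L)
        if (!grepl(site, substr(s, max(1L, as.integer(hit) - nchar(site)),
                                as.integer(hit) + 2L * nchar(site)),
                   fixed = TRUE)) {
          picks[i] <- s
          break
        }
      }
    }
  }
  seq_set(id = id, bases = paste(picks, collapse = ""), source = source)
}

#' Simulate paired-end reads from a tandem array
#'
#' Inserts are placed uniformly along the array; mate 1 is the insert
#' prefix and mate 2 the reverse complement of the insert suffix, each
#' of `read_length` bp, with independent per-base substitution errors at
#' `error_rate` and constant Q30 qualities. Output is byte-identical
#' under a fixed seed.
#'
#' @param array single-row [seq_set] from [build_array()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param n_pairs number of pairs (defaults to `config$n_pairs`).
#' @return List with `fwd` and `rev` ([seq_set]s with `/1`, `/2` id
#'   suffixes) and `truth` (data frame: `id`, `array_id`, `start`,
#'   `end`, `source`; coordinates 0-based half-open on the array).
#' @export
simulate_reads <- function(array, config, seed = 1L,
                           n_pairs = config$n_pairs) {
  stopifnot(inherits(config, "sim_config"))
  L <- nchar(array$bases)
  ins <- config$insert_size
  rl <- config$read_length
  stopifnot(ins >= rl, L >= ins)
  set.seed(seed)
  if (n_pairs == 0L)
    return(list(fwd = seq_set(character(0), character(0)),
                rev = seq_set(character(0), character(0)),
                truth = data.frame(id = character(0), array_id = character(0),
                                   start = integer(0), end = integer(0),
                                   source = character(0))))
  starts <- sample.int(L - ins + 1L, n_pairs, replace = TRUE) - 1L
  inserts <- substring(array$bases, starts + 1L, starts + ins)
  m1 <- substring(inserts, 1L, rl)
  m2 <- revcomp(substring(inserts, ins - rl + 1L, ins))
  add_err <- function(reads) {
    vapply(reads, function(s) {
      chars <- strsplit(s, "")[[1]]
      hit <- which(runif(length(chars)) < config$error_rate)
      for (p in hit) chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
      paste(chars, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  m1 <- add_err(m1)
  m2 <- add_err(m2)
  ids <- sprintf("%s_r%05d", array$id, seq_len(n_pairs))
  q <- strrep(rawToChar(as.raw(63L)), rl)   # '?' = Q30
  list(fwd = seq_set(paste0(ids, "/1"), m1, quals = q, source = array$source),
       rev = seq_set(paste0(ids, "/2"), m2, quals = q, source = array$source),
       truth = data.frame(id = ids, array_id = array$id,
                          start = starts, end = starts + ins,
                          source = array$source, stringsAsFactors = FALSE))
}

#' Simulate a full multi-species dataset
#'
#' Convenience wrapper: evolves the species libraries, builds one tandem
#' array per species, and simulates `n_pairs` read pairs per species.
#'
#' @param config a [sim_config()].
#' @return List with `library` (pooled monomer [seq_set]), `per_species`
#'   (named list of the per-species monomer sets), `arrays` (named list
#'   of arrays) and `runs` (named list of `list(fwd, rev, truth)`).
#' @export
simulate_dataset <- function(config) {
  lib <- evolve_library(config)
  species <- names(lib)
  arrays <- list()
  runs <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    arrays[[sp]] <- build_array(lib[[sp]], config$copies_per_array,
                                config$site_ablation_prob,
                                seed = config$seed + 1000L + i,
                                site = config$site,
                                id = paste0(sp, "_array"), source = sp)
    runs[[sp]] <- simulate_reads(arrays[[sp]], config,
                                 seed = config$seed + 2000L + i)
  }
  pooled <- do.call(rbind, lapply(lib, as.data.frame))
  pooled <- seq_set(pooled$id, pooled$bases, source = pooled$source)
  list(library = pooled, per_species = lib, arrays = arrays, runs = runs)
}

#' Write a simulated dataset to disk
#'
#' Emits `monomers.fasta`, `arrays.fasta`, `reads_1.fastq`,
#' `reads_2.fastq` and `truth.tsv` under `dir`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @return The dataset list from [simulate_dataset()], invisibly.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_dataset(config)
  write_sequences(ds$library, file.path(dir, "monomers.fasta"))
  arr <- do.call(rbind, lapply(ds$arrays, as.data.frame))
  arr <- seq_set(arr$id, arr$bases, source = arr$source)
  write_sequences(arr, file.path(dir, "arrays.fasta"))
  fwd <- do.call(rbind, lapply(ds$runs, function(r) as.data.frame(r$fwd)))
  rev <- do.call(rbind, lapply(ds$runs, function(r) as.data.frame(r$rev)))
  truth <- do.call(rbind, lapply(ds$runs, function(r) r$truth))
  write_sequences(seq_set(fwd$id, fwd$bases, fwd$quals, fwd$source),
                  file.path(dir, "reads_1.fastq"), "fastq")
  write_sequences(seq_set(rev$id, rev$bases, rev$quals, rev$source),
                  file.path(dir, "reads_2.fastq"), "fastq")
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(ds)
}
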