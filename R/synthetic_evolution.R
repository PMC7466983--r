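# Ground-truth sequence evolution simulator: an ancestral region containing
# short highly conserved blocks embedded in rapidly diverging spacers is
# evolved independently in N species (star phylogeny). Substitutions are
# i.i.d. per base at a regional rate (block vs spacer), indels occur only in
# spacers (so block coordinates and strand stay exact), and one block copy
# may be inverted or translocated in a chosen species.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' `p_block`, `p_spacer` and `indel_rate` may be scalars or per-species
#' vectors (recycled to `n_species`), which supports divergence ladders and
#' near-identical clades.
#'
#' @param ancestor_length Ancestor length in bp.
#' @param blocks Two-column matrix or data.frame of 0-based block `start` and
#'   `length`; blocks must be non-overlapping and inside the ancestor.
#' @param n_species Number of independently evolved species.
#' @param p_block Per-base substitution probability inside blocks.
#' @param p_spacer Per-base substitution probability in spacers
#'   (`p_block <= p_spacer`).
#' @param indel_rate Per-base probability of starting an indel in spacers.
#' @param indel_length_range Integer `c(min, max)` indel length.
#' @param inversion Optional `c(species_index, block_index)`: that species'
#'   copy of that block is reverse-complemented in place.
#' @param translocation Optional `c(species_index, block_index, new_offset)`:
#'   that species' copy is excised and reinserted so it starts at
#'   `new_offset` (0-based, clamped) in the final sequence.
#' @param seed RNG seed; the dataset is fully reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(ancestor_length, blocks, n_species,
                              p_block = 0.02, p_spacer = 0.30,
                              indel_rate = 0.01,
                              indel_length_range = c(1L, 10L),
                              inversion = NULL, translocation = NULL,
                              seed = 1L) {
  blocks <- as.data.frame(blocks)
  names(blocks)[1:2] <- c("start", "length")
  blocks$start <- as.integer(blocks$start)
  blocks$length <- as.integer(blocks$length)
  if (nrow(blocks) > 0L) {
    blocks <- blocks[order(blocks$start), , drop = FALSE]
    if (any(blocks$start < 0L) || any(blocks$length < 1L) ||
        any(blocks$start + blocks$length > ancestor_length)) {
      stop("config error: block outside ancestor", call. = FALSE)
    }
    if (nrow(blocks) > 1L &&
        any(blocks$start[-1] < (blocks$start + blocks$length)[-nrow(blocks)])) {
      stop("config error: overlapping blocks", call. = FALSE)
    }
  }
  pb <- rep_len(p_block, n_species)
  ps <- rep_len(p_spacer, n_species)
  if (any(pb < 0) || any(ps > 1) || any(pb > ps)) {
    stop("config error: need 0 <= p_block <= p_spacer <= 1 (per species)",
         call. = FALSE)
  }
  ir <- rep_len(indel_rate, n_species)
  stopifnot(ancestor_length >= 1L, n_species >= 1L, all(ir >= 0), all(ir <= 1),
            length(indel_length_range) == 2L,
            indel_length_range[1] >= 1L,
            indel_length_range[2] >= indel_length_range[1])
  for (ed in list(inversion, translocation)) {
    if (!is.null(ed)) {
      if (ed[1] < 1L || ed[1] > n_species || ed[2] < 1L || ed[2] > nrow(blocks))
        stop("config error: inversion/translocation indices out of range",
             call. = FALSE)
    }
  }
  structure(list(ancestor_length = as.integer(ancestor_length),
                 blocks = blocks, n_species = as.integer(n_species),
                 p_block = pb, p_spacer = ps, indel_rate = ir,
                 indel_length_range = as.integer(indel_length_range),
                 inversion = inversion, translocation = translocation,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# substitute residues in a character vector at rate p (new base != old)
substitute_bases <- function(chars, p) {
  if (p <= 0 || length(chars) == 0L) return(chars)
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit)) {
    idx <- match(chars[hit], BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- BASES[((idx - 1L + shift) %% 4L) + 1L]
  }
  chars
}

# apply indels within one spacer character vector
apply_indels <- function(chars, rate, len_range) {
  if (rate <= 0 || length(chars) == 0L) return(chars)
  starts <- which(stats::runif(length(chars)) < rate)
  if (length(starts) == 0L) return(chars)
  out <- list()
  cursor <- 1L
  for (s in starts) {
    if (s < cursor) next               # swallowed by a previous deletion
    len <- sample(seq(len_range[1], len_range[2]), 1L)
    if (stats::runif(1) < 0.5) {       # deletion, clipped to the spacer
      if (s > cursor) out[[length(out) + 1L]] <- chars[cursor:(s - 1L)]
      cursor <- min(s + len, length(chars) + 1L)
    } else {                           # insertion after position s
      out[[length(out) + 1L]] <- chars[cursor:s]
      out[[length(out) + 1L]] <- sample(BASES, len, replace = TRUE)
      cursor <- s + 1L
    }
  }
  if (cursor <= length(chars)) out[[length(out) + 1L]] <- chars[cursor:length(chars)]
  unlist(out)
}

#' Generate a simulated multi-species dataset with ground truth
#'
#' @param config A [simulation_config()].
#' @return A `simulated_dataset`: `ancestor` ([seq_record] "ancestor"),
#'   `species_seqs` (list of [seq_record]s "sp01", "sp02", ...), `truth`
#'   (per-species data.frame with `block_id`, `start`, `end`, `strand` in
#'   that species' coordinates, 0-based half-open) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  anc <- sample(BASES, config$ancestor_length, replace = TRUE)
  blocks <- config$blocks
  nb <- nrow(blocks)
  # segment decomposition: alternate spacers and blocks, in ancestor order
  seg_start <- integer(0); seg_end <- integer(0); seg_block <- integer(0)
  cursor <- 0L
  for (b in seq_len(nb)) {
    if (blocks$start[b] > cursor) {
      seg_start <- c(seg_start, cursor); seg_end <- c(seg_end, blocks$start[b])
      seg_block <- c(seg_block, 0L)
    }
    seg_start <- c(seg_start, blocks$start[b])
    seg_end <- c(seg_end, blocks$start[b] + blocks$length[b])
    seg_block <- c(seg_block, b)
    cursor <- blocks$start[b] + blocks$length[b]
  }
  if (cursor < config$ancestor_length || nb == 0L) {
    seg_start <- c(seg_start, cursor)
    seg_end <- c(seg_end, config$ancestor_length)
    seg_block <- c(seg_block, 0L)
  }

  species_seqs <- vector("list", config$n_species)
  truth <- vector("list", config$n_species)
  for (sp in seq_len(config$n_species)) {
    pieces <- vector("list", length(seg_start))
    strands <- rep("+", nb)
    for (i in seq_along(seg_start)) {
      chars <- anc[(seg_start[i] + 1L):seg_end[i]]
      if (seg_block[i] > 0L) {
        chars <- substitute_bases(chars, config$p_block[sp])
        ed <- config$inversion
        if (!is.null(ed) && ed[1] == sp && ed[2] == seg_block[i]) {
          chars <- seq_chars(reverse_complement(paste(chars, collapse = "")))
          strands[seg_block[i]] <- "-"
        }
      } else {
        chars <- substitute_bases(chars, config$p_spacer[sp])
        chars <- apply_indels(chars, config$indel_rate[sp],
                              config$indel_length_range)
      }
      pieces[[i]] <- chars
    }
    tr <- config$translocation
    moved <- if (!is.null(tr) && tr[1] == sp) as.integer(tr[2]) else 0L
    keep <- if (moved > 0L) which(seg_block != moved) else seq_along(pieces)
    lens <- vapply(pieces[keep], length, integer(1))
    offs <- cumsum(c(0L, lens))[seq_along(keep)]
    tdf <- data.frame(block_id = sprintf("block_%d", seq_len(nb)),
                      start = rep(NA_integer_, nb),
                      end = rep(NA_integer_, nb),
                      strand = strands, stringsAsFactors = FALSE)
    for (b in seq_len(nb)) {
      if (b == moved) next
      i <- which(seg_block[keep] == b)
      tdf$start[b] <- offs[i]
      tdf$end[b] <- offs[i] + lens[i]
    }
    seq_chars_all <- unlist(pieces[keep])
    if (moved > 0L) {
      blk_chars <- pieces[[which(seg_block == moved)]]
      off <- max(0L, min(as.integer(tr[3]), length(seq_chars_all)))
      seq_chars_all <- append(seq_chars_all, blk_chars, after = off)
      shift <- length(blk_chars)
      later <- !is.na(tdf$start) & tdf$start >= off
      tdf$start[later] <- tdf$start[later] + shift
      tdf$end[later] <- tdf$end[later] + shift
      tdf$start[moved] <- off
      tdf$end[moved] <- off + length(blk_chars)
    }
    species_seqs[[sp]] <- seq_record(sprintf("sp%02d", sp),
                                     paste(seq_chars_all, collapse = ""))
    truth[[sp]] <- tdf
  }
  names(truth) <- vapply(species_seqs, `[[`, character(1), "id")
  structure(list(ancestor = seq_record("ancestor",
                                       paste(anc, collapse = "")),
                 species_seqs = species_seqs, truth = truth,
                 config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d bp ancestor, %d blocks, %d species (seed %d)\n",
              x$config$ancestor_length, nrow(x$config$blocks),
              x$config$n_species, x$config$seed))
  invisible(x)
}

#' Write per-species ground-truth BED6 files
#'
#' One BED6 file per species (`<species>.truth.bed`), strand column
#' reflecting inversions. Translocated-away blocks keep their record at the
#' new location.
#'
#' @param ds A `simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
truth_to_bed <- function(ds, dir) {
  stopifnot(inherits(ds, "simulated_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sp in names(ds$truth)) {
    tdf <- ds$truth[[sp]]
    tdf <- tdf[!is.na(tdf$start), , drop = FALSE]
    df <- data.frame(chrom = rep(sp, nrow(tdf)), start = tdf$start,
                     end = tdf$end, name = tdf$block_id,
                     score = tdf$end - tdf$start, strand = tdf$strand,
                     stringsAsFactors = FALSE)
    p <- file.path(dir, paste0(sp, ".truth.bed"))
    write_bed(df, p)
    paths[sp] <- p
  }
  invisible(paths)
}

#' Preset: divergence-ladder configuration
#'
#' Eight test species with a two-level structure emulating a close clade
#' plus increasingly divergent outgroups: the first four species evolve
#' slowly (near-identical clade), the remaining four at stepwise higher
#' spacer divergence. Blocks stay slowly evolving in all species.
#'
#' @param ancestor_length Ancestor length (default 2000).
#' @param seed RNG seed.
#' @return A [simulation_config()].
#' @export
preset_gambiae_ladder <- function(ancestor_length = 2000L, seed = 1L) {
  simulation_config(
    ancestor_length = ancestor_length,
    blocks = default_blocks(ancestor_length),
    n_species = 8L,
    p_block = c(rep(0.01, 4), 0.02, 0.02, 0.03, 0.03),
    p_spacer = c(rep(0.05, 4), 0.10, 0.15, 0.22, 0.30),
    indel_rate = c(rep(0.002, 4), rep(0.01, 4)),
    seed = seed)
}

# evenly spaced 30-60 bp blocks, ~1 per 330 bp of ancestor
default_blocks <- function(ancestor_length, spacing = 330L) {
  n <- max(1L, ancestor_length %/% spacing)
  lens <- rep_len(c(40L, 55L, 30L, 60L, 45L, 35L), n)
  starts <- (seq_len(n) - 1L) * spacing + 150L
  keep <- starts + lens <= ancestor_length
  cbind(start = starts[keep], length = lens[keep])
}
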