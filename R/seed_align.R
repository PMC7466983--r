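# BLAT-style k-mer seeded local alignment of a test-species sequence against
# the reference: exact-match seeding on both strands (k = 9 and 11 by
# default), diagonal merging, ungapped x-drop extension, and colinear
# chaining. All coordinates are 0-based half-open. Minus-strand seeding and
# extension happen in "strand space" (coordinates on the reverse complement
# of the test sequence); reported MatchBlock test coordinates are on the
# original test sequence, so for "-" chains they decrease as reference
# coordinates increase.

#' Alignment parameters
#'
#' Defaults reproduce near base-pair resolution footprinting on diverged
#' spacers: seeds of length 9 and 11 (union of hits), ungapped extension with
#' match +1 / mismatch -1 terminated when the score falls `x_drop` below its
#' running maximum, blocks of at least `min_block_len` bp chained per strand
#' when colinear on both sequences within `max_chain_gap`, and chains with
#' fewer than `min_chain_matches` identical bases discarded. K-mers occurring
#' more than `max_kmer_hits` times in the test index are skipped as seeds
#' (BLAT-like over-representation filtering; such regions remain reachable
#' via extension).
#'
#' @param k_values Integer vector of seed lengths, each >= 4.
#' @param max_chain_gap Maximum unaligned stretch (bp) bridged within a chain.
#' @param min_block_len Minimum ungapped block length retained.
#' @param min_chain_matches Minimum total identical bases per reported chain.
#' @param x_drop Score drop-off terminating ungapped extension.
#' @param max_kmer_hits Seed occurrence cap per k-mer.
#' @return An `align_params` list.
#' @export
align_params <- function(k_values = c(9L, 11L), max_chain_gap = 500L,
                         min_block_len = 6L, min_chain_matches = 20L,
                         x_drop = 50L, max_kmer_hits = 32L) {
  k_values <- as.integer(k_values)
  stopifnot(length(k_values) >= 1L, all(k_values >= 4L),
            max_chain_gap >= 1L, min_block_len >= 1L,
            min_chain_matches >= 1L, x_drop >= 1L, max_kmer_hits >= 1L)
  structure(list(k_values = k_values,
                 max_chain_gap = as.integer(max_chain_gap),
                 min_block_len = as.integer(min_block_len),
                 min_chain_matches = as.integer(min_chain_matches),
                 x_drop = as.integer(x_drop),
                 max_kmer_hits = as.integer(max_kmer_hits)),
            class = "align_params")
}

# split a sequence string into a character vector of residues
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Build a k-mer index of a test sequence
#'
#' Indexes every overlapping k-mer of the test sequence and of its reverse
#' complement; k-mers containing N are omitted. Positions are 0-based starts
#' within the indexed strand (for `"-"`, within the reverse complement).
#'
#' @param test A [seq_record] (or DNA string).
#' @param k Seed length; must not exceed the test length.
#' @return A `kmer_index`: list with `k`, `test_length`, and a data.frame
#'   `table` with columns `kmer`, `pos`, `strand`.
#' @export
build_kmer_index <- function(test, k) {
  s <- if (inherits(test, "seq_record")) test$residues else toupper(test)
  k <- as.integer(k)
  L <- nchar(s)
  if (k > L) stop("k (", k, ") exceeds test sequence length (", L, ")",
                  call. = FALSE)
  starts <- seq_len(L - k + 1L)
  fwd <- substring(s, starts, starts + k - 1L)
  rc <- reverse_complement(s)
  rev <- substring(rc, starts, starts + k - 1L)
  tab <- data.frame(kmer = c(fwd, rev),
                    pos = c(starts, starts) - 1L,
                    strand = rep(c("+", "-"), each = length(starts)),
                    stringsAsFactors = FALSE)
  tab <- tab[!grepl("N", tab$kmer, fixed = TRUE), , drop = FALSE]
  structure(list(k = k, test_length = L, table = tab), class = "kmer_index")
}

#' Find exact k-mer seed matches between a reference and an indexed test
#'
#' Reports one hit per exact k-mer match between the reference and either
#' strand of the test. K-mers whose total occurrence count in the index
#' exceeds `max_kmer_hits` are skipped (over-representation filter).
#'
#' @param ref A [seq_record] (or DNA string).
#' @param index A `kmer_index` from [build_kmer_index()].
#' @param k Seed length; must equal `index$k`.
#' @param max_kmer_hits Occurrence cap; `Inf` disables the filter.
#' @return data.frame with columns `ref_pos`, `test_pos` (0-based, strand
#'   space), `strand`, `len`.
#' @export
find_seeds <- function(ref, index, k = index$k, max_kmer_hits = 32L) {
  stopifnot(inherits(index, "kmer_index"))
  if (as.integer(k) != index$k) stop("k does not match index", call. = FALSE)
  s <- if (inherits(ref, "seq_record")) ref$residues else toupper(ref)
  L <- nchar(s)
  empty <- data.frame(ref_pos = integer(0), test_pos = integer(0),
                      strand = character(0), len = integer(0),
                      stringsAsFactors = FALSE)
  if (k > L) return(empty)
  starts <- seq_len(L - k + 1L)
  refmers <- substring(s, starts, starts + k - 1L)
  keep <- !grepl("N", refmers, fixed = TRUE)
  if (!any(keep)) return(empty)
  refdf <- data.frame(kmer = refmers[keep], ref_pos = starts[keep] - 1L,
                      stringsAsFactors = FALSE)
  tab <- index$table
  if (is.finite(max_kmer_hits)) {
    counts <- table(tab$kmer)
    over <- names(counts)[counts > max_kmer_hits]
    if (length(over)) tab <- tab[!tab$kmer %in% over, , drop = FALSE]
  }
  hits <- merge(refdf, tab, by = "kmer")
  if (nrow(hits) == 0L) return(empty)
  data.frame(ref_pos = hits$ref_pos, test_pos = hits$pos,
             strand = hits$strand, len = rep.int(as.integer(k), nrow(hits)),
             stringsAsFactors = FALSE)
}

# Ungapped x-drop extension length to the right along a diagonal.
# refv/testv: residue vectors; a0/b0: 0-based positions just past the block.
xdrop_extend <- function(refv, testv, a0, b0, x_drop, tie = c("last", "first")) {
  tie <- match.arg(tie)
  n <- min(length(refv) - a0, length(testv) - b0)
  if (n <= 0L) return(0L)
  ra <- refv[(a0 + 1L):(a0 + n)]
  tb <- testv[(b0 + 1L):(b0 + n)]
  m <- ra == tb & ra != "N" & tb != "N"
  cs <- cumsum(ifelse(m, 1L, -1L))
  best <- pmax(cummax(cs), 0L)
  viol <- which(best - cs > x_drop)
  scanned <- if (length(viol)) viol[1] else n
  sub <- cs[seq_len(scanned)]
  if (max(sub) <= 0L) return(0L)
  # score ties follow the exact-DP traceback conventions observed for local
  # alignment: leading net-zero stretches are kept (tie = "last"), trailing
  # ones shed (tie = "first")
  if (tie == "last") max(which(sub == max(sub))) else which.max(sub)
}

# count identical (non-N) bases between refv[a1..a2] and testv[b1..b2] (1-based)
count_ident <- function(refv, testv, a1, a2, b1, b2) {
  ra <- refv[a1:a2]; tb <- testv[b1:b2]
  sum(ra == tb & ra != "N" & tb != "N")
}

# merge intervals on a shared diagonal: x = matrix with cols start,end (0-based
# half-open, same diagonal), returns merged matrix
merge_diag_runs <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

# Build extended ungapped blocks for one strand from seed hits (strand space).
# Returns data.frame rs, re, ts, te, ni (0-based half-open).
build_blocks <- function(seeds, refv, testv, params) {
  if (nrow(seeds) == 0L) {
    return(data.frame(rs = integer(0), re = integer(0), ts = integer(0),
                      te = integer(0), ni = integer(0)))
  }
  diag <- seeds$ref_pos - seeds$test_pos
  out <- vector("list", 0L)
  for (d in unique(diag)) {
    sel <- diag == d
    runs <- merge_diag_runs(seeds$ref_pos[sel], seeds$ref_pos[sel] + seeds$len[sel])
    # x-drop extend each run, then re-merge overlaps created by extension
    ext <- t(apply(runs, 1L, function(r) {
      rs <- r[[1]]; re <- r[[2]]
      ts <- rs - d
      right <- xdrop_extend(refv, testv, re, re - d, params$x_drop,
                            tie = "first")
      left <- xdrop_extend(rev(refv), rev(testv),
                           length(refv) - rs, length(testv) - ts,
                           params$x_drop, tie = "last")
      c(rs - left, re + right)
    }))
    merged <- merge_diag_runs(ext[, 1], ext[, 2])
    out[[length(out) + 1L]] <- data.frame(rs = merged[, "start"],
                                          re = merged[, "end"], d = d)
  }
  blk <- do.call(rbind, out)
  blk$ts <- blk$rs - blk$d
  blk$te <- blk$re - blk$d
  blk$ni <- mapply(function(a1, a2, b1) {
    count_ident(refv, testv, a1 + 1L, a2, b1 + 1L, b1 + (a2 - a1))
  }, blk$rs, blk$re, blk$ts)
  blk <- blk[blk$re - blk$rs >= params$min_block_len, , drop = FALSE]
  blk[order(blk$rs, blk$ts), c("rs", "re", "ts", "te", "ni"), drop = FALSE]
}

# Join two consecutive chain blocks (strand space) the way an exact DP
# would. Same diagonal: merge into one ungapped block spanning the gap.
# Different diagonals: place the single implied indel at the cut point c
# maximizing total identities — the left block covers [rs1, c) on its
# diagonal, the right [c + shift, re2) on its own, where shift is the number
# of reference bases the gap consumes (deletion in test). Ties: leftmost cut.
split_blocks <- function(b1, b2, refv, testv) {
  if (b1$re <= b1$rs) return(rbind(b1, b2))
  d1 <- b1$rs - b1$ts
  d2 <- b2$rs - b2$ts
  recalc <- function(b, d) {
    b$ts <- b$rs - d
    b$te <- b$re - d
    b$ni <- if (b$re > b$rs)
      count_ident(refv, testv, b$rs + 1L, b$re, b$ts + 1L,
                  b$ts + (b$re - b$rs)) else 0L
    b
  }
  if (d1 == d2) {          # bridge the gap: one ungapped block
    b1$re <- max(b1$re, b2$re)
    b2$rs <- b2$re        # emptied; dropped by the caller
    return(rbind(recalc(b1, d1), recalc(b2, d2)))
  }
  shift <- max(0L, d2 - d1)
  # candidate cuts c (0-based): left = [rs1, c) on d1, right = [c+shift, re2)
  clo <- max(b1$rs, d2 - shift)
  chi <- min(b2$re - shift, length(refv), length(testv) + d1)
  if (clo > chi) {         # no valid cut: plain trim of the later block
    delta <- max(0L, b1$re - b2$rs, b1$te - b2$ts)
    b2$rs <- min(b2$rs + delta, b2$re)
    return(rbind(recalc(b1, d1), recalc(b2, d2)))
  }
  if (chi > clo) {
    pos <- (clo + 1L):chi                  # 1-based residue positions
    a1 <- refv[pos]; t1 <- testv[pos - d1]
    m1 <- a1 == t1 & a1 != "N" & t1 != "N"
    a2 <- refv[pos + shift]; t2 <- testv[pos + shift - d2]
    m2 <- a2 == t2 & a2 != "N" & t2 != "N"
    # net gain of moving the cut from clo to c = clo + k
    gain <- c(0L, cumsum(m1) - cumsum(m2))
    cut <- clo + max(which(gain == max(gain))) - 1L   # ties: rightmost cut
  } else {
    cut <- clo
  }
  b1$re <- max(cut, b1$rs)
  b2$rs <- min(cut + shift, b2$re)
  rbind(recalc(b1, d1), recalc(b2, d2))
}

# Gapped end patching: a chain cannot grow past an indel by seeding alone
# when the remaining tail is shorter than a seed, but an exact DP aligns it
# through the gap. Try shifted diagonals (|delta| <= max_shift, charged the
# linear gap cost of 2 per base) off both chain ends and append/prepend the
# best net-positive ungapped extension; repeat for multi-indel tails.
patch_chain_ends <- function(chain, refv, testv, params, max_shift = 32L,
                             max_rounds = 4L) {
  Lr <- length(refv); Lt <- length(testv)
  deltas <- setdiff(order(abs(seq(-max_shift, max_shift))) - max_shift - 1L, 0L)
  new_block <- function(rs, re, ts, te) {
    data.frame(rs = rs, re = re, ts = ts, te = te,
               ni = count_ident(refv, testv, rs + 1L, re, ts + 1L, te))
  }
  for (round in seq_len(max_rounds)) {          # right end
    re <- chain$re[nrow(chain)]; te <- chain$te[nrow(chain)]
    best_net <- 0L; best <- NULL
    for (delta in deltas) {
      a0 <- re + max(delta, 0L); b0 <- te + max(-delta, 0L)
      if (a0 >= Lr || b0 >= Lt) next
      ext <- xdrop_extend(refv, testv, a0, b0, params$x_drop, tie = "first")
      if (ext == 0L) next
      matches <- count_ident(refv, testv, a0 + 1L, a0 + ext, b0 + 1L, b0 + ext)
      net <- (2L * matches - ext) - 2L * abs(delta)
      if (net > best_net) { best_net <- net; best <- c(a0, b0, ext) }
    }
    if (is.null(best)) break
    chain <- rbind(chain, new_block(best[1], best[1] + best[3],
                                    best[2], best[2] + best[3]))
  }
  for (round in seq_len(max_rounds)) {          # left end
    rs <- chain$rs[1]; ts <- chain$ts[1]
    best_net <- 0L; best <- NULL
    for (delta in deltas) {
      a0 <- Lr - rs + max(delta, 0L); b0 <- Lt - ts + max(-delta, 0L)
      if (a0 >= Lr || b0 >= Lt) next
      ext <- xdrop_extend(rev(refv), rev(testv), a0, b0, params$x_drop,
                          tie = "last")
      if (ext == 0L) next
      re_new <- Lr - a0; rs_new <- re_new - ext
      te_new <- Lt - b0; ts_new <- te_new - ext
      matches <- count_ident(refv, testv, rs_new + 1L, re_new,
                             ts_new + 1L, te_new)
      net <- (2L * matches - ext) - 2L * abs(delta)
      if (net > best_net) {
        best_net <- net; best <- c(rs_new, re_new, ts_new, te_new)
      }
    }
    if (is.null(best)) break
    chain <- rbind(new_block(best[1], best[2], best[3], best[4]), chain)
  }
  chain
}

# DP chain extraction over blocks of one strand (strand space). Repeatedly
# pulls the best-scoring colinear chain, trims overlaps between consecutive
# blocks, and removes used blocks, until no chain reaches min_chain_matches.
# Returns list of data.frames (chain blocks).
extract_chains <- function(blocks, refv, testv, params) {
  chains <- list()
  avail <- blocks
  for (iter in seq_len(1000L)) {
    n <- nrow(avail)
    if (n == 0L) break
    score <- avail$ni
    pred <- integer(n)
    if (n > 1L) {
      for (i in 2:n) {
        for (j in 1:(i - 1L)) {
          if (avail$re[j] >= avail$re[i] || avail$te[j] >= avail$te[i] ||
              avail$ts[j] > avail$ts[i]) next
          gr <- avail$rs[i] - avail$re[j]
          gt <- avail$ts[i] - avail$te[j]
          if (gr > params$max_chain_gap || gt > params$max_chain_gap) next
          ov <- max(0L, -gr, -gt)
          cand <- score[j] + avail$ni[i] - ov
          if (cand > score[i]) { score[i] <- cand; pred[i] <- j }
        }
      }
    }
    best <- which.max(score)
    if (score[best] < params$min_chain_matches) break
    path <- best
    while (pred[path[1]] > 0L) path <- c(pred[path[1]], path)
    chain <- avail[path, , drop = FALSE]
    avail <- avail[-path, , drop = FALSE]
    # resolve overlaps between consecutive blocks by the identity-optimal
    # split point (mirrors how an exact DP would place the gap)
    if (nrow(chain) > 1L) {
      prev <- 1L
      for (i in 2:nrow(chain)) {
        res <- split_blocks(chain[prev, ], chain[i, ], refv, testv)
        chain[prev, ] <- res[1L, ]
        chain[i, ] <- res[2L, ]
        if (chain$re[i] > chain$rs[i]) prev <- i
      }
      chain <- chain[chain$re > chain$rs, , drop = FALSE]
    }
    if (nrow(chain) == 0L || sum(chain$ni) < params$min_chain_matches) next
    chain <- patch_chain_ends(chain, refv, testv, params)
    chains[[length(chains) + 1L]] <- chain
  }
  chains
}

#' Chain seed matches into local alignments
#'
#' Merges seeds along diagonals into ungapped blocks, extends them with
#' x-drop, chains colinear same-strand blocks within `max_chain_gap`, and
#' returns chains with at least `min_chain_matches` identical bases, sorted
#' by score (total identical bases) descending.
#'
#' @param seeds Seed data.frame from [find_seeds()] (rows from several k
#'   values may be concatenated).
#' @param ref,test [seq_record]s the seeds were computed from.
#' @param params [align_params()].
#' @return List of `chained_alignment` objects. Each has `species_id`,
#'   `strand`, `score`, and a `blocks` data.frame with 0-based half-open
#'   `ref_start`, `ref_end`, `test_start`, `test_end` (original test
#'   coordinates) and `n_ident`.
#' @export
chain_and_extend <- function(seeds, ref, test, params = align_params()) {
  refv <- seq_chars(ref$residues)
  test_fwd <- seq_chars(test$residues)
  test_rc <- seq_chars(reverse_complement(test$residues))
  Lt <- length(test_fwd)
  chains <- list()
  for (strand in c("+", "-")) {
    sd <- seeds[seeds$strand == strand, , drop = FALSE]
    testv <- if (strand == "+") test_fwd else test_rc
    blocks <- build_blocks(sd, refv, testv, params)
    for (ch in extract_chains(blocks, refv, testv, params)) {
      if (strand == "+") {
        blk <- data.frame(ref_start = ch$rs, ref_end = ch$re,
                          test_start = ch$ts, test_end = ch$te,
                          n_ident = ch$ni)
      } else {
        blk <- data.frame(ref_start = ch$rs, ref_end = ch$re,
                          test_start = Lt - ch$te, test_end = Lt - ch$ts,
                          n_ident = ch$ni)
      }
      chains[[length(chains) + 1L]] <-
        structure(list(species_id = test$id, strand = strand,
                       score = sum(ch$ni), blocks = blk),
                  class = "chained_alignment")
    }
  }
  if (length(chains) == 0L) return(chains)
  ord <- order(-vapply(chains, `[[`, numeric(1), "score"),
               vapply(chains, function(c) c$blocks$ref_start[1], numeric(1)))
  chains[ord]
}

#' @export
print.chained_alignment <- function(x, ...) {
  cat(sprintf("<chained_alignment> %s strand %s score %d (%d blocks)\n",
              x$species_id, x$strand, x$score, nrow(x$blocks)))
  invisible(x)
}

#' Align one test species against the reference and call per-base conservation
#'
#' Runs the full seed/extend/chain pipeline (union of seed hits over
#' `params$k_values`, both strands) and marks each reference base as
#' conserved for this species iff it lies inside a retained chain block and
#' the aligned test base is identical (N never matches). Where chains overlap
#' on the reference, the higher-scoring chain decides per base (ties: the
#' chain starting leftmost on the reference).
#'
#' @param ref,test [seq_record]s.
#' @param params [align_params()].
#' @return List with `conserved` (logical vector over reference positions)
#'   and `chains` (the retained [chain_and_extend()] output).
#' @export
align_species <- function(ref, test, params = align_params()) {
  stopifnot(inherits(ref, "seq_record"), inherits(test, "seq_record"))
  Lr <- seq_length(ref)
  Lt <- seq_length(test)
  seed_list <- list()
  for (k in params$k_values) {
    if (k > Lt || k > Lr) next
    idx <- build_kmer_index(test, k)
    seed_list[[length(seed_list) + 1L]] <-
      find_seeds(ref, idx, k, max_kmer_hits = params$max_kmer_hits)
  }
  conserved <- rep(FALSE, Lr)
  if (length(seed_list) == 0L) {
    return(list(conserved = conserved, chains = list()))
  }
  seeds <- unique(do.call(rbind, seed_list))
  chains <- chain_and_extend(seeds, ref, test, params)
  if (length(chains) == 0L) {
    return(list(conserved = conserved, chains = chains))
  }
  refv <- seq_chars(ref$residues)
  test_fwd <- seq_chars(test$residues)
  test_rc <- seq_chars(reverse_complement(test$residues))
  claimed <- rep(FALSE, Lr)
  for (ch in chains) {   # already in priority order (score desc, leftmost)
    testv <- if (ch$strand == "+") test_fwd else test_rc
    for (b in seq_len(nrow(ch$blocks))) {
      rs <- ch$blocks$ref_start[b]; re <- ch$blocks$ref_end[b]
      ts <- if (ch$strand == "+") ch$blocks$test_start[b] else
        Lt - ch$blocks$test_end[b]
      pos <- (rs + 1L):re
      free <- !claimed[pos]
      if (!any(free)) next
      off <- which(free)
      ra <- refv[pos[off]]
      tb <- testv[ts + off]
      conserved[pos[off]] <- ra == tb & ra != "N" & tb != "N"
      claimed[pos[off]] <- TRUE
    }
  }
  list(conserved = conserved, chains = chains)
}
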