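# Conserved sequence block (CSB) calling: maximal uppercase runs of an
# EvoPrint mask, and their greedy clustering into enhancer-scale units
# separated by poorly conserved spacers.

#' CSB caller parameters
#'
#' @param L_min Minimum CSB length in bp (default 10).
#' @param G Maximum gap (bp) between consecutive CSBs within one cluster
#'   (default 100).
#' @param max_interruptions Number of isolated (length-1) non-conserved bases
#'   that may be bridged inside a single CSB (default 0: a CSB is a literal
#'   uppercase run).
#' @return A `caller_params` list.
#' @export
caller_params <- function(L_min = 10L, G = 100L, max_interruptions = 0L) {
  stopifnot(L_min >= 0L, G >= 0L, max_interruptions >= 0L)
  structure(list(L_min = as.integer(L_min), G = as.integer(G),
                 max_interruptions = as.integer(max_interruptions)),
            class = "caller_params")
}

#' Call conserved sequence blocks from an EvoPrint
#'
#' Returns all maximal true-runs of the mask (after optionally bridging up to
#' `max_interruptions` isolated false bases per block) of length at least
#' `L_min`, left to right.
#'
#' @param ep An `evoprint` from [make_evoprint()].
#' @param params [caller_params()].
#' @return List of `csb` objects, each with `id`, `interval`
#'   ([genomic_interval] on the reference, 0-based half-open), `residues` and
#'   `length`.
#' @export
call_csbs <- function(ep, params = caller_params()) {
  stopifnot(inherits(ep, "evoprint"))
  mask <- ep$mask
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])  # 1-based inclusive
  if (params$max_interruptions > 0L && nrow(runs) > 1L) {
    merged <- runs[1L, , drop = FALSE]
    used <- 0L
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap == 1L && used < params$max_interruptions) {
        merged$end[nrow(merged)] <- runs$end[i]
        used <- used + 1L
      } else {
        merged <- rbind(merged, runs[i, ])
        used <- 0L
      }
    }
    runs <- merged
  }
  runs <- runs[runs$end - runs$start + 1L >= params$L_min, , drop = FALSE]
  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    s0 <- runs$start[i] - 1L   # to 0-based half-open
    e0 <- runs$end[i]
    out[[i]] <- structure(
      list(id = sprintf("csb_%04d", i),
           interval = genomic_interval(ep$ref_id, s0, e0, "+"),
           residues = substr(ep$ref_residues, runs$start[i], runs$end[i]),
           length = e0 - s0),
      class = "csb")
  }
  out
}

#' @export
print.csb <- function(x, ...) {
  cat(sprintf("<csb> %s %s:%d-%d (%d bp)\n", x$id, x$interval$chrom,
              x$interval$start, x$interval$end, x$length))
  invisible(x)
}

#' Cluster CSBs separated by short gaps
#'
#' Greedy left-to-right clustering: a new cluster starts whenever the gap to
#' the previous CSB exceeds `G`. Clusters correspond to enhancer-scale units
#' flanked by long poorly conserved spacers.
#'
#' @param csbs List of `csb` objects sorted by start.
#' @param params [caller_params()].
#' @return List of `csb_cluster` objects with `csbs`, `span`
#'   ([genomic_interval] from first start to last end) and `max_gap_allowed`.
#' @export
cluster_csbs <- function(csbs, params = caller_params()) {
  if (length(csbs) == 0L) return(list())
  starts <- vapply(csbs, function(x) x$interval$start, integer(1))
  ends <- vapply(csbs, function(x) x$interval$end, integer(1))
  if (is.unsorted(starts)) stop("CSBs must be sorted by start", call. = FALSE)
  gaps <- starts[-1] - ends[-length(ends)]
  new_cluster <- c(TRUE, gaps > params$G)
  grp <- cumsum(new_cluster)
  lapply(split(seq_along(csbs), grp), function(idx) {
    members <- csbs[idx]
    structure(list(
      csbs = members,
      span = genomic_interval(members[[1]]$interval$chrom,
                              members[[1]]$interval$start,
                              members[[length(members)]]$interval$end, "+"),
      max_gap_allowed = params$G),
      class = "csb_cluster")
  })
}

#' @export
print.csb_cluster <- function(x, ...) {
  cat(sprintf("<csb_cluster> %d CSBs spanning %s:%d-%d\n", length(x$csbs),
              x$span$chrom, x$span$start, x$span$end))
  invisible(x)
}

#' Export CSBs as BED6
#'
#' Name = csb id, score = length, strand "+".
#'
#' @param csbs List of `csb` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
csbs_to_bed <- function(csbs, path) {
  write_bed(lapply(csbs, `[[`, "interval"), path,
            names = vapply(csbs, `[[`, character(1), "id"),
            scores = vapply(csbs, `[[`, integer(1), "length"))
}

#' Export CSB residues as FASTA
#'
#' @param csbs List of `csb` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
csbs_to_fasta <- function(csbs, path) {
  write_fasta(lapply(csbs, function(x) seq_record(x$id, x$residues)), path)
}
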