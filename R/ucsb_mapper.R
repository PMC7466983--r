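# Cross-taxon uCSB mapping: local alignment of reference CSBs into distant
# target sequence, presence calls, linear-order / orientation (colinearity
# and microinversion) analysis, and two-target sharing classification.

#' Map one CSB into a distant target sequence
#'
#' Aligns the CSB locally against both strands of the target with the
#' seed-and-extend engine and reports matches passing the identity and
#' coverage thresholds, best first. An empty result means the CSB is absent
#' (not an ultraconserved CSB for this taxon). Identity is the fraction of
#' aligned CSB bases that are identical; coverage the fraction of the CSB
#' length that is aligned — "a portion of a CSB" counts, hence the permissive
#' default coverage.
#'
#' @param csb A `csb` object (or a [seq_record], taken as the CSB sequence).
#' @param target Target contig [seq_record].
#' @param min_identity Minimum identity (default 0.8).
#' @param min_coverage Minimum coverage of the CSB length (default 0.5).
#' @param params [align_params()]; `min_chain_matches` is capped at half the
#'   CSB length so short CSBs remain mappable.
#' @return List of `ucsb_match` objects: `csb_id`, `target_id`,
#'   `target_interval` ([genomic_interval] on the target, 0-based half-open,
#'   strand-annotated), `strand`, `identity`, `coverage`.
#' @export
map_csb <- function(csb, target, min_identity = 0.8, min_coverage = 0.5,
                    params = align_params()) {
  rec <- if (inherits(csb, "csb")) seq_record(csb$id, csb$residues) else csb
  stopifnot(inherits(rec, "seq_record"), inherits(target, "seq_record"))
  csb_len <- seq_length(rec)
  if (csb_len < min(params$k_values)) {
    stop("CSB '", rec$id, "' (", csb_len,
         " bp) is shorter than the minimum seed length", call. = FALSE)
  }
  params$min_chain_matches <- max(1L, min(params$min_chain_matches,
                                          as.integer(csb_len / 2)))
  aln <- align_species(rec, target, params)
  out <- list()
  for (ch in aln$chains) {
    aligned <- sum(ch$blocks$ref_end - ch$blocks$ref_start)
    n_ident <- sum(ch$blocks$n_ident)
    if (aligned == 0L) next
    identity <- n_ident / aligned
    coverage <- aligned / csb_len
    if (identity < min_identity || coverage < min_coverage) next
    ts <- min(ch$blocks$test_start)
    te <- max(ch$blocks$test_end)
    out[[length(out) + 1L]] <- structure(
      list(csb_id = rec$id, target_id = target$id,
           target_interval = genomic_interval(target$id, ts, te, ch$strand),
           strand = ch$strand, identity = identity, coverage = coverage,
           score = ch$score),
      class = "ucsb_match")
  }
  if (length(out) > 1L) {
    ord <- order(-vapply(out, `[[`, numeric(1), "identity"),
                 -vapply(out, `[[`, numeric(1), "coverage"),
                 vapply(out, function(m) m$target_interval$start, numeric(1)))
    out <- out[ord]
  }
  out
}

#' @export
print.ucsb_match <- function(x, ...) {
  cat(sprintf("<ucsb_match> %s -> %s:%d-%d(%s) identity %.3f coverage %.3f\n",
              x$csb_id, x$target_id, x$target_interval$start,
              x$target_interval$end, x$strand, x$identity, x$coverage))
  invisible(x)
}

#' Map a whole CSB set against one target, best match per CSB
#'
#' Convenience wrapper used by colinearity and sharing analysis: maps every
#' CSB and keeps the best qualifying match (identity, then coverage, then
#' leftmost target start). CSBs too short to seed are reported as missing.
#'
#' @inheritParams map_csb
#' @param csbs List of `csb` objects.
#' @return Named list (by csb id) of `ucsb_match` or `NULL` for absent CSBs.
#' @export
map_csb_set <- function(csbs, target, min_identity = 0.8, min_coverage = 0.5,
                        params = align_params()) {
  ids <- vapply(csbs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate csb ids", call. = FALSE)
  out <- stats::setNames(vector("list", length(csbs)), ids)
  for (i in seq_along(csbs)) {
    hits <- tryCatch(
      map_csb(csbs[[i]], target, min_identity, min_coverage, params),
      error = function(e) list())
    if (length(hits)) out[[i]] <- hits[[1]]
  }
  out
}

#' Analyze linear order and orientation of mapped CSBs
#'
#' Retains at most one match per CSB, sorts matches by reference CSB start
#' (the "query start position" order), computes the majority strand, and
#' reports: `is_colinear` — whether the same-strand (majority) matches'
#' target starts are strictly monotone (increasing for a "+" majority,
#' decreasing for "-"); `inversions` — csb ids on the minority strand
#' (microinversion candidates); `missing` — csb ids with no qualifying
#' match. Every input CSB appears exactly once across matches and missing.
#'
#' @param matches Named list from [map_csb_set()] (or list of `ucsb_match`,
#'   at most one per CSB).
#' @param csbs The CSB list the matches were derived from.
#' @return A `colinearity_report`: `matches` (ordered list of `ucsb_match`),
#'   `majority_strand`, `is_colinear`, `inversions`, `missing`.
#' @export
analyze_colinearity <- function(matches, csbs) {
  csb_ids <- vapply(csbs, `[[`, character(1), "id")
  csb_starts <- vapply(csbs, function(x) x$interval$start, integer(1))
  hit <- Filter(Negate(is.null), matches)
  hit_ids <- vapply(hit, `[[`, character(1), "csb_id")
  if (anyDuplicated(hit_ids)) stop("duplicate csb ids in matches",
                                   call. = FALSE)
  if (!all(hit_ids %in% csb_ids)) stop("match csb_id not among input CSBs",
                                       call. = FALSE)
  ord <- order(csb_starts[match(hit_ids, csb_ids)])
  hit <- hit[ord]
  strands <- vapply(hit, `[[`, character(1), "strand")
  majority <- if (length(strands) == 0L) "+" else
    if (sum(strands == "-") > sum(strands == "+")) "-" else "+"
  inversions <- vapply(hit, `[[`, character(1), "csb_id")[strands != majority]
  tstarts <- vapply(hit, function(m) m$target_interval$start,
                    numeric(1))[strands == majority]
  is_colinear <- if (length(tstarts) < 2L) TRUE else {
    if (majority == "+") all(diff(tstarts) > 0) else all(diff(tstarts) < 0)
  }
  structure(list(matches = hit, majority_strand = majority,
                 is_colinear = is_colinear,
                 inversions = as.character(inversions),
                 missing = setdiff(csb_ids, hit_ids)),
            class = "colinearity_report")
}

#' @export
print.colinearity_report <- function(x, ...) {
  cat(sprintf(
    "<colinearity_report> %d uCSBs, majority strand %s, colinear: %s, %d inversion(s), %d missing\n",
    length(x$matches), x$majority_strand, x$is_colinear,
    length(x$inversions), length(x$missing)))
  invisible(x)
}

#' Classify CSB sharing across two distant targets
#'
#' Each CSB is assigned `both`, `target1_only`, `target2_only` or `neither`
#' by presence of a qualifying match in each target (the classic pattern:
#' some blocks conserved in both distant taxa, some in only one).
#'
#' @param csbs List of `csb` objects.
#' @param matches_t1,matches_t2 Named lists from [map_csb_set()] against the
#'   two targets.
#' @return A `sharing_table` data.frame with columns `csb_id`, `category`;
#'   attribute `counts` holds the per-category tally.
#' @export
classify_sharing <- function(csbs, matches_t1, matches_t2) {
  ids <- vapply(csbs, `[[`, character(1), "id")
  p1 <- !vapply(matches_t1[ids], is.null, logical(1))
  p2 <- !vapply(matches_t2[ids], is.null, logical(1))
  category <- ifelse(p1 & p2, "both",
                     ifelse(p1, "target1_only",
                            ifelse(p2, "target2_only", "neither")))
  df <- data.frame(csb_id = ids, category = category,
                   stringsAsFactors = FALSE)
  attr(df, "counts") <- vapply(
    c("both", "target1_only", "target2_only", "neither"),
    function(k) sum(category == k), integer(1))
  class(df) <- c("sharing_table", "data.frame")
  df
}
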