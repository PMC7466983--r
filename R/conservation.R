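# Strict and relaxed EvoPrints: per-species conservation calls combined into
# a single uninterrupted view of the reference, plus the per-species
# scorecard.

#' Build a multi-species conservation profile
#'
#' Aligns every test species against the reference with [align_species()] and
#' stacks the per-base match calls into a species-by-position boolean matrix.
#' The reference length and base order are preserved exactly — the profile is
#' a single uninterrupted view of the reference.
#'
#' @param ref Reference [seq_record].
#' @param tests List of test-species [seq_record]s (ids must be unique).
#' @param params [align_params()].
#' @return A `conservation_profile`: list with `ref_id`, `ref_residues`,
#'   `species` (ids, in input order) and `conserved` (logical matrix,
#'   species x positions).
#' @export
build_profile <- function(ref, tests, params = align_params()) {
  stopifnot(inherits(ref, "seq_record"))
  if (inherits(tests, "seq_record")) tests <- list(tests)
  if (length(tests) < 1L) stop("at least one test species is required",
                               call. = FALSE)
  ids <- vapply(tests, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate species ids: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "), call. = FALSE)
  mat <- matrix(FALSE, nrow = length(tests), ncol = seq_length(ref),
                dimnames = list(ids, NULL))
  for (i in seq_along(tests)) {
    mat[i, ] <- align_species(ref, tests[[i]], params)$conserved
  }
  structure(list(ref_id = ref$id, ref_residues = ref$residues,
                 species = ids, conserved = mat),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %s (%d bp) x %d species\n",
              x$ref_id, nchar(x$ref_residues), length(x$species)))
  invisible(x)
}

#' Compute a (relaxed) EvoPrint from a conservation profile
#'
#' A reference base is printed uppercase (mask true) iff it is conserved in
#' all but at most `R` of the test species. `R = 0` is the strict print;
#' `R = 1` is the standard relaxed print ("conserved in all or all but one").
#'
#' @param profile A `conservation_profile`.
#' @param R Relaxation parameter: maximum number of species allowed to miss a
#'   base; must be less than the number of species.
#' @return An `evoprint` object: `ref_residues`, `missing_count` (integer per
#'   position), `R`, `mask` (logical per position), and `missing_species`
#'   (per-position list of the species ids that miss the base).
#' @export
make_evoprint <- function(profile, R = 0L) {
  stopifnot(inherits(profile, "conservation_profile"))
  R <- as.integer(R)
  n_sp <- length(profile$species)
  if (R < 0L) stop("R must be non-negative", call. = FALSE)
  if (R >= n_sp) stop("R (", R, ") must be less than the number of species (",
                      n_sp, "): the print would be vacuous", call. = FALSE)
  missing_count <- as.integer(colSums(!profile$conserved))
  mask <- missing_count <= R
  missing_species <- apply(!profile$conserved, 2L,
                           function(col) profile$species[col],
                           simplify = FALSE)
  structure(list(ref_id = profile$ref_id,
                 ref_residues = profile$ref_residues,
                 species = profile$species,
                 missing_count = missing_count, R = R, mask = mask,
                 missing_species = missing_species),
            class = "evoprint")
}

#' @export
print.evoprint <- function(x, ...) {
  cat(sprintf("<evoprint> %s (%d bp), R = %d, %d/%d bases conserved\n",
              x$ref_id, nchar(x$ref_residues), x$R, sum(x$mask),
              length(x$mask)))
  invisible(x)
}

#' Render an EvoPrint as text
#'
#' Uppercase where the mask is true, lowercase where false. The output has
#' exactly the reference length; with `ruler = TRUE` (used by the CLI) lines
#' are wrapped at `width` columns with a 1-based position label, and with
#' `annotate = TRUE` a second track under each line names the single missing
#' species at positions where exactly one species misses the base
#' (first letter of its id; `.` elsewhere).
#'
#' @param ep An `evoprint`.
#' @param ruler Wrap and label lines?
#' @param width Columns per line when wrapped.
#' @param annotate Emit the missing-species track?
#' @return A single string. With `ruler = FALSE` it is exactly the
#'   case-masked reference sequence.
#' @export
render_evoprint <- function(ep, ruler = FALSE, width = 60L, annotate = FALSE) {
  stopifnot(inherits(ep, "evoprint"))
  chars <- seq_chars(ep$ref_residues)
  chars[!ep$mask] <- tolower(chars[!ep$mask])
  line <- paste(chars, collapse = "")
  if (!ruler) return(line)
  n <- nchar(line)
  starts <- seq(1L, n, by = width)
  pieces <- character(0)
  for (s in starts) {
    e <- min(s + width - 1L, n)
    pieces <- c(pieces, sprintf("%9d %s", s, substr(line, s, e)))
    if (annotate) {
      track <- vapply(s:e, function(p) {
        if (ep$missing_count[p] == 1L)
          substr(ep$missing_species[[p]][1], 1L, 1L) else "."
      }, character(1))
      pieces <- c(pieces, sprintf("%9s %s", "", paste(track, collapse = "")))
    }
  }
  paste(pieces, collapse = "\n")
}

#' Per-species conservation scorecard
#'
#' The score of a test species is the number of reference bases conserved in
#' that species; it decreases with evolutionary divergence from the
#' reference. The self score (reference against itself) is the reference
#' length.
#'
#' @param profile A `conservation_profile`.
#' @return A `scorecard` data.frame with columns `species`, `score` and
#'   `fraction` (score / self score), plus attribute `self_score`.
#' @export
scorecard <- function(profile) {
  stopifnot(inherits(profile, "conservation_profile"))
  self_score <- nchar(profile$ref_residues)
  df <- data.frame(species = profile$species,
                   score = as.integer(rowSums(profile$conserved)),
                   stringsAsFactors = FALSE)
  df$fraction <- df$score / self_score
  attr(df, "self_score") <- self_score
  class(df) <- c("scorecard", "data.frame")
  df
}
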