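# Sequence and interval I/O: FASTA, BED6 and the "chrom:start-end" region
# convention used in genome-browser derived tables.

VALID_RESIDUES <- c("A", "C", "G", "T", "N")

#' Create a sequence record
#'
#' A `seq_record` holds one DNA sequence with an identifier and an optional
#' free-text description. Residues are normalized to uppercase and restricted
#' to the alphabet A, C, G, T, N. `N` is treated as unknown and never counts
#' as identical to any base downstream.
#'
#' @param id Sequence identifier (no whitespace).
#' @param residues DNA string over A/C/G/T/N, case-insensitive.
#' @param description Optional free-text description.
#' @return An object of class `seq_record` with fields `id`, `description`
#'   and `residues` (uppercase).
#' @examples
#' seq_record("x", "acgt")
#' @export
seq_record <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("'id' must be a non-empty character scalar", call. = FALSE)
  }
  if (grepl("[[:space:]]", id)) {
    stop("sequence id must not contain whitespace: ", sQuote(id), call. = FALSE)
  }
  residues <- toupper(as.character(residues))
  if (length(residues) != 1L || is.na(residues) || nchar(residues) < 1L) {
    stop("'residues' must be a non-empty DNA string", call. = FALSE)
  }
  bad <- gregexpr("[^ACGTN]", residues)[[1]]
  if (bad[1] != -1L) {
    stop(sprintf("record '%s': invalid residue '%s' at position %d",
                 id, substr(residues, bad[1], bad[1]), bad[1]), call. = FALSE)
  }
  structure(list(id = id, description = description, residues = residues),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d bp)%s\n", x$id, nchar(x$residues),
              if (nzchar(x$description)) paste0(" ", x$description) else ""))
  invisible(x)
}

#' Sequence length of a record
#' @param x A `seq_record`.
#' @return Integer number of residues.
#' @export
seq_length <- function(x) nchar(x$residues)

#' Read a FASTA file
#'
#' Reads a (multi-record) FASTA file into a list of [seq_record]s, preserving
#' record order. Residues are uppercased; gap characters `-` are stripped with
#' a warning (curated alignments are sometimes pasted in); any other residue
#' outside A/C/G/T/N raises a format error naming the record and position.
#'
#' @param path Path to a FASTA file.
#' @return List of `seq_record` objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  if (length(set) == 0L) stop("FASTA format error: no records in ", path,
                              call. = FALSE)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  out <- vector("list", length(set))
  for (i in seq_along(seqs)) {
    id <- sub("[[:space:]].*$", "", headers[i])
    desc <- sub("^[^[:space:]]+[[:space:]]*", "", headers[i])
    s <- seqs[i]
    if (grepl("-", s, fixed = TRUE)) {
      warning(sprintf("record '%s': stripping gap characters", id),
              call. = FALSE)
      s <- gsub("-", "", s, fixed = TRUE)
    }
    if (!nzchar(s)) {
      stop(sprintf("FASTA format error: record '%s' is empty", id),
           call. = FALSE)
    }
    bad <- regexpr("[^ACGTN]", s)
    if (bad != -1L) {
      stop(sprintf("FASTA format error: record '%s' has invalid residue '%s' at position %d",
                   id, substr(s, bad, bad), bad), call. = FALSE)
    }
    out[[i]] <- seq_record(id, s, desc)
  }
  out
}

#' Write records to a FASTA file
#'
#' @param records A `seq_record` or list of them.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$residues, character(1))
  ids <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed; `N` maps to `N`.
#'
#' @param s DNA string over A/C/G/T/N (case-insensitive).
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(s) {
  s <- toupper(s)
  if (grepl("[^ACGTN]", s)) {
    stop("invalid residue in sequence passed to reverse_complement()",
         call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Create a genomic interval
#'
#' Coordinates are 0-based, half-open: `start` is the first base, `end` is one
#' past the last, and the span is `end - start`. This matches the printed
#' spans of genome-browser region strings such as
#' `"chr3L: 6,821,518-6,823,267"` (span 1,749 bp).
#'
#' @param chrom Chromosome / contig name.
#' @param start 0-based start (inclusive), non-negative.
#' @param end End (exclusive), must exceed `start`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return A `genomic_interval` with fields `chrom`, `start`, `end`, `strand`
#'   and `span`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || start < 0L) stop("start must be a non-negative integer",
                                       call. = FALSE)
  if (is.na(end) || end <= start) stop("end must be greater than start",
                                       call. = FALSE)
  if (!strand %in% c("+", "-", ".")) stop("strand must be +, - or .",
                                          call. = FALSE)
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand, span = end - start),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%d-%d(%s) span %d bp\n",
              x$chrom, x$start, x$end, x$strand, x$span))
  invisible(x)
}

#' Parse a "chrom:start-end" region string
#'
#' Accepts optional internal whitespace and thousands-separator commas, e.g.
#' `"chr3L: 6,821,518-6,823,267"`. The span is reported as `end - start`
#' (0-based half-open convention).
#'
#' @param text Region string.
#' @return A [genomic_interval].
#' @examples
#' parse_region("chr3L: 6,821,518-6,823,267")$span  # 1749
#' @export
parse_region <- function(text) {
  cleaned <- gsub("[[:space:],]", "", as.character(text))
  m <- regexec("^([^:]+):([0-9]+)-([0-9]+)$", cleaned)[[1]]
  if (m[1] == -1L) stop("malformed region string: ", sQuote(text),
                        call. = FALSE)
  parts <- regmatches(cleaned, list(regexec("^([^:]+):([0-9]+)-([0-9]+)$",
                                            cleaned)[[1]]))[[1]]
  start <- as.numeric(parts[3]); end <- as.numeric(parts[4])
  if (end <= start) stop("region end must exceed start in ", sQuote(text),
                         call. = FALSE)
  genomic_interval(parts[2], start, end)
}

#' Write intervals as BED6
#'
#' @param intervals List of [genomic_interval]s (or data.frame with columns
#'   chrom, start, end, name, score, strand).
#' @param path Output path.
#' @param names Feature names (recycled); default `feature_0001`...
#' @param scores Score column (recycled), default 0.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, names = NULL, scores = 0L) {
  if (is.data.frame(intervals)) {
    df <- intervals
  } else {
    if (inherits(intervals, "genomic_interval")) intervals <- list(intervals)
    n <- length(intervals)
    if (is.null(names)) names <- sprintf("feature_%04d", seq_len(n))
    df <- data.frame(
      chrom = vapply(intervals, `[[`, character(1), "chrom"),
      start = vapply(intervals, `[[`, integer(1), "start"),
      end = vapply(intervals, `[[`, integer(1), "end"),
      name = rep_len(names, n),
      score = rep_len(scores, n),
      strand = vapply(intervals, function(x) {
        if (x$strand == ".") "+" else x$strand
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED file path (0-based half-open).
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand")[1:6])
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}
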