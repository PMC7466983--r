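# Shared fixtures: random sequences, mutation helpers, and independent
# oracles (exact local-DP alignment via Biostrings::pairwiseAlignment and a
# brute-force all-pairs k-mer scan). Oracles never call the seed-align path
# they check.

BASES4 <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES4, n, replace = TRUE),
                                collapse = "")

# substitute at rate p; substituted base always differs from the original
mutate_subs <- function(s, p) {
  chars <- strsplit(s, "")[[1]]
  hit <- which(runif(length(chars)) < p)
  if (length(hit)) {
    idx <- match(chars[hit], BASES4)
    chars[hit] <- BASES4[((idx - 1L + sample.int(3L, length(hit),
                                                 replace = TRUE)) %% 4L) + 1L]
  }
  paste(chars, collapse = "")
}

# apply n_indels random short insertions/deletions
mutate_indels <- function(s, n_indels, max_len = 8L) {
  for (i in seq_len(n_indels)) {
    L <- nchar(s)
    pos <- sample(seq_len(L - 1L), 1L)
    len <- sample(max_len, 1L)
    if (runif(1) < 0.5) {
      s <- paste0(substr(s, 1, pos), substr(s, min(pos + len, L) + 1L, L))
    } else {
      s <- paste0(substr(s, 1, pos), random_dna(len),
                  substr(s, pos + 1L, L))
    }
  }
  s
}

# a random sequence sharing no k-mer (either strand) with ref
unrelated_dna <- function(ref, n, k = 9L) {
  ref_k <- unique(c(kmer_set(ref, k), kmer_set(evoprintr::reverse_complement(ref), k)))
  repeat {
    cand <- random_dna(n)
    if (!any(kmer_set(cand, k) %in% ref_k)) return(cand)
  }
}

kmer_set <- function(s, k) {
  starts <- seq_len(nchar(s) - k + 1L)
  substring(s, starts, starts + k - 1L)
}

# --- exact local-DP oracles (match +1, mismatch -1, gap -2, linear) --------
# Primary oracle: Biostrings::pairwiseAlignment (type = "local"), an
# independent mature implementation; sw_identity_positions() extracts the
# 0-based reference positions aligned to an identical test base in its best
# alignment. A hand-rolled full Smith-Waterman (sw_matrix/sw_score) provides
# a second, dependency-free route used to cross-validate the optimal score,
# which is tie-free even though co-optimal paths abound under a linear gap
# cost.
sw_matrix <- function(ref, test) {
  rv <- strsplit(ref, "")[[1]]
  tv <- strsplit(test, "")[[1]]
  m <- length(tv); n <- length(rv)
  H <- matrix(0L, nrow = m + 1L, ncol = n + 1L)
  idx2 <- 2L * seq_len(n)
  for (i in seq_len(m)) {
    s <- ifelse(rv == tv[i] & rv != "N" & tv[i] != "N", 1L, -1L)
    cand <- pmax(0L, H[i, seq_len(n)] + s,       # diagonal
                 H[i, -1L] - 2L)                 # gap in ref (up move)
    # gap in test (left move) resolved by the cummax trick
    H[i + 1L, -1L] <- pmax(cand, cummax(cand + idx2) - idx2)
  }
  H
}

sw_score <- function(ref, test) max(sw_matrix(ref, test))

sw_identity_positions <- function(ref, test) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(test),
    subject = Biostrings::DNAString(ref),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_pos <- Biostrings::start(Biostrings::subject(aln)) - 1L  # 0-based
  out <- integer(0)
  for (i in seq_along(p)) {
    if (s[i] != "-") {
      if (p[i] == s[i] && s[i] != "N") out <- c(out, ref_pos)
      ref_pos <- ref_pos + 1L
    }
  }
  out
}

sw_oracle_score <- function(ref, test) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(test),
    subject = Biostrings::DNAString(ref),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2))
}

# --- brute-force all-pairs k-mer seed oracle -------------------------------
bruteforce_seeds <- function(ref, test, k) {
  refmers <- kmer_set(ref, k)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") test else evoprintr::reverse_complement(test)
    testmers <- kmer_set(s, k)
    eq <- outer(refmers, testmers, "==")
    idx <- which(eq, arr.ind = TRUE)
    if (nrow(idx)) {
      out[[strand]] <- data.frame(ref_pos = idx[, 1] - 1L,
                                  test_pos = idx[, 2] - 1L,
                                  strand = strand,
                                  stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) df <- data.frame(ref_pos = integer(0),
                                    test_pos = integer(0),
                                    strand = character(0))
  rownames(df) <- NULL
  df[order(df$strand, df$ref_pos, df$test_pos), ]
}

# construct an evoprint object directly from a mask (caller unit tests)
fake_evoprint <- function(mask, residues = random_dna(length(mask)),
                          ref_id = "ref") {
  structure(list(ref_id = ref_id, ref_residues = residues,
                 species = "s1", missing_count = as.integer(!mask),
                 R = 0L, mask = mask,
                 missing_species = lapply(mask, function(m)
                   if (m) character(0) else "s1")),
            class = "evoprint")
}

# construct a conservation_profile from a logical matrix (species x pos)
fake_profile <- function(mat, residues = random_dna(ncol(mat))) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("s%d", seq_len(nrow(mat)))
  structure(list(ref_id = "ref", ref_residues = residues,
                 species = rownames(mat), conserved = mat),
            class = "conservation_profile")
}

# csb object from explicit coordinates on a reference string
make_csb <- function(id, start, residues_ref) {
  len <- nchar(residues_ref)
  stop_at <- start + len
  structure(list(id = id,
                 interval = evoprintr::genomic_interval("ref", start, stop_at, "+"),
                 residues = residues_ref, length = len),
            class = "csb")
}

# shuffle composition: permute non-overlapping dinucleotides
dinuc_shuffle <- function(s) {
  n <- nchar(s) %/% 2L
  dinucs <- substring(s, seq(1, 2 * n, by = 2), seq(2, 2 * n, by = 2))
  paste(c(sample(dinucs), if (nchar(s) %% 2) substr(s, nchar(s), nchar(s))),
        collapse = "")
}
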