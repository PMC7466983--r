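test_that("build_kmer_index covers both strands and omits N k-mers", {
  idx <- build_kmer_index(seq_record("t", "ACGTACGT"), 8)
  expect_equal(nrow(idx$table), 2L)  # palindromic revcomp indexes itself too
  expect_setequal(idx$table$kmer, "ACGTACGT")
  expect_equal(idx$table$pos, c(0L, 0L))
  expect_setequal(idx$table$strand, c("+", "-"))

  set.seed(2)
  L <- 60L
  idx <- build_kmer_index(seq_record("t", random_dna(L)), 9)
  expect_equal(sum(idx$table$strand == "+"), L - 8L)

  # 20 bp poly-A: one distinct key, 12 start positions per strand
  idx <- build_kmer_index(seq_record("t", strrep("A", 20)), 9)
  expect_equal(unique(idx$table$kmer[idx$table$strand == "+"]), "AAAAAAAAA")
  expect_equal(sum(idx$table$strand == "+"), 12L)

  expect_equal(nrow(build_kmer_index(seq_record("t", "ACGTNCGTA"), 9)$table),
               0L)  # k-mers containing N are dropped
  expect_error(build_kmer_index(seq_record("t", "ACGT"), 9), "exceeds")
})

test_that("find_seeds reports exact k-mer matches on both strands", {
  set.seed(3)
  s <- random_dna(100)
  ref <- seq_record("r", s)
  idx <- build_kmer_index(seq_record("t", s), 9)
  hits <- find_seeds(ref, idx, 9)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$ref_pos, fwd$test_pos)  # self-match diagonal
  expect_equal(nrow(fwd), 92L)

  idx_rc <- build_kmer_index(seq_record("t", reverse_complement(s)), 9)
  hits_rc <- find_seeds(ref, idx_rc, 9)
  expect_true(all(hits_rc$strand == "-"))
  expect_equal(nrow(hits_rc), 92L)
})

test_that("find_seeds equals the brute-force all-pairs k-mer oracle", {
  set.seed(4)
  for (rep in 1:5) {
    a <- random_dna(200)
    b <- mutate_subs(a, 0.15)
    got <- find_seeds(seq_record("r", a),
                      build_kmer_index(seq_record("t", b), 9), 9,
                      max_kmer_hits = Inf)
    got <- got[order(got$strand, got$ref_pos, got$test_pos),
               c("ref_pos", "test_pos", "strand")]
    rownames(got) <- NULL
    want <- bruteforce_seeds(a, b, 9)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("over-represented k-mers are skipped as seeds", {
  s <- strrep("A", 60)
  idx <- build_kmer_index(seq_record("t", s), 9)
  hits <- find_seeds(seq_record("r", s), idx, 9, max_kmer_hits = 32L)
  expect_equal(nrow(hits), 0L)   # poly-A 9-mer occurs 104x in the index
  hits <- find_seeds(seq_record("r", s), idx, 9, max_kmer_hits = Inf)
  expect_gt(nrow(hits), 0L)
})

test_that("chain_and_extend handles identity, deletion and inversion", {
  set.seed(5)
  s <- random_dna(300)
  ref <- seq_record("r", s)
  p <- align_params()

  # exact copy: one chain, one block, score 300
  seeds <- find_seeds(ref, build_kmer_index(seq_record("t", s), 9), 9)
  ch <- chain_and_extend(seeds, ref, seq_record("t", s), p)
  expect_length(ch, 1)
  expect_equal(nrow(ch[[1]]$blocks), 1L)
  expect_equal(ch[[1]]$score, 300L)
  expect_equal(ch[[1]]$blocks$ref_start, 0L)
  expect_equal(ch[[1]]$blocks$ref_end, 300L)
  expect_equal(ch[[1]]$strand, "+")

  # 50 bp central deletion: one chain of two blocks flanking it
  del <- seq_record("t", paste0(substr(s, 1, 125), substr(s, 176, 300)))
  seeds <- find_seeds(ref, build_kmer_index(del, 9), 9)
  ch <- chain_and_extend(seeds, ref, del, p)
  expect_length(ch, 1)
  expect_equal(nrow(ch[[1]]$blocks), 2L)
  expect_equal(ch[[1]]$blocks$ref_start[1], 0L)
  expect_equal(ch[[1]]$blocks$ref_end[2], 300L)
  # deletion breakpoint: ref resumes at 175 on the test diagonal shifted by 50
  expect_equal(ch[[1]]$blocks$ref_start[2] - ch[[1]]$blocks$test_start[2], 50L)

  # central 60 bp inverted: flanks on "+", inverted segment on "-"
  inv <- seq_record("t", paste0(substr(s, 1, 120),
                                reverse_complement(substr(s, 121, 180)),
                                substr(s, 181, 300)))
  seeds <- find_seeds(ref, build_kmer_index(inv, 9), 9)
  ch <- chain_and_extend(seeds, ref, inv, p)
  strands <- vapply(ch, `[[`, character(1), "strand")
  expect_setequal(strands, c("+", "-"))
  minus <- ch[[which(strands == "-")[1]]]
  expect_gte(minus$blocks$ref_start[1], 115L)
  expect_lte(minus$blocks$ref_end[nrow(minus$blocks)], 185L)
})

test_that("align_species marks identity under chains, with N never matching", {
  set.seed(6)
  s <- random_dna(300)
  ref <- seq_record("r", s)
  out <- align_species(ref, seq_record("t", s))
  expect_true(all(out$conserved))

  un <- seq_record("u", unrelated_dna(s, 300))
  expect_false(any(align_species(ref, un)$conserved))

  # point substitutions punch single-base holes
  mut <- s
  substr(mut, 150, 150) <- chartr("ACGT", "GTAC", substr(mut, 150, 150))
  out <- align_species(ref, seq_record("t", mut))
  expect_false(out$conserved[150])
  expect_equal(sum(!out$conserved), 1L)
})

test_that("align_species is strand-symmetric", {
  set.seed(8)
  for (rep in 1:3) {
    s <- random_dna(250)
    t <- mutate_subs(s, 0.1)
    ref <- seq_record("r", s)
    m1 <- align_species(ref, seq_record("t", t))$conserved
    m2 <- align_species(ref, seq_record("t", reverse_complement(t)))$conserved
    expect_equal(m1, m2)
  }
})

test_that("raising chain thresholds never adds marked bases", {
  set.seed(9)
  s <- random_dna(400)
  t <- mutate_indels(mutate_subs(s, 0.15), 2)
  ref <- seq_record("r", s); tst <- seq_record("t", t)
  loose <- align_species(ref, tst, align_params(min_chain_matches = 10))
  tight <- align_species(ref, tst, align_params(min_chain_matches = 60))
  expect_true(all(loose$conserved[tight$conserved]))
  small <- align_species(ref, tst, align_params(min_block_len = 12))
  expect_true(all(loose$conserved[small$conserved]))
})

test_that("marked set tracks the exact local-DP oracle on small instances", {
  # exact set equality is only defined up to the DP traceback's tie choices
  # (linear gap cost: co-optimal paths abound), so require high per-case
  # Jaccard always and exact equality for at least half the cases
  set.seed(10)
  ok <- 0L
  for (rep in 1:10) {
    a <- random_dna(200)
    b <- mutate_indels(mutate_subs(a, runif(1, 0.02, 0.2)), sample(0:2, 1))
    marked <- which(align_species(seq_record("r", a),
                                  seq_record("t", b))$conserved) - 1L
    oracle <- sw_identity_positions(a, b)
    if (identical(marked, oracle)) ok <- ok + 1L
    jac <- length(intersect(marked, oracle)) /
      length(union(marked, oracle))
    expect_gte(jac, 0.95)
  }
  expect_gte(ok, 5L)
})

test_that("the two oracle routes agree on optimal alignment scores", {
  set.seed(12)
  for (rep in 1:8) {
    a <- random_dna(120)
    b <- mutate_indels(mutate_subs(a, runif(1, 0.05, 0.25)), sample(0:2, 1))
    expect_equal(sw_score(a, b), sw_oracle_score(a, b))
  }
})
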