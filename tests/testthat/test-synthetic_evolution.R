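test_that("zero-rate config reproduces the ancestor exactly", {
  cfg <- simulation_config(500, cbind(start = c(100, 300), length = c(40, 50)),
                           n_species = 3, p_block = 0, p_spacer = 0,
                           indel_rate = 0, seed = 50)
  ds <- generate_dataset(cfg)
  for (sp in ds$species_seqs) {
    expect_equal(sp$residues, ds$ancestor$residues)
  }
  for (tdf in ds$truth) {
    expect_equal(tdf$start, c(100L, 300L))
    expect_equal(tdf$end, c(140L, 350L))
    expect_equal(tdf$strand, c("+", "+"))
  }
})

test_that("datasets are reproducible from the seed", {
  cfg <- function(seed) simulation_config(800, cbind(c(200, 500), c(40, 40)),
                                          n_species = 4, seed = seed)
  d1 <- generate_dataset(cfg(7))
  d2 <- generate_dataset(cfg(7))
  d3 <- generate_dataset(cfg(8))
  expect_identical(d1$species_seqs, d2$species_seqs)
  expect_identical(d1$truth, d2$truth)
  expect_false(identical(d1$species_seqs, d3$species_seqs))
})

test_that("spacer substitution counts follow the binomial expectation", {
  # 1000 bp pure spacer at p = 0.3: mean substituted bases across replicates
  # within 3 standard errors of 300
  n_rep <- 30
  counts <- vapply(seq_len(n_rep), function(i) {
    cfg <- simulation_config(1000, cbind(integer(0), integer(0)),
                             n_species = 1, p_spacer = 0.3, p_block = 0,
                             indel_rate = 0, seed = 1000 + i)
    ds <- generate_dataset(cfg)
    a <- strsplit(ds$ancestor$residues, "")[[1]]
    b <- strsplit(ds$species_seqs[[1]]$residues, "")[[1]]
    sum(a != b)
  }, numeric(1))
  se <- sqrt(1000 * 0.3 * 0.7) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - 300), 3 * se)
})

test_that("blocks diverge less than spacers for every species", {
  cfg <- simulation_config(1200, cbind(c(200, 600, 950), c(50, 60, 40)),
                           n_species = 5, p_block = 0.02, p_spacer = 0.3,
                           indel_rate = 0, seed = 51)
  ds <- generate_dataset(cfg)
  anc <- strsplit(ds$ancestor$residues, "")[[1]]
  in_block <- rep(FALSE, 1200)
  for (b in seq_len(nrow(cfg$blocks))) {
    in_block[(cfg$blocks$start[b] + 1):(cfg$blocks$start[b] + cfg$blocks$length[b])] <- TRUE
  }
  for (sp in ds$species_seqs) {
    spc <- strsplit(sp$residues, "")[[1]]  # no indels: same coordinates
    div_block <- mean(anc[in_block] != spc[in_block])
    div_spacer <- mean(anc[!in_block] != spc[!in_block])
    expect_lt(div_block, div_spacer)
  }
})

test_that("indels only move blocks, never corrupt them", {
  cfg <- simulation_config(1000, cbind(c(300, 700), c(50, 40)),
                           n_species = 3, p_block = 0, p_spacer = 0.1,
                           indel_rate = 0.02, seed = 52)
  ds <- generate_dataset(cfg)
  anc <- ds$ancestor$residues
  for (i in seq_along(ds$species_seqs)) {
    sp <- ds$species_seqs[[i]]
    tdf <- ds$truth[[i]]
    for (b in 1:2) {
      got <- substr(sp$residues, tdf$start[b] + 1, tdf$end[b])
      want <- substr(anc, cfg$blocks$start[b] + 1,
                     cfg$blocks$start[b] + cfg$blocks$length[b])
      expect_equal(got, want)   # p_block = 0: block copies are exact
    }
  }
})

test_that("inversion flips the block copy and its truth strand", {
  cfg <- simulation_config(600, cbind(c(150, 400), c(40, 40)), n_species = 3,
                           p_block = 0, p_spacer = 0, indel_rate = 0,
                           inversion = c(2, 1), seed = 53)
  ds <- generate_dataset(cfg)
  anc_block <- substr(ds$ancestor$residues, 151, 190)
  sp2 <- ds$species_seqs[[2]]
  tdf <- ds$truth[[2]]
  expect_equal(tdf$strand, c("-", "+"))
  expect_equal(substr(sp2$residues, tdf$start[1] + 1, tdf$end[1]),
               reverse_complement(anc_block))
  expect_equal(ds$truth[[1]]$strand, c("+", "+"))
  expect_equal(substr(ds$species_seqs[[1]]$residues, 151, 190), anc_block)
})

test_that("translocation relocates the block copy with exact truth", {
  cfg <- simulation_config(600, cbind(c(150, 400), c(40, 40)), n_species = 2,
                           p_block = 0, p_spacer = 0, indel_rate = 0,
                           translocation = c(1, 2, 10), seed = 54)
  ds <- generate_dataset(cfg)
  anc_block2 <- substr(ds$ancestor$residues, 401, 440)
  tdf <- ds$truth[[1]]
  expect_equal(tdf$start[2], 10L)
  expect_equal(substr(ds$species_seqs[[1]]$residues, 11, 50), anc_block2)
  expect_equal(nchar(ds$species_seqs[[1]]$residues), 600L)
  # block 1 shifted right by the inserted copy
  expect_equal(tdf$start[1], 190L)
  expect_equal(substr(ds$species_seqs[[1]]$residues, 191, 230),
               substr(ds$ancestor$residues, 151, 190))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(500, cbind(c(100, 120), c(40, 40)), 2),
               "overlapping")
  expect_error(simulation_config(500, cbind(480, 40), 2), "outside")
  expect_error(simulation_config(500, cbind(100, 40), 2, p_block = 0.5,
                                 p_spacer = 0.1), "p_block <= p_spacer")
  expect_error(simulation_config(500, cbind(100, 40), 2,
                                 inversion = c(3, 1)), "out of range")
})

test_that("truth_to_bed writes parseable BED6 with strands", {
  cfg <- simulation_config(600, cbind(c(150, 400), c(40, 40)), n_species = 2,
                           p_block = 0, p_spacer = 0, indel_rate = 0,
                           inversion = c(2, 1), seed = 55)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- truth_to_bed(ds, dir)
  expect_length(paths, 2)
  bed1 <- read_bed(paths[["sp01"]])
  expect_equal(bed1$start, c(150L, 400L))
  expect_equal(bed1$strand, c("+", "+"))
  bed2 <- read_bed(paths[["sp02"]])
  expect_equal(bed2$strand, c("-", "+"))
  expect_equal(bed2$name, c("block_1", "block_2"))
})

test_that("the ladder preset echoes a two-level divergence structure", {
  cfg <- preset_gambiae_ladder(seed = 9)
  expect_equal(cfg$n_species, 8L)
  expect_equal(length(unique(cfg$p_spacer[1:4])), 1L)
  expect_true(all(diff(cfg$p_spacer[4:8]) > 0))
  ds <- generate_dataset(cfg)
  expect_length(ds$species_seqs, 8)
})
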