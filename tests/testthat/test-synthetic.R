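test_that("random genomes hit the requested composition and are seeded", {
  g <- generate_genome(1e5, gc = 0.5, seed = 10)
  gc_frac <- nchar(gsub("[^GC]", "", g)) / nchar(g)
  expect_equal(gc_frac, 0.5, tolerance = 0.01)
  expect_identical(g, generate_genome(1e5, gc = 0.5, seed = 10))
  expect_false(identical(g, generate_genome(1e5, gc = 0.5, seed = 11)))
  g2 <- generate_genome(2e4, gc = 0.3, seed = 1)
  expect_equal(nchar(gsub("[^GC]", "", g2)) / 2e4, 0.3, tolerance = 0.02)
  expect_error(generate_genome(100, gc = 0), "gc")
  expect_error(generate_genome(0, gc = 0.5), "length")
})

test_that("planted tracts follow their spec and are recorded truthfully", {
  genome <- generate_genome(2e4, seed = 4)
  # n = 0 leaves the genome untouched
  p0 <- plant_lcrs(genome, 0)
  expect_identical(p0$genome, genome)
  expect_equal(nrow(p0$regions), 0L)

  planted <- plant_lcrs(genome, 8, lcr_spec("GA", 60, purity = 1),
                        region_length = 120, seed = 5)
  expect_equal(nrow(planted$regions), 8L)
  for (i in 1:8) {
    reg <- planted$regions[i, ]
    tract <- substr(planted$genome, reg$tract_start + 1, reg$tract_end)
    oracle <- substr(strrep("GA", 30), 1, 60)
    if (reg$strand == "-") oracle <- revcomp(oracle)
    expect_identical(tract, oracle)
    # region purine composition reflects the construction
    seqs <- extract_region_sequence(c(chr1 = planted$genome), reg)
    expect_gte(polypurine_content(seqs[[1]]), 100 * 60 / 120)
  }
  # non-overlap among planted regions
  o <- order(planted$regions$start)
  expect_true(all(diff(planted$regions$start[o]) >= 120))
  expect_error(plant_lcrs(genome, 5, lcr_spec("A", 100),
                          region_length = 50), "tract_length")
  expect_error(lcr_spec("AT", 50), "unit")
})

test_that("control regions match requested lengths and avoid exclusions", {
  genome <- generate_genome(5e4, seed = 6)
  excl <- data.frame(start = c(0L, 20000L), end = c(10000L, 30000L))
  lens <- c(100L, 200L, 300L)
  bed <- sample_control_regions(genome, lens, exclude = excl, seed = 7)
  expect_equal(sort(bed$end - bed$start), sort(lens))
  for (i in seq_len(nrow(bed)))
    expect_false(any(bed$start[i] < excl$end & bed$end[i] > excl$start))
  expect_identical(bed, sample_control_regions(genome, lens,
                                               exclude = excl, seed = 7))
  # infeasible packing fails loudly
  expect_error(sample_control_regions(1000, rep(400, 5), seed = 1,
                                      max_tries = 50),
               "placement error")
})

test_that("panel transcripts carry the requested runs and composition", {
  panel <- generate_rna_panel(20, length = 1000, gc = 0.5, seed = 8)
  expect_equal(length(panel), 20L)
  expect_true(all(nchar(panel) == 1000))
  expect_identical(panel, generate_rna_panel(20, 1000, 0.5, seed = 8))

  with_runs <- generate_rna_panel(
    10, 1000, 0.5, runs = run_spec(c("C", "U"), 12, 2), seed = 9)
  for (tx in with_runs) {
    m <- gregexpr("[CU]{12,}", tx)[[1]]
    expect_true(m[1] != -1)
    expect_gte(sum(attr(m, "match.length")), 24)
  }
  expect_error(generate_rna_panel(2, 20, 0.5,
                                  runs = run_spec(c("C", "U"), 12, 2)),
               "do not fit")
  expect_error(run_spec(c("A", "C"), 12, 1), "alphabet")
})

test_that("the default fixture composes all parts consistently", {
  cfg <- fixture_config(genome_length = 1e5, n_planted = 10,
                        n_background = 10, n_rnas = 5)
  fx <- make_fixture(cfg, seed = 1)
  expect_equal(nrow(fx$planted), 10L)
  expect_equal(nrow(fx$background), 10L)
  expect_equal(length(fx$panel), 5L)
  expect_equal(nrow(fx$truth), 20L)
  # planted and background coordinates are disjoint
  all_reg <- rbind(fx$planted[, c("start", "end")],
                   fx$background[, c("start", "end")])
  o <- order(all_reg$start)
  expect_true(all(all_reg$start[o][-1] >= all_reg$end[o][-nrow(all_reg)]))
  # planted regions are much more purine-biased than background
  g <- fx$genome
  pl <- extract_region_sequence(g, fx$planted)
  bg <- extract_region_sequence(g, fx$background)
  expect_gt(mean(vapply(pl, polypurine_content, numeric(1))),
            mean(vapply(bg, polypurine_content, numeric(1))))
  # different seed moves coordinates but keeps the counts
  fx2 <- make_fixture(cfg, seed = 2)
  expect_equal(nrow(fx2$planted), 10L)
  expect_false(identical(fx$planted$start, fx2$planted$start))
})

test_that("fixture files round-trip through the standard formats", {
  dir <- withr::local_tempdir()
  cfg <- fixture_config(genome_length = 5e4, n_planted = 4,
                        n_background = 4, n_rnas = 3)
  fx <- make_fixture(cfg, seed = 3, out_dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("genome.fasta", "planted.bed", "background.bed",
           "panel.fasta", "truth.tsv")))))
  genome <- read_fasta(file.path(dir, "genome.fasta"), "DNA")
  expect_identical(genome, fx$genome)
  planted <- read_bed(file.path(dir, "planted.bed"))
  expect_equal(planted$start, fx$planted$start)
  panel <- read_fasta(file.path(dir, "panel.fasta"), "RNA")
  expect_identical(panel, fx$panel)
})
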