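#' Generate a random genome sequence
#'
#' I.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`.
#' A neutral background standing in for randomly sampled genomic
#' sequence; no repeat structure is emulated.
#'
#' @param length genome length in bp, >= 1.
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed.
#' @return a single DNA string.
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1L) {
  if (length < 1) stop("length must be >= 1")
  if (!(gc > 0 && gc < 1)) stop("gc must be in (0, 1)")
  set.seed(seed)
  random_seq(length, DNA_ALPHABET,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Specification of a planted purine-rich low-complexity tract
#'
#' @param unit short all-purine repeat unit over `G`/`A` (e.g. `"A"`,
#'   `"G"`, `"GA"`, `"GGA"`).
#' @param tract_length tract length in bp, >= 10.
#' @param purity probability in (0, 1\] that a position follows the unit
#'   pattern; otherwise a uniform random base is substituted.
#' @return list of class `"lcr_spec"`.
#' @export
lcr_spec <- function(unit = "A", tract_length = 100L, purity = 1) {
  if (!nzchar(unit) || grepl("[^GA]", unit))
    stop("unit must be a non-empty string over {G, A}")
  if (tract_length < 10) stop("tract_length must be >= 10")
  if (!(purity > 0 && purity <= 1)) stop("purity must be in (0, 1]")
  structure(list(unit = unit, tract_length = as.integer(tract_length),
                 purity = purity), class = "lcr_spec")
}

lcr_tract <- function(spec) {
  tract <- strsplit(strrep(spec$unit,
                           ceiling(spec$tract_length / nchar(spec$unit))),
                    "", fixed = TRUE)[[1]][seq_len(spec$tract_length)]
  if (spec$purity < 1) {
    corrupt <- runif(spec$tract_length) > spec$purity
    tract[corrupt] <- sample(DNA_ALPHABET, sum(corrupt), replace = TRUE)
  }
  paste(tract, collapse = "")
}

place_nonoverlapping <- function(total_length, lengths, exclude_starts,
                                 exclude_ends, max_tries = 10000L) {
  starts <- integer(0)
  ends <- integer(0)
  for (len in lengths) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(total_length - len + 1L, 1L) - 1L
      e <- s + len
      if (!any(s < c(exclude_ends, ends) & e > c(exclude_starts, starts))) {
        starts <- c(starts, s)
        ends <- c(ends, e)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("placement error: could not place a region of length ", len,
           " without overlap after ", max_tries, " tries")
  }
  data.frame(start = starts, end = ends)
}

#' Plant purine-rich low-complexity tracts into a genome
#'
#' Places `n` non-overlapping regions of `region_length` bp; within each
#' region a tract built by repeating the unit of an [lcr_spec()] (with
#' per-position corruption at rate `1 - purity`) is inserted at a random
#' offset on a randomly chosen strand. Several specs may be supplied and
#' are recycled across the planted regions.
#'
#' @param genome a single DNA string.
#' @param n number of regions to plant.
#' @param spec an [lcr_spec()] or a list of them (recycled over regions).
#' @param region_length length of each planted region in bp.
#' @param seed integer seed.
#' @param chrom chromosome name recorded in the truth table.
#' @return list with `genome` (modified string) and `regions`
#'   (data.frame: `chrom`, `start`, `end`, `name`, `strand`, `unit`,
#'   `tract_start`, `tract_end`).
#' @export
plant_lcrs <- function(genome, n, spec = lcr_spec(),
                       region_length = 200L, seed = 1L, chrom = "chr1") {
  if (inherits(spec, "lcr_spec")) spec <- list(spec)
  stopifnot(all(vapply(spec, inherits, logical(1), "lcr_spec")))
  glen <- nchar(genome)
  if (n == 0)
    return(list(genome = genome,
                regions = data.frame(chrom = character(0),
                                     start = integer(0), end = integer(0),
                                     name = character(0),
                                     strand = character(0),
                                     unit = character(0),
                                     tract_start = integer(0),
                                     tract_end = integer(0),
                                     stringsAsFactors = FALSE)))
  if (n * region_length > glen / 2)
    stop("n * region_length must be <= half the genome length")
  if (any(vapply(spec, `[[`, integer(1), "tract_length") > region_length))
    stop("tract_length must be <= region_length")
  set.seed(seed)
  placed <- place_nonoverlapping(glen, rep(region_length, n),
                                 integer(0), integer(0))
  regions <- data.frame(chrom = chrom, start = placed$start,
                        end = placed$end,
                        name = sprintf("planted_%03d", seq_len(n)),
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        unit = NA_character_,
                        tract_start = NA_integer_,
                        tract_end = NA_integer_,
                        stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sp <- spec[[(i - 1L) %% length(spec) + 1L]]
    tract <- lcr_tract(sp)
    if (regions$strand[i] == "-") tract <- revcomp(tract)
    offset <- sample.int(region_length - sp$tract_length + 1L, 1L) - 1L
    t0 <- regions$start[i] + offset
    substr(genome, t0 + 1L, t0 + sp$tract_length) <- tract
    regions$unit[i] <- sp$unit
    regions$tract_start[i] <- t0
    regions$tract_end[i] <- t0 + sp$tract_length
  }
  list(genome = genome, regions = regions)
}

#' Sample length-matched control regions
#'
#' Uniformly placed regions with the requested lengths, avoiding overlap
#' with `exclude` and with one another — the analog of control regions
#' randomly sampled from a genome with lengths matched to a peak set.
#'
#' @param genome a single DNA string (or its length as a number).
#' @param lengths integer vector of region lengths to sample.
#' @param exclude data.frame of regions to avoid (`start`, `end`), or
#'   `NULL`.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @param max_tries placement attempts per region before failing.
#' @return data.frame: `chrom`, `start`, `end`, `name`.
#' @export
sample_control_regions <- function(genome, lengths, exclude = NULL,
                                   seed = 1L, chrom = "chr1",
                                   max_tries = 10000L) {
  glen <- if (is.character(genome)) nchar(genome) else as.integer(genome)
  if (any(lengths > glen)) stop("region length exceeds genome length")
  set.seed(seed)
  ex_s <- if (is.null(exclude)) integer(0) else exclude$start
  ex_e <- if (is.null(exclude)) integer(0) else exclude$end
  placed <- place_nonoverlapping(glen, lengths, ex_s, ex_e, max_tries)
  data.frame(chrom = chrom, start = placed$start, end = placed$end,
             name = sprintf("control_%03d", seq_along(lengths)),
             stringsAsFactors = FALSE)
}

#' Specification of injected runs for panel transcripts
#'
#' Describes low-complexity runs injected into otherwise i.i.d.
#' transcripts. Each injected run is a homopolymer tract whose base
#' cycles through `alphabet` (run 1 uses the first letter, run 2 the
#' second, wrapping around), emulating the simple-repeat runs real
#' transcripts carry; uniform i.i.d. transcripts almost never contain
#' the >= 10 nt single-motif runs that drive triplex counts.
#'
#' @param alphabet one of the motif alphabets `c("C","U")`, `c("G","U")`
#'   or `c("G","A")`.
#' @param run_length run length in nt, >= 10.
#' @param n_runs runs per transcript.
#' @return list of class `"run_spec"`.
#' @export
run_spec <- function(alphabet = c("C", "U"), run_length = 12L,
                     n_runs = 2L) {
  allowed <- list(c("C", "U"), c("G", "U"), c("G", "A"))
  if (!any(vapply(allowed, function(a) setequal(a, alphabet), logical(1))))
    stop('alphabet must be one of {C,U}, {G,U}, {G,A}')
  if (run_length < 10) stop("run_length must be >= 10")
  if (n_runs < 1) stop("n_runs must be >= 1")
  structure(list(alphabet = alphabet,
                 run_length = as.integer(run_length),
                 n_runs = as.integer(n_runs)), class = "run_spec")
}

#' Generate a panel of transcripts with controlled composition
#'
#' I.i.d. RNA background at the requested GC fraction with optional
#' low-complexity runs (see [run_spec()]) injected at random
#' non-overlapping positions of every transcript.
#'
#' @param n number of transcripts, >= 1.
#' @param length transcript length in nt.
#' @param gc GC fraction in (0, 1).
#' @param runs `NULL`, a [run_spec()], or a list of them (all applied to
#'   every transcript).
#' @param seed integer seed.
#' @return named character vector of RNA sequences (`tx001`, ...).
#' @export
generate_rna_panel <- function(n, length = 1000L, gc = 0.5,
                               runs = NULL, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (!(gc > 0 && gc < 1)) stop("gc must be in (0, 1)")
  if (inherits(runs, "run_spec")) runs <- list(runs)
  stopifnot(is.null(runs) ||
              all(vapply(runs, inherits, logical(1), "run_spec")))
  set.seed(seed)
  run_bases <- character(0)
  if (!is.null(runs)) {
    for (sp in runs)
      for (k in seq_len(sp$n_runs))
        run_bases <- c(run_bases,
                       strrep(sp$alphabet[(k - 1L) %% base::length(sp$alphabet) + 1L],
                              sp$run_length))
  }
  if (sum(nchar(run_bases)) > length)
    stop("injected runs do not fit in the transcript length")
  panel <- character(n)
  for (i in seq_len(n)) {
    tx <- random_seq(length, RNA_ALPHABET,
                     prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    if (base::length(run_bases)) {
      placed <- place_nonoverlapping(length, nchar(run_bases),
                                     integer(0), integer(0))
      for (j in seq_along(run_bases))
        substr(tx, placed$start[j] + 1L, placed$end[j]) <- run_bases[j]
    }
    panel[i] <- tx
  }
  names(panel) <- sprintf("tx%03d", seq_len(n))
  panel
}

#' Default desk-scale fixture configuration
#'
#' A 500 kb neutral genome with 50 planted pure poly-purine regions
#' (alternating poly-A and poly-G tracts of 100 bp inside 200 bp
#' regions), 50 length-matched background regions, and a panel of 20
#' transcripts of 1000 nt carrying two pyrimidine runs (one poly-C, one
#' poly-U) and one purine (poly-G) run of 12 nt each.
#'
#' @param genome_length,genome_gc genome size and GC fraction.
#' @param n_planted,region_length,tract_length,purity,units planted-tract
#'   parameters; `units` are recycled across planted regions.
#' @param n_background number of length-matched control regions.
#' @param n_rnas,rna_length,rna_gc panel parameters.
#' @param panel_runs list of [run_spec()]s applied to every transcript.
#' @return configuration list.
#' @export
fixture_config <- function(genome_length = 5e5, genome_gc = 0.5,
                           n_planted = 50L, region_length = 200L,
                           tract_length = 100L, purity = 1,
                           units = c("A", "G"),
                           n_background = 50L,
                           n_rnas = 20L, rna_length = 1000L,
                           rna_gc = 0.5,
                           panel_runs = list(
                             run_spec(c("C", "U"), 12L, 2L),
                             run_spec(c("G", "A"), 12L, 1L))) {
  as.list(environment())
}

#' Build the complete synthetic fixture
#'
#' Composes [generate_genome()], [plant_lcrs()],
#' [sample_control_regions()] and [generate_rna_panel()] into a full
#' dataset with a machine-readable truth table. Planted and background
#' regions are disjoint in coordinates; the expected positive set is the
#' planted region names.
#'
#' @param config list from [fixture_config()].
#' @param seed integer master seed (sub-generators are seeded from it).
#' @param out_dir optional directory; when given, writes `genome.fasta`,
#'   `planted.bed`, `background.bed`, `panel.fasta` and `truth.tsv`.
#' @return list with `genome` (named, one chromosome), `planted`,
#'   `background` (region data.frames), `panel` (named RNA vector),
#'   `truth` (per-region class table).
#' @export
make_fixture <- function(config = fixture_config(), seed = 1L,
                         out_dir = NULL) {
  seed <- as.integer(seed)
  genome <- generate_genome(config$genome_length, config$genome_gc,
                            seed = seed)
  specs <- lapply(config$units, function(u)
    lcr_spec(u, config$tract_length, config$purity))
  planted <- plant_lcrs(genome, config$n_planted, specs,
                        region_length = config$region_length,
                        seed = seed + 1L)
  background <- sample_control_regions(
    planted$genome, rep(config$region_length, config$n_background),
    exclude = planted$regions, seed = seed + 2L)
  panel <- generate_rna_panel(config$n_rnas, config$rna_length,
                              config$rna_gc, runs = config$panel_runs,
                              seed = seed + 3L)
  truth <- rbind(
    data.frame(name = planted$regions$name, class = "planted",
               unit = planted$regions$unit, stringsAsFactors = FALSE),
    data.frame(name = background$name, class = "background",
               unit = NA_character_, stringsAsFactors = FALSE))
  out <- list(genome = c(chr1 = planted$genome),
              planted = planted$regions, background = background,
              panel = panel, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$genome, file.path(out_dir, "genome.fasta"))
    write_bed(planted$regions[, c("chrom", "start", "end", "name")],
              file.path(out_dir, "planted.bed"))
    write_bed(background[, c("chrom", "start", "end", "name")],
              file.path(out_dir, "background.bed"))
    write_fasta(out$panel, file.path(out_dir, "panel.fasta"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}
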