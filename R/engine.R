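MOTIFS <- c("TC", "GA", "GT")

#' Triplex search parameters
#'
#' Bundles the thresholds of the triplex enumeration engine. Defaults
#' correspond to the standard search configuration used throughout the
#' package: minimum window length 10, at most 10% mismatching triples per
#' window, all three motif families, both orientations, both DNA strands,
#' and no low-complexity masking.
#'
#' @param min_length minimum triplex window length (nt), >= 2.
#' @param max_error_rate maximum percentage of positions in a window that
#'   may violate the pairing rules; the allowance for a window of length
#'   L is `floor(L * max_error_rate / 100)`.
#' @param motifs subset of `c("TC", "GA", "GT")`. TC is the pyrimidine
#'   motif (parallel only: C.G, U.A), GA the purine motif (antiparallel
#'   only: G.G, A.A), GT the mixed motif (both orientations: G.G, U.A).
#' @param orientations subset of `c("parallel", "antiparallel")`:
#'   orientation of the third strand relative to the purine strand of
#'   the duplex.
#' @param require_terminal_match if `TRUE` (default) the first and last
#'   aligned positions of a window must be valid triples, so windows
#'   cannot be padded with boundary mismatches.
#' @param scan_both_dna_strands scan both strands of the DNA duplex for
#'   the purine tract (default `TRUE`).
#' @param max_consecutive_errors optional cap on consecutive mismatches
#'   within a window; `Inf` (default) disables the filter.
#' @param min_guanine_rate optional minimum percentage of guanines on the
#'   purine-strand window; 0 (default) disables the filter.
#' @return object of class `"engine_params"`.
#' @export
engine_params <- function(min_length = 10L,
                          max_error_rate = 10,
                          motifs = MOTIFS,
                          orientations = c("parallel", "antiparallel"),
                          require_terminal_match = TRUE,
                          scan_both_dna_strands = TRUE,
                          max_consecutive_errors = Inf,
                          min_guanine_rate = 0) {
  min_length <- as.integer(min_length)
  if (is.na(min_length) || min_length < 2L)
    stop("min_length must be an integer >= 2")
  if (max_error_rate < 0 || max_error_rate >= 100)
    stop("max_error_rate must be in [0, 100)")
  motifs <- match.arg(motifs, MOTIFS, several.ok = TRUE)
  orientations <- match.arg(orientations,
                            c("parallel", "antiparallel"),
                            several.ok = TRUE)
  structure(list(min_length = min_length,
                 max_error_rate = max_error_rate,
                 motifs = motifs,
                 orientations = orientations,
                 require_terminal_match = isTRUE(require_terminal_match),
                 scan_both_dna_strands = isTRUE(scan_both_dna_strands),
                 max_consecutive_errors = max_consecutive_errors,
                 min_guanine_rate = min_guanine_rate),
            class = "engine_params")
}

#' Hoogsteen pairing rule table
#'
#' Decides whether an RNA base can form a Hoogsteen triple with a purine
#' base of the DNA duplex under a given motif family and orientation.
#' The rule set: TC motif (parallel only) validates C.G and U.A; GA motif
#' (antiparallel only) validates G.G and A.A; GT motif (both
#' orientations) validates G.G and U.A. Equivalently, DNA guanine binds
#' RNA guanine in both orientations and RNA cytosine in parallel only,
#' while DNA adenine binds RNA uracil in both orientations and RNA
#' adenine in antiparallel only.
#'
#' @param rna_base character vector over `A`, `C`, `G`, `U`.
#' @param dna_purine_base character vector over `A`, `G` (base on the
#'   purine-tract strand).
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @param motif `"TC"`, `"GA"` or `"GT"`.
#' @return logical vector.
#' @export
pairing_valid <- function(rna_base, dna_purine_base, orientation, motif) {
  stopifnot(all(rna_base %in% c("A", "C", "G", "U")),
            all(dna_purine_base %in% c("A", "G")),
            all(orientation %in% c("parallel", "antiparallel")),
            all(motif %in% MOTIFS))
  key <- paste(motif, orientation, rna_base, dna_purine_base)
  ok <- c("TC parallel C G", "TC parallel U A",
          "GA antiparallel G G", "GA antiparallel A A",
          "GT parallel G G", "GT parallel U A",
          "GT antiparallel G G", "GT antiparallel U A")
  key %in% ok
}

check_scan_inputs <- function(rna, dna) {
  if (length(rna) != 1L || length(dna) != 1L)
    stop("rna and dna must be single sequences")
  if (!nzchar(rna) || !nzchar(dna)) stop("empty sequence")
  if (grepl("T", rna, fixed = TRUE))
    stop("rna contains 'T': RNA passed as DNA?")
  if (grepl("U", dna, fixed = TRUE))
    stop("dna contains 'U': DNA passed as RNA?")
  if (grepl("[^ACGUN]", rna)) stop("invalid character in RNA sequence")
  if (grepl("[^ACGTN]", dna)) stop("invalid character in DNA sequence")
}

tpx_scan <- function(rna, dna, params, count_only) {
  check_scan_inputs(rna, dna)
  stopifnot(inherits(params, "engine_params"))
  .tpx_scan_cpp(rna, dna,
                params$min_length, params$max_error_rate,
                MOTIFS %in% params$motifs,
                "parallel" %in% params$orientations,
                "antiparallel" %in% params$orientations,
                params$require_terminal_match,
                params$scan_both_dna_strands,
                params$max_consecutive_errors,
                params$min_guanine_rate,
                count_only)
}

#' Enumerate all qualifying triplex windows for one RNA-DNA pair
#'
#' Returns every distinct window of length `>= min_length` in which the
#' RNA, aligned against the purine-tract strand of the DNA duplex
#' (index-aligned for the parallel orientation, reverse-index-aligned for
#' the antiparallel orientation), violates the pairing rules of at least
#' one enabled motif family at no more than
#' `floor(max_error_rate / 100 * length)` positions. Motif families are
#' evaluated window-wide and never mixed within a window; a window
#' validated by several families is reported once with all validating
#' motifs. Overlapping windows are all reported ("overlaps allowed"), so
#' a single long perfect triplex yields every sub-window above the
#' minimum length as well.
#'
#' @param rna RNA sequence (single string over `A`, `C`, `G`, `U`).
#' @param dna forward-strand DNA sequence of the duplex (single string
#'   over `A`, `C`, `G`, `T`).
#' @param params an [engine_params()] object.
#' @return data.frame with one row per window: `rna_start`, `rna_end`,
#'   `dna_start`, `dna_end` (0-based half-open; DNA coordinates always on
#'   the forward strand), `dna_strand` (strand carrying the purine
#'   tract), `orientation`, `motifs` (comma-separated validating
#'   families) and `n_errors` (minimum over validating families), sorted
#'   deterministically.
#' @examples
#' enumerate_triplexes("GAGAGAGAGAG", "GAGAGAGAGAG")
#' @export
enumerate_triplexes <- function(rna, dna, params = engine_params()) {
  res <- tpx_scan(rna, dna, params, count_only = FALSE)
  df <- data.frame(rna_start = res$rna_start, rna_end = res$rna_end,
                   dna_start = res$dna_start, dna_end = res$dna_end,
                   dna_strand = res$dna_strand,
                   orientation = res$orientation,
                   motifs = vapply(res$motif_mask, function(mask)
                     paste(MOTIFS[bitwAnd(mask, c(1L, 2L, 4L)) > 0L],
                           collapse = ","), character(1)),
                   n_errors = res$n_errors,
                   stringsAsFactors = FALSE)
  df[order(df$rna_start, df$rna_end, df$dna_start, df$dna_end,
           df$dna_strand, df$orientation), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Count qualifying triplex windows (N_tpx)
#'
#' The total number of all possible triplex windows that satisfy the
#' thresholds, overlaps allowed — the quantity scored against the Poisson
#' null by [triplex_pvalue()]. Equals `nrow(enumerate_triplexes(...))`
#' but avoids materialising the window table.
#'
#' @inheritParams enumerate_triplexes
#' @return non-negative integer-valued count.
#' @examples
#' count_triplexes("GAGAGAGAGAG", "GAGAGAGAGAG")  # 3
#' @export
count_triplexes <- function(rna, dna, params = engine_params()) {
  tpx_scan(rna, dna, params, count_only = TRUE)$count
}
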