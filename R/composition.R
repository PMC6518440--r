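#' Purine fraction of one strand of a DNA duplex
#'
#' Percentage of purines (G or A) on the requested strand of the duplex.
#' The minus strand is evaluated on the reverse complement of the
#' forward-strand sequence; since purines on one strand face pyrimidines
#' on the other, the two strand values always sum to 100% for unmasked
#' sequences.
#'
#' @param dna forward-strand DNA sequence (single string).
#' @param strand `"+"` or `"-"`.
#' @return percentage in \[0, 100\].
#' @export
strand_purine_fraction <- function(dna, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (length(dna) != 1 || !nzchar(dna)) stop("empty sequence")
  s <- if (strand == "+") dna else revcomp(dna)
  n_pur <- nchar(gsub("[^GA]", "", s))
  100 * n_pur / nchar(dna)
}

#' GA content of a DNA region
#'
#' The purine content of a duplex: the maximum over the two strands of
#' the strand purine fraction. Unlike GC content this is strand-resolved
#' and is always >= 50% (for unmasked sequences), because a purine-poor
#' strand implies a purine-rich complement.
#'
#' @inheritParams strand_purine_fraction
#' @return percentage in \[50, 100\] (unmasked input).
#' @export
ga_content <- function(dna) {
  max(strand_purine_fraction(dna, "+"), strand_purine_fraction(dna, "-"))
}

#' Locate poly-purine runs on both strands
#'
#' Maximal runs of `min_run` or more consecutive purines on either strand
#' of the duplex, reported in forward-strand coordinates (0-based
#' half-open). A minus-strand run corresponds to a pyrimidine (C/T) run
#' on the forward-strand string. Masked characters (`N`) break runs and
#' count as non-purines on both strands.
#'
#' @inheritParams strand_purine_fraction
#' @param min_run minimum run length (default 10).
#' @return data.frame with columns `strand`, `start`, `end`, `length`.
#' @export
purine_runs <- function(dna, min_run = 10L) {
  if (length(dna) != 1 || !nzchar(dna)) stop("empty sequence")
  min_run <- as.integer(min_run)
  if (min_run < 1L) stop("min_run must be >= 1")
  chars <- strsplit(dna, "", fixed = TRUE)[[1]]
  runs_for <- function(is_run, strand) {
    r <- rle(is_run)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths >= min_run
    data.frame(strand = rep(strand, sum(keep)),
               start = starts[keep], end = ends[keep],
               length = r$lengths[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(runs_for(chars %in% c("G", "A"), "+"),
               runs_for(chars %in% c("C", "T"), "-"))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Poly-purine content of a DNA region
#'
#' For each strand, the summed length of that strand's purine runs of
#' `min_run` or more, divided by the region length; the maximum over the
#' two strands is returned as a percentage. Runs from different strands
#' are never mixed. Unlike [ga_content()] this measure spans the full
#' \[0, 100\] range.
#'
#' @inheritParams purine_runs
#' @return percentage in \[0, 100\].
#' @export
polypurine_content <- function(dna, min_run = 10L) {
  runs <- purine_runs(dna, min_run = min_run)
  if (nrow(runs) == 0) return(0)
  per_strand <- tapply(runs$length, runs$strand, sum)
  100 * max(per_strand) / nchar(dna)
}

#' Composition profile of DNA regions
#'
#' @param seqs named character vector of forward-strand DNA sequences.
#' @param min_run minimum poly-purine run length (default 10).
#' @return data.frame with one row per sequence: `id`, `length`,
#'   `ga_content`, `ga_strand` (strand attaining the maximum purine
#'   fraction; `"+"` on ties), `polypurine_content`, `n_runs`.
#' @export
composition_profile <- function(seqs, min_run = 10L) {
  ids <- if (is.null(names(seqs))) as.character(seq_along(seqs))
         else names(seqs)
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    plus <- strand_purine_fraction(s, "+")
    minus <- strand_purine_fraction(s, "-")
    runs <- purine_runs(s, min_run = min_run)
    data.frame(id = ids[i], length = nchar(s),
               ga_content = max(plus, minus),
               ga_strand = if (plus >= minus) "+" else "-",
               polypurine_content = polypurine_content(s, min_run),
               n_runs = nrow(runs), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
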