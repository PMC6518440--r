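#' Exact dinucleotide-preserving shuffle of one sequence
#'
#' Produces a random permutation of the input that preserves the exact
#' 16-entry dinucleotide count vector (and therefore the mononucleotide
#' counts, the length, and the first and last residue). Sampling follows
#' the Altschul-Erickson scheme: the dinucleotide transition multigraph
#' is built, a random last-exit edge is drawn for every vertex until the
#' chosen edges form an arborescence converging on the terminal residue,
#' the remaining edges are permuted uniformly, and the resulting Eulerian
#' path is walked to spell the shuffled sequence. Used to build
#' composition-matched control RNAs.
#'
#' @param seq a single sequence (RNA or DNA; the alphabet is shuffled
#'   as-is, length >= 2).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return shuffled sequence (single string).
#' @examples
#' dinucleotide_shuffle("GAGAGA", seed = 1)  # "GAGAGA" (unique arrangement)
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  if (length(seq) != 1) stop("seq must be a single sequence")
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  if (n < 2) stop("sequence must have length >= 2")
  if (!is.null(seed)) set.seed(seed)
  verts <- unique(x)
  if (length(verts) == 1L) return(seq)
  s1 <- x[1]
  sL <- x[n]
  adj <- split(x[-1], factor(x[-n], levels = verts))

  # vertices needing a designated last-exit edge
  need_last <- verts[verts != sL & lengths(adj[verts]) > 0]
  repeat {
    last <- vapply(need_last, function(v) {
      targets <- adj[[v]]
      targets[sample.int(length(targets), 1L)]
    }, character(1))
    # the last-exit edges must form paths that all reach the terminal
    reaches <- vapply(need_last, function(v) {
      for (step in seq_len(length(verts))) {
        v <- last[[v]]
        if (identical(v, sL)) return(TRUE)
        if (!v %in% need_last) return(FALSE)
      }
      FALSE
    }, logical(1))
    if (all(reaches)) break
  }

  ordered <- adj
  for (v in verts) {
    targets <- adj[[v]]
    if (v %in% need_last) {
      drop <- match(last[[v]], targets)
      rest <- targets[-drop]
      ordered[[v]] <- c(rest[sample.int(length(rest))], last[[v]])
    } else if (length(targets)) {
      ordered[[v]] <- targets[sample.int(length(targets))]
    }
  }

  res <- character(n)
  res[1] <- s1
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  cur <- s1
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Dinucleotide-shuffled control panel
#'
#' Generates `n_per_seq` independent dinucleotide-preserving shuffles of
#' each input sequence (default 153, the size of the standard control
#' panel).
#'
#' @param seqs named character vector of sequences.
#' @param n_per_seq shuffles per input sequence.
#' @param seed integer seed.
#' @return named character vector with ids `<id>_shuf<k>`.
#' @export
shuffle_panel <- function(seqs, n_per_seq = 153L, seed = 1L) {
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  set.seed(seed)
  out <- character(0)
  for (id in names(seqs)) {
    for (k in seq_len(n_per_seq)) {
      shuf <- dinucleotide_shuffle(seqs[[id]])
      out[paste0(id, "_shuf", k)] <- shuf
    }
  }
  out
}

#' Dinucleotide count vector of a sequence
#'
#' Convenience used to verify shuffle exactness.
#'
#' @param seq a single sequence.
#' @return named integer table of overlapping dinucleotide counts.
#' @export
dinucleotide_counts <- function(seq) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(x) < 2) stop("sequence must have length >= 2")
  table(paste0(x[-length(x)], x[-1]))
}
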