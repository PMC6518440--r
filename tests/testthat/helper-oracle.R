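# Independent brute-force oracle for triplex window enumeration.
# Written directly from the Hoogsteen rule table: every (rna interval,
# dna interval, strand, orientation, motif) combination is materialised
# and checked position by position; no pruning, no sharing with the
# package's scanning engine. Biostrings supplies the reverse complement.

oracle_rules <- list(
  TC = list(orient = "parallel", ok = c("C G", "U A")),
  GA = list(orient = "antiparallel", ok = c("G G", "A A")),
  GT = list(orient = c("parallel", "antiparallel"), ok = c("G G", "U A"))
)

oracle_revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

# All qualifying windows for one (strand, orientation, motif), with the
# purine strand pre-oriented so the RNA is index-aligned against B.
oracle_windows_aligned <- function(r, B, ok, min_length, rate, terminal) {
  n <- length(r)
  m <- length(B)
  hits <- list()
  for (delta in (-(n - 1)):(m - 1)) {
    i0 <- max(0L, -delta)
    j0 <- i0 + delta
    len <- min(n - i0, m - j0)
    if (len < min_length) next
    good <- paste(r[(i0 + 1):(i0 + len)], B[(j0 + 1):(j0 + len)]) %in% ok
    E <- c(0L, cumsum(!good))
    for (L in min_length:len) {
      s <- seq_len(len - L + 1L) - 1L      # 0-based local offsets
      errs <- E[s + L + 1L] - E[s + 1L]
      keep <- errs <= floor(L * rate / 100)
      if (terminal) keep <- keep & good[s + 1L] & good[s + L]
      if (any(keep))
        hits[[length(hits) + 1L]] <-
          data.frame(i = i0 + s[keep], jB = j0 + s[keep], L = L,
                     n_errors = errs[keep])
    }
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(i = integer(0), jB = integer(0), L = integer(0),
                  n_errors = integer(0))
}

oracle_enumerate <- function(rna, dna, min_length = 10L, rate = 10,
                             terminal = TRUE,
                             motifs = c("TC", "GA", "GT"),
                             orientations = c("parallel", "antiparallel"),
                             both_strands = TRUE) {
  r <- strsplit(rna, "", fixed = TRUE)[[1]]
  m <- nchar(dna)
  rows <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (strand in strands) {
    P <- strsplit(if (strand == "+") dna else oracle_revcomp(dna),
                  "", fixed = TRUE)[[1]]
    for (orient in orientations) {
      B <- if (orient == "parallel") P else rev(P)
      for (motif in motifs) {
        if (!orient %in% oracle_rules[[motif]]$orient) next
        w <- oracle_windows_aligned(r, B, oracle_rules[[motif]]$ok,
                                    min_length, rate, terminal)
        if (nrow(w) == 0) next
        jP <- if (orient == "parallel") w$jB else m - w$jB - w$L
        dna_start <- if (strand == "+") jP else m - jP - w$L
        rows[[length(rows) + 1L]] <-
          data.frame(rna_start = w$i, rna_end = w$i + w$L,
                     dna_start = dna_start, dna_end = dna_start + w$L,
                     dna_strand = strand, orientation = orient,
                     motif = motif, n_errors = w$n_errors,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(rna_start = integer(0), rna_end = integer(0),
                      dna_start = integer(0), dna_end = integer(0),
                      dna_strand = character(0), orientation = character(0),
                      motifs = character(0), n_errors = integer(0),
                      stringsAsFactors = FALSE))
  all_rows <- do.call(rbind, rows)
  # deduplicate on (rna interval, dna interval, strand, orientation),
  # unioning motifs (in TC < GA < GT order) and taking the minimum
  # error count
  key <- paste(all_rows$rna_start, all_rows$rna_end, all_rows$dna_start,
               all_rows$dna_end, all_rows$dna_strand,
               all_rows$orientation)
  parts <- split(all_rows, key)
  dedup <- do.call(rbind, lapply(parts, function(g) {
    g1 <- g[1, , drop = FALSE]
    g1$motif <- paste(intersect(c("TC", "GA", "GT"), g$motif),
                      collapse = ",")
    g1$n_errors <- min(g$n_errors)
    g1
  }))
  names(dedup)[names(dedup) == "motif"] <- "motifs"
  dedup <- dedup[order(dedup$rna_start, dedup$rna_end, dedup$dna_start,
                       dedup$dna_end, dedup$dna_strand,
                       dedup$orientation), , drop = FALSE]
  rownames(dedup) <- NULL
  dedup
}

oracle_count <- function(...) nrow(oracle_enumerate(...))

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
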