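#' @useDynLib triplexhub, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef ppois runif aggregate setNames
#' @importFrom utils read.table write.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")
RNA_ALPHABET <- c("A", "C", "G", "U")

#' Validate and normalise nucleic-acid sequences
#'
#' Sequences are handled throughout the package as named character
#' vectors of upper-case residues. DNA records always denote the forward
#' strand of the duplex; the reverse strand is derived on demand and
#' never stored. `T`/`U` are interconverted to match `kind`.
#'
#' Ambiguous residues (IUPAC codes, `N`, ...) are either rejected
#' (`ambiguous = "error"`, the default, mirroring the removal of regions
#' containing `N`) or hard-masked to `"N"` (`ambiguous = "mask"`), a
#' character that can never satisfy any pairing rule and therefore counts
#' as an unconditional mismatch in every downstream computation.
#'
#' @param x character vector of sequences (optionally named).
#' @param kind `"DNA"` or `"RNA"`.
#' @param ambiguous policy for residues outside the 4-letter alphabet.
#' @return named character vector of validated sequences.
#' @export
as_nucleic <- function(x, kind = c("DNA", "RNA"),
                       ambiguous = c("error", "mask")) {
  kind <- match.arg(kind)
  ambiguous <- match.arg(ambiguous)
  if (length(x) == 0) stop("no sequences supplied")
  nm <- names(x)
  x <- toupper(as.character(x))
  x <- if (kind == "DNA") gsub("U", "T", x, fixed = TRUE)
       else gsub("T", "U", x, fixed = TRUE)
  names(x) <- nm
  alphabet <- if (kind == "DNA") DNA_ALPHABET else RNA_ALPHABET
  bad_re <- paste0("[^", paste(alphabet, collapse = ""), "]")
  for (i in seq_along(x)) {
    if (!nzchar(x[[i]]))
      stop("empty sequence in record ", i,
           if (!is.null(names(x))) paste0(" ('", names(x)[i], "')") else "")
    hit <- regexpr(bad_re, x[[i]])
    if (hit > 0) {
      if (ambiguous == "error")
        stop("disallowed character '", substr(x[[i]], hit, hit),
             "' in record ",
             if (!is.null(names(x))) paste0("'", names(x)[i], "'")
             else i,
             " at position ", as.integer(hit))
      x[[i]] <- gsub(bad_re, "N", x[[i]])
    }
  }
  x
}

#' Read sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @inheritParams as_nucleic
#' @return named character vector, case-folded to upper case with `T`/`U`
#'   normalised to the declared `kind`.
#' @export
read_fasta <- function(path, kind = c("DNA", "RNA"),
                       ambiguous = c("error", "mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e)))
  if (length(set) == 0) stop("no FASTA records in ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  as_nucleic(seqs, kind = kind, ambiguous = ambiguous)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read genomic regions from a BED file
#'
#' Coordinates are kept 0-based half-open (the BED convention), the
#' single coordinate convention used everywhere in this package; region
#' length is always `end - start`.
#'
#' @param path path to a tab-separated BED file with at least 3 columns.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`
#'   (name is `NA` for 3-column input); extra columns are ignored.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "",
                   quote = "", colClasses = "character")
  if (ncol(df) < 3) stop("BED file must have >= 3 tab-separated columns")
  start <- suppressWarnings(as.numeric(df[[2]]))
  end <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(start) || anyNA(end) ||
      any(start != floor(start)) || any(end != floor(end)))
    stop("non-integer coordinate in BED file ", path)
  regions <- data.frame(chrom = df[[1]],
                        start = as.integer(start),
                        end = as.integer(end),
                        name = if (ncol(df) >= 4) df[[4]] else NA_character_,
                        stringsAsFactors = FALSE)
  validate_regions(regions)
  regions
}

validate_regions <- function(regions) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end") %in% names(regions)))
  if (any(regions$start < 0)) stop("negative start coordinate")
  bad <- which(regions$start >= regions$end)
  if (length(bad))
    stop("start >= end for region ", bad[1], " (", regions$chrom[bad[1]],
         ":", regions$start[bad[1]], "-", regions$end[bad[1]], ")")
  invisible(regions)
}

#' Write genomic regions to a BED file
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand` columns.
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  validate_regions(regions)
  cols <- c("chrom", "start", "end")
  for (extra in c("name", "score", "strand")) {
    if (extra %in% names(regions)) cols <- c(cols, extra)
    else break
  }
  write.table(regions[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract forward-strand sequences for genomic regions
#'
#' @param genome named character vector of chromosome sequences (DNA).
#' @param regions data.frame as returned by [read_bed()].
#' @return named character vector of forward-strand subsequences, one per
#'   region, each of length `end - start`. Names come from the region
#'   `name` column when present, else `chrom:start-end`.
#' @export
extract_region_sequence <- function(genome, regions) {
  validate_regions(regions)
  out <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    if (!chrom %in% names(genome))
      stop("unknown chromosome '", chrom, "'")
    len <- nchar(genome[[chrom]])
    if (regions$end[i] > len)
      stop("region ", chrom, ":", regions$start[i], "-", regions$end[i],
           " out of bounds (chromosome length ", len, ")")
    out[i] <- substr(genome[[chrom]], regions$start[i] + 1L, regions$end[i])
  }
  names(out) <- region_names(regions)
  out
}

region_names <- function(regions) {
  nm <- regions$name
  if (is.null(nm)) nm <- rep(NA_character_, nrow(regions))
  fallback <- paste0(regions$chrom, ":", regions$start, "-", regions$end)
  ifelse(is.na(nm) | !nzchar(nm), fallback, nm)
}

#' Reverse complement of DNA sequences
#'
#' @param x character vector of forward-strand DNA sequences (may contain
#'   the mask character `N`, which is complemented to itself).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}
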