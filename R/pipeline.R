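#' Score every RNA-region pair against the Poisson null
#'
#' For each pair of panel RNA and DNA region: counts qualifying triplex
#' windows with [count_triplexes()], evaluates the expected count from
#' the calibration model at the pair's lengths, converts the observed
#' count to a Poisson upper-tail p-value and applies the Bonferroni
#' adjustment within the configured family. With
#' `adjust_family = "per-rna"` (default) each RNA's scan over all regions
#' is one family (`m` = number of regions); `"global"` uses all
#' RNA x region tests as a single family.
#'
#' @param rnas named character vector of panel RNA sequences.
#' @param region_seqs named character vector of forward-strand region
#'   sequences (from FASTA, or [extract_region_sequence()] on BED +
#'   genome; both routes give identical results).
#' @param model a `"calibration_model"` (default:
#'   [reference_calibration()]).
#' @param params an [engine_params()] object.
#' @param alpha significance level on the adjusted p-value (strict `<`).
#' @param adjust_family `"per-rna"` or `"global"`.
#' @return data.frame with one row per RNA x region pair: `rna_id`,
#'   `region`, `L_RNA`, `L_DNA`, `n_tpx`, `lambda`, `p`, `adj_p`,
#'   `significant`.
#' @export
scan_matrix <- function(rnas, region_seqs,
                        model = reference_calibration(),
                        params = engine_params(),
                        alpha = 0.01,
                        adjust_family = c("per-rna", "global")) {
  adjust_family <- match.arg(adjust_family)
  if (length(rnas) == 0) stop("empty RNA panel")
  if (length(region_seqs) == 0) stop("empty region set")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (is.null(names(rnas))) names(rnas) <- paste0("rna", seq_along(rnas))
  if (is.null(names(region_seqs)))
    names(region_seqs) <- paste0("region", seq_along(region_seqs))
  if (anyDuplicated(names(rnas)) || anyDuplicated(names(region_seqs)))
    stop("RNA and region names must be unique")

  res <- expand.grid(rna_id = names(rnas), region = names(region_seqs),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$L_RNA <- nchar(rnas)[res$rna_id]
  res$L_DNA <- nchar(region_seqs)[res$region]
  res$n_tpx <- mapply(function(r, d)
    count_triplexes(rnas[[r]], region_seqs[[d]], params),
    res$rna_id, res$region, USE.NAMES = FALSE)
  res$lambda <- expected_lambda(model, res$L_RNA, res$L_DNA)
  res$p <- triplex_pvalue(res$n_tpx, res$lambda)
  m <- if (adjust_family == "per-rna") length(region_seqs)
       else length(rnas) * length(region_seqs)
  res$adj_p <- bonferroni_adjust(res$p, m)
  res$significant <- res$adj_p < alpha
  res
}

check_complete_panel <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("rna_id", "region", "significant") %in% names(results)))
  if (nrow(results) == 0) stop("empty result set")
  tab <- table(results$region, results$rna_id)
  if (any(tab != 1))
    stop("every region must be tested against the same RNA panel ",
         "exactly once")
  invisible(results)
}

#' Call universal triplex target sites
#'
#' A region is a universal TTS when the fraction of the RNA panel with a
#' significant (Bonferroni-adjusted p < alpha) triplex count strictly
#' exceeds `universal_fraction` ("more than 90% of the transcripts"
#' under the default 0.9).
#'
#' @param results data.frame from [scan_matrix()].
#' @param universal_fraction fraction threshold (strict `>`).
#' @return data.frame with one row per region: `region`,
#'   `n_rnas_tested`, `n_significant`, `fraction`, `is_universal`.
#' @export
classify_universal <- function(results, universal_fraction = 0.9) {
  check_complete_panel(results)
  agg <- aggregate(significant ~ region, data = results,
                   FUN = function(z) c(n = length(z), k = sum(z)))
  out <- data.frame(region = agg$region,
                    n_rnas_tested = agg$significant[, "n"],
                    n_significant = agg$significant[, "k"],
                    stringsAsFactors = FALSE)
  out$fraction <- out$n_significant / out$n_rnas_tested
  out$is_universal <- out$fraction > universal_fraction
  out <- out[order(out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-RNA significance summary
#'
#' @param results data.frame from [scan_matrix()].
#' @return data.frame with one row per RNA: `rna_id`, `n_regions`,
#'   `n_significant`, `fraction`.
#' @export
summarize_per_rna <- function(results) {
  if (nrow(results) == 0) stop("empty result set")
  agg <- aggregate(significant ~ rna_id, data = results,
                   FUN = function(z) c(n = length(z), k = sum(z)))
  out <- data.frame(rna_id = agg$rna_id,
                    n_regions = agg$significant[, "n"],
                    n_significant = agg$significant[, "k"],
                    stringsAsFactors = FALSE)
  out$fraction <- out$n_significant / out$n_regions
  out <- out[order(out$rna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significance matrix of -log10 adjusted p-values
#'
#' Numeric export of the interaction landscape: regions as rows, RNAs as
#' columns, entries `-log10(adj_p)` (0 where `adj_p = 1`, including
#' pairs with no predicted triplexes).
#'
#' @param results data.frame from [scan_matrix()] covering the complete
#'   RNA x region grid.
#' @return numeric matrix with region row names and RNA column names.
#' @export
export_matrix <- function(results) {
  check_complete_panel(results)
  regions <- sort(unique(results$region))
  rnas <- sort(unique(results$rna_id))
  mat <- matrix(NA_real_, length(regions), length(rnas),
                dimnames = list(regions, rnas))
  mat[cbind(match(results$region, regions),
            match(results$rna_id, rnas))] <- -log10(results$adj_p)
  mat
}

#' Write a matrix as TSV with a header row and row-name column
#'
#' @param mat matrix from [export_matrix()].
#' @param path output path.
#' @param rowname_header header of the row-name column.
#' @export
write_matrix_tsv <- function(mat, path, rowname_header = "region") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- rowname_header
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full universal-TTS analysis
#'
#' Convenience wrapper: [scan_matrix()] then [classify_universal()] and
#' [summarize_per_rna()], optionally writing `interactions.tsv`,
#' `universal_calls.tsv`, `per_rna_summary.tsv`, `matrix.tsv` and
#' `universal.bed` (when region coordinates are supplied) to `out_dir`.
#'
#' @inheritParams scan_matrix
#' @param universal_fraction fraction threshold for universal calls.
#' @param regions optional data.frame of region coordinates (as from
#'   [read_bed()]) whose names match `region_seqs`.
#' @param out_dir optional output directory.
#' @return list with elements `interactions`, `universal`, `per_rna`,
#'   `matrix`.
#' @export
run_universal_pipeline <- function(rnas, region_seqs,
                                   model = reference_calibration(),
                                   params = engine_params(),
                                   alpha = 0.01,
                                   universal_fraction = 0.9,
                                   adjust_family = c("per-rna", "global"),
                                   regions = NULL, out_dir = NULL) {
  interactions <- scan_matrix(rnas, region_seqs, model = model,
                              params = params, alpha = alpha,
                              adjust_family = adjust_family)
  universal <- classify_universal(interactions, universal_fraction)
  per_rna <- summarize_per_rna(interactions)
  mat <- export_matrix(interactions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(interactions, file.path(out_dir, "interactions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(universal, file.path(out_dir, "universal_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(per_rna, file.path(out_dir, "per_rna_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(mat, file.path(out_dir, "matrix.tsv"))
    if (!is.null(regions)) {
      called <- universal$region[universal$is_universal]
      bed <- regions[region_names(regions) %in% called, , drop = FALSE]
      if (nrow(bed))
        write_bed(bed, file.path(out_dir, "universal.bed"))
    }
  }
  list(interactions = interactions, universal = universal,
       per_rna = per_rna, matrix = mat)
}
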