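#' Calibration model for the expected triplex count
#'
#' The expected number of qualifying triplex windows between random
#' sequences grows approximately linearly with both sequence lengths and
#' is modelled as
#' \deqn{\lambda(L_{RNA}, L_{DNA}) = \theta_0 + \theta_1 L_{RNA} +
#'   \theta_2 L_{DNA}}
#' For short inputs the fitted plane can dip below zero; predictions are
#' clamped at `lambda_floor` because the Poisson null requires a positive
#' mean.
#'
#' @param theta0,theta1,theta2 regression coefficients.
#' @param lambda_floor positive lower bound applied to predictions.
#' @param adj_r2 adjusted R-squared of the fit, or `NA`.
#' @param provenance `"reference"` for the shipped coefficients,
#'   `"refit"` for a model fitted with [fit_lambda_model()].
#' @return object of class `"calibration_model"`.
#' @export
calibration_model <- function(theta0, theta1, theta2,
                              lambda_floor = 1e-3, adj_r2 = NA_real_,
                              provenance = c("refit", "reference")) {
  provenance <- match.arg(provenance)
  if (!is.finite(lambda_floor) || lambda_floor <= 0)
    stop("lambda_floor must be > 0")
  structure(list(theta0 = theta0, theta1 = theta1, theta2 = theta2,
                 lambda_floor = lambda_floor, adj_r2 = adj_r2,
                 provenance = provenance),
            class = "calibration_model")
}

#' Reference calibration model
#'
#' The shipped reference coefficients for the standard search
#' configuration (minimum length 10, 10% error rate, all motifs, both
#' orientations), calibrated on uniform-composition random sequences:
#' theta0 = -0.688, theta1 = 5.37e-4, theta2 = 6.03e-4. This model is
#' the default scoring model of the pipeline; refitting against the
#' bundled engine via [simulate_lambda_grid()] + [fit_lambda_model()] is
#' an explicit user action.
#'
#' @param lambda_floor positive lower bound applied to predictions.
#' @return a `"calibration_model"`.
#' @export
reference_calibration <- function(lambda_floor = 1e-3) {
  calibration_model(-0.688, 5.37e-4, 6.03e-4,
                    lambda_floor = lambda_floor,
                    provenance = "reference")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Triplex count calibration model (", x$provenance, ")\n", sep = "")
  cat(sprintf("  lambda = %.4g + %.4g * L_RNA + %.4g * L_DNA\n",
              x$theta0, x$theta1, x$theta2))
  cat(sprintf("  lambda_floor = %g, adj. R^2 = %s\n", x$lambda_floor,
              if (is.na(x$adj_r2)) "NA" else sprintf("%.3f", x$adj_r2)))
  invisible(x)
}

random_seq <- function(length, alphabet, prob = NULL) {
  paste(sample(alphabet, length, replace = TRUE, prob = prob),
        collapse = "")
}

#' Simulate the expected-count grid on random sequences
#'
#' For each cell of the `rna_lengths` x `dna_lengths` grid, generates
#' `reps_per_side` random RNA and `reps_per_side` random DNA sequences
#' with equal frequencies of the four nucleotides, counts qualifying
#' triplex windows for all `reps_per_side^2` pairs and records the mean
#' count. The full-scale calibration uses RNA lengths
#' {500, 1000, 1500, 2000}, DNA lengths {200, 400, ..., 2000} and 100
#' sequences per side (10000 pairs per cell).
#'
#' @param params an [engine_params()] object.
#' @param rna_lengths,dna_lengths integer vectors of sequence lengths.
#' @param reps_per_side number of random sequences generated per side of
#'   each cell.
#' @param seed integer seed; the grid is fully reproducible from it.
#' @return data.frame with one row per cell: `L_RNA`, `L_DNA`, `n_pairs`,
#'   `mean_count`.
#' @export
simulate_lambda_grid <- function(params = engine_params(),
                                 rna_lengths = c(500, 1000, 1500, 2000),
                                 dna_lengths = seq(200, 2000, by = 200),
                                 reps_per_side = 100L,
                                 seed = 1L) {
  rna_lengths <- as.integer(rna_lengths)
  dna_lengths <- as.integer(dna_lengths)
  if (any(c(rna_lengths, dna_lengths) < params$min_length))
    stop("all lengths must be >= min_length")
  reps_per_side <- as.integer(reps_per_side)
  if (reps_per_side < 1L) stop("reps_per_side must be >= 1")
  set.seed(seed)
  grid <- expand.grid(L_RNA = rna_lengths, L_DNA = dna_lengths,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$L_RNA, grid$L_DNA), , drop = FALSE]
  rownames(grid) <- NULL
  grid$n_pairs <- reps_per_side^2
  grid$mean_count <- NA_real_
  for (cell in seq_len(nrow(grid))) {
    rnas <- replicate(reps_per_side,
                      random_seq(grid$L_RNA[cell], RNA_ALPHABET))
    dnas <- replicate(reps_per_side,
                      random_seq(grid$L_DNA[cell], DNA_ALPHABET))
    counts <- vapply(rnas, function(r)
      vapply(dnas, function(d) count_triplexes(r, d, params),
             numeric(1)), numeric(reps_per_side))
    grid$mean_count[cell] <- mean(counts)
  }
  grid
}

#' Fit the linear expected-count model to a simulated grid
#'
#' Ordinary least squares of the per-cell mean count on the two sequence
#' lengths, with intercept.
#'
#' @param grid data.frame from [simulate_lambda_grid()] (columns `L_RNA`,
#'   `L_DNA`, `mean_count`).
#' @param lambda_floor positive lower bound stored in the model.
#' @return a `"calibration_model"` with `provenance = "refit"` and the
#'   adjusted R-squared of the fit.
#' @export
fit_lambda_model <- function(grid, lambda_floor = 1e-3) {
  stopifnot(is.data.frame(grid),
            all(c("L_RNA", "L_DNA", "mean_count") %in% names(grid)))
  if (nrow(grid) < 3 ||
      length(unique(grid$L_RNA)) < 2 || length(unique(grid$L_DNA)) < 2)
    stop("underdetermined fit: need >= 3 cells spanning >= 2 distinct ",
         "values in each length dimension")
  fit <- lm(mean_count ~ L_RNA + L_DNA, data = grid)
  th <- coef(fit)
  calibration_model(unname(th[1]), unname(th[2]), unname(th[3]),
                    lambda_floor = lambda_floor,
                    adj_r2 = summary(fit)$adj.r.squared,
                    provenance = "refit")
}

#' Expected triplex count for given sequence lengths
#'
#' Evaluates the linear calibration model; predictions at or below zero
#' are clamped to `model$lambda_floor` with a warning, since the Poisson
#' null is undefined for a non-positive mean. Clamping can occur for
#' short inputs (e.g. L_RNA = 500, L_DNA = 200 under the reference
#' model, where the raw prediction is -0.2989).
#'
#' @param model a `"calibration_model"`.
#' @param L_RNA,L_DNA sequence lengths (vectors recycle).
#' @return numeric vector of positive expected counts.
#' @export
expected_lambda <- function(model, L_RNA, L_DNA) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(L_RNA < 1) || any(L_DNA < 1)) stop("lengths must be >= 1")
  lam <- model$theta0 + model$theta1 * L_RNA + model$theta2 * L_DNA
  clamped <- lam <= 0
  if (any(clamped)) {
    warning(sum(clamped), " expected count(s) <= 0 clamped to ",
            "lambda_floor = ", model$lambda_floor,
            " (short input lengths)")
    lam[clamped] <- model$lambda_floor
  }
  pmax(lam, model$lambda_floor)
}

#' Poisson upper-tail p-value of an observed triplex count
#'
#' `P(X >= n_tpx | X ~ Pois(lambda))`, the exact upper tail; `p = 1`
#' when `n_tpx = 0`.
#'
#' @param n_tpx observed window count(s), non-negative.
#' @param lambda positive Poisson mean(s); callers must clamp
#'   non-positive expected counts first (see [expected_lambda()]).
#' @return p-values in (0, 1].
#' @export
triplex_pvalue <- function(n_tpx, lambda) {
  if (any(n_tpx < 0) || any(n_tpx != floor(n_tpx)))
    stop("n_tpx must be a non-negative integer")
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("lambda must be > 0 (clamp with expected_lambda first)")
  ppois(n_tpx - 1, lambda, lower.tail = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p p-value(s) in (0, 1]; exact zeros are tolerated because deep
#'   Poisson tails underflow double precision.
#' @param m family size, integer >= 1.
#' @return `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m) {
  if (length(m) != 1 || is.na(m) || m < 1 || m != floor(m))
    stop("m must be a single integer >= 1")
  if (any(p < 0) || any(p > 1)) stop("p must be in (0, 1]")
  pmin(1, m * p)
}
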