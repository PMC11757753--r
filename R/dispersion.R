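#' Wave-number grid for dispersion relations
#'
#' Linear grid from 0 to `k_max` in steps of `step`; the protocol default
#' is `k_max = 10`, `step = 0.01`. Surveys use a coarser `step = 0.05` by
#' default (see [run_size_variance_heatmap()]); class assignments are
#' insensitive to this refinement (tested).
#'
#' @param k_max Largest wave number scanned.
#' @param step Grid step \eqn{\Delta k}.
#' @return Numeric vector of wave numbers including 0.
#' @export
k_grid <- function(k_max = 10, step = 0.01) {
  if (k_max <= 0 || step <= 0) stop("k_max and step must be positive",
                                    call. = FALSE)
  n <- round(k_max / step)
  if (abs(n * step - k_max) > 1e-8 * k_max)
    stop("`step` must divide `k_max`", call. = FALSE)
  seq(0, k_max, length.out = n + 1L)
}

#' Jacobian of the wave-like perturbation, J(k) = J0 - k^2 D
#'
#' @param j0 Square reaction Jacobian \eqn{J_0}.
#' @param diff A [diffusion_spec()]; only nodes 1 and 2 diffuse.
#' @param k Nonnegative wave number.
#' @return The matrix \eqn{J_0 - k^2 D}.
#' @examples
#' jacobian_at_k(matrix(c(-1, -2, 2, -1), 2), diffusion_spec(1, 10), 1)
#' @export
jacobian_at_k <- function(j0, diff, k) {
  if (!is.matrix(j0) || nrow(j0) != ncol(j0))
    stop("`j0` must be a square matrix", call. = FALSE)
  if (k < 0) stop("`k` must be nonnegative", call. = FALSE)
  d <- diffusion_vector(diff, nrow(j0))
  jk <- j0
  diag(jk) <- diag(jk) - k^2 * d
  jk
}

#' Dispersion relation of a reaction-diffusion Jacobian
#'
#' Diagonalizes \eqn{J(k) = J_0 - k^2 D} over the wave-number grid and
#' records the leading eigenvalue: `lead_real` is the maximal real part
#' \eqn{Re\,\lambda_{max}(k)} and `lead_imag` the imaginary part of an
#' eigenvalue attaining it (ties resolved towards the largest `|Im|`, so
#' oscillatory pairs are never hidden).
#'
#' @inheritParams jacobian_at_k
#' @param grid Wave-number grid from [k_grid()].
#' @param classify If `TRUE` (default) also attach the instability class.
#' @return An object of class `"dispersion_result"`: a list with
#'   `k_values`, `lead_real`, `lead_imag`, `k_peak` (argmax of `lead_real`
#'   over k > 0) and `klass` (one of `stable`,
#'   `unstable_without_diffusion`, `turing_I`, `turing_II`, `turing_hopf`,
#'   or `NA` when `classify = FALSE`).
#' @examples
#' set.seed(4)
#' j0 <- sample_jacobian(ensemble_spec(10, sigma2 = 0.25))
#' dispersion_relation(j0, diffusion_spec(1, 10))
#' @export
dispersion_relation <- function(j0, diff, grid = k_grid(), classify = TRUE) {
  if (!is.matrix(j0) || nrow(j0) != ncol(j0))
    stop("`j0` must be a square matrix", call. = FALSE)
  d <- diffusion_vector(diff, nrow(j0))
  sweep <- dispersion_sweep_cpp(j0, d, grid)
  res <- structure(
    list(k_values = grid,
         lead_real = as.numeric(sweep$lead_real),
         lead_imag = as.numeric(sweep$lead_imag),
         k_peak = grid[-1L][which.max(sweep$lead_real[-1L])],
         klass = NA_character_),
    class = "dispersion_result")
  if (classify) res$klass <- classify(res)
  res
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Dispersion relation over k in [",
      format(min(x$k_values)), ", ", format(max(x$k_values)), "], ",
      length(x$k_values), " points\n", sep = "")
  cat(sprintf("  Re lambda_max: %.4g at k=0; peak %.4g at k=%.3g; %.4g at k_max\n",
              x$lead_real[1L], max(x$lead_real[-1L]), x$k_peak,
              x$lead_real[length(x$lead_real)]))
  cat("  class:", if (is.na(x$klass)) "(unclassified)" else x$klass, "\n")
  invisible(x)
}

# Numeric summary (same five quantities the C++ batch code returns) from
# full curves; kept as the single R-side reduction used by classify().
summarize_dispersion <- function(result) {
  re <- result$lead_real
  im <- result$lead_imag
  ipk <- which.max(re[-1L]) + 1L
  c(re0 = re[1L], peak_re = re[ipk], im_peak = im[ipk],
    re_kmax = re[length(re)], k_peak = result$k_values[ipk])
}

#' Classify a dispersion relation
#'
#' Implements the simplified classification scheme: a sample must be
#' stable without diffusion (\eqn{Re\,\lambda_{max}(0) < 0}) to qualify as
#' diffusion-driven. Among diffusion-driven instabilities, a complex
#' leading eigenvalue at the most unstable wave number gives Turing-Hopf;
#' otherwise a positive real part surviving at `k_max` gives Turing II,
#' and an interior peak that restabilizes gives Turing I (the class with a
#' well-defined pattern wavelength).
#'
#' @param result A `"dispersion_result"` from [dispersion_relation()].
#' @param tol_imag Threshold on `|Im|` of the peak eigenvalue for the Hopf
#'   test. Complex pairs of real matrices are exact conjugates, so the
#'   imaginary part is either 0 or order 1; 1e-9 separates the two.
#' @return A single string, one of
#'   `c("stable", "unstable_without_diffusion", "turing_I", "turing_II",
#'   "turing_hopf")`.
#' @export
classify <- function(result, tol_imag = 1e-9) {
  stopifnot(inherits(result, "dispersion_result"))
  if (!length(result$lead_real) || anyNA(result$lead_real))
    stop("dispersion curves contain missing values; flagged sample",
         call. = FALSE)
  s <- summarize_dispersion(result)
  classify_summary(rbind(s), tol_imag = tol_imag)
}

# Vectorized classification from an n x 5 summary matrix
# (re0, peak_re, im_peak, re_kmax, k_peak). Early-exited rows (NaN past
# col 1) are only ever unstable at k = 0, which needs col 1 alone.
classify_summary <- function(summary, tol_imag = 1e-9) {
  re0 <- summary[, 1L]
  peak <- summary[, 2L]
  im <- summary[, 3L]
  rkm <- summary[, 4L]
  out <- character(nrow(summary))
  unst <- re0 >= 0
  out[unst] <- "unstable_without_diffusion"
  out[!unst & peak <= 0] <- "stable"
  dd <- !unst & peak > 0          # diffusion-driven instability
  out[dd & abs(im) > tol_imag] <- "turing_hopf"
  out[dd & abs(im) <= tol_imag & rkm > 0] <- "turing_II"
  out[dd & abs(im) <= tol_imag & rkm <= 0] <- "turing_I"
  out
}

#' Classify a batch of reaction Jacobians
#'
#' Batch version of [dispersion_relation()] + [classify()]: computes the
#' dispersion summary of every matrix in compiled code (skipping the k
#' sweep for matrices already unstable at k = 0) and classifies each.
#'
#' @param jmats `N x N x n` array of reaction Jacobians.
#' @param diff A [diffusion_spec()].
#' @param grid Wave-number grid.
#' @param tol_imag Hopf tolerance passed to the classifier.
#' @return Character vector of instability classes, length `n`.
#' @export
classify_jacobians <- function(jmats, diff, grid = k_grid(step = 0.05),
                               tol_imag = 1e-9) {
  stopifnot(length(dim(jmats)) == 3L, dim(jmats)[1L] == dim(jmats)[2L])
  d <- diffusion_vector(diff, dim(jmats)[1L])
  s <- dispersion_summary_cpp(jmats, d, grid)
  classify_summary(s, tol_imag = tol_imag)
}

#' Export a dispersion relation as CSV
#'
#' Two data columns (`k`, `lead_real`) plus `lead_imag` and the class
#' label repeated per row.
#'
#' @param result A `"dispersion_result"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dispersion_csv <- function(result, path) {
  stopifnot(inherits(result, "dispersion_result"))
  df <- data.frame(k = result$k_values, lead_real = result$lead_real,
                   lead_imag = result$lead_imag, class = result$klass)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
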