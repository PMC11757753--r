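#' Beta-distribution fits of Jacobian-element samples
#'
#' Jacobian elements are unbounded, so a sample is first mapped affinely
#' onto the unit interval using the support `[min - eps, max + eps]` with
#' `eps = 1e-6 * range`; the mapping is stored in the fit so fits on
#' different elements remain comparable. `fit_moments()` matches the
#' mapped sample mean `m` and variance `v`:
#' `alpha = m (m(1-m)/v - 1)`, `beta = (1-m) (m(1-m)/v - 1)`.
#' `fit_mle()` then maximizes the beta log-likelihood starting from the
#' moments fit.
#'
#' @param sample Numeric sample (length >= 2, nondegenerate variance),
#'   either raw (mapped internally) or already inside (0, 1) if
#'   `support` is given.
#' @param support Optional `c(lo, hi)` affine support; default derives it
#'   from the sample as above.
#' @return An object of class `"beta_fit"`: list with `alpha`, `beta`,
#'   `support_lo`, `support_hi`, `log_likelihood` (on the mapped scale),
#'   `method` (`"moments"` or `"mle"`), `n`, and `degraded` (TRUE when
#'   the MLE optimizer failed and the moments fit was returned).
#' @examples
#' set.seed(1)
#' x <- rbeta(5000, 2, 5)
#' fit_mle(x, support = c(0, 1))
#' @export
fit_moments <- function(sample, support = NULL) {
  prep <- map_to_unit(sample, support)
  m <- mean(prep$u)
  v <- var(prep$u)
  if (v <= 0) stop("sample variance is degenerate", call. = FALSE)
  if (v >= m * (1 - m))
    stop("no beta distribution matches these moments (v >= m(1-m))",
         call. = FALSE)
  common <- m * (1 - m) / v - 1
  new_beta_fit(m * common, (1 - m) * common, prep$lo, prep$hi, prep$u,
               method = "moments")
}

#' @rdname fit_moments
#' @param init Optional `"beta_fit"` used as the optimizer start; default
#'   is the moments fit of the same sample.
#' @export
fit_mle <- function(sample, init = NULL, support = NULL) {
  if (is.null(init)) init <- fit_moments(sample, support)
  stopifnot(inherits(init, "beta_fit"))
  prep <- map_to_unit(sample, c(init$support_lo, init$support_hi))
  negll <- function(par) -sum(dbeta(prep$u, exp(par[1L]), exp(par[2L]),
                                    log = TRUE))
  opt <- tryCatch(
    optim(log(c(init$alpha, init$beta)), negll, method = "BFGS"),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) {
    out <- init
    out$degraded <- TRUE
    return(out)
  }
  fit <- new_beta_fit(exp(opt$par[1L]), exp(opt$par[2L]), prep$lo, prep$hi,
                      prep$u, method = "mle")
  # the optimum can never undercut its own starting point
  if (fit$log_likelihood < init$log_likelihood) {
    out <- init
    out$degraded <- TRUE
    return(out)
  }
  fit
}

map_to_unit <- function(sample, support = NULL) {
  if (length(sample) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (is.null(support)) {
    r <- range(sample)
    eps <- 1e-6 * (r[2L] - r[1L])
    if (eps <= 0) stop("sample is constant; no support mapping exists",
                       call. = FALSE)
    support <- c(r[1L] - eps, r[2L] + eps)
  }
  if (support[1L] >= support[2L]) stop("invalid support", call. = FALSE)
  u <- (sample - support[1L]) / (support[2L] - support[1L])
  if (any(u <= 0 | u >= 1))
    stop("mapped data must lie strictly inside (0, 1)", call. = FALSE)
  list(u = u, lo = support[1L], hi = support[2L])
}

new_beta_fit <- function(alpha, beta, lo, hi, u, method) {
  structure(
    list(alpha = alpha, beta = beta, support_lo = lo, support_hi = hi,
         log_likelihood = sum(dbeta(u, alpha, beta, log = TRUE)),
         method = method, n = length(u), degraded = FALSE),
    class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("Beta fit (%s%s): alpha = %.4g, beta = %.4g\n", x$method,
              if (x$degraded) ", degraded" else "", x$alpha, x$beta))
  cat(sprintf("  support [%.4g, %.4g], logLik %.4g, n = %d\n",
              x$support_lo, x$support_hi, x$log_likelihood, x$n))
  invisible(x)
}

#' Per-element summaries of screened Jacobian records
#'
#' Groups a screen's element records by matrix position and instability
#' class (Turing I versus everything that is not Turing I) and reports
#' sample mean, variance and count per group, plus the distribution of
#' the per-steady-state sum of off-diagonal elements with its skewness
#' and excess kurtosis (the central-limit diagnostic across network
#' sizes). Because Hill-model Jacobian elements are heavy-tailed (their
#' magnitude scales like `n V / (4 K)` with loguniform `V`, `K`), the raw
#' moment skewness of the sums is dominated by a handful of extreme
#' records; a trimmed skewness over the central 99% of the sample is
#' reported alongside it as the stable bulk-shape statistic.
#'
#' @param records Data frame with columns `set_id`, `state_id`, `i`, `j`,
#'   `value`, `class` (as produced by [screen_models()]).
#' @param non_turing One of `"all_other"` (every non-Turing-I record) or
#'   `"stable_only"` (drop systems unstable without diffusion from the
#'   non-Turing pool before summarizing).
#' @return List with `elements` (per-(i, j, group) data frame) and `sums`
#'   (per-group data frame of n, mean, variance, skewness, excess
#'   kurtosis of the off-diagonal sums).
#' @export
element_summary <- function(records, non_turing = c("all_other",
                                                    "stable_only")) {
  non_turing <- match.arg(non_turing)
  stopifnot(all(c("set_id", "state_id", "i", "j", "value", "class") %in%
                  names(records)))
  records$group <- ifelse(records$class == "turing_I", "turing_I",
                          "non_turing")
  if (non_turing == "stable_only")
    records <- records[records$group == "turing_I" |
                         records$class != "unstable_without_diffusion", ]
  if (!nrow(records))
    return(list(elements = data.frame(), sums = data.frame()))
  el <- do.call(rbind, lapply(
    split(records, interaction(records$i, records$j, records$group,
                               drop = TRUE)),
    function(d) data.frame(i = d$i[1L], j = d$j[1L], group = d$group[1L],
                           n = nrow(d), mean = mean(d$value),
                           variance = if (nrow(d) > 1L) var(d$value)
                                      else NA_real_)))
  rownames(el) <- NULL
  off <- records[records$i != records$j, ]
  sums <- do.call(rbind, lapply(split(off, off$group), function(d) {
    s <- tapply(d$value, interaction(d$set_id, d$state_id, drop = TRUE), sum)
    s <- as.numeric(s)
    trim <- if (length(s) > 10L) {
      q <- stats::quantile(s, c(0.005, 0.995))
      s[s >= q[1L] & s <= q[2L]]
    } else s
    data.frame(group = d$group[1L], n = length(s), mean = mean(s),
               variance = if (length(s) > 1L) var(s) else NA_real_,
               skewness = if (length(s) > 2L) e1071::skewness(s) else NA_real_,
               skewness_trimmed = if (length(trim) > 2L)
                 e1071::skewness(trim) else NA_real_,
               excess_kurtosis = if (length(s) > 3L) e1071::kurtosis(s)
                                 else NA_real_)
  }))
  rownames(sums) <- NULL
  list(elements = el, sums = sums)
}

#' Export beta fits as JSON
#'
#' @param fits Named list of `"beta_fit"` objects (names identify the
#'   element/class each fit describes).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_beta_fits_json <- function(fits, path) {
  stopifnot(all(vapply(fits, inherits, logical(1), "beta_fit")))
  out <- lapply(fits, function(f)
    list(alpha = f$alpha, beta = f$beta,
         support = c(f$support_lo, f$support_hi),
         loglik = f$log_likelihood, method = f$method, n = f$n))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
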