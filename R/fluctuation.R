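# Dependent measures used to compare regulation strategies: time-series
# variability, DFA scaling exponents, and direct error-correction
# regression.

#' Detrended fluctuation analysis scaling exponent
#'
#' Quantifies statistical persistence of a step-to-step series.  The
#' series is mean-centered and cumulatively summed; for each segment
#' length `j` the profile is partitioned into `floor(N/j)` non-overlapping
#' segments anchored at the series start (the tail remainder is
#' discarded), a least-squares line is removed from each segment, and
#' `F(j)` is the root mean square of the residuals over all covered
#' points.  `alpha` is the least-squares slope of `log F(j)` versus
#' `log j`.
#'
#' Interpretation: `alpha = 1/2` uncorrelated fluctuations, `alpha > 1/2`
#' persistence, `alpha < 1/2` anti-persistence, `alpha = 3/2` integrated
#' white noise (Brownian-like).
#'
#' @param x numeric series, length >= 16, finite, non-constant.
#' @param n_scales number of segment lengths (default 50), distributed
#'   between 4 and `floor(N/4)`.
#' @param spacing `"linear"` (default) or `"log"` spacing of the segment
#'   lengths; duplicates after integer rounding are removed.
#' @return An object of class `dfa_result`: list with `scales`, `F`,
#'   `alpha`, `fit_r2`.
#' @examples
#' set.seed(1)
#' dfa_alpha(rnorm(290))$alpha          # about 0.5
#' dfa_alpha(cumsum(rnorm(290)))$alpha  # about 1.5
#' @export
dfa_alpha <- function(x, n_scales = 50, spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 16L)
    stop("series too short for DFA: need N >= 16, got ", n)
  if (!all(is.finite(x)))
    stop("series contains non-finite values")
  if (stats::sd(x) == 0)
    stop("constant series: DFA fluctuation is zero, alpha undefined")
  j_max <- n %/% 4L
  scales <- if (spacing == "linear") seq(4, j_max, length.out = n_scales)
            else exp(seq(log(4), log(j_max), length.out = n_scales))
  scales <- unique(as.integer(round(scales)))
  y <- cumsum(x - mean(x))
  F_j <- vapply(scales, function(j) .dfa_fluctuation(y, j), numeric(1))
  if (any(F_j == 0))
    stop("zero fluctuation at scale ", scales[which(F_j == 0)[1L]],
         ": alpha undefined")
  fit <- stats::lm.fit(cbind(1, log(scales)), log(F_j))
  r2 <- 1 - sum(fit$residuals^2) /
    sum((log(F_j) - mean(log(F_j)))^2)
  structure(list(scales = scales, F = F_j,
                 alpha = unname(fit$coefficients[2L]), fit_r2 = r2),
            class = "dfa_result")
}

# RMS residual of per-segment linear detrending at segment length j.
# Segments are the columns of a j x m reshape of the covered profile;
# the within-segment regressor k = 1..j is shared, so slopes and
# intercepts for all segments come from closed-form column sums.
.dfa_fluctuation <- function(y, j) {
  m <- length(y) %/% j
  yy <- matrix(y[seq_len(m * j)], nrow = j)
  k <- seq_len(j)
  k_c <- k - mean(k)
  sxx <- sum(k_c^2)
  slope <- colSums(yy * k_c) / sxx
  intercept <- colMeans(yy)           # at the segment's centered midpoint
  resid <- yy - rep(intercept, each = j) - outer(k_c, slope)
  sqrt(mean(resid^2))
}

#' @export
print.dfa_result <- function(x, ...) {
  cat("<dfa_result> alpha =", format(x$alpha, digits = 4),
      " (", length(x$scales), "scales",
      min(x$scales), "...", max(x$scales),
      ", fit r2 =", format(x$fit_r2, digits = 3), ")\n")
  invisible(x)
}

#' Sample standard deviation of a series
#'
#' @param x numeric series, length >= 2.
#' @return sample SD (n-1 denominator).
#' @export
series_sd <- function(x) {
  if (length(x) < 2L)
    stop("need at least 2 observations, got ", length(x))
  stats::sd(x)
}

#' Direct step-to-step error-correction regression
#'
#' Regresses the next-step change `dq_{n+1} = q_{n+1} - q_n` on the
#' current deviation from the series mean, `q'_n = q_n - mean(q)`,
#' by ordinary least squares.  A slope near -1 with high `r2` indicates
#' strong linear one-step error correction; a slope near 0 with low `r2`
#' indicates an unregulated (random-walk-like) variable.
#'
#' @param q numeric series, length >= 3, non-constant.
#' @return An object of class `direct_control_result`: list with `slope`,
#'   `intercept`, `r2`.
#' @examples
#' set.seed(1)
#' direct_control_regression(rnorm(1000))$slope        # about -1
#' direct_control_regression(cumsum(rnorm(1000)))$slope # about 0
#' @export
direct_control_regression <- function(q) {
  q <- as.numeric(q)
  n <- length(q)
  if (n < 3L)
    stop("need at least 3 observations, got ", n)
  if (!all(is.finite(q)))
    stop("series contains non-finite values")
  qp <- (q - mean(q))[-n]
  dq <- diff(q)
  if (sum(qp^2) == 0 || stats::sd(qp) == 0)
    stop("zero variance in the deviation series: slope undefined")
  sxx <- sum((qp - mean(qp))^2)
  sxy <- sum((qp - mean(qp)) * (dq - mean(dq)))
  slope <- sxy / sxx
  intercept <- mean(dq) - slope * mean(qp)
  syy <- sum((dq - mean(dq))^2)
  r2 <- if (syy == 0) 1 else sxy^2 / (sxx * syy)
  structure(list(slope = slope, intercept = intercept, r2 = r2),
            class = "direct_control_result")
}

#' @export
print.direct_control_result <- function(x, ...) {
  cat("<direct_control_result> slope =", format(x$slope, digits = 4),
      " r2 =", format(x$r2, digits = 3), "\n")
  invisible(x)
}

# Measures computed per variable in summarize_trial.
.SUMMARY_VARS <- c("z_B", "dz_B", "w")
.FOOT_VARS <- c("z_L", "z_R")

#' Summary statistics of a stepping trial
#'
#' Applies [series_sd()], [dfa_alpha()], and
#' [direct_control_regression()] to the derived series `z_B`, `dz_B`
#' (length N-1), and `w`, plus SD and DFA for the foot placements `z_L`,
#' `z_R`.  Degenerate series (constant, e.g. from a noise-free
#' simulation) yield `NA` for the measures that are undefined on them.
#'
#' @param trial a [foot_placement_trial()].
#' @param n_scales passed to [dfa_alpha()].
#' @return one-row `data.frame` with columns `sd_*`, `alpha_*`,
#'   `slope_*`, `r2_*` for `z_B`, `dz_B`, `w`, and `sd_zL`, `sd_zR`,
#'   `alpha_zL`, `alpha_zR`.
#' @export
summarize_trial <- function(trial, n_scales = 50) {
  stopifnot(inherits(trial, "foot_placement_trial"))
  if (n_steps(trial) < 16L)
    stop("trial too short to summarize: need N >= 16")
  s <- derive_state_series(trial)
  series <- list(z_B = s$z_B, dz_B = s$dz_B, w = s$w)
  out <- list()
  for (v in .SUMMARY_VARS) {
    x <- series[[v]]
    key <- sub("^dz_B$", "dzB", sub("^z_B$", "zB", v))
    out[[paste0("sd_", key)]] <- series_sd(x)
    out[[paste0("alpha_", key)]] <-
      tryCatch(dfa_alpha(x, n_scales)$alpha, error = function(e) NA_real_)
    dc <- tryCatch(direct_control_regression(x),
                   error = function(e) list(slope = NA_real_, r2 = NA_real_))
    out[[paste0("slope_", key)]] <- dc$slope
    out[[paste0("r2_", key)]] <- dc$r2
  }
  feet <- list(zL = trial$z_L, zR = trial$z_R)
  for (v in names(feet)) {
    out[[paste0("sd_", v)]] <- series_sd(feet[[v]])
    out[[paste0("alpha_", v)]] <-
      tryCatch(dfa_alpha(feet[[v]], n_scales)$alpha,
               error = function(e) NA_real_)
  }
  as.data.frame(out)
}
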