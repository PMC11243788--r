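# Evaluation metrics: RMSE, Pearson correlation, SNR, NRMSE, convergence rate.

#' Root-mean-square error
#'
#' `sqrt(mean((estimated - measured)^2))`, in the units of the inputs
#' (degrees for knee angles).
#'
#' @param measured,estimated Equal-length numeric vectors.
#' @return Nonnegative scalar.
#' @export
rmse <- function(measured, estimated) {
  if (length(measured) != length(estimated)) stop("length mismatch")
  if (length(measured) < 1L) stop("empty input")
  sqrt(mean((estimated - measured)^2))
}

#' Pearson correlation coefficient between measured and estimated angles
#'
#' Computed from centered cross- and auto-moments; errors on constant input,
#' where the correlation is undefined.
#'
#' @inheritParams rmse
#' @return Scalar in \[-1, 1\].
#' @export
cc <- function(measured, estimated) {
  if (length(measured) != length(estimated)) stop("length mismatch")
  if (length(measured) < 2L) stop("need at least 2 samples")
  dm <- measured - mean(measured)
  de <- estimated - mean(estimated)
  den <- sqrt(mean(dm^2)) * sqrt(mean(de^2))
  if (den == 0) stop("undefined correlation: constant input")
  mean(dm * de) / den
}

#' Signal-to-noise ratio of the estimate, in dB
#'
#' The default (`method = "literal"`) is the power ratio of the measured to
#' the estimated signal, `10 log10(mean(theta^2) / mean(theta_hat^2))`. An
#' error-based alternative (`method = "error"`, measured power over error
#' power) is available since the literal form is atypical.
#'
#' @inheritParams rmse
#' @param method `"literal"` (default) or `"error"`.
#' @return SNR in dB.
#' @export
snr <- function(measured, estimated, method = c("literal", "error")) {
  method <- match.arg(method)
  if (length(measured) != length(estimated)) stop("length mismatch")
  if (method == "literal") {
    pe <- mean(estimated^2)
    if (pe == 0) stop("zero-power estimate")
    10 * log10(mean(measured^2) / pe)
  } else {
    perr <- mean((measured - estimated)^2)
    if (perr == 0) stop("zero error power")
    10 * log10(mean(measured^2) / perr)
  }
}

#' Normalized RMSE
#'
#' RMSE divided by the range of the measured signal.
#'
#' @inheritParams rmse
#' @return Dimensionless fraction.
#' @export
nrmse <- function(measured, estimated) {
  rng <- max(measured) - min(measured)
  if (rng == 0) stop("zero measured range")
  rmse(measured, estimated) / rng
}

#' Average convergence rate of a sequential run
#'
#' Slope of the line connecting the first and last per-stride RMSE:
#' `(rmse_last - rmse_first) / (n - 1)`, in degrees per stride. Negative
#' values mean the estimate improves over the run.
#'
#' @param per_stride_rmse Numeric vector of per-stride RMSE values (n >= 2).
#' @return Slope in degrees/stride.
#' @export
convergence_rate <- function(per_stride_rmse) {
  n <- length(per_stride_rmse)
  if (n < 2L) stop("need at least 2 strides")
  (per_stride_rmse[n] - per_stride_rmse[1]) / (n - 1)
}

#' Per-stride evaluation report
#'
#' @param measured,estimated Matrices of angles (strides x samples), aligned
#'   row-wise.
#' @param snr_method Passed to [snr()].
#' @return A `data.frame` of class `"stride_metrics"` with columns `stride`,
#'   `rmse`, `cc`, `snr`, `nrmse`.
#' @export
stride_metrics <- function(measured, estimated,
                           snr_method = c("literal", "error")) {
  snr_method <- match.arg(snr_method)
  if (is.vector(measured)) measured <- matrix(measured, 1L)
  if (is.vector(estimated)) estimated <- matrix(estimated, 1L)
  if (!all(dim(measured) == dim(estimated))) stop("dimension mismatch")
  n <- nrow(measured)
  df <- data.frame(
    stride = seq_len(n),
    rmse = vapply(seq_len(n), function(i) rmse(measured[i, ], estimated[i, ]),
                  numeric(1)),
    cc = vapply(seq_len(n), function(i) cc(measured[i, ], estimated[i, ]),
                numeric(1)),
    snr = vapply(seq_len(n), function(i)
      snr(measured[i, ], estimated[i, ], snr_method), numeric(1)),
    nrmse = vapply(seq_len(n), function(i) nrmse(measured[i, ], estimated[i, ]),
                   numeric(1)))
  class(df) <- c("stride_metrics", "data.frame")
  df
}

#' @export
print.stride_metrics <- function(x, ...) {
  cat(sprintf("stride metrics (n = %d):\n", nrow(x)))
  cat(sprintf("  RMSE %.2f +/- %.2f deg; CC %.3f +/- %.3f; SNR %.2f dB; NRMSE %.3f\n",
              mean(x$rmse), stats::sd(x$rmse), mean(x$cc), stats::sd(x$cc),
              mean(x$snr), mean(x$nrmse)))
  invisible(x)
}
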