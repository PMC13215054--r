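#' Two-channel ratiometric fluorescence trace
#'
#' A time series of numerator- and denominator-channel intensities from a
#' bouton region of interest, with one or two background regions per channel,
#' and the stimulation window.
#'
#' @param time Sample times (s).
#' @param signal_num,signal_den Bouton-ROI intensities per sample.
#' @param background_num,background_den Background intensities: a vector (one
#'   region or pre-averaged) or a matrix with one column per background region.
#' @param stim_start,stim_end Stimulation window (s), within the time range.
#' @return An object of class `ratiometric_trace`.
#' @export
ratiometric_trace <- function(time, signal_num, signal_den,
                              background_num, background_den,
                              stim_start, stim_end) {
  background_num <- as.matrix(background_num)
  background_den <- as.matrix(background_den)
  n <- length(time)
  if (length(signal_num) != n || length(signal_den) != n ||
      nrow(background_num) != n || nrow(background_den) != n) {
    stop("all series must have the same length", call. = FALSE)
  }
  if (stim_start < min(time) || stim_end > max(time) ||
      stim_end < stim_start) {
    stop("stimulus window must lie within the time range", call. = FALSE)
  }
  if (!any(time < stim_start)) {
    stop("trace has no pre-stimulus samples", call. = FALSE)
  }
  structure(list(time = time, signal_num = signal_num,
                 signal_den = signal_den, background_num = background_num,
                 background_den = background_den,
                 stim_start = stim_start, stim_end = stim_end),
            class = "ratiometric_trace")
}

# Background-corrected fluorescence ratio: per frame, the average of the
# background regions is subtracted from the bouton ROI in each channel.
trace_ratio <- function(trace) {
  num <- trace$signal_num - rowMeans(trace$background_num)
  den <- trace$signal_den - rowMeans(trace$background_den)
  if (any(den <= 0)) {
    stop("background exceeds signal in the denominator channel", call. = FALSE)
  }
  num / den
}

#' Fractional ratio change relative to the pre-stimulus baseline
#'
#' Computes the background-corrected channel ratio R, optionally corrects it
#' for bleaching (see [bleach_correct()]), and returns
#' `dR/R = (R - R_rest)/R_rest` with `R_rest` the pre-stimulus mean, so the
#' pre-stimulus portion of the output averages zero.
#'
#' @param trace A [ratiometric_trace()].
#' @param bleach Apply bleach correction to the ratio before normalizing.
#' @param window Correction window relative to stimulus onset (s); when
#'   `bleach = TRUE` the baseline mean is taken over the pre-stimulus samples
#'   inside this window (the corrected region).
#' @param ... Passed to [bleach_correct()].
#' @return Numeric dR/R series with attributes `r_rest` and (when `bleach`)
#'   the fit attributes of [bleach_correct()].
#' @export
delta_r_over_r <- function(trace, bleach = FALSE, window = c(-10, 40), ...) {
  r <- trace_ratio(trace)
  atts <- NULL
  if (bleach) {
    r <- bleach_correct(r, trace$time, trace$stim_start, window = window, ...)
    atts <- attributes(r)
  }
  pre <- trace$time < trace$stim_start
  if (bleach) pre <- pre & trace$time >= trace$stim_start + window[1]
  r_rest <- mean(r[pre])
  out <- (r - r_rest) / r_rest
  attr(out, "r_rest") <- r_rest
  if (!is.null(atts)) {
    attr(out, "bleach_tau") <- atts$tau
    attr(out, "bleach_converged") <- atts$converged
  }
  out
}

#' Monoexponential bleach correction of a ratio series
#'
#' Fits `a * exp(-t/tau) + c` (offset included by default; set
#' `offset = FALSE` for a pure exponential) to the pre-stimulus portion of the
#' ratio by Levenberg-Marquardt least squares, initialized from a log-linear
#' regression, then divides the ratio by the fitted curve over the correction
#' window and rescales so the pre-stimulus mean is 1. Outside the correction
#' window the series is returned unchanged. If the fit fails the series is
#' returned uncorrected with attribute `converged = FALSE` and a warning.
#'
#' @param ratio Numeric ratio series.
#' @param time Sample times (s).
#' @param stim_start Stimulus onset (s); time zero of the correction window.
#' @param pre_window Length of pre-stimulus data used for the fit (s),
#'   default 20.
#' @param window Correction window relative to `stim_start` (s), default
#'   `c(-10, 40)`.
#' @param offset Include the additive offset term.
#' @return Corrected series with attributes `tau` (fitted bleach constant, s)
#'   and `converged`.
#' @export
bleach_correct <- function(ratio, time, stim_start, pre_window = 20,
                           window = c(-10, 40), offset = TRUE) {
  stopifnot(length(ratio) == length(time))
  pre <- time < stim_start & time >= stim_start - pre_window
  if (sum(pre) < 4) stop("not enough pre-stimulus samples for the bleach fit",
                         call. = FALSE)
  tp <- time[pre]; rp <- ratio[pre]

  # log-linear initialization on (ratio - floor)
  floor0 <- if (offset) min(rp) - 0.05 * diff(range(rp)) - 1e-12 else 0
  pos <- rp - floor0
  init_ok <- all(pos > 0)
  tau0 <- pre_window; a0 <- max(rp) - floor0
  if (init_ok && diff(range(rp)) > 0) {
    ll <- stats::lm(log(pos) ~ tp)
    sl <- coef(ll)[2]
    if (is.finite(sl) && sl < 0) {
      tau0 <- unname(-1 / sl)
      a0 <- unname(exp(coef(ll)[1]))
    }
  }

  in_win <- time >= stim_start + window[1] & time <= stim_start + window[2]

  # a flat baseline needs no exponential: normalize by its mean directly
  if (diff(range(rp)) <= 1e-12 * max(abs(rp), 1)) {
    out <- ratio
    out[in_win] <- ratio[in_win] / mean(rp)
    attr(out, "tau") <- Inf
    attr(out, "converged") <- TRUE
    return(out)
  }

  model <- function(p, t) p[1] * exp(-t / p[2]) + if (offset) p[3] else 0
  p0 <- if (offset) c(a0, tau0, floor0) else c(a0, tau0)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = function(p) rp - model(p, tp),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)

  if (is.null(fit) || !fit$info %in% 1:3 || !all(is.finite(fit$par)) ||
      fit$par[2] <= 0) {
    warning("bleach fit did not converge; returning uncorrected series",
            call. = FALSE)
    out <- ratio
    attr(out, "tau") <- NA_real_
    attr(out, "converged") <- FALSE
    return(out)
  }

  cf <- fit$par
  fitted_curve <- model(cf, time)
  out <- ratio
  out[in_win] <- ratio[in_win] / fitted_curve[in_win]
  pre_out <- in_win & time < stim_start
  if (any(pre_out)) out[in_win] <- out[in_win] / mean(out[pre_out])
  attr(out, "tau") <- unname(cf[2])
  attr(out, "converged") <- TRUE
  out
}

#' Median-absolute-deviation outlier flags
#'
#' Flags values beyond `median(x) + 3*MAD` or `median(x) - 3*MAD`, where MAD
#' is the unscaled median absolute deviation `median(|x - median(x)|)` (no
#' 1.4826 consistency constant). Values exactly on a bound are kept. When
#' MAD = 0 every value differing from the median is flagged, with a warning.
#'
#' @param values Numeric vector, length >= 3.
#' @param n_mad Multiplier (default 3).
#' @return Logical vector, `TRUE` = outlier.
#' @export
mad_outlier_flags <- function(values, n_mad = 3) {
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  med <- stats::median(values)
  mad0 <- stats::median(abs(values - med))
  if (mad0 == 0) {
    flags <- values != med
    if (any(flags)) {
      warning("MAD is zero: flagging every value that differs from the median",
              call. = FALSE)
    }
    return(flags)
  }
  values < med - n_mad * mad0 | values > med + n_mad * mad0
}

#' Quantal content with non-linear summation correction
#'
#' The mean evoked EJP amplitude is first corrected for non-linear summation
#' with the simple Martin-type form `v / (1 - v/driving)` (unit correction
#' factor), where `driving` is the effective driving force in mV; miniature
#' amplitudes are never corrected. Quantal content is the corrected mean EJP
#' divided by the mean mEJP amplitude.
#'
#' @param ejp Evoked EJP amplitudes (mV), positive.
#' @param mejp Miniature EJP amplitudes (mV), positive, non-empty.
#' @param driving Effective driving force (mV); must exceed the mean EJP.
#'   There is no default: it must be supplied.
#' @return List with `qc`, `mean_ejp`, `corrected_mean_ejp`, `mean_mejp`.
#' @export
quantal_content <- function(ejp, mejp, driving) {
  if (missing(driving)) stop("driving force must be supplied", call. = FALSE)
  if (length(mejp) == 0 || length(ejp) == 0) {
    stop("ejp and mejp samples must be non-empty", call. = FALSE)
  }
  if (any(ejp <= 0) || any(mejp <= 0)) {
    stop("amplitudes must be positive", call. = FALSE)
  }
  m_ejp <- mean(ejp)
  if (m_ejp >= driving) {
    stop("mean EJP amplitude must be below the driving force", call. = FALSE)
  }
  corrected <- m_ejp / (1 - m_ejp / driving)
  m_mejp <- mean(mejp)
  list(qc = corrected / m_mejp, mean_ejp = m_ejp,
       corrected_mean_ejp = corrected, mean_mejp = m_mejp)
}
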