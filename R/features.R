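# Excitability and physiological measures extracted from recordings.

#' Detect spikes in a voltage trace
#'
#' One spike per upward crossing of `threshold`, with successive spikes
#' separated by at least `refractory` ms; spike times are taken at the first
#' sample at or above threshold.
#'
#' @param trace Numeric membrane-potential trace (mV).
#' @param dt Sample interval (ms).
#' @param window Length-2 numeric, analysis window (ms from trace start).
#' @param threshold Detection threshold (mV).
#' @param refractory Minimum spike separation (ms).
#' @return Numeric vector of spike times (ms), strictly increasing.
#' @export
detect_spikes <- function(trace, dt, window = c(0, Inf), threshold = -10,
                          refractory = 2) {
  above <- trace >= threshold
  cross <- which(above & !c(FALSE, above[-length(above)]))
  times <- (cross - 1) * dt
  keep <- numeric()
  last <- -Inf
  for (t in times) {
    if (t - last >= refractory) {
      keep <- c(keep, t)
      last <- t
    }
  }
  keep[keep >= window[1] & keep <= window[2]]
}

#' Input-output curve of a recording
#'
#' Spike count and first-spike latency per sweep, counted within each
#' sweep's analysis window (the 400 ms step for the static protocol, the
#' 2.5 s on-phase for the synaptic protocol). Latencies are relative to
#' window onset and `NA` for sweeps without spikes.
#'
#' @param rec A `vc_recording`.
#' @return An object of class `io_curve`: data.frame with the stimulus axis
#'   (`amplitude` pA or `g_ampa` nS according to the protocol), `count` and
#'   `latency`.
#' @export
io_curve <- function(rec) {
  stopifnot(inherits(rec, "vc_recording"))
  n <- length(rec$spikes)
  count <- integer(n)
  latency <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- rec$spikes[[i]]
    s <- s[s >= rec$window[i, 1] & s <= rec$window[i, 2]]
    count[i] <- length(s)
    if (length(s)) latency[i] <- s[1] - rec$window[i, 1]
  }
  axis <- if (identical(rec$protocol, "dynamic")) "g_ampa" else "amplitude"
  out <- data.frame(rec$stimulus[[axis]], count = count, latency = latency)
  names(out)[1] <- axis
  class(out) <- c("io_curve", "data.frame")
  attr(out, "axis") <- axis
  out
}

#' Rheobase of a static input-output curve
#'
#' @param curve An [io_curve()] from the current-step protocol.
#' @return Smallest current (pA) evoking at least one spike, or `NA` when
#'   the neuron never fired.
#' @export
rheobase <- function(curve) {
  stopifnot(inherits(curve, "io_curve"))
  i <- which(curve$count >= 1)
  if (!length(i)) return(NA_real_)
  curve[[attr(curve, "axis")]][min(i)]
}

#' Threshold AMPA-conductance of a dynamic input-output curve
#'
#' @param curve An [io_curve()] from the synaptic protocol.
#' @return Smallest excitatory conductance (nS) evoking at least one spike,
#'   or `NA` when the neuron never fired up to the schedule maximum.
#' @export
threshold_conductance <- function(curve) {
  stopifnot(inherits(curve, "io_curve"))
  i <- which(curve$count >= 1)
  if (!length(i)) return(NA_real_)
  curve[[attr(curve, "axis")]][min(i)]
}

#' Total (cumulative) spike count
#'
#' Sum of the per-sweep spike counts over the whole protocol; the scalar
#' excitability measure used for the static-vs-dynamic comparison.
#'
#' @param curve An [io_curve()].
#' @return Nonnegative integer.
#' @export
cumulative_spike_count <- function(curve) {
  sum(curve$count)
}

#' Fit a Belehradek function to first-spike latencies
#'
#' Least-squares fit of the three-parameter power law
#' \eqn{L(I) = a (I - b)^c} with `c < 0` and the offset constrained below
#' the smallest fitted current (`b <= min(I) - 1` pA), fitted in log space
#' (the scale on which latencies spread over decades): `a` and `c` are
#' profiled out by linear regression of `log L` on `log(I - b)` and `b` is
#' found by one-dimensional minimisation.
#'
#' @param currents Currents (pA) of the fitted sweeps.
#' @param latencies First-spike latencies (ms), same length, all finite.
#' @return An object of class `belehradek_fit`: list with `a`, `b`, `c`,
#'   `residual` (log-space RSS), `converged`, and the fitted range.
#' @export
fit_belehradek <- function(currents, latencies) {
  ok <- is.finite(currents) & is.finite(latencies) & latencies > 0
  currents <- currents[ok]; latencies <- latencies[ok]
  if (length(currents) < 4)
    stop("Belehradek fit needs at least 4 (current, latency) pairs")
  o <- order(currents)
  currents <- currents[o]; latencies <- latencies[o]
  upper <- min(currents) - 1
  logl <- log(latencies)
  rss_for <- function(b) {
    x <- log(currents - b)
    f <- stats::lm.fit(cbind(1, x), logl)
    sum(f$residuals^2)
  }
  opt <- stats::optimize(rss_for, lower = upper - 2000, upper = upper,
                         tol = 1e-9)
  b <- opt$minimum
  x <- log(currents - b)
  f <- stats::lm.fit(cbind(1, x), logl)
  a <- exp(f$coefficients[1])
  cc <- f$coefficients[2]
  fit <- structure(list(a = unname(a), b = b, c = unname(cc),
                        residual = opt$objective,
                        converged = is.finite(opt$objective) && cc < 0,
                        range = range(currents)),
                   class = "belehradek_fit")
  if (!fit$converged)
    warning("Belehradek fit did not yield a decreasing latency curve")
  fit
}

#' @export
print.belehradek_fit <- function(x, ...) {
  cat(sprintf(
    "<belehradek_fit> L(I) = %.4g * (I - %.4g)^%.4g  (log-RSS %.3g)\n",
    x$a, x$b, x$c, x$residual))
  invisible(x)
}

#' Predicted first-spike latency from a Belehradek fit
#'
#' @param object A `belehradek_fit`.
#' @param newdata Currents (pA) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Latencies (ms).
#' @export
predict.belehradek_fit <- function(object, newdata, ...) {
  if (any(newdata <= object$b))
    stop("evaluation point at or below the fitted offset b")
  object$a * (newdata - object$b)^object$c
}

#' First-spike latency at 1.3 times rheobase
#'
#' The fitted Belehradek function evaluated at `1.3 * rheobase`; a measure
#' of spike-response speed robust to the 5 pA protocol resolution.
#'
#' @param fit A `belehradek_fit` (or `NULL`).
#' @param rheobase Rheobase (pA); `NA` propagates.
#' @return Latency (ms) or `NA`.
#' @export
latency_1_3 <- function(fit, rheobase) {
  if (is.null(fit) || is.na(rheobase)) return(NA_real_)
  x <- 1.3 * rheobase
  if (x <= fit$b) stop("1.3 * rheobase lies at or below the fitted offset")
  predict(fit, x)
}

#' Input resistance from subthreshold current steps
#'
#' Slope of the steady-state voltage deflection versus injected current over
#' the small hyperpolarizing steps (range pA), with the steady state
#' measured over the last 50 ms of each step.
#'
#' @param rec A `vc_recording` from the current-step protocol.
#' @param range Length-2 numeric, current range used for the slope (pA).
#' @return Resistance in MOhm.
#' @export
input_resistance <- function(rec, range = c(-20, 0)) {
  stopifnot(inherits(rec, "vc_recording"))
  amps <- rec$stimulus$amplitude
  sel <- which(amps >= range[1] & amps <= range[2])
  sel <- sel[vapply(sel, function(i) length(rec$spikes[[i]]) == 0,
                    logical(1))]
  if (length(sel) < 2) stop("no subthreshold sweeps in the slope range")
  v <- rec$summary[sel, "v_steady"]
  i <- amps[sel]
  # mV / pA = GOhm
  1000 * unname(stats::coef(stats::lm(v ~ i))[2])
}

#' Voltage sag ratio
#'
#' On the most hyperpolarized sweep: (peak hyperpolarization - steady state)
#' / (peak hyperpolarization - baseline), clamped to [0, 1]; 0 for a
#' monotone charging curve.
#'
#' @param rec A `vc_recording` from the current-step protocol.
#' @return Dimensionless ratio in `[0, 1]`.
#' @export
sag_ratio <- function(rec) {
  stopifnot(inherits(rec, "vc_recording"))
  i <- which.min(rec$stimulus$amplitude)
  vmin <- rec$summary[i, "v_min"]
  vsteady <- rec$summary[i, "v_steady"]
  vbase <- rec$summary[i, "v_base"]
  den <- vmin - vbase
  if (!is.finite(den) || abs(den) < 1e-9) return(0)
  max(0, min(1, (vmin - vsteady) / den))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data (ties receive average ranks).
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return Coefficient in `[-1, 1]`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0)
    stop("zero variance in ranked data; correlation undefined")
  sum(dx * dy) / (sx * sy)
}

#' Relative change in spike counts
#'
#' `100 * (after - before) / before`, in percent. A zero baseline count has
#' no defined relative change and yields `NA` (callers exclude such rows
#' from averages but keep the raw counts).
#'
#' @param before,after Nonnegative counts.
#' @return Percent change, or `NA` when `before == 0`.
#' @export
relative_change <- function(before, after) {
  ifelse(before > 0, 100 * (after - before) / before, NA_real_)
}

#' Extract the full feature record from a protocol pair
#'
#' @param static_rec `vc_recording` from [run_static_protocol()].
#' @param dynamic_rec `vc_recording` from [run_dynamic_protocol()], or
#'   `NULL`.
#' @return One-row data.frame: `rheobase` (pA), `threshold_g` (nS),
#'   `static_count`, `dynamic_count`, `latency13` (ms), `r_in` (MOhm),
#'   `v_rest` (mV), `sag`. Missing rheobase or threshold conductance is
#'   reported as `NA` with a zero count.
#' @export
feature_record <- function(static_rec, dynamic_rec = NULL) {
  sc <- io_curve(static_rec)
  rheo <- rheobase(sc)
  lat13 <- NA_real_
  if (!is.na(rheo)) {
    sup <- sc[sc$count >= 1 & !is.na(sc$latency) & sc[[1]] > 0, ]
    lat13 <- tryCatch({
      if (nrow(sup) >= 4) {
        fit <- suppressWarnings(fit_belehradek(sup[[1]], sup$latency))
        if (fit$converged && 1.3 * rheo > fit$b)
          latency_1_3(fit, rheo) else NA_real_
      } else NA_real_
    }, error = function(e) NA_real_)
  }
  dyn_g <- NA_real_
  dyn_count <- NA_integer_
  if (!is.null(dynamic_rec)) {
    dc <- io_curve(dynamic_rec)
    dyn_g <- threshold_conductance(dc)
    dyn_count <- cumulative_spike_count(dc)
  }
  data.frame(
    rheobase = rheo, threshold_g = dyn_g,
    static_count = cumulative_spike_count(sc), dynamic_count = dyn_count,
    latency13 = lat13,
    r_in = tryCatch(input_resistance(static_rec), error = function(e)
      NA_real_),
    v_rest = if (!is.null(static_rec$v_rest)) static_rec$v_rest else
      NA_real_,
    sag = sag_ratio(static_rec))
}
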