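# Poissonian presynaptic voltage waveforms: the stimulus material of the
# simulated synaptic bombardment. One excitatory and one inhibitory waveform
# are generated once per experiment and replayed identically to every
# instance and sweep.

#' Generate a Poissonian presynaptic voltage waveform
#'
#' Event times follow a homogeneous Poisson process at `rate`; each event is
#' rendered as a brief suprathreshold rectangular pulse (`v_peak`) on a
#' subthreshold baseline (`v_base`). Fed through the synaptic release rate
#' law, each pulse drives the synaptic activation close to saturation.
#'
#' @param rate Mean presynaptic firing rate (Hz), nonnegative.
#' @param duration Waveform duration (ms); must cover the protocol on-phase.
#' @param dt Sample interval (ms).
#' @param seed Integer seed; identical seeds give bit-identical waveforms.
#' @param pulse_width Pulse duration (ms), at least `dt`.
#' @param v_base Baseline potential (mV), below the release threshold.
#' @param v_peak Pulse potential (mV), above the release threshold.
#' @return An object of class `presyn_waveform`: list with the sample vector
#'   `v` (mV), `dt`, `rate`, `seed`, pulse descriptors and event times.
#' @export
generate_presynaptic_waveform <- function(rate = 50, duration = 2500,
                                          dt = 0.025, seed = 1,
                                          pulse_width = 1, v_base = -65,
                                          v_peak = 20) {
  stopifnot(rate >= 0, duration > 0, dt > 0)
  if (pulse_width < dt) stop("pulse_width must be at least dt")
  n <- round(duration / dt)
  v <- rep(v_base, n)
  events <- numeric()
  if (rate > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    n_ev <- stats::rpois(1, rate * duration / 1000)
    events <- sort(stats::runif(n_ev, 0, duration))
    for (t0 in events) {
      i0 <- floor(t0 / dt) + 1
      i1 <- min(n, floor((t0 + pulse_width) / dt))
      if (i0 <= n) v[i0:max(i0, i1)] <- v_peak
    }
  }
  structure(list(v = v, dt = dt, rate = rate, seed = seed,
                 pulse_width = pulse_width, v_base = v_base,
                 v_peak = v_peak, events = events),
            class = "presyn_waveform")
}

#' @export
print.presyn_waveform <- function(x, ...) {
  cat(sprintf(
    "<presyn_waveform> %g ms at dt = %g ms, rate %g Hz, %d events (seed %d)\n",
    length(x$v) * x$dt, x$dt, x$rate, length(x$events), x$seed))
  invisible(x)
}

#' Generate the excitatory/inhibitory waveform pair for an experiment
#'
#' @param master_seed Experiment master seed; the two waveform seeds are
#'   derived deterministically from it.
#' @param rate_exc,rate_inh Presynaptic rates (Hz).
#' @param duration,dt,... Passed to [generate_presynaptic_waveform()].
#' @return List with elements `exc` and `inh`.
#' @export
experiment_waveforms <- function(master_seed = 1, rate_exc = 8,
                                 rate_inh = 50, duration = 2500, dt = 0.025,
                                 ...) {
  seeds <- child_seeds(master_seed)
  list(exc = generate_presynaptic_waveform(rate_exc, duration, dt,
                                           seed = seeds["wave_exc"], ...),
       inh = generate_presynaptic_waveform(rate_inh, duration, dt,
                                           seed = seeds["wave_inh"], ...))
}

#' Write a presynaptic waveform as an ASCII file
#'
#' Plain-text format: `#`-prefixed header lines (dt, rate, seed, pulse shape)
#' followed by one membrane-potential sample (mV) per line.
#'
#' @param wave A `presyn_waveform`.
#' @param path Output file path.
#' @export
write_waveform_ascii <- function(wave, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt %.17g", wave$dt),
               sprintf("# rate %.17g", wave$rate),
               sprintf("# seed %d", as.integer(wave$seed)),
               sprintf("# pulse_width %.17g", wave$pulse_width),
               sprintf("# v_base %.17g", wave$v_base),
               sprintf("# v_peak %.17g", wave$v_peak)), con)
  writeLines(sprintf("%.17g", wave$v), con)
  invisible(path)
}

#' Read a presynaptic waveform from an ASCII file
#'
#' Accepts files written by [write_waveform_ascii()] or any user-supplied
#' file with a `# dt <ms>` header and one sample per line.
#'
#' @param path File path.
#' @return A `presyn_waveform`.
#' @export
read_waveform_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NA_real_) {
    m <- grep(paste0("^#\\s*", key, "\\s"), hdr, value = TRUE)
    if (!length(m)) return(default)
    as.numeric(sub(paste0("^#\\s*", key, "\\s+"), "", m[1]))
  }
  dt <- get("dt")
  if (is.na(dt)) stop("waveform file lacks a '# dt' header")
  v <- as.numeric(lines[!grepl("^#", lines) & nzchar(lines)])
  structure(list(v = v, dt = dt, rate = get("rate"),
                 seed = as.integer(get("seed", 0)),
                 pulse_width = get("pulse_width"),
                 v_base = get("v_base"), v_peak = get("v_peak"),
                 events = numeric()),
            class = "presyn_waveform")
}

# Master-seed policy: every source of randomness draws its seed from a fixed
# position of one seeded stream, so a single integer reproduces a whole
# experiment.
child_seeds <- function(master_seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(master_seed))
  s <- sample.int(.Machine$integer.max - 1L, 12L)
  stats::setNames(s, c("pop_regular", "pop_delayed", "pop_stuttering",
                       "wave_exc", "wave_inh", "lif", "subset", "extra1",
                       "extra2", "extra3", "extra4", "extra5"))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
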