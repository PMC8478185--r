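# Orchestration of the virtual-electrophysiology experiments: population
# maps, virtual pharmacology (current removal), kinetic-parameter sweeps and
# the LIF control.

#' Repetitive-firing transition current
#'
#' The lowest step current whose window contains at least `min_spikes`
#' spikes with all inter-spike intervals shorter than `max_isi`;
#' distinguishes the single-spike/stutter regime from tonic firing at the
#' protocol's current resolution.
#'
#' @param rec A `vc_recording` from the current-step protocol.
#' @param min_spikes Minimum spike count for the tonic regime.
#' @param max_isi Largest inter-spike interval still counted as tonic (ms).
#' @return Current (pA), or `NA` when no sweep reaches tonic firing.
#' @export
transition_current <- function(rec, min_spikes = 3, max_isi = 200) {
  stopifnot(inherits(rec, "vc_recording"))
  for (i in seq_along(rec$spikes)) {
    s <- rec$spikes[[i]]
    s <- s[s >= rec$window[i, 1] & s <= rec$window[i, 2]]
    if (length(s) >= min_spikes && all(diff(s) < max_isi))
      return(rec$stimulus$amplitude[i])
  }
  NA_real_
}

#' Run both protocols over a model population
#'
#' Each instance is settled, run through the current-step and (optionally)
#' synaptic protocol, and reduced to a [feature_record()]. When a
#' `manipulation` function is given (e.g. a [block_current()] wrapper), the
#' pair of protocols is repeated on the manipulated copy and paired rows are
#' returned. Per-instance simulation failures are reported as flagged rows
#' (`ok = FALSE`), never aborting the population.
#'
#' @param models List of [neuron_model()] (from [sample_population()]).
#' @param static_protocol A [current_step_protocol()].
#' @param dynamic_protocol A [synaptic_protocol()] or `NULL` to skip the
#'   synaptic protocol.
#' @param waveforms Presynaptic waveform pair ([experiment_waveforms()]).
#' @param manipulation Optional function `model -> model`.
#' @param dt Integration step (ms).
#' @param progress Print one line per instance.
#' @return A `result_table` data.frame: one row per instance (x condition
#'   `"before"`/`"after"` when manipulated) with the feature columns, plus
#'   `phenotype`, `instance`, `condition`, `ok`, `note`.
#' @export
run_population_experiment <- function(models, static_protocol =
                                        current_step_protocol(),
                                      dynamic_protocol =
                                        synaptic_protocol(),
                                      waveforms = NULL,
                                      manipulation = NULL, dt = 0.025,
                                      progress = FALSE) {
  stopifnot(length(models) >= 1)
  phen <- attr(models, "phenotype")
  if (is.null(phen)) phen <- NA_character_
  rows <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    id <- attr(m, "instance")
    if (is.null(id)) id <- i
    conds <- list(before = m)
    if (!is.null(manipulation)) conds$after <- manipulation(m)
    for (cond in names(conds)) {
      lab <- sprintf("%s#%d/%s", phen, id, cond)
      row <- tryCatch({
        srec <- run_static_protocol(conds[[cond]], static_protocol,
                                    dt = dt, label = lab)
        drec <- if (!is.null(dynamic_protocol))
          run_dynamic_protocol(conds[[cond]], dynamic_protocol, waveforms,
                               dt = dt, label = lab)
        fr <- feature_record(srec, drec)
        fr$transition <- transition_current(srec)
        cbind(data.frame(phenotype = phen, instance = id,
                         condition = cond, ok = TRUE, note = ""), fr)
      }, error = function(e) {
        data.frame(phenotype = phen, instance = id, condition = cond,
                   ok = FALSE, note = conditionMessage(e),
                   rheobase = NA_real_, threshold_g = NA_real_,
                   static_count = NA_integer_, dynamic_count = NA_integer_,
                   latency13 = NA_real_, r_in = NA_real_, v_rest = NA_real_,
                   sag = NA_real_, transition = NA_real_)
      })
      rows[[length(rows) + 1]] <- row
      if (progress)
        message(sprintf("  %s: static %s / dynamic %s", lab,
                        row$static_count, row$dynamic_count))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("result_table", "data.frame")
  out
}

#' Population maps and headline correlation over all three phenotypes
#'
#' Samples `n` instances per phenotype, runs both protocols on every
#' instance (identical waveforms throughout) and summarises the excitability
#' maps: the Spearman correlation of dynamic versus static cumulative spike
#' counts over the pooled population, and of threshold conductance versus
#' rheobase.
#'
#' @param n Instances per phenotype.
#' @param seed Master seed; per-phenotype and waveform seeds derive from it.
#' @param static_protocol,dynamic_protocol Protocol definitions.
#' @param rate_exc,rate_inh Presynaptic Poisson rates (Hz).
#' @param dt Integration step (ms).
#' @param progress Print per-instance progress.
#' @return List of class `experiment_result`: `features` (result table over
#'   all instances), `summary` (named list with `corr_counts`,
#'   `corr_thresholds`, `n`), `waveforms`, and the call parameters.
#' @export
experiment_population <- function(n = 200, seed = 1,
                                  static_protocol = current_step_protocol(),
                                  dynamic_protocol = synaptic_protocol(),
                                  rate_exc = 8, rate_inh = 50, dt = 0.025,
                                  progress = FALSE) {
  seeds <- child_seeds(seed)
  waves <- experiment_waveforms(seed, rate_exc, rate_inh,
                                duration = dynamic_protocol$on, dt = dt)
  feats <- list()
  for (phen in c("regular", "delayed", "stuttering")) {
    pop <- sample_population(phenotype_distribution(phen), n,
                             seed = seeds[[paste0("pop_", phen)]])
    feats[[phen]] <- run_population_experiment(
      pop, static_protocol, dynamic_protocol, waves, dt = dt,
      progress = progress)
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  ok <- features$ok
  summary <- list(
    n = sum(ok),
    corr_counts = spearman(features$static_count[ok],
                           features$dynamic_count[ok]),
    corr_thresholds = tryCatch({
      cc <- stats::complete.cases(features$rheobase[ok],
                                  features$threshold_g[ok])
      spearman(features$rheobase[ok][cc], features$threshold_g[ok][cc])
    }, error = function(e) NA_real_))
  structure(list(features = features, summary = summary, waveforms = waves,
                 n = n, seed = seed), class = "experiment_result")
}

#' Virtual pharmacology: current-removal experiment
#'
#' Samples a phenotype population, runs both protocols before and after
#' complete removal of the named current, and summarises the paired relative
#' changes of the cumulative spike counts. Instances with a zero baseline
#' count are excluded from the percent-change averages (their counts are
#' retained in the table).
#'
#' @param phenotype `"delayed"` (Kir removal), `"stuttering"` (D removal)
#'   or any phenotype name.
#' @param current Current name to remove; defaults to `"Kir"` for delayed
#'   and `"D"` for stuttering.
#' @param n Number of instances.
#' @param seed Master seed.
#' @param remove_h Also remove I_h before the comparison (the
#'   stuttering-without-h control).
#' @param static_protocol,dynamic_protocol Protocol definitions.
#' @param dt Integration step (ms).
#' @return List of class `experiment_result` with `features` (paired rows)
#'   and `summary`: medians of the static/dynamic percent changes, mean
#'   percent changes, the number of excluded zero-baseline rows, and the
#'   direction differential.
#' @export
experiment_blockade <- function(phenotype, current = NULL, n = 50,
                                seed = 1, remove_h = FALSE,
                                static_protocol = current_step_protocol(),
                                dynamic_protocol = synaptic_protocol(),
                                dt = 0.025) {
  if (is.null(current))
    current <- switch(phenotype, delayed = "Kir", stuttering = "D",
                      stop("specify the current to remove"))
  seeds <- child_seeds(seed)
  waves <- experiment_waveforms(seed)
  pop <- sample_population(phenotype_distribution(phenotype), n,
                           seed = seeds[[paste0("pop_", phenotype)]])
  if (remove_h)
    pop <- structure(lapply(pop, block_current, name = "h"),
                     manifest = attr(pop, "manifest"),
                     phenotype = attr(pop, "phenotype"))
  features <- run_population_experiment(
    pop, static_protocol, dynamic_protocol,
    manipulation = function(m) block_current(m, current),
    waveforms = waves, dt = dt)
  before <- features[features$condition == "before" & features$ok, ]
  after <- features[features$condition == "after" & features$ok, ]
  after <- after[match(before$instance, after$instance), ]
  dstat <- relative_change(before$static_count, after$static_count)
  ddyn <- relative_change(before$dynamic_count, after$dynamic_count)
  summary <- list(
    current = current, n = nrow(before),
    excluded_static = sum(is.na(dstat)), excluded_dynamic = sum(is.na(ddyn)),
    median_pct_static = stats::median(dstat, na.rm = TRUE),
    median_pct_dynamic = stats::median(ddyn, na.rm = TRUE),
    mean_pct_static = mean(dstat, na.rm = TRUE),
    mean_pct_dynamic = mean(ddyn, na.rm = TRUE),
    median_delta_static = stats::median(after$static_count -
                                          before$static_count),
    median_delta_dynamic = stats::median(after$dynamic_count -
                                           before$dynamic_count))
  structure(list(features = features, summary = summary, seed = seed,
                 n = n, phenotype = phenotype, current = current),
            class = "experiment_result")
}

#' Select a representative instance subset, stratified on static count
#'
#' Orders the instances by their baseline cumulative static spike count,
#' splits them into `k` equally sized strata and draws one instance per
#' stratum (seeded), giving a subset spanning the population's excitability
#' range.
#'
#' @param static_counts Baseline cumulative static counts, one per instance.
#' @param k Subset size.
#' @param seed Integer seed.
#' @return Integer indices of the selected instances.
#' @export
stratified_subset <- function(static_counts, k = 25, seed = 1) {
  stopifnot(k >= 1, k <= length(static_counts))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  o <- order(static_counts, sample.int(length(static_counts)))
  strata <- split(o, cut(seq_along(o), k, labels = FALSE))
  sort(vapply(strata, function(ix) ix[sample.int(length(ix), 1)],
              integer(1)))
}

#' Kinetic-parameter sweep experiment
#'
#' Runs both protocols on a representative instance subset at every grid
#' point of one kinetic manipulation of the Kir or D current:
#' \describe{
#'   \item{`"kir_vhalf"`}{Kir activation midpoint, default grid -91 to
#'     -75 mV in +2 mV steps (9 settings).}
#'   \item{`"kir_tau"`}{Kir maximal activation time constant, default grid
#'     10 to 130 ms in 15 ms steps (9 settings, tau_min co-scaled).}
#'   \item{`"d_vhalf"`}{D activation midpoint shifted synchronously with the
#'     inactivation midpoint (overlap preserved), default 9 settings of
#'     +2 mV from the canonical midpoint.}
#'   \item{`"d_tau"`}{D maximal activation time constant, default grid 2 to
#'     18 ms in 2 ms steps with the inactivation time constants co-scaled
#'     (ratio preserved).}
#' }
#'
#' @param kind One of the four sweep kinds above.
#' @param n_population Population size from which the subset is drawn.
#' @param n_subset Number of representative instances.
#' @param seed Master seed.
#' @param grid Optional grid override (midpoints in mV or tau_max in ms),
#'   at least 2 strictly monotone values.
#' @param static_protocol,dynamic_protocol Protocol definitions.
#' @param dt Integration step (ms).
#' @return List of class `experiment_result`: `features` has one row per
#'   instance x grid point (columns `setting` and the feature columns), in
#'   grid order per instance.
#' @export
experiment_kinetics <- function(kind = c("kir_vhalf", "kir_tau", "d_vhalf",
                                         "d_tau"),
                                n_population = 200, n_subset = 25, seed = 1,
                                grid = NULL,
                                static_protocol = current_step_protocol(),
                                dynamic_protocol = synaptic_protocol(),
                                dt = 0.025) {
  kind <- match.arg(kind)
  phen <- if (startsWith(kind, "kir")) "delayed" else "stuttering"
  cur <- if (startsWith(kind, "kir")) "Kir" else "D"
  canon <- canonical_model(phen)
  if (is.null(grid))
    grid <- switch(kind,
      kir_vhalf = seq(-91, -75, by = 2),
      kir_tau = seq(10, 130, by = 15),
      d_vhalf = canon$currents$D$activation$v_half + seq(0, 16, by = 2),
      d_tau = seq(2, 18, by = 2))
  stopifnot(length(grid) >= 2 || length(grid) == 1,
            all(diff(grid) > 0) || all(diff(grid) < 0))
  seeds <- child_seeds(seed)
  waves <- experiment_waveforms(seed)
  pop <- sample_population(phenotype_distribution(phen), n_population,
                           seed = seeds[[paste0("pop_", phen)]])
  base <- run_population_experiment(pop, static_protocol,
                                    dynamic_protocol = NULL, dt = dt)
  idx <- stratified_subset(base$static_count, k = n_subset,
                           seed = seeds[["subset"]])
  manip <- function(m, value) switch(kind,
    kir_vhalf = shift_activation_midpoint(m, cur, value),
    kir_tau = scale_time_constants(m, cur, value),
    d_vhalf = shift_activation_midpoint(m, cur, value,
                                        couple_inactivation = TRUE),
    d_tau = scale_time_constants(m, cur, value,
                                 couple_inactivation = TRUE))
  rows <- list()
  for (value in grid) {
    sub <- structure(lapply(pop[idx], manip, value = value),
                     phenotype = phen)
    ft <- run_population_experiment(sub, static_protocol, dynamic_protocol,
                                    waveforms = waves, dt = dt)
    ft$instance <- idx
    ft$setting <- value
    rows[[length(rows) + 1]] <- ft
  }
  features <- do.call(rbind, rows)
  features <- features[order(features$instance, features$setting), ]
  rownames(features) <- NULL
  structure(list(features = features, kind = kind, grid = grid,
                 subset = idx, seed = seed), class = "experiment_result")
}

#' LIF control experiment
#'
#' Runs 200 (by default) leaky integrate-and-fire instances, whose four
#' passive/threshold parameters are randomly varied, through both protocols
#' and computes the Spearman correlations of the paired excitability
#' measures. Undefined correlations (n too small or zero variance) are
#' flagged as `NA` rather than raising.
#'
#' @param n Number of LIF instances.
#' @param seed Master seed.
#' @param nominal Nominal [lif_model()].
#' @param cv Coefficient of variation of capacitance and leak conductance.
#' @param sd_e_leak,sd_v_th Absolute SDs of the varied voltages (mV).
#' @param static_protocol,dynamic_protocol Protocol definitions.
#' @param dt Integration step (ms).
#' @return List of class `experiment_result` with `features` and `summary`
#'   (`corr_counts`, `corr_thresholds`, `n`).
#' @export
experiment_lif <- function(n = 200, seed = 1, nominal = lif_model(),
                           cv = 0.05, sd_e_leak = 1, sd_v_th = 4,
                           static_protocol = current_step_protocol(),
                           dynamic_protocol = synaptic_protocol(),
                           dt = 0.025) {
  seeds <- child_seeds(seed)
  waves <- experiment_waveforms(seed, duration = dynamic_protocol$on,
                                dt = dt)
  pop <- sample_lif_population(nominal, cv = cv, n = n,
                               seed = seeds[["lif"]], sd_e_leak = sd_e_leak,
                               sd_v_th = sd_v_th)
  rows <- lapply(seq_along(pop), function(i) {
    srec <- run_lif_protocol(pop[[i]], static_protocol, dt = dt)
    drec <- run_lif_protocol(pop[[i]], dynamic_protocol, waveforms = waves,
                             dt = dt)
    sc <- io_curve(srec); dc <- io_curve(drec)
    data.frame(instance = i, rheobase = rheobase(sc),
               threshold_g = threshold_conductance(dc),
               static_count = cumulative_spike_count(sc),
               dynamic_count = cumulative_spike_count(dc))
  })
  features <- do.call(rbind, rows)
  safe_spearman <- function(x, y) {
    cc <- stats::complete.cases(x, y)
    tryCatch(spearman(x[cc], y[cc]), error = function(e) NA_real_)
  }
  summary <- list(
    n = nrow(features),
    corr_counts = safe_spearman(features$static_count,
                                features$dynamic_count),
    corr_thresholds = safe_spearman(features$rheobase,
                                    features$threshold_g))
  structure(list(features = features, summary = summary, seed = seed,
                 n = n), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  if (!is.null(x$kind)) cat(sprintf("  sweep: %s over %s\n", x$kind,
                                    paste(x$grid, collapse = ", ")))
  if (!is.null(x$summary)) {
    for (nm in names(x$summary)) {
      v <- x$summary[[nm]]
      if (is.numeric(v)) v <- signif(v, 4)
      cat(sprintf("  %s: %s\n", nm, paste(v, collapse = " ")))
    }
  }
  cat(sprintf("  feature rows: %d\n", nrow(x$features)))
  invisible(x)
}

#' Write a result table as delimited text
#'
#' @param result An `experiment_result` or `result_table`.
#' @param path Output path (tab-separated).
#' @export
write_result_table <- function(result, path) {
  tab <- if (inherits(result, "experiment_result")) result$features else
    result
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
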