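# Structured-text model configuration: one document per phenotype, mirroring
# the parameter tables field for field. Values are written with 17
# significant digits so write/read round-trips are bit-exact.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a neuron model as a structured text configuration
#'
#' Sections: `[passive]` (capacitances, leak, couplings, phenotype),
#' one `[current <name>]` per ionic current with its gating parameters and
#' compartment split, and `[calcium]` when a calcium pool is present.
#' Round-trips through [read_model_config()] bit-exactly.
#'
#' @param model A [neuron_model()].
#' @param path Output file path.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "neuron_model"))
  ln <- c("[passive]",
          paste("phenotype =", model$phenotype),
          paste("capacitance =", paste(fmt_num(model$capacitance),
                                       collapse = " ")),
          paste("g_leak =", paste(fmt_num(model$g_leak), collapse = " ")),
          paste("e_leak =", fmt_num(model$e_leak)),
          paste("g_sx =", fmt_num(model$g_sx)),
          paste("g_sd =", fmt_num(model$g_sd)))
  gate_lines <- function(prefix, g) {
    c(paste0(prefix, "_v_half = ", fmt_num(g$v_half)),
      paste0(prefix, "_v_slope = ", fmt_num(g$v_slope)),
      paste0(prefix, "_tau_max = ", fmt_num(g$tau_max)),
      paste0(prefix, "_tau_min = ", fmt_num(g$tau_min)),
      paste0(prefix, "_v_tau_half = ", fmt_num(g$v_tau_half)),
      paste0(prefix, "_v_tau_slope = ", fmt_num(g$v_tau_slope)),
      paste0(prefix, "_p = ", g$p))
  }
  for (cur in model$currents) {
    ln <- c(ln, sprintf("[current %s]", cur$name),
            paste("g_total =", fmt_num(cur$g_total)),
            paste("e_rev =", fmt_num(cur$e_rev)),
            paste("split =", paste(fmt_num(cur$split), collapse = " ")),
            paste("kca =", cur$kca),
            paste("ca_source =", cur$ca_source))
    if (!is.null(cur$activation)) ln <- c(ln, gate_lines("act",
                                                         cur$activation))
    if (!is.null(cur$inactivation)) ln <- c(ln, gate_lines("inact",
                                                           cur$inactivation))
  }
  if (!is.null(model$calcium))
    ln <- c(ln, "[calcium]",
            paste("gain =", fmt_num(model$calcium$gain)),
            paste("rest =", fmt_num(model$calcium$rest)),
            paste("tau =", fmt_num(model$calcium$tau)),
            paste("kca_half =", fmt_num(model$calcium$kca_half)))
  writeLines(ln, path)
  invisible(path)
}

#' Read a neuron model from a structured text configuration
#'
#' @param path File written by [write_model_config()].
#' @return A [neuron_model()].
#' @export
read_model_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sec_at <- grep("^\\[", lines)
  sections <- list()
  for (i in seq_along(sec_at)) {
    name <- gsub("^\\[|\\]$", "", lines[sec_at[i]])
    end <- if (i < length(sec_at)) sec_at[i + 1] - 1 else length(lines)
    body <- lines[seq(sec_at[i] + 1, length.out = max(0, end - sec_at[i]))]
    kv <- strsplit(body, "\\s*=\\s*")
    vals <- stats::setNames(lapply(kv, `[[`, 2),
                            vapply(kv, `[[`, character(1), 1))
    sections[[length(sections) + 1]] <- list(name = name, vals = vals)
  }
  num <- function(x) as.numeric(strsplit(x, "\\s+")[[1]])
  pas <- sections[[which(vapply(sections, function(s)
    s$name == "passive", logical(1)))]]$vals
  gate_from <- function(vals, prefix) {
    key <- function(k) vals[[paste0(prefix, "_", k)]]
    if (is.null(key("v_half"))) return(NULL)
    gating_spec(num(key("v_half")), num(key("v_slope")),
                num(key("tau_max")), num(key("tau_min")),
                num(key("v_tau_half")), num(key("v_tau_slope")),
                p = as.integer(key("p")))
  }
  currents <- list()
  calcium <- NULL
  for (s in sections) {
    if (startsWith(s$name, "current ")) {
      nm <- sub("^current ", "", s$name)
      v <- s$vals
      currents[[length(currents) + 1]] <- ionic_current_spec(
        nm, num(v$g_total), num(v$e_rev),
        activation = gate_from(v, "act"),
        inactivation = gate_from(v, "inact"),
        split = num(v$split), kca = as.logical(v$kca),
        ca_source = as.logical(v$ca_source))
    } else if (s$name == "calcium") {
      v <- s$vals
      calcium <- calcium_spec(num(v$gain), num(v$rest), num(v$tau),
                              num(v$kca_half))
    }
  }
  neuron_model(capacitance = num(pas$capacitance),
               g_leak = num(pas$g_leak), e_leak = num(pas$e_leak),
               g_sx = num(pas$g_sx), g_sd = num(pas$g_sd),
               currents = currents, calcium = calcium,
               phenotype = pas$phenotype)
}

#' Export a recording as multi-column delimited text
#'
#' First column is time within the sweep (ms), then one column of somatic
#' membrane potential per sweep; a `#`-prefixed header carries the sweep
#' stimulus descriptors and window bounds.
#'
#' @param rec A `vc_recording` made with `record_trace = TRUE`.
#' @param path Output path.
#' @export
write_recording_text <- function(rec, path) {
  if (is.null(rec$traces)) stop("recording carries no traces")
  n <- max(vapply(rec$traces, length, integer(1)))
  m <- vapply(rec$traces, function(v) c(v, rep(NA_real_, n - length(v))),
              numeric(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dt %s", fmt_num(rec$dt)),
    sprintf("# amplitude %s", paste(fmt_num(rec$stimulus$amplitude),
                                    collapse = " ")),
    sprintf("# g_ampa %s", paste(fmt_num(rec$stimulus$g_ampa),
                                 collapse = " ")),
    sprintf("# g_gaba %s", paste(fmt_num(rec$stimulus$g_gaba),
                                 collapse = " ")),
    sprintf("# win0 %s", paste(fmt_num(rec$window[, 1]), collapse = " ")),
    sprintf("# win1 %s", paste(fmt_num(rec$window[, 2]), collapse = " "))),
    con)
  utils::write.table(cbind(time = (seq_len(n) - 1) * rec$dt, m), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("time",
                                   paste0("sweep", seq_along(rec$traces))))
  invisible(path)
}
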