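#' Write a voltage trace to CSV
#'
#' Columnar export (`time_ms`, `Vm_mV`, and `theta_mV` when present); spike
#' times go to a separate event table if `events_file` is given.
#'
#' @param trace a `voltage_trace`.
#' @param file path for the samples CSV.
#' @param events_file optional path for the spike-time CSV.
#' @export
write_voltage_trace <- function(trace, file, events_file = NULL) {
  utils::write.csv(as.data.frame(trace), file, row.names = FALSE)
  if (!is.null(events_file)) {
    utils::write.csv(data.frame(spike_time_ms = trace$spikes), events_file,
                     row.names = FALSE)
  }
  invisible(file)
}

#' Write sweeps as a long CSV with a sidecar metadata table
#'
#' `<prefix>_sweeps.csv` holds (`sweep_id`, `time_ms`, `Vm_mV`);
#' `<prefix>_meta.csv` holds (`sweep_id`, `stimulus_id`, `onset_ms`,
#' `holding_state`). For a full [generate_session()] a
#' `<prefix>_ground_truth.csv` sidecar is written too.
#'
#' @param x a list of [make_sweep()] objects or a `synthetic_session`.
#' @param prefix path prefix for the output files.
#' @return The metadata file path, invisibly.
#' @export
write_sweeps <- function(x, prefix) {
  session <- NULL
  if (inherits(x, "synthetic_session")) {
    session <- x
    x <- x$sweeps
  }
  long <- do.call(rbind, lapply(seq_along(x), function(i) {
    data.frame(sweep_id = i, time_ms = x[[i]]$times, Vm_mV = x[[i]]$Vm)
  }))
  meta <- do.call(rbind, lapply(seq_along(x), function(i) {
    data.frame(sweep_id = i, stimulus_id = x[[i]]$stimulus_id,
               onset_ms = x[[i]]$onset, holding_state = x[[i]]$state)
  }))
  utils::write.csv(long, paste0(prefix, "_sweeps.csv"), row.names = FALSE)
  utils::write.csv(meta, paste0(prefix, "_meta.csv"), row.names = FALSE)
  if (!is.null(session)) {
    utils::write.csv(session$ground_truth,
                     paste0(prefix, "_ground_truth.csv"), row.names = FALSE)
  }
  invisible(paste0(prefix, "_meta.csv"))
}

#' Read sweeps written by [write_sweeps()]
#'
#' @param prefix the path prefix used when writing.
#' @return A list of [make_sweep()] objects.
#' @export
read_sweeps <- function(prefix) {
  long <- utils::read.csv(paste0(prefix, "_sweeps.csv"))
  meta <- utils::read.csv(paste0(prefix, "_meta.csv"))
  lapply(seq_len(nrow(meta)), function(i) {
    d <- long[long$sweep_id == meta$sweep_id[i], ]
    make_sweep(d$time_ms, d$Vm_mV, stimulus_id = meta$stimulus_id[i],
               onset = meta$onset_ms[i], state = meta$holding_state[i])
  })
}
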