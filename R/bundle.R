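#' Write a sweep bundle to disk
#'
#' The package's plain-text interchange format: a directory holding one JSON
#' manifest (`manifest.json`, with a cell table and a sweep table) and one
#' tab-delimited two-column trace file per sweep (`time_s`, `vm_mV`) under
#' `traces/`. Samples are written with full double precision (well beyond the
#' guaranteed 6 significant digits).
#'
#' @param cells list of [cell_recording()] objects.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_sweep_bundle <- function(cells, path) {
  if (inherits(cells, "msn_cell")) cells <- list(cells)
  ok <- tryCatch({
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(path, "traces"), showWarnings = FALSE)
    file.access(path, mode = 2) == 0
  }, error = function(e) FALSE)
  if (!isTRUE(ok)) abort(sprintf("cannot write to '%s'", path),
                         "msnephys_io_error")

  cell_tab <- data.frame(
    cell_id = vapply(cells, `[[`, character(1), "cell_id"),
    subtype = vapply(cells, `[[`, character(1), "subtype"),
    slice_id = vapply(cells, function(c) as.character(c$slice_id %||% NA),
                      character(1)),
    mouse_id = vapply(cells, function(c) as.character(c$mouse_id %||% NA),
                      character(1)),
    access_resistance_MOhm =
      vapply(cells, `[[`, numeric(1), "access_resistance_MOhm"),
    stringsAsFactors = FALSE
  )

  sweep_rows <- list()
  for (cell in cells) {
    for (s in cell$sweeps) {
      fname <- sprintf("%s_sweep%03d.tsv", cell$cell_id, s$sweep_index)
      tt <- (seq_along(s$vm) - 1L) / s$sample_rate_hz
      data.table::fwrite(data.table::data.table(time_s = tt, vm_mV = s$vm),
                         file.path(path, "traces", fname), sep = "\t")
      p <- s$protocol
      sweep_rows[[length(sweep_rows) + 1L]] <- data.frame(
        cell_id = s$cell_id, sweep_index = s$sweep_index,
        sample_rate_hz = s$sample_rate_hz, n_samples = length(s$vm),
        step_amplitude_pA = s$step_amplitude_pA,
        step_onset_s = s$step_onset_s, step_offset_s = s$step_offset_s,
        condition = s$condition,
        protocol_kind = p$kind, pulse_onset_s = p$pulse_onset_s,
        pulse_duration_ms = p$pulse_duration_ms, n_pulses = p$n_pulses,
        train_rate_hz = p$train_rate_hz,
        pharmacology = paste(s$pharmacology, collapse = ";"),
        trace_file = fname, stringsAsFactors = FALSE)
    }
  }
  sweep_tab <- if (length(sweep_rows)) do.call(rbind, sweep_rows) else
    data.frame()

  manifest <- list(format = "msnephys-sweep-bundle", version = 1L,
                   cells = cell_tab, sweeps = sweep_tab)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a sweep bundle from disk
#'
#' Inverse of [write_sweep_bundle()]. Sweeps are returned in deterministic
#' order by (cell_id, sweep_index), independent of file-system enumeration
#' order. A missing manifest raises a format error; a mismatch between the
#' manifest's `n_samples`/`sample_rate_hz` and a trace file raises an
#' integrity error naming the sweep.
#'
#' @param path bundle directory.
#' @return list of [cell_recording()] objects.
#' @export
read_sweep_bundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!dir.exists(path) || !file.exists(mf)) {
    format_error(sprintf("no sweep-bundle manifest found at '%s'", path))
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "msnephys-sweep-bundle")) {
    format_error("manifest is not an msnephys sweep bundle")
  }
  cell_tab <- manifest$cells
  sweep_tab <- manifest$sweeps
  if (length(cell_tab) == 0L || nrow(as.data.frame(cell_tab)) == 0L) {
    return(list())
  }
  cell_tab <- as.data.frame(cell_tab)
  cell_tab <- cell_tab[order(cell_tab$cell_id), , drop = FALSE]
  has_sweeps <- length(sweep_tab) > 0L && nrow(as.data.frame(sweep_tab)) > 0L
  if (has_sweeps) sweep_tab <- as.data.frame(sweep_tab)

  cells <- vector("list", nrow(cell_tab))
  for (i in seq_len(nrow(cell_tab))) {
    cid <- cell_tab$cell_id[i]
    sweeps <- list()
    if (has_sweeps) {
      rows <- sweep_tab[sweep_tab$cell_id == cid, , drop = FALSE]
      rows <- rows[order(rows$sweep_index), , drop = FALSE]
      sweeps <- lapply(seq_len(nrow(rows)), function(j) {
        r <- rows[j, ]
        tf <- file.path(path, "traces", r$trace_file)
        if (!file.exists(tf)) {
          integrity_error(sprintf("trace file missing for cell %s sweep %d",
                                  cid, r$sweep_index))
        }
        tr <- data.table::fread(tf, sep = "\t", header = TRUE)
        if (!all(c("time_s", "vm_mV") %in% names(tr)) ||
            nrow(tr) != r$n_samples) {
          integrity_error(sprintf(
            "trace/manifest mismatch for cell %s sweep %d (expected %d samples, found %d)",
            cid, r$sweep_index, r$n_samples, nrow(tr)))
        }
        if (nrow(tr) > 1) {
          dt_obs <- tr$time_s[2] - tr$time_s[1]
          if (abs(dt_obs - 1 / r$sample_rate_hz) > 1e-9) {
            integrity_error(sprintf(
              "sample-rate mismatch for cell %s sweep %d", cid, r$sweep_index))
          }
        }
        prot <- if (identical(r$protocol_kind, "none")) {
          stim_protocol("none")
        } else {
          stim_protocol(r$protocol_kind,
                        pulse_onset_s = r$pulse_onset_s,
                        pulse_duration_ms = r$pulse_duration_ms,
                        n_pulses = r$n_pulses,
                        train_rate_hz = r$train_rate_hz)
        }
        pharm <- if (is.na(r$pharmacology) || r$pharmacology == "")
          character() else strsplit(r$pharmacology, ";")[[1]]
        msn_sweep(cell_id = cid, sweep_index = r$sweep_index,
              sample_rate_hz = r$sample_rate_hz, vm = tr$vm_mV,
              step_amplitude_pA = r$step_amplitude_pA,
              step_onset_s = r$step_onset_s, step_offset_s = r$step_offset_s,
              condition = r$condition, protocol = prot,
              pharmacology = pharm)
      })
    }
    cells[[i]] <- cell_recording(
      cell_id = cid, sweeps = sweeps,
      subtype = cell_tab$subtype[i],
      slice_id = cell_tab$slice_id[i], mouse_id = cell_tab$mouse_id[i],
      access_resistance_MOhm = cell_tab$access_resistance_MOhm[i])
  }
  cells
}

#' Adapter contract for vendor episodic files
#'
#' The core package contains no vendor-binary logic. To ingest a vendor
#' episodic file (e.g. an Axon ABF), supply a `reader` function that maps
#' `(path, mapping)` to a [cell_recording()]; this wrapper validates the
#' result so downstream stages can rely on the type invariants. Concrete
#' readers can live behind an optional dependency.
#'
#' @param path vendor file path.
#' @param reader function of `(path, mapping)` returning a `msn_cell`.
#' @param mapping list describing channel/protocol mapping, passed through.
#' @return a validated [cell_recording()].
#' @export
read_vendor_recording <- function(path, reader, mapping = list()) {
  if (!is.function(reader)) parameter_error("`reader` must be a function")
  cell <- reader(path, mapping)
  if (!inherits(cell, "msn_cell")) {
    format_error("vendor reader did not return a cell_recording")
  }
  cell
}

#' Quality-control filter
#'
#' Applies the recording quality rules: cells with access resistance
#' strictly larger than `ra_max_MOhm` (default 30) are discarded; cells with
#' missing access resistance are discarded with their own reason rather than
#' silently kept; optionally, cells whose no-light current-step series
#' contains a zero-spike sweep between the first spiking sweep and the
#' depolarization-block sweep (a "discontinuous spike train") are discarded.
#' Filtering never raises: the result partitions the input.
#'
#' @param cells list of [cell_recording()] objects.
#' @param ra_max_MOhm access-resistance cutoff; discard iff strictly larger.
#' @param require_continuous_trains check spike-train continuity.
#' @param ... detection parameters passed to [detect_aps()].
#' @return list with `kept` (list of cells) and `discarded` (data.frame with
#'   `cell_id`, `reason`).
#' @export
qc_filter <- function(cells, ra_max_MOhm = 30,
                      require_continuous_trains = TRUE, ...) {
  if (inherits(cells, "msn_cell")) cells <- list(cells)
  kept <- list()
  disc <- list()
  for (cell in cells) {
    ra <- cell$access_resistance_MOhm
    if (is.na(ra)) {
      disc[[length(disc) + 1L]] <- data.frame(cell_id = cell$cell_id,
                                              reason = "missing_Ra")
      next
    }
    if (ra > ra_max_MOhm) {
      disc[[length(disc) + 1L]] <- data.frame(cell_id = cell$cell_id,
                                              reason = "Ra")
      next
    }
    if (require_continuous_trains) {
      sw <- fi_sweeps(cell, "no_light")
      if (length(sw) > 0) {
        n_aps <- vapply(sw, function(s) nrow(detect_aps(s, ...)), integer(1))
        spiking <- which(n_aps > 0)
        if (length(spiking) > 0) {
          first <- min(spiking)
          last <- max(spiking)
          if (any(n_aps[first:last] == 0)) {
            disc[[length(disc) + 1L]] <- data.frame(
              cell_id = cell$cell_id, reason = "discontinuous_train")
            next
          }
        }
      }
    }
    kept[[length(kept) + 1L]] <- cell
  }
  discarded <- if (length(disc)) do.call(rbind, disc) else
    data.frame(cell_id = character(), reason = character())
  list(kept = kept, discarded = discarded)
}
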