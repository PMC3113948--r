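# Minimal EDF (16-bit European Data Format) writer/reader plus a CSV
# annotation sidecar, so synthetic sessions round-trip to disk and real
# recordings in the same layout can replace them. One data record per
# second; channels are scaled symmetrically to the 16-bit range.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width) # left-aligned, space padded
}

#' Write a session to an EDF file with an annotation sidecar
#'
#' `write_session()` writes `<prefix>.edf` (the multichannel signal) and
#' `<prefix>_annotations.csv` (columns `start_sample`, `end_sample`,
#' `class_id`, `phase`; half-open 0-based intervals). `read_session()` reads
#' the pair back into an [emg_session()]; amplitudes are subject to 16-bit
#' quantization.
#'
#' @param session An [emg_session()]; the sampling rate must be a whole
#'   number of samples per second.
#' @param prefix Output path prefix (without extension).
#' @return `write_session()` returns the prefix invisibly; `read_session()`
#'   returns an `emg_session`.
#' @export
write_session <- function(session, prefix) {
  stopifnot(inherits(session, "emg_session"))
  write_edf(session$signal, session$fs, paste0(prefix, ".edf"))
  ann <- session$annotations
  utils::write.csv(
    data.frame(start_sample = ann$start, end_sample = ann$end,
               class_id = ann$class_id, phase = ann$phase),
    paste0(prefix, "_annotations.csv"), row.names = FALSE
  )
  invisible(prefix)
}

#' @rdname write_session
#' @param subject_id,session_index Provenance carried into the returned
#'   object.
#' @export
read_session <- function(prefix, subject_id = NA, session_index = NA) {
  sig <- read_edf(paste0(prefix, ".edf"))
  ann <- utils::read.csv(paste0(prefix, "_annotations.csv"),
                         stringsAsFactors = FALSE)
  n <- max(ann$end_sample)
  emg_session(sig$signal[, seq_len(n), drop = FALSE], sig$fs,
              tibble(start = ann$start_sample, end = ann$end_sample,
                     class_id = ann$class_id, phase = ann$phase),
              subject_id = subject_id, session = session_index)
}

write_edf <- function(signal, fs, path) {
  signal <- as.matrix(signal)
  if (fs != round(fs)) abort("EDF export requires an integer sampling rate.")
  ns <- nrow(signal)
  n <- ncol(signal)
  n_rec <- ceiling(n / fs)
  pad_n <- n_rec * fs - n
  if (pad_n > 0) signal <- cbind(signal, matrix(0, ns, pad_n))

  pm <- apply(abs(signal), 1, max)
  pm[pm == 0] <- 1
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic subject", 80),
    edf_pad("emgdyn session", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(seq_len(ns), function(i) edf_pad(sprintf("EMG ch%d", i), 16),
                 ""), collapse = ""),
    paste(rep(edf_pad("AgAgCl bipolar", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pm, function(p) edf_pad(sprintf("%.6g", -p), 8), ""),
          collapse = ""),
    paste(vapply(pm, function(p) edf_pad(sprintf("%.6g", p), 8), ""),
          collapse = ""),
    paste(rep(edf_pad(-dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("BP 47-440 Hz", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)

  scale <- dig_max / pm
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round(signal[, idx, drop = FALSE] * scale)
    for (ch in seq_len(ns)) {
      writeBin(as.integer(block[ch, ]), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rd_sig <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  rd_sig(16); rd_sig(80); rd_sig(8)
  phys_min <- as.numeric(rd_sig(8))
  phys_max <- as.numeric(rd_sig(8))
  dig_min <- as.numeric(rd_sig(8))
  dig_max <- as.numeric(rd_sig(8))
  rd_sig(80)
  spr <- as.integer(rd_sig(8)) # samples per record per channel
  rd_sig(32)

  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little",
                   signed = TRUE)
      out[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        phys_min[ch] + (d - dig_min[ch]) *
          (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
    }
  }
  list(signal = out, fs = spr[1] / rec_dur)
}

#' Write or read a whole dataset directory
#'
#' `write_dataset()` lays a [generate_dataset()] result out as one EDF +
#' annotation CSV pair per subject and session (`subNN_sesM.edf`), plus a
#' `subjects.csv` manifest. `read_dataset()` reads such a directory back
#' into the in-memory structure accepted by [run_experiment()].
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Target directory (created if needed).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns the dataset list.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (s in dataset) {
    for (k in seq_along(s$sessions)) {
      prefix <- file.path(dir, sprintf("sub%02d_ses%d", s$subject$id, k))
      write_session(s$sessions[[k]], prefix)
    }
    manifest[[length(manifest) + 1L]] <- data.frame(
      subject = s$subject$id, n_sessions = length(s$sessions),
      snr_db = s$subject$snr_db, seed = s$subject$seed
    )
  }
  utils::write.csv(do.call(rbind, manifest), file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "subjects.csv")
  if (!file.exists(man_path)) {
    abort(sprintf("no subjects.csv manifest in '%s'.", dir))
  }
  man <- utils::read.csv(man_path)
  lapply(seq_len(nrow(man)), function(i) {
    id <- man$subject[i]
    sessions <- lapply(seq_len(man$n_sessions[i]), function(k) {
      prefix <- file.path(dir, sprintf("sub%02d_ses%d", id, k))
      if (!file.exists(paste0(prefix, "_annotations.csv"))) {
        abort(sprintf("missing annotation sidecar for subject %d session %d.",
                      id, k))
      }
      read_session(prefix, subject_id = id, session_index = k)
    })
    list(subject = list(id = id, snr_db = man$snr_db[i]), sessions = sessions)
  })
}
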