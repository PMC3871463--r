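#' Voltage-command protocol
#'
#' A per-sweep sequence of constant-voltage epochs.  Exactly one epoch may
#' vary across sweeps (its level is `NA` in the epoch table and is taken
#' per sweep from `sweep_levels`).  Time origin is t = 0 at sweep start
#' and epochs are half-open `[start, end)` intervals.
#'
#' @param holding holding potential (mV); also used to seed the simulator
#'   state before the first epoch.
#' @param epochs data.frame with columns `level` (mV, `NA` for the varying
#'   epoch) and `duration` (ms, > 0).
#' @param sweep_levels per-sweep level (mV) of the varying epoch; may be
#'   `NULL` when no epoch varies (single sweep).
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(holding, epochs, sweep_levels = NULL) {
  stopifnot(is.numeric(holding), length(holding) == 1L, is.finite(holding))
  stopifnot(is.data.frame(epochs), all(c("level", "duration") %in% names(epochs)))
  if (any(epochs$duration <= 0)) {
    stop("epoch durations must be positive", call. = FALSE)
  }
  varying <- which(is.na(epochs$level))
  if (length(varying) > 1L) {
    stop("at most one epoch may vary across sweeps", call. = FALSE)
  }
  if (length(varying) == 1L && is.null(sweep_levels)) {
    stop("sweep_levels required when an epoch varies", call. = FALSE)
  }
  if (length(varying) == 0L && !is.null(sweep_levels) &&
      length(sweep_levels) > 1L) {
    stop("sweep_levels given but no epoch varies", call. = FALSE)
  }
  structure(list(holding = holding, epochs = epochs,
                 sweep_levels = sweep_levels,
                 varying_epoch = if (length(varying)) varying else NA_integer_),
            class = "voltage_protocol")
}

#' Number of sweeps in a protocol
#' @param prot a [voltage_protocol()].
#' @return Integer sweep count.
#' @export
n_sweeps <- function(prot) {
  stopifnot(inherits(prot, "voltage_protocol"))
  if (is.null(prot$sweep_levels)) 1L else length(prot$sweep_levels)
}

#' Total sweep duration of a protocol (ms)
#' @param prot a [voltage_protocol()].
#' @return Duration in ms (identical for every sweep).
#' @export
protocol_duration <- function(prot) {
  stopifnot(inherits(prot, "voltage_protocol"))
  sum(prot$epochs$duration)
}

# Start/end times (ms) of each epoch; half-open [start, end).
epoch_bounds <- function(prot) {
  ends <- cumsum(prot$epochs$duration)
  data.frame(start = c(0, ends[-length(ends)]), end = ends)
}

#' Tail-current protocol builder
#'
#' Sweeps step from the holding potential to prepulse levels enumerated
#' from `pre_from` to `pre_to` in steps of `dV`, then every sweep jumps to
#' a common tail potential to elicit tail currents (e.g. prepulses -100 to
#' +200 mV in 20 mV steps followed by 5 ms at -200 mV).
#'
#' @param hold holding potential (mV).
#' @param pre_from,pre_to first/last prepulse level (mV), `pre_to >= pre_from`.
#' @param dV prepulse increment (mV), > 0; must divide `pre_to - pre_from`.
#' @param pre_dur prepulse duration (ms).
#' @param tail_V,tail_dur tail potential (mV) and duration (ms).
#' @param hold_dur duration of the initial holding epoch (ms).
#' @return A [voltage_protocol()] whose varying epoch is the prepulse.
#' @export
build_tail_protocol <- function(hold, pre_from, pre_to, dV, pre_dur,
                                tail_V, tail_dur, hold_dur = 10) {
  stopifnot(dV > 0, pre_to >= pre_from)
  span <- pre_to - pre_from
  if (abs(span / dV - round(span / dV)) > 1e-9) {
    stop("prepulse range is not divisible by dV", call. = FALSE)
  }
  levels <- seq(pre_from, pre_to, by = dV)
  voltage_protocol(
    holding = hold,
    epochs = data.frame(level = c(hold, NA, tail_V),
                        duration = c(hold_dur, pre_dur, tail_dur)),
    sweep_levels = levels)
}

#' Instantaneous I-V protocol builder
#'
#' A fixed depolarizing prepulse (to open channels maximally) followed by
#' test potentials enumerated from `test_from` to `test_to`; the
#' instantaneous current immediately after the jump reports the open-pore
#' I-V relation.
#'
#' @param hold holding potential (mV).
#' @param pre_V,pre_dur fixed prepulse level (mV) and duration (ms).
#' @param test_from,test_to,dV test-potential range (mV) and step (> 0).
#' @param test_dur test epoch duration (ms).
#' @param hold_dur duration of the initial holding epoch (ms).
#' @return A [voltage_protocol()] whose varying epoch is the test epoch.
#' @export
build_instantaneous_iv_protocol <- function(hold, pre_V, pre_dur,
                                            test_from, test_to, dV,
                                            test_dur, hold_dur = 10) {
  stopifnot(dV > 0, test_to >= test_from)
  span <- test_to - test_from
  if (abs(span / dV - round(span / dV)) > 1e-9) {
    stop("test range is not divisible by dV", call. = FALSE)
  }
  levels <- seq(test_from, test_to, by = dV)
  voltage_protocol(
    holding = hold,
    epochs = data.frame(level = c(hold, pre_V, NA),
                        duration = c(hold_dur, pre_dur, test_dur)),
    sweep_levels = levels)
}

#' Scale every commanded voltage of a protocol
#'
#' Used to construct P/-4 sub-sweep commands (factor -1/4).
#'
#' @param prot a [voltage_protocol()].
#' @param factor multiplicative factor applied to holding, epoch levels
#'   and sweep levels.
#' @return A scaled [voltage_protocol()].
#' @export
scale_protocol <- function(prot, factor) {
  stopifnot(inherits(prot, "voltage_protocol"), is.numeric(factor))
  ep <- prot$epochs
  ep$level <- ep$level * factor
  voltage_protocol(prot$holding * factor, ep,
                   if (is.null(prot$sweep_levels)) NULL
                   else prot$sweep_levels * factor)
}

#' Commanded voltage waveform, sampled
#'
#' @param prot a [voltage_protocol()].
#' @param dt sampling interval (ms).
#' @return A sweeps x samples matrix of commanded voltage (mV).
#' @export
command_waveform <- function(prot, dt) {
  stopifnot(inherits(prot, "voltage_protocol"), dt > 0)
  counts <- round(prot$epochs$duration / dt)
  ns <- n_sweeps(prot)
  out <- matrix(0, nrow = ns, ncol = sum(counts))
  for (s in seq_len(ns)) {
    lev <- prot$epochs$level
    if (!is.na(prot$varying_epoch)) {
      lev[prot$varying_epoch] <- prot$sweep_levels[s]
    }
    out[s, ] <- rep(lev, times = counts)
  }
  out
}

#' Multi-sweep current recording
#'
#' Container for time-aligned current traces: a sweeps x samples matrix in
#' pA with its sampling interval, the protocol that produced it, the
#' analog filter cutoff and free-form provenance metadata.  A companion
#' background recording (agonist-free, seal noise only) may be attached as
#' `seal`.
#'
#' @param traces sweeps x samples numeric matrix (pA).
#' @param dt sampling interval (ms).
#' @param protocol a [voltage_protocol()] or `NULL`.
#' @param filter_khz low-pass cutoff applied to the traces (kHz), or `NA`.
#' @param meta named list of provenance (seed, model id, units, ...).
#' @param seal optional companion `sweep_set` of background sweeps.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(traces, dt, protocol = NULL, filter_khz = NA_real_,
                      meta = list(), seal = NULL) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1L)
  stopifnot(is.matrix(traces), is.numeric(traces))
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "voltage_protocol"))
    expect <- round(protocol_duration(protocol) / dt)
    if (abs(ncol(traces) - expect) > 1L) {
      stop("sample count does not match protocol duration", call. = FALSE)
    }
  }
  structure(list(traces = traces, dt = dt, protocol = protocol,
                 filter_khz = filter_khz, meta = meta, seal = seal),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("sweep_set: %d sweeps x %d samples, dt = %g ms (fs = %g kHz)\n",
              nrow(x$traces), ncol(x$traces), x$dt, 1 / x$dt))
  if (!is.na(x$filter_khz)) cat(sprintf("  low-pass: %g kHz\n", x$filter_khz))
  if (!is.null(x$seal)) cat("  paired background (seal) sweeps attached\n")
  invisible(x)
}

# --- 4-pole Bessel low-pass -------------------------------------------------

# Analog prototype poles of the 4th-order Bessel filter, frequency-scaled
# so that |H| = -3 dB at omega = 1.  Poles are the roots of the reversed
# Bessel polynomial s^4 + 10 s^3 + 45 s^2 + 105 s + 105.
bessel4_prototype <- function() {
  p <- polyroot(c(105, 105, 45, 10, 1))
  gain <- 105
  magsq <- function(w) {
    h <- gain / Reduce(`*`, lapply(p, function(pk) 1i * w - pk))
    Mod(h)^2
  }
  w3 <- stats::uniroot(function(w) magsq(w) - 0.5, c(0.1, 10),
                       tol = 1e-12)$root
  list(poles = p / w3, gain = gain / w3^4)
}

# Digital 4-pole Bessel low-pass (bilinear transform with prewarping).
# fc, fs in kHz; returns list(b, a) filter coefficients.
bessel4_lowpass <- function(fc, fs) {
  proto <- bessel4_prototype()
  T <- 1 / fs
  # prewarp so the digital -3 dB point lands at fc
  wa <- (2 / T) * tan(pi * fc * T)          # rad/ms
  zpg <- signal::bilinear(Sz = complex(0), Sp = proto$poles * wa,
                          Sg = proto$gain * wa^4, T = T)
  arma <- signal::as.Arma(zpg)
  list(b = Re(arma$b), a = Re(arma$a))
}

#' White-noise r.m.s. gain of the recording filter
#'
#' Fraction of the r.m.s. of white Gaussian noise (sampled at `fs`) that
#' survives the 4-pole Bessel low-pass at `fc`, computed by numerical
#' integration of the filter's squared magnitude response (equivalent
#' noise bandwidth).  Used so that a quoted seal-noise r.m.s. refers to
#' the stated bandwidth.
#'
#' @param fc cutoff (kHz); @param fs sampling rate (kHz).
#' @return Scalar r.m.s. gain in (0, 1\].
#' @export
filter_noise_gain <- function(fc, fs) {
  co <- bessel4_lowpass(fc, fs)
  fr <- signal::freqz(co$b, co$a, n = 8192)
  sqrt(mean(Mod(fr$h)^2))
}

#' Low-pass filter a recording
#'
#' Applies a causal digital 4-pole Bessel-type low-pass (DC gain 1) to
#' every sweep, emulating the recording amplifier's output filter.
#'
#' @param rec a [sweep_set()].
#' @param fc cutoff frequency (kHz); must be below the Nyquist rate.
#' @return The filtered `sweep_set` with `filter_khz` updated.
#' @export
lowpass <- function(rec, fc) {
  stopifnot(inherits(rec, "sweep_set"), is.numeric(fc), fc > 0)
  fs <- 1 / rec$dt
  if (fc >= fs / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  co <- bessel4_lowpass(fc, fs)
  out <- rec
  for (s in seq_len(nrow(rec$traces))) {
    # pad with the initial level so the causal filter starts settled
    x <- rec$traces[s, ]
    pad <- rep(x[1], 64L)
    y <- signal::filter(co$b, co$a, c(pad, x))
    out$traces[s, ] <- y[-seq_along(pad)]
  }
  out$filter_khz <- fc
  out
}

#' P/-4 leak and capacitance subtraction
#'
#' Classic correction: four sub-sweeps driven at -1/4 of the main command
#' are averaged, scaled by 4 and added to the main sweep, so any strictly
#' linear (ohmic plus linear-capacitive) membrane response cancels exactly
#' while nonlinear components (gating charge) survive.
#'
#' @param main a [sweep_set()] recorded under the main command.
#' @param subs a [sweep_set()] holding 4 sub-sweeps per main sweep, in
#'   order (rows 1-4 belong to main sweep 1, etc.).
#' @return The corrected `sweep_set`.
#' @export
p_over_minus4 <- function(main, subs) {
  stopifnot(inherits(main, "sweep_set"), inherits(subs, "sweep_set"))
  nm <- nrow(main$traces)
  if (nrow(subs$traces) != 4L * nm) {
    stop("subs must hold exactly 4 sub-sweeps per main sweep", call. = FALSE)
  }
  if (ncol(subs$traces) != ncol(main$traces)) {
    stop("main and sub-sweeps differ in length", call. = FALSE)
  }
  out <- main
  for (s in seq_len(nm)) {
    grp <- subs$traces[(4L * s - 3L):(4L * s), , drop = FALSE]
    out$traces[s, ] <- main$traces[s, ] + 4 * colMeans(grp)
  }
  out$meta$p_over_minus4 <- TRUE
  out
}

# --- Axon Text File (ATF) I/O ----------------------------------------------

#' Write a recording as an Axon Text File
#'
#' Minimal tab-separated ATF dialect: version line `ATF<TAB>1.0`, a header
#' line with the optional-record and column counts, quoted optional
#' `key=value` records, a column-title line (time in ms, one current
#' column per sweep in pA), then the data.
#'
#' @param rec a [sweep_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_atf <- function(rec, path) {
  stopifnot(inherits(rec, "sweep_set"))
  ns <- nrow(rec$traces)
  np <- ncol(rec$traces)
  con <- file(path, "w")
  on.exit(close(con))
  optional <- sprintf("\"filter_khz=%s\"",
                      ifelse(is.na(rec$filter_khz), "NA", rec$filter_khz))
  writeLines(c("ATF\t1.0",
               sprintf("%d\t%d", length(optional), ns + 1L),
               optional,
               paste(c("\"Time (ms)\"",
                       sprintf("\"Trace #%d (pA)\"", seq_len(ns))),
                     collapse = "\t")), con)
  tt <- (seq_len(np) - 1L) * rec$dt
  dat <- cbind(tt, t(rec$traces))
  utils::write.table(format(dat, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an Axon Text File
#'
#' Parses the dialect written by [write_atf()].  Malformed headers and
#' ragged data lines raise errors naming the offending line.
#'
#' @param path input file path.
#' @return A [sweep_set()] (protocol `NULL`; dt and filter cutoff
#'   recovered from the file).
#' @export
read_atf <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty ATF file: ", path, call. = FALSE)
  if (!grepl("^ATF\t", lines[1])) {
    stop("line 1: not an ATF version line", call. = FALSE)
  }
  if (length(lines) < 2L) stop("line 2: missing header counts", call. = FALSE)
  hdr <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("line 2: malformed header counts", call. = FALSE)
  }
  n_opt <- as.integer(hdr[1]); n_col <- as.integer(hdr[2])
  filter_khz <- NA_real_
  for (i in seq_len(n_opt)) {
    rec <- gsub("\"", "", lines[2L + i])
    if (grepl("^filter_khz=", rec)) {
      filter_khz <- suppressWarnings(as.numeric(sub("filter_khz=", "", rec)))
    }
  }
  title_ln <- 3L + n_opt
  if (length(lines) < title_ln + 1L) {
    stop("line ", title_ln, ": missing column titles or data", call. = FALSE)
  }
  data_lines <- lines[(title_ln + 1L):length(lines)]
  data_lines <- data_lines[nzchar(data_lines)]
  if (length(data_lines) == 0L) {
    stop("no data rows in ATF file: ", path, call. = FALSE)
  }
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != n_col)
  if (length(bad)) {
    stop("line ", title_ln + bad[1],
         ": expected ", n_col, " columns, found ",
         length(parts[[bad[1]]]), call. = FALSE)
  }
  mat <- matrix(as.numeric(unlist(parts)), ncol = n_col, byrow = TRUE)
  if (anyNA(mat)) stop("non-numeric data in ATF file: ", path, call. = FALSE)
  tt <- mat[, 1]
  dt <- if (length(tt) > 1L) stats::median(diff(tt)) else 1
  sweep_set(t(mat[, -1, drop = FALSE]), dt = dt,
            filter_khz = filter_khz,
            meta = list(source = path))
}

#' Write / read derived curve tables as CSV
#'
#' Curve tables (`V_mV`, `value`, `sem`, `n`) are exchanged as plain CSV.
#'
#' @param df a data.frame (typically a [curve_table()]).
#' @param path file path.
#' @return `write_table` returns `path` invisibly; `read_table` returns a
#'   data.frame.
#' @export
write_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path)
}
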