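#' Stationary variance-to-mean noise analysis
#'
#' For each sweep (voltage) the current variance over a stationary window
#' is computed for the agonist-activated recording and for its paired
#' background (seal) recording; the background is subtracted and the
#' ratio `sigma^2 / I_mean` formed.  For a homogeneous population of
#' two-state channels this ratio equals `i_sc(V) * (1 - Po(V))`.
#'
#' Background subtraction defaults to variances (quadrature), which is
#' exact for independent noise sources; `mode = "rms"` reproduces the
#' literal r.m.s. difference `(sd_cgmp - sd_seal)^2` sometimes quoted.
#'
#' @param rec_cgmp a [sweep_set()] with channels active; if `rec_seal` is
#'   `NULL` its attached `$seal` companion is used.
#' @param rec_seal matching background [sweep_set()] (same protocol).
#' @param window time window `c(t0, t1)` (ms from sweep start) over which
#'   the segment is stationary; defaults to the last half of the varying
#'   epoch.
#' @param mode `"variance"` (default) or `"rms"` background subtraction.
#' @param floor_pA points with `|I_mean|` below this floor are masked.
#' @return A data.frame of class `noise_table`: `V_mV`, `I_mean` (pA),
#'   `var_cgmp`, `var_seal` (pA^2) and `ratio` = sigma^2/I (pA).
#' @export
variance_to_mean <- function(rec_cgmp, rec_seal = NULL, window = NULL,
                             mode = c("variance", "rms"), floor_pA = 0.5) {
  stopifnot(inherits(rec_cgmp, "sweep_set"))
  mode <- match.arg(mode)
  if (is.null(rec_seal)) rec_seal <- rec_cgmp$seal
  if (is.null(rec_seal)) stop("no background recording supplied", call. = FALSE)
  stopifnot(inherits(rec_seal, "sweep_set"))
  if (nrow(rec_seal$traces) != nrow(rec_cgmp$traces) ||
      ncol(rec_seal$traces) != ncol(rec_cgmp$traces)) {
    stop("background recording does not match the main recording",
         call. = FALSE)
  }
  prot <- rec_cgmp$protocol
  if (is.null(prot)) stop("recording carries no protocol", call. = FALSE)
  if (is.null(window)) {
    ve <- prot$varying_epoch
    if (is.na(ve)) ve <- nrow(prot$epochs)
    eb <- epoch_bounds(prot)
    window <- c((eb$start[ve] + eb$end[ve]) / 2, eb$end[ve])
  }
  idx <- window_index(rec_cgmp$dt, ncol(rec_cgmp$traces),
                      window[1], window[2])
  V <- if (is.null(prot$sweep_levels)) prot$epochs$level[prot$varying_epoch]
       else prot$sweep_levels
  I_mean <- rowMeans(rec_cgmp$traces[, idx, drop = FALSE]) -
    rowMeans(rec_seal$traces[, idx, drop = FALSE])
  v_c <- apply(rec_cgmp$traces[, idx, drop = FALSE], 1L, stats::var)
  v_s <- apply(rec_seal$traces[, idx, drop = FALSE], 1L, stats::var)
  sig2 <- if (mode == "variance") {
    pmax(v_c - v_s, 0)
  } else {
    pmax(sqrt(v_c) - sqrt(v_s), 0)^2
  }
  ratio <- ifelse(abs(I_mean) < floor_pA, NA_real_, sig2 / I_mean)
  o <- order(V)
  structure(data.frame(V_mV = V[o], I_mean = I_mean[o],
                       var_cgmp = v_c[o], var_seal = v_s[o],
                       ratio = ratio[o]),
            class = c("noise_table", "data.frame"), mode = mode)
}

#' Predicted variance-to-mean curve of a channel model
#'
#' The closed-form expectation `i_sc(V) * (1 - Po(V))` used to overlay
#' measured noise tables.
#'
#' @param model a [channel_model()].
#' @param V voltage grid (mV).
#' @return A [curve_table()] labelled `tau`-free `ratio` values (pA).
#' @export
predicted_ratio <- function(model, V) {
  stopifnot(inherits(model, "channel_model"))
  isc <- open_pore_current(V, model$perm)
  po <- eval_two_boltzmann(V, model$po_law)
  curve_table(sort(V), (isc * (1 - po))[order(V)], label = "ratio_pred")
}

#' Absolute open probability from stationary noise
#'
#' `Po = 1 - (sigma^2/I) / i_sc`, the anchor used to scale relative
#' Po curves to absolute values.
#'
#' @param ratio measured sigma^2/I at one voltage (pA).
#' @param i_sc single-channel current at the same voltage (pA), non-zero.
#' @return A list: `Po` (clamped to \[0, 1\]) and `out_of_range` flag.
#' @export
absolute_po_from_noise <- function(ratio, i_sc) {
  if (!is.numeric(i_sc) || any(i_sc == 0)) {
    stop("i_sc must be non-zero", call. = FALSE)
  }
  po <- 1 - ratio / i_sc
  list(Po = pmin(pmax(po, 0), 1), out_of_range = po < 0 | po > 1)
}

#' Fractional r.m.s. inflation from open-channel noise
#'
#' If open channels carry excess noise `sigma_o = r * i_sc`, the total
#' fluctuation is `sigma_tot^2 = sigma^2 + sigma_e^2` with
#' `sigma^2 = N i_sc^2 Po (1 - Po)` and `sigma_e^2 = N Po sigma_o^2`; the
#' channel count and the single-channel current cancel, leaving the
#' fractional increase `sqrt(1 + r^2 / (1 - Po)) - 1`, which depends only
#' on `sigma_o/i_sc` and `Po`.  At `r = 0.5`, `Po = 0.5` this is ~22%
#' (under 25%); at the typical `r = 0.1` it is ~1%.
#'
#' @param sigma_o_over_i ratio sigma_o / i_sc (>= 0).
#' @param Po open probability, in \[0, 1).
#' @return Fractional r.m.s. increase (dimensionless).
#' @export
open_noise_inflation <- function(sigma_o_over_i, Po) {
  stopifnot(is.numeric(sigma_o_over_i), all(sigma_o_over_i >= 0))
  if (any(Po < 0) || any(Po >= 1)) {
    stop("Po must lie in [0, 1): inflation is undefined at Po = 1",
         call. = FALSE)
  }
  sqrt(1 + sigma_o_over_i^2 / (1 - Po)) - 1
}

#' All-point amplitude histogram
#'
#' Pools every sample of the recording into an amplitude histogram; the
#' default bin width is one fifth of the closed-state (seal) noise s.d.
#'
#' @param rec a [sweep_set()] (single-channel scale).
#' @param bin_width bin width (pA); default `seal_sd / 5`.
#' @param seal_sd closed-state noise s.d. (pA); estimated from the
#'   attached `$seal` companion when absent.
#' @return A data.frame `mid` (bin center, pA), `count`.
#' @export
amplitude_histogram <- function(rec, bin_width = NULL, seal_sd = NULL) {
  stopifnot(inherits(rec, "sweep_set"))
  x <- as.vector(rec$traces)
  if (length(x) == 0L) stop("empty recording", call. = FALSE)
  if (is.null(bin_width)) {
    if (is.null(seal_sd)) {
      if (is.null(rec$seal)) {
        stop("supply bin_width or seal_sd (no background attached)",
             call. = FALSE)
      }
      seal_sd <- stats::sd(as.vector(rec$seal$traces))
    }
    bin_width <- seal_sd / 5
  }
  breaks <- seq(floor(min(x) / bin_width) * bin_width,
                ceiling(max(x) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}

#' Gaussian-mixture fit of an amplitude distribution / channel counting
#'
#' Maximum-likelihood Gaussian mixture fit of the all-point amplitude
#' distribution with model selection over 1..4 components by BIC.  For a
#' patch holding `n` identical channels the closed level plus `n` open
#' levels give `n + 1` components, so the inferred channel count is the
#' selected number of components minus one.
#'
#' @param rec a [sweep_set()] or a numeric vector of samples (pA).
#' @param n_components `NULL` (BIC selection over `max_components`) or a
#'   fixed component count.
#' @param max_components upper bound for model selection (default 4).
#' @param max_points samples are thinned to at most this many points
#'   before fitting (default 5000).  Thinning both bounds the cost and
#'   keeps the BIC penalty honest: consecutive samples of a filtered
#'   dwell are strongly correlated, and model selection over effectively
#'   duplicated observations favours spurious extra components.
#' @return An object of class `histogram_fit`: `means`, `sds`, `weights`
#'   (summing to 1), `n_components`, `channel_count`, `bic`.
#' @importFrom mclust mclustBIC
#' @export
fit_gaussian_mixture <- function(rec, n_components = NULL,
                                 max_components = 4, max_points = 5000) {
  x <- if (inherits(rec, "sweep_set")) as.vector(rec$traces) else as.numeric(rec)
  if (length(x) == 0L) stop("empty recording", call. = FALSE)
  if (length(x) > max_points) {
    x <- x[round(seq(1, length(x), length.out = max_points))]
  }
  G <- if (is.null(n_components)) seq_len(max_components) else n_components
  fit <- mclust::Mclust(x, G = G, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
  o <- order(fit$parameters$mean)
  structure(list(
    means = unname(fit$parameters$mean[o]),
    sds = unname(sqrt(fit$parameters$variance$sigmasq))[
      if (length(fit$parameters$variance$sigmasq) > 1L) o else 1L],
    weights = unname(fit$parameters$pro[o]),
    n_components = fit$G,
    channel_count = fit$G - 1L,
    bic = unclass(fit$bic)), class = "histogram_fit")
}

#' @export
print.histogram_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture: %d components -> %d channel(s)\n",
              x$n_components, x$channel_count))
  for (i in seq_len(x$n_components)) {
    cat(sprintf("  level %d: mean %7.3f pA, sd %6.3f, weight %.3f\n",
                i - 1L, x$means[i],
                x$sds[min(i, length(x$sds))], x$weights[i]))
  }
  invisible(x)
}
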