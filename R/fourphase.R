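#' Construct a four-phase rhinomanometry recording
#'
#' A 4-PR recording samples the differential pressure between nasopharynx and
#' mask together with the volume flux over (part of) a respiration cycle.
#' Units are fixed to the rhinomanometric convention: pressure in Pa, volume
#' flux in cm^3/s (positive at inspiration, negative at expiration), time in
#' seconds.
#'
#' @param t numeric vector of sample times in seconds, strictly increasing.
#' @param delta_p numeric vector, differential pressure in Pa.
#' @param vdot numeric vector, signed volume flux in cm^3/s.
#' @param side one of `"left"`, `"right"`, `"total"`.
#' @return An object of class `four_phase_recording` with fields `t`,
#'   `delta_p`, `vdot`, `side` and the cycle duration `T` (seconds).
#' @export
four_phase_recording <- function(t, delta_p, vdot,
                                 side = c("left", "right", "total")) {
  side <- match.arg(side)
  if (length(t) < 4L)
    stop("a recording needs at least 4 samples")
  if (length(delta_p) != length(t) || length(vdot) != length(t))
    stop("t, delta_p and vdot must have equal length")
  if (anyNA(t) || anyNA(delta_p) || anyNA(vdot))
    stop("recording contains missing values")
  if (any(diff(t) <= 0))
    stop("non-monotone time")
  rec <- structure(
    list(t = as.numeric(t), delta_p = as.numeric(delta_p),
         vdot = as.numeric(vdot), side = side,
         T = t[length(t)] - t[1L]),
    class = "four_phase_recording")
  rec$full_cycle <- any(diff(sign(rec$vdot[rec$vdot != 0])) != 0)
  rec
}

#' @export
print.four_phase_recording <- function(x, ...) {
  cat(sprintf("<four_phase_recording> side=%s, %d samples, T=%.3g s, flux range [%.3g, %.3g] cm^3/s\n",
              x$side, length(x$t), x$T, min(x$vdot), max(x$vdot)))
  invisible(x)
}

#' Read a 4-PR waveform CSV
#'
#' Expects a header with columns `time_s`, `delta_p_pa`, `vdot_cm3s`.
#'
#' @param path path to the CSV file.
#' @param side nasal side the recording belongs to.
#' @return A [four_phase_recording()].
#' @export
load_recording <- function(path, side = c("left", "right", "total")) {
  side <- match.arg(side)
  df <- utils::read.csv(path)
  need <- c("time_s", "delta_p_pa", "vdot_cm3s")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  four_phase_recording(df$time_s, df$delta_p_pa, df$vdot_cm3s, side = side)
}

#' Write a 4-PR waveform CSV
#'
#' @param rec a [four_phase_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "four_phase_recording"))
  utils::write.csv(
    data.frame(time_s = rec$t, delta_p_pa = rec$delta_p, vdot_cm3s = rec$vdot),
    path, row.names = FALSE)
  invisible(path)
}

# trapezoidal quadrature over possibly non-uniform samples
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Effective nasal resistance over a respiration cycle
#'
#' The effective resistance relates the effective (RMS) differential
#' pressure to the effective volume flux, `R_eff = dp_eff / vdot_eff`.
#' Two evaluations are available:
#' \describe{
#'   \item{`rms_ratio`}{`RMS(delta_p) / RMS(vdot)` with RMS values computed
#'     by trapezoidal quadrature over the cycle (the defining equality;
#'     default).}
#'   \item{`printed_integral`}{`sqrt(mean(delta_p/vdot))` with the time mean
#'     taken by trapezoidal quadrature over the part of the cycle where
#'     `|vdot|` is at least `flux_floor` times the cycle maximum, which
#'     excludes the division blow-up at flow reversal. Note the two forms
#'     only agree for `R_eff = 1`; for `delta_p = c * vdot` the first gives
#'     `c`, the second `sqrt(c)`.}
#' }
#'
#' @param rec a [four_phase_recording()].
#' @param method `"rms_ratio"` (default) or `"printed_integral"`.
#' @param flux_floor fraction of the cycle's maximum `|vdot|` below which
#'   samples are excluded from the `printed_integral` integrand.
#' @return Effective resistance in Pa*s/cm^3.
#' @export
effective_resistance <- function(rec,
                                 method = c("rms_ratio", "printed_integral"),
                                 flux_floor = 0.01) {
  stopifnot(inherits(rec, "four_phase_recording"))
  method <- match.arg(method)
  if (all(rec$vdot == 0)) stop("degenerate recording: vdot identically zero")
  if (method == "rms_ratio") {
    num <- trapz(rec$t, rec$delta_p^2)
    den <- trapz(rec$t, rec$vdot^2)
    if (den <= 0) stop("degenerate recording: zero effective flux")
    return(sqrt(num / den))
  }
  floor_abs <- flux_floor * max(abs(rec$vdot))
  keep <- abs(rec$vdot) >= floor_abs
  if (!any(keep)) stop("degenerate recording: all samples below flux floor")
  ratio <- rec$delta_p / rec$vdot
  if (any(ratio[keep] < 0))
    warning("delta_p/vdot negative above the flux floor; integrand clipped at 0")
  ratio <- pmax(ratio, 0)
  # integrate over the contiguous kept runs and normalize by the kept time
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  tot <- 0; T_kept <- 0
  for (k in seq_along(runs$values)) {
    if (!runs$values[k] || runs$lengths[k] < 2L) next
    idx <- starts[k]:ends[k]
    tot <- tot + trapz(rec$t[idx], ratio[idx])
    T_kept <- T_kept + rec$t[ends[k]] - rec$t[starts[k]]
  }
  if (T_kept <= 0) stop("degenerate recording: kept time is zero")
  sqrt(tot / T_kept)
}

#' Vertex resistance at the peak of a respiration phase
#'
#' The vertex resistance is `delta_p / vdot` evaluated at the highest point
#' of the respiration wave (the sample of maximum `|vdot|`) within the
#' requested phase, at quiet breathing.
#'
#' @param rec a [four_phase_recording()].
#' @param phase `"inspiration"` (`vdot > 0`) or `"expiration"` (`vdot < 0`).
#' @return Vertex resistance in Pa*s/cm^3.
#' @export
vertex_resistance <- function(rec, phase = c("inspiration", "expiration")) {
  stopifnot(inherits(rec, "four_phase_recording"))
  phase <- match.arg(phase)
  sel <- if (phase == "inspiration") rec$vdot > 0 else rec$vdot < 0
  if (!any(sel)) stop(sprintf("phase '%s' absent from recording", phase))
  idx <- which(sel)[which.max(abs(rec$vdot[sel]))]
  rec$delta_p[idx] / rec$vdot[idx]
}

#' One-sided logarithmic effective resistance
#'
#' `LR_eff^1 = log10(10 * R_eff)`, the scale on which the clinical
#' obstruction classes are defined.
#'
#' @param r_eff effective resistance in Pa*s/cm^3, must be positive.
#' @return Dimensionless log-resistance.
#' @export
log_effective_resistance <- function(r_eff) {
  if (any(!is.finite(r_eff)) || any(r_eff <= 0))
    stop("r_eff must be positive and finite")
  log10(10 * r_eff)
}

#' Two-sided (combined) logarithmic effective resistance
#'
#' Combines the left and right effective resistances like parallel electric
#' resistors: `LR_eff^2 = log10(10 * r_l*r_r/(r_l+r_r))`.
#'
#' @param r_left,r_right one-sided effective resistances in Pa*s/cm^3.
#' @return Dimensionless combined log-resistance.
#' @export
combined_log_resistance <- function(r_left, r_right) {
  if (any(!is.finite(c(r_left, r_right))) || any(c(r_left, r_right) <= 0))
    stop("resistances must be positive and finite")
  log10(10 * (r_left * r_right) / (r_left + r_right))
}

#' Clinical resistance classification thresholds
#'
#' Returns the printed upper bounds of classes 1..4 on the logarithmic
#' effective resistance scale (class 5 is everything above the last bound).
#' The printed two-sided column is internally non-monotone; the engine uses
#' its upper bounds sorted ascending, so classification stays monotone.
#'
#' @param sided `"one"` or `"two"`.
#' @return Numeric vector of 4 ordered upper bounds.
#' @export
resistance_class_bounds <- function(sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (sided == "one") c(0.755, 0.960, 1.135, 1.365)
  else sort(c(0.423, 0.703, 0.592, 0.755))
}

#' Obstruction class labels
#' @return Character vector of the five class labels.
#' @export
resistance_class_labels <- function() {
  c("very low", "low", "moderate", "high", "very high")
}

#' Classify a logarithmic effective resistance
#'
#' Maps `lr_eff` to one of five obstruction classes using ordered upper
#' bounds (class k is assigned to the smallest k with `lr_eff <= bound[k]`,
#' so values in printed overlap regions resolve to the lower class).
#'
#' @param lr_eff logarithmic effective resistance (finite).
#' @param sided `"one"` for a single nasal side, `"two"` for the combined
#'   resistance.
#' @param bounds optional override of the 4 ordered upper bounds.
#' @return A list with `class` (integer 1..5) and `label`.
#' @export
classify_resistance <- function(lr_eff, sided = c("one", "two"),
                                bounds = NULL) {
  sided <- match.arg(sided)
  if (any(!is.finite(lr_eff))) stop("lr_eff must be finite")
  if (is.null(bounds)) bounds <- resistance_class_bounds(sided)
  if (is.unsorted(bounds)) stop("bounds must be ordered")
  cls <- vapply(lr_eff, function(x) sum(x > bounds) + 1L, integer(1))
  list(class = cls, label = resistance_class_labels()[cls])
}

#' Full 4-PR resistance analysis of one or two sides
#'
#' Computes effective resistance, vertex resistances, log-resistances and
#' obstruction classes; when both sides are supplied the combined two-sided
#' quantity is added.
#'
#' @param left,right optional [four_phase_recording()] objects (at least one).
#' @param method resistance evaluation, see [effective_resistance()].
#' @return A list of class `resistance_result`.
#' @export
analyze_4pr <- function(left = NULL, right = NULL,
                        method = c("rms_ratio", "printed_integral")) {
  method <- match.arg(method)
  if (is.null(left) && is.null(right)) stop("supply at least one recording")
  one_side <- function(rec) {
    if (is.null(rec)) return(NULL)
    r <- effective_resistance(rec, method)
    lr <- log_effective_resistance(r)
    cl <- classify_resistance(lr, "one")
    vr_i <- tryCatch(vertex_resistance(rec, "inspiration"), error = function(e) NA_real_)
    vr_e <- tryCatch(vertex_resistance(rec, "expiration"), error = function(e) NA_real_)
    list(r_eff = r, lr_eff_1 = lr, vr_insp = vr_i, vr_exp = vr_e,
         obstruction_class = cl$class, class_label = cl$label)
  }
  res <- list(method = method,
              left = one_side(left), right = one_side(right))
  if (!is.null(res$left) && !is.null(res$right)) {
    lr2 <- combined_log_resistance(res$left$r_eff, res$right$r_eff)
    cl2 <- classify_resistance(lr2, "two")
    res$combined <- list(lr_eff_2 = lr2, obstruction_class = cl2$class,
                         class_label = cl2$label)
  }
  class(res) <- "resistance_result"
  res
}

#' @export
print.resistance_result <- function(x, ...) {
  cat("<resistance_result> (method:", x$method, ")\n")
  for (s in c("left", "right")) {
    if (is.null(x[[s]])) next
    cat(sprintf("  %-5s R_eff=%.4g Pa.s/cm^3, LR_eff^1=%.4g, class %d (%s)\n",
                s, x[[s]]$r_eff, x[[s]]$lr_eff_1,
                x[[s]]$obstruction_class, x[[s]]$class_label))
  }
  if (!is.null(x$combined))
    cat(sprintf("  total LR_eff^2=%.4g, class %d (%s)\n",
                x$combined$lr_eff_2, x$combined$obstruction_class,
                x$combined$class_label))
  invisible(x)
}

#' Export a resistance result as JSON
#'
#' @param x a `resistance_result` from [analyze_4pr()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_resistance_json <- function(x, path) {
  stopifnot(inherits(x, "resistance_result"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Flux-over-pressure overlay table for measurements and simulations
#'
#' Merges the inspiration/expiration measurement loops with steady
#' simulation operating points (Strouhal number 0) into one plot-ready
#' table of volume flux over pressure loss.
#'
#' @param rec_insp,rec_exp [four_phase_recording()] objects for the two
#'   phases (may be the same full-cycle recording).
#' @param sim_points optional data.frame with columns `delta_p`, `vdot`
#'   (and optionally `sr`, which must be 0 for steady simulations).
#' @return A data.frame with columns `delta_p`, `vdot`, `sr`, `source`,
#'   `phase`.
#' @export
overlay_data <- function(rec_insp, rec_exp, sim_points = NULL) {
  stopifnot(inherits(rec_insp, "four_phase_recording"),
            inherits(rec_exp, "four_phase_recording"))
  meas <- rbind(
    data.frame(delta_p = rec_insp$delta_p, vdot = rec_insp$vdot,
               sr = NA_real_, source = "measurement", phase = "inspiration"),
    data.frame(delta_p = rec_exp$delta_p, vdot = rec_exp$vdot,
               sr = NA_real_, source = "measurement", phase = "expiration"))
  if (!is.null(sim_points) && nrow(sim_points)) {
    if (is.null(sim_points$sr)) sim_points$sr <- 0
    if (any(sim_points$sr != 0))
      stop("steady simulation points must have Strouhal number sr == 0")
    meas <- rbind(meas, data.frame(
      delta_p = sim_points$delta_p, vdot = sim_points$vdot,
      sr = sim_points$sr, source = "simulation", phase = "steady"))
  }
  rownames(meas) <- NULL
  meas
}
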