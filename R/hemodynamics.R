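#' 4D dynamic series container
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param times frame times in seconds, strictly increasing.
#' @param voxel_size_mm voxel size, mm.
#' @return object of class `series4d`.
#' @export
series4d <- function(data, times, voxel_size_mm) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4] == length(times),
            all(diff(times) > 0), length(voxel_size_mm) == 3L)
  structure(list(data = data, times = as.numeric(times),
                 voxel_size_mm = voxel_size_mm),
            class = "series4d")
}

#' @export
print.series4d <- function(x, ...) {
  d <- dim(x$data)
  cat("<series4d>", paste(d[1:3], collapse = "x"), "voxels,", d[4],
      "frames,", round(utils::tail(x$times, 1) - x$times[1], 2),
      "s span\n")
  invisible(x)
}

#' Signal intensity-time curve
#'
#' @param times seconds, strictly increasing, length >= 5.
#' @param intensities same length, no missing values.
#' @return object of class `time_curve`.
#' @export
time_curve <- function(times, intensities) {
  if (length(times) < 5L) stop("time_curve: need at least 5 samples")
  if (length(times) != length(intensities))
    stop("time_curve: length mismatch")
  if (any(!is.finite(times)) || any(!is.finite(intensities)))
    stop("time_curve: missing or non-finite values")
  if (any(diff(times) <= 0))
    stop("time_curve: times must be strictly increasing")
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities)),
            class = "time_curve")
}

#' Extract a mean ROI signal intensity-time curve
#'
#' Per-frame mean intensity over the voxels of one atlas label, the
#' standard way the arterial (contralateral MCA) and venous (superior
#' sagittal sinus) reference curves are obtained.
#'
#' @param series a [series4d()].
#' @param atlas a `region_atlas`.
#' @param label atlas label of the ROI (21 arterial, 22 venous).
#' @return a [time_curve()].
#' @export
extract_curve <- function(series, atlas, label) {
  stopifnot(inherits(series, "series4d"), inherits(atlas, "region_atlas"))
  roi <- which(atlas$labels == label)
  if (!length(roi)) stop("extract_curve: empty ROI")
  nf <- dim(series$data)[4]
  m <- matrix(series$data, ncol = nf)
  time_curve(series$times, colMeans(m[roi, , drop = FALSE]))
}

#' Detect bolus landmarks on a signal intensity-time curve
#'
#' Baseline is the median of the initial 10% of frames (minimum 3);
#' the peak is the global maximum; arrival is the first time the
#' intensity exceeds `baseline + arrival_fraction * (peak - baseline)`;
#' half-decay and late-decay are the first post-peak times at which the
#' intensity falls to 50% and 10% of the peak elevation (or the end of
#' acquisition, flagged truncated).  A curve whose peak elevation is
#' below five times the robust pre-bolus noise level
#' (`1.4826 * MAD` of the baseline frames) raises a "no bolus detected"
#' error.
#'
#' @param curve a [time_curve()].
#' @param arrival_fraction rising-limb fraction defining arrival.
#' @return object of class `bolus_landmarks` with fields `baseline`,
#'   `arrival`, `peak_time`, `peak_value`, `half_decay`, `late_decay`,
#'   `truncated`.
#' @export
detect_bolus <- function(curve, arrival_fraction = 0.1) {
  stopifnot(inherits(curve, "time_curve"),
            arrival_fraction > 0, arrival_fraction < 1)
  t <- curve$times; y <- curve$intensities
  n <- length(y)
  nb <- max(3L, ceiling(0.1 * n))
  base <- stats::median(y[seq_len(nb)])
  noise <- 1.4826 * stats::mad(y[seq_len(nb)], constant = 1)
  ipk <- which.max(y)
  peak <- y[ipk]
  if (peak - base <= max(5 * noise, sqrt(.Machine$double.eps) *
                           max(1, abs(peak))))
    stop("no bolus detected")
  lev_arr <- base + arrival_fraction * (peak - base)
  iarr <- which(y[seq_len(ipk)] > lev_arr)[1]
  if (is.na(iarr) || iarr >= ipk) iarr <- max(1L, ipk - 1L)
  first_below <- function(frac) {
    lev <- base + frac * (peak - base)
    post <- seq(ipk, n)
    i <- post[which(y[post] <= lev)[1]]
    if (is.na(i)) list(time = t[n], truncated = TRUE)
    else list(time = t[i], truncated = FALSE)
  }
  hd <- first_below(0.5)
  ld <- first_below(0.1)
  structure(list(baseline = base, arrival = t[iarr], peak_time = t[ipk],
                 peak_value = peak, half_decay = hd$time,
                 late_decay = max(ld$time, hd$time),
                 truncated = hd$truncated || ld$truncated,
                 noise = noise),
            class = "bolus_landmarks")
}

#' @export
print.bolus_landmarks <- function(x, ...) {
  cat(sprintf(paste0("<bolus_landmarks> arrival %.2f s, peak %.2f s ",
                     "(%.1f), half-decay %.2f s, late %.2f s%s\n"),
              x$arrival, x$peak_time, x$peak_value, x$half_decay,
              x$late_decay, if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Phase windows of the collateral map
#'
#' Five contiguous half-open intervals `[start, end)` in seconds:
#' arterial, capillary, early venous, late venous and delay; their union
#' covers `[arterial arrival, acquisition end)`.
#'
#' @param boundaries numeric length 5: starts of the five phases
#'   (arterial arrival, arterial peak, venous peak, venous half-decay,
#'   venous late-decay).
#' @param acquisition_end end of the acquisition in seconds.
#' @return object of class `phase_windows`.
#' @export
phase_windows <- function(boundaries, acquisition_end) {
  stopifnot(length(boundaries) == 5L, all(is.finite(boundaries)))
  b <- cummax(boundaries)
  edges <- c(b, acquisition_end)
  if (any(diff(edges) < 0)) stop("phase boundaries exceed acquisition end")
  nm <- c("arterial", "capillary", "early_venous", "late_venous", "delay")
  w <- lapply(seq_len(5), function(i) c(start = edges[i], end = edges[i + 1]))
  names(w) <- nm
  structure(list(windows = w), boundaries = edges,
            class = "phase_windows")
}

#' @export
print.phase_windows <- function(x, ...) {
  for (nm in names(x$windows))
    cat(sprintf("  %-12s [%6.2f, %6.2f) s\n", nm,
                x$windows[[nm]]["start"], x$windows[[nm]]["end"]))
  invisible(x)
}

#' Divide the acquisition into the five collateral-map phases
#'
#' Phase boundaries follow the arterial and venous bolus landmarks:
#' arterial phase from arterial arrival to arterial peak, capillary from
#' arterial peak to venous peak, early venous to the venous half-decay,
#' late venous to the venous late-decay, and delay to the end of the
#' acquisition.  When `frame_times` are supplied, any window containing
#' no frame is widened to include one frame (with a warning), so every
#' phase image has at least one contributing frame.
#'
#' @param arterial,venous `bolus_landmarks` of the arterial and venous
#'   reference curves.
#' @param acquisition_end end of acquisition, seconds.
#' @param frame_times optional frame times used to guarantee non-empty
#'   windows.
#' @return a [phase_windows()].
#' @export
segment_phases <- function(arterial, venous, acquisition_end,
                           frame_times = NULL) {
  stopifnot(inherits(arterial, "bolus_landmarks"),
            inherits(venous, "bolus_landmarks"))
  if (venous$peak_time <= arterial$peak_time)
    stop(paste("venous peak does not follow arterial peak;",
               "check ROI placement"))
  b <- c(arterial$arrival, arterial$peak_time, venous$peak_time,
         venous$half_decay, venous$late_decay)
  b <- pmin(cummax(b), acquisition_end)
  if (!is.null(frame_times)) {
    ft <- sort(frame_times)
    edges <- c(b, acquisition_end)
    for (i in seq_len(5)) {
      inside <- ft >= edges[i] & ft < edges[i + 1]
      if (!any(inside)) {
        nxt <- ft[ft >= edges[i]][1]
        if (is.na(nxt)) { # collapse onto the last frame
          edges[i] <- utils::tail(ft, 1)
          warning(sprintf("phase %d collapsed to the trailing frame", i))
        } else {
          step <- if (length(ft) > 1) min(diff(ft)) else 1
          edges[i + 1] <- max(edges[i + 1], nxt + step / 2)
          warning(sprintf("phase %d widened to include one frame", i))
        }
        edges <- cummax(edges)
      }
    }
    edges[6] <- max(edges[6], acquisition_end)
    b <- edges[1:5]
    acquisition_end <- edges[6]
  }
  if (venous$truncated)
    warning("venous decay truncated by end of acquisition")
  phase_windows(b, acquisition_end)
}

#' Export a time curve as a two-column CSV
#' @param curve a [time_curve()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_s = curve$times,
                              intensity = curve$intensities),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export phase windows as JSON
#' @param windows a [phase_windows()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_windows_json <- function(windows, path) {
  jsonlite::write_json(lapply(windows$windows, as.list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
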