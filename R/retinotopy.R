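# Receptive-field mapping by reverse correlation, retinotopic surface fitting
# and border-zone exclusion.

#' Deconvolve a fluorescence trace into event amplitudes
#'
#' Non-negative deconvolution of a calcium trace against the
#' difference-of-exponentials kernel. The trace is first detrended by
#' subtracting a rolling 10th-percentile baseline, then the non-negative
#' least-squares problem is solved by accelerated projected gradient descent
#' using the convolution operator directly (no dictionary matrix), followed
#' by an exact least-squares re-fit on the detected support to debias
#' amplitudes.
#'
#' @param trace numeric fluorescence (or dF/F) trace; must be finite.
#' @param frame_rate Hz.
#' @param rise_s,decay_s kernel time constants (s).
#' @param max_iter iteration budget for the projected gradient solve.
#' @param tol relative convergence tolerance.
#' @return non-negative per-frame event amplitudes, same length as `trace`.
#' @export
deconvolve_trace <- function(trace, frame_rate, rise_s = 0.1, decay_s = 1.5,
                             max_iter = 2000, tol = 1e-9) {
  if (any(!is.finite(trace))) stop("trace must be finite")
  if (decay_s <= 0 || rise_s <= 0) stop("kernel time constants must be positive")
  n <- length(trace)
  y <- trace - rolling_percentile(trace, min(n, 2000L), 0.1)
  if (max(abs(y)) == 0) return(numeric(n))
  K <- function(x) doe_convolve(x, frame_rate, rise_s, decay_s)
  Kt <- function(r) rev(doe_convolve(rev(r), frame_rate, rise_s, decay_s))
  k <- calcium_kernel(frame_rate, rise_s, decay_s)
  L <- sum(k)^2
  x <- numeric(n); z <- x; tk <- 1
  for (it in seq_len(max_iter)) {
    grad <- Kt(K(z) - y)
    xn <- pmax(0, z - grad / L)
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- xn + ((tk - 1) / tk1) * (xn - x)
    delta <- max(abs(xn - x))
    x <- xn; tk <- tk1
    if (delta < tol * max(abs(y))) break
  }
  # debias on the detected support (exact LS, active-set style clipping)
  supp <- which(x > 1e-3 * max(x))
  if (length(supp) && length(supp) <= 500L) {
    repeat {
      A <- vapply(supp, function(i) {
        e <- numeric(n); e[i] <- 1; K(e)
      }, numeric(n))
      beta <- tryCatch(qr.solve(A, y), error = function(e) NULL)
      if (is.null(beta)) break
      if (all(beta >= -1e-8)) {
        x[] <- 0; x[supp] <- pmax(0, beta); break
      }
      supp <- supp[beta > min(beta)]
      if (!length(supp)) { x[] <- 0; break }
    }
  }
  x
}

#' Denoise an event trace by thresholding
#'
#' Zeroes event amplitudes at or below mean + 2 s.d. of the trace (strict
#' comparison: ties are zeroed, the conservative reading of a two-s.d.
#' threshold). A zero-variance trace degenerates to threshold = mean, so all
#' of its values are zeroed; a warning flags this case.
#'
#' @param events numeric event trace (>= 2 frames).
#' @return thresholded event trace.
#' @export
denoise_events <- function(events) {
  if (length(events) < 2L) stop("need at least two frames")
  s <- stats::sd(events)
  if (s == 0) warning("zero-variance event trace")
  thr <- mean(events) + 2 * s
  events[!(events > thr)] <- 0
  events
}

# Median filter along the stimulus-lag axis, per grid position (window 3).
# A spatial median would erase receptive fields confined to a single grid
# square, which are legitimate at coarse grids; filtering across lags
# removes single-frame noise while preserving them.
median_filter_lags <- function(zarr) {
  if (dim(zarr)[1] < 3L) return(zarr)
  for (i in seq_len(dim(zarr)[2])) {
    for (j in seq_len(dim(zarr)[3])) {
      zarr[, i, j] <- stats::runmed(zarr[, i, j], 3, endrule = "keep")
    }
  }
  zarr
}

#' Map a receptive field by reverse correlation
#'
#' Builds the event-triggered stimulus ensemble from a deconvolved event
#' trace and a sparse-noise stimulus: stimuli in a 2-s window preceding each
#' event are collected, weighted by event size, averaged, expressed as a
#' Z-score over all stimulus-lag and grid-position combinations, and median
#' filtered (window 3) along the lag axis at each grid position. ON and OFF
#' maps are computed separately.
#' The preferred location is the grid position maximizing Z within a 600-ms
#' window centred on the peak lag of the triggered average; a unit is
#' included if either polarity reaches `z_threshold` (default 5), and when
#' both do, the preference is the Z-weighted average of the two peak
#' locations.
#'
#' @param events non-negative event trace.
#' @param stimulus logical/numeric array `frames x rows x cols x 2`
#'   (polarity 1 = ON, 2 = OFF), on the same time base as `events`.
#' @param frame_rate Hz.
#' @param grid_azimuth_deg azimuth of each grid column (length `cols`).
#' @param grid_elevation_deg elevation of each grid row (length `rows`).
#' @param window_s triggered-ensemble window (s).
#' @param peak_window_s window over the temporal peak used to read the map.
#' @param z_threshold inclusion threshold on the maximum Z-score.
#' @return object of class `fbmap_rfmap`: Z maps per polarity
#'   (`lags x rows x cols`), `max_z_on`, `max_z_off`, `included`,
#'   `preferred_azimuth_deg`, `preferred_elevation_deg`.
#' @export
map_receptive_field <- function(events, stimulus, frame_rate,
                                grid_azimuth_deg = NULL,
                                grid_elevation_deg = NULL,
                                window_s = 2, peak_window_s = 0.6,
                                z_threshold = 5) {
  d <- dim(stimulus)
  if (length(d) != 4L || d[4] != 2L)
    stop("stimulus must be a frames x rows x cols x 2 array")
  if (length(events) != d[1])
    stop("events and stimulus must share a time base")
  if (is.null(grid_azimuth_deg)) grid_azimuth_deg <- seq_len(d[3])
  if (is.null(grid_elevation_deg)) grid_elevation_deg <- seq_len(d[2])
  n_lag <- max(1L, ceiling(window_s * frame_rate))
  half_pk <- ceiling(peak_window_s * frame_rate)

  empty <- structure(list(z_on = NULL, z_off = NULL,
                          max_z_on = NA_real_, max_z_off = NA_real_,
                          included = FALSE,
                          preferred_azimuth_deg = NA_real_,
                          preferred_elevation_deg = NA_real_),
                     class = "fbmap_rfmap")
  if (sum(events) == 0) return(empty)

  pol_res <- lapply(1:2, function(p) {
    sm <- matrix(stimulus[, , , p], d[1], d[2] * d[3])
    ens <- matrix(0, n_lag, d[2] * d[3])
    for (lag in 0:(n_lag - 1L)) {
      w <- events[(lag + 1L):d[1]]
      ens[lag + 1L, ] <- colSums(sm[seq_len(d[1] - lag), , drop = FALSE] * w) /
        sum(events)
    }
    z <- (ens - mean(ens)) / stats::sd(ens)
    zarr <- median_filter_lags(array(z, c(n_lag, d[2], d[3])))
    # temporal peak of the triggered average, then a centred window over it
    lag_strength <- apply(zarr, 1L, max)
    pk <- which.max(lag_strength)
    win <- max(1L, pk - half_pk %/% 2L):min(n_lag, pk + half_pk %/% 2L)
    zwin <- apply(zarr[win, , , drop = FALSE], c(2, 3), max)
    idx <- which(zwin == max(zwin), arr.ind = TRUE)[1, ]
    list(z = zarr, max_z = max(zwin),
         az = grid_azimuth_deg[idx[2]], el = grid_elevation_deg[idx[1]])
  })
  on <- pol_res[[1]]; off <- pol_res[[2]]
  included <- max(on$max_z, off$max_z) >= z_threshold
  if (!included) {
    out <- empty
    out$z_on <- on$z; out$z_off <- off$z
    out$max_z_on <- on$max_z; out$max_z_off <- off$max_z
    return(out)
  }
  if (on$max_z >= z_threshold && off$max_z >= z_threshold) {
    w <- c(on$max_z, off$max_z)
    az <- sum(w * c(on$az, off$az)) / sum(w)
    el <- sum(w * c(on$el, off$el)) / sum(w)
  } else if (on$max_z >= z_threshold) {
    az <- on$az; el <- on$el
  } else {
    az <- off$az; el <- off$el
  }
  structure(list(z_on = on$z, z_off = off$z, max_z_on = on$max_z,
                 max_z_off = off$max_z, included = TRUE,
                 preferred_azimuth_deg = az, preferred_elevation_deg = el),
            class = "fbmap_rfmap")
}

#' Fit a smoothed retinotopic surface
#'
#' Locally weighted linear (LOWESS) surfaces mapping field-of-view position
#' to azimuth and elevation, with robust bisquare reweighting, used as the
#' template for receptive-field approximation at arbitrary ROI positions.
#'
#' @param x_um,y_um ROI positions.
#' @param azimuth_deg,elevation_deg preferred locations of included ROIs.
#' @param span_frac LOWESS span as a fraction of points (default 0.2).
#' @return object of class `fbmap_retmap`; use [predict.fbmap_retmap()] to
#'   interpolate. Queries outside the convex hull of the fitted ROIs are
#'   extrapolated from the local-linear fit and flagged.
#' @export
fit_smooth_map <- function(x_um, y_um, azimuth_deg, elevation_deg,
                           span_frac = 0.2) {
  ok <- is.finite(x_um) & is.finite(y_um) & is.finite(azimuth_deg) &
    is.finite(elevation_deg)
  if (sum(ok) < 10L) stop("need at least 10 included ROIs to fit a surface")
  df <- data.frame(x = x_um[ok], y = y_um[ok], az = azimuth_deg[ok],
                   el = elevation_deg[ok])
  ctrl <- stats::loess.control(surface = "direct", iterations = 3)
  fit_az <- stats::loess(az ~ x + y, data = df, span = span_frac, degree = 1,
                         family = "symmetric", control = ctrl)
  fit_el <- stats::loess(el ~ x + y, data = df, span = span_frac, degree = 1,
                         family = "symmetric", control = ctrl)
  hull <- df[grDevices::chull(df$x, df$y), c("x", "y")]
  structure(list(fit_az = fit_az, fit_el = fit_el, hull = hull,
                 n_points = nrow(df)),
            class = "fbmap_retmap")
}

# ray-casting point-in-polygon
in_hull <- function(px, py, hull) {
  n <- nrow(hull)
  vapply(seq_along(px), function(i) {
    inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      if ((hull$y[k] > py[i]) != (hull$y[j] > py[i])) {
        xint <- hull$x[k] + (py[i] - hull$y[k]) / (hull$y[j] - hull$y[k]) *
          (hull$x[j] - hull$x[k])
        if (px[i] < xint) inside <- !inside
      }
      j <- k
    }
    inside
  }, logical(1))
}

#' Interpolate a retinotopic surface at new positions
#'
#' @param object a [fit_smooth_map()] result.
#' @param x_um,y_um query positions.
#' @param ... unused.
#' @return data.frame with `azimuth_deg`, `elevation_deg` and a logical
#'   `extrapolated` flag for queries outside the convex hull of the fit.
#' @export
predict.fbmap_retmap <- function(object, x_um, y_um, ...) {
  nd <- data.frame(x = x_um, y = y_um)
  data.frame(azimuth_deg = as.numeric(stats::predict(object$fit_az, nd)),
             elevation_deg = as.numeric(stats::predict(object$fit_el, nd)),
             extrapolated = !in_hull(x_um, y_um, object$hull))
}

#' Assign cortical area and border exclusion from a border polyline
#'
#' Signed distance from each ROI to the area border determines the area
#' (`A1` on the left of the polyline direction, where the signed distance is
#' positive; `A2` on the right); ROIs closer than the exclusion
#' distance on either side are flagged excluded, and ROIs exactly on the
#' border are assigned area `"border"`.
#'
#' @param x_um,y_um ROI positions.
#' @param border numeric matrix (>= 2 x 2) of polyline vertices (x, y) in um.
#' @param exclusion_um exclusion half-width (default 75, i.e. a 150-um zone).
#' @return data.frame with `area`, `excluded`, `signed_distance_um`.
#' @export
assign_area_and_border <- function(x_um, y_um, border, exclusion_um = 75) {
  border <- as.matrix(border)
  if (nrow(border) < 2L) stop("border polyline needs at least 2 vertices")
  seg_len <- sqrt(diff(border[, 1])^2 + diff(border[, 2])^2)
  if (all(seg_len == 0)) stop("degenerate (zero-length) border polyline")
  n <- length(x_um)
  sd_um <- vapply(seq_len(n), function(i) {
    best <- Inf; best_sign <- 1
    for (s in seq_len(nrow(border) - 1L)) {
      if (seg_len[s] == 0) next
      ax <- border[s, 1]; ay <- border[s, 2]
      dx <- border[s + 1, 1] - ax; dy <- border[s + 1, 2] - ay
      t <- ((x_um[i] - ax) * dx + (y_um[i] - ay) * dy) / seg_len[s]^2
      t <- min(1, max(0, t))
      px <- ax + t * dx; py <- ay + t * dy
      d <- sqrt((x_um[i] - px)^2 + (y_um[i] - py)^2)
      if (d < best) {
        best <- d
        cross <- dx * (y_um[i] - ay) - dy * (x_um[i] - ax)
        best_sign <- if (cross == 0) 0 else sign(cross)
      }
    }
    best * if (best_sign == 0) 1 else best_sign
  }, numeric(1))
  on_border <- vapply(seq_len(n), function(i) {
    abs(sd_um[i]) < .Machine$double.eps^0.5
  }, logical(1))
  # positive signed distance = left of the polyline direction = A1
  area <- ifelse(on_border, "border", ifelse(sd_um > 0, "A1", "A2"))
  data.frame(area = area, excluded = abs(sd_um) < exclusion_um | on_border,
             signed_distance_um = sd_um)
}
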