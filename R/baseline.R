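#' Iterative polynomial baseline (modified polyfit)
#'
#' Estimates a slowly varying fluorescence baseline under sharp Raman peaks by
#' iterated least-squares polynomial fitting: the input is presmoothed once
#' with a moving average, a polynomial is fitted over the whole axis, fitted
#' values exceeding the current working spectrum are clipped down to it
#' (truncating the peaks), and the clipped curve becomes the next iteration's
#' input. Iteration stops when the fitted curve changes by less than
#' `tol` times the input dynamic range.
#'
#' @param s A [raman_spectrum()].
#' @param order Polynomial order (default 12).
#' @param presmooth Moving-average window length in points, applied once
#'   before the first iteration (default 20; 1 disables).
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence tolerance as a fraction of the input range
#'   (default 1e-4).
#' @return A `baseline_result`: list with `baseline` (numeric vector),
#'   `method`, `iterations`, `converged` and `params`.
#' @export
fit_baseline_iterpoly <- function(s, order = 12L, presmooth = 20L,
                                  max_iter = 100L, tol = 1e-4) {
  stopifnot(inherits(s, "raman_spectrum"))
  y <- s$intensities
  n <- length(y)
  if (n < order + 1L) stop("need at least order+1 pixels for the fit")
  work <- if (presmooth > 1L) moving_average(y, presmooth) else y
  rng <- diff(range(work))
  if (rng == 0) { # constant input: the baseline is the input
    return(baseline_result(work, "iterpoly", 0L, TRUE,
                           list(order = order, presmooth = presmooth,
                                tol = tol)))
  }
  # order-12 fits need a conditioned abscissa; the projector is fixed across
  # iterations, so build it once
  x <- s$axis$shifts
  xc <- (x - mean(x)) / stats::sd(x)
  X <- outer(xc, 0:order, `^`)
  qrX <- qr(X)
  fit_prev <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    fit <- qr.fitted(qrX, work)
    if (!is.null(fit_prev) && max(abs(fit - fit_prev)) < tol * rng) {
      converged <- TRUE
      fit_prev <- fit
      break
    }
    fit_prev <- fit
    work <- pmin(fit, work)
  }
  baseline_result(fit_prev, "iterpoly", iter, converged,
                  list(order = order, presmooth = presmooth, tol = tol))
}

baseline_result <- function(baseline, method, iterations, converged, params) {
  structure(
    list(baseline = as.numeric(baseline), method = method,
         iterations = iterations, converged = converged, params = params),
    class = "baseline_result"
  )
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("<baseline_result> method %s, %d iteration(s)%s\n",
              x$method, x$iterations,
              if (x$converged) ", converged" else " (not converged)"))
  invisible(x)
}

# centered moving average with shrinking windows at the edges
moving_average <- function(y, window) {
  window <- as.integer(window)
  if (window <= 1L) return(y)
  n <- length(y)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  cs <- cumsum(c(0, y))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Andrew's monotone-chain lower convex hull, evaluated at every x
lower_convex_hull <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2L) {
      k <- length(hull)
      o <- hull[k - 1L]; a <- hull[k]
      cross <- (x[a] - x[o]) * (y[i] - y[o]) - (y[a] - y[o]) * (x[i] - x[o])
      if (cross <= 0) hull <- hull[-k] else break
    }
    hull <- c(hull, i)
  }
  stats::approx(x[hull], y[hull], xout = x)$y
}

# rolling minimum with shrinking windows at the edges; tracks the baseline
# under positive peaks
rolling_min <- function(y, window) {
  n <- length(y)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    min(y[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Arc-corrected convex-hull baseline (arc hull)
#'
#' A rubber-band (lower convex hull) baseline cannot follow a concave-down
#' fluorescence hump: the hull under a dome is just its chord. The arc hull
#' corrects for the smooth curvature first: a rolling minimum of the profile
#' (window ~ 1/20 of the axis) estimates the peak-free baseline, a circular
#' arc is fitted through the two endpoints and the interior point where that
#' estimate deviates most from the endpoint chord (for a profile that dips
#' below the chord this is its global minimum), the arc is subtracted to
#' flatten the curvature, the lower convex hull of the residual is taken, and
#' the arc is added back. The circle is fitted in chord-subtracted
#' coordinates rescaled to a fixed modest sagitta, so the arc is always
#' single-valued over the window. The result never exceeds the input at any
#' pixel.
#'
#' Degenerate geometry (near-collinear anchors) falls back to the plain lower
#' convex hull, which is exact for linear baselines.
#'
#' @param s A [raman_spectrum()].
#' @return A `baseline_result` with `method = "archull"`; `params$fallback`
#'   records whether the plain hull fallback was taken.
#' @export
fit_baseline_archull <- function(s) {
  stopifnot(inherits(s, "raman_spectrum"))
  y <- s$intensities
  n <- length(y)
  if (n < 3L) stop("need at least 3 pixels")
  px <- (seq_len(n) - 1) / (n - 1)
  yr <- diff(range(y))
  if (yr == 0) {
    return(baseline_result(y, "archull", 1L, TRUE, list(fallback = FALSE)))
  }
  plain <- function(fallback = TRUE) {
    baseline_result(lower_convex_hull(px, y), "archull", 1L, TRUE,
                    list(fallback = fallback))
  }
  w <- max(3L, n %/% 20L)
  rmin <- rolling_min(y, w)
  # anchor the chord at the first/last fully-windowed pixels: the shrinking
  # edge windows (and the half-window lag on slopes) would otherwise fake a
  # deviation on perfectly linear baselines
  h <- w %/% 2L
  i_lo <- min(h + 1L, n - 2L)
  i_hi <- max(n - h, 3L)
  slope <- (rmin[i_hi] - rmin[i_lo]) / (px[i_hi] - px[i_lo])
  chord <- rmin[i_lo] + slope * (px - px[i_lo])
  dev <- rmin - chord
  interior <- (i_lo + 1L):(i_hi - 1L)
  i_anchor <- interior[which.max(abs(dev[interior]))]
  sag <- dev[i_anchor]
  if (abs(sag) < 1e-6 * yr) return(plain()) # collinear anchors
  # circle through the chord endpoints and (x_anchor, +/-0.25) in
  # chord-subtracted, sagitta-normalized coordinates
  sy <- 0.25 / abs(sag)
  arc_s <- circle_through(c(px[i_lo], px[i_anchor], px[i_hi]),
                          c(0, sign(sag) * 0.25, 0), px)
  if (is.null(arc_s)) return(plain())
  arc <- arc_s / sy + chord
  resid <- y - arc
  hull <- lower_convex_hull(px, resid)
  baseline_result(hull + arc, "archull", 1L, TRUE,
                  list(fallback = FALSE, anchor = i_anchor))
}

# y(x) on the circle through three points, single-valued branch; NULL when
# degenerate or the branch is not defined over all of xout
circle_through <- function(x3, y3, xout) {
  ax <- x3[1L]; ay <- y3[1L]
  bx <- x3[2L]; by <- y3[2L]
  cx <- x3[3L]; cy <- y3[3L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-9) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  r2 <- (ax - ux)^2 + (ay - uy)^2
  under <- r2 - (xout - ux)^2
  if (any(under <= 0)) return(NULL)
  branch <- sign(ay - uy)
  if (branch == 0) return(NULL)
  arc <- uy + branch * sqrt(under)
  # all three anchors must sit on the chosen branch
  at <- uy + branch * sqrt(pmax(r2 - (x3 - ux)^2, 0))
  if (max(abs(at - y3)) > 1e-6) return(NULL)
  arc
}
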