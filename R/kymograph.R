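# Kymograph construction along user paths and recruitment-kinetics
# extraction with steady-state detection.

#' Build a kymograph along a polyline
#'
#' For every frame, intensity is sampled at 1-px steps along the path with
#' bilinear interpolation and perpendicular averaging over `width` pixels;
#' the samples are assembled into a position x time matrix.
#'
#' @param stack an [ImageStack-class] with at least 2 frames
#' @param polyline n x 2 matrix of `(y, x)` px vertices
#' @param width odd perpendicular averaging width (px)
#' @param channel channel index or label
#' @return a [Kymograph-class]
#' @export
makeKymograph <- function(stack, polyline, width = 1L, channel = 1L) {
  if (nFrames(stack) < 2L)
    stop("a kymograph needs a time axis: the stack has a single frame")
  cols <- lapply(seq_len(nFrames(stack)), function(f)
    profileAlongPath(getPlane(stack, f, channel), polyline, width)$value)
  new("Kymograph", values = do.call(cbind, cols),
      path = as.matrix(polyline), width = as.numeric(width),
      pixelSize = pixelSize(stack), frameInterval = frameInterval(stack))
}

#' Recruitment curve with saturating-kinetics fit
#'
#' Extracts the mean ROI intensity per frame and fits
#' `I(t) = plateau * (1 - exp(-t / tau))`. The steady-state time is the
#' first time the fitted curve reaches 95% of the plateau
#' (`tau * log(20)`). A near-constant trace is reported as already at
#' steady state (`tau = 0`); a non-convergent fit returns the curve with
#' the fit flagged absent.
#'
#' @param stack an [ImageStack-class]
#' @param roi logical mask matrix matching the image shape, or `NULL` for
#'   the whole frame
#' @param channel channel index or label
#' @return list of class `RecruitmentCurve`: `times`, `intensity`,
#'   `plateau`, `tau`, `steadyStateTime`, `fitted` (logical)
#' @export
recruitmentCurve <- function(stack, roi = NULL, channel = 1L) {
  nt <- nFrames(stack)
  times <- (seq_len(nt) - 1L) * frameInterval(stack)
  intensity <- vapply(seq_len(nt), function(f) {
    pl <- getPlane(stack, f, channel)
    if (is.null(roi)) mean(pl) else {
      if (!identical(dim(roi), dim(pl))) stop("ROI shape mismatch")
      mean(pl[roi])
    }
  }, numeric(1))
  out <- list(times = times, intensity = intensity, plateau = NA_real_,
              tau = NA_real_, steadyStateTime = NA_real_, fitted = FALSE)
  rng <- diff(range(intensity))
  if (rng <= 1e-10 * max(abs(intensity), 1)) {
    out$plateau <- mean(intensity)
    out$tau <- 0
    out$steadyStateTime <- 0
    out$fitted <- TRUE
    return(structure(out, class = "RecruitmentCurve"))
  }
  tau0 <- times[max(which.min(abs(intensity - 0.63 * max(intensity))), 2L)]
  fit <- tryCatch(
    minpack.lm::nlsLM(intensity ~ plateau * (1 - exp(-times / tau)),
                      start = list(plateau = max(intensity),
                                   tau = max(tau0, frameInterval(stack))),
                      lower = c(0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    out$plateau <- unname(cf["plateau"])
    out$tau <- unname(cf["tau"])
    out$steadyStateTime <- out$tau * log(20)  # 95% of plateau
    out$fitted <- TRUE
  }
  structure(out, class = "RecruitmentCurve")
}

#' @export
print.RecruitmentCurve <- function(x, ...) {
  if (x$fitted)
    cat(sprintf(
      "RecruitmentCurve: %d frames; plateau = %.4g, tau = %.4g s, steady state at %.4g s\n",
      length(x$times), x$plateau, x$tau, x$steadyStateTime))
  else
    cat(sprintf("RecruitmentCurve: %d frames; fit did not converge\n",
                length(x$times)))
  invisible(x)
}

#' Partition tracks into long-lived and transient puncta
#'
#' @param tracks track data.frame (`trackId`, `frame`, `time`, `y`, `x`) as
#'   returned by [trackParticles()]
#' @param threshold dwell-time threshold in s (declared, default 60)
#' @return list with `longLived`, `transient` counts and the `dwellTimes`
#'   data.frame (per track, in s)
#' @export
punctaLifetimeClasses <- function(tracks, threshold = 60) {
  if (nrow(tracks) == 0L)
    return(list(longLived = 0L, transient = 0L,
                dwellTimes = data.frame(trackId = integer(0),
                                        dwell = numeric(0))))
  sp <- split(tracks$time, tracks$trackId)
  dwell <- vapply(sp, function(t) max(t) - min(t), numeric(1))
  dw <- data.frame(trackId = as.integer(names(sp)), dwell = unname(dwell))
  list(longLived = sum(dw$dwell >= threshold),
       transient = sum(dw$dwell < threshold),
       dwellTimes = dw)
}
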