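#' Specify an idealised diel transcript waveform
#'
#' A waveform describes one gene's mRNA abundance `m(t)` over the 24-h cycle
#' in an analytically tractable family. Amplitude follows the peak/mean
#' convention used for rhythm classification: `rel_amplitude = 1` is a flat
#' profile, `2` means the peak is twice the daily mean.
#'
#' Shapes:
#' \describe{
#'   \item{`cosine`}{`mean_level * (1 + a*cos(2*pi*(t - peak)/24))` with
#'     `a = rel_amplitude - 1`; requires `rel_amplitude <= 2` so the profile
#'     stays non-negative.}
#'   \item{`clipped_cosine`}{the cosine with `a > 0` (possibly `> 1`),
#'     truncated at zero and rescaled so the daily mean equals `mean_level`.
#'     Allows peak/mean ratios above 2.}
#'   \item{`gaussian_bump`}{a circularly wrapped Gaussian centred on the peak;
#'     `width_h` is the full width at half maximum (hours).}
#'   \item{`rect_pulse`}{a rectangular pulse of duration `width_h` centred on
#'     `peak_phase_h` (support `[peak - width/2, peak + width/2)`, circular),
#'     with height `24 * mean_level / width_h`.}
#' }
#'
#' @param shape one of `"cosine"`, `"clipped_cosine"`, `"gaussian_bump"`,
#'   `"rect_pulse"`.
#' @param peak_phase_h peak phase in Zeitgeber hours, in `[0, 24)` (dawn = ZT0).
#' @param rel_amplitude peak/mean ratio, `>= 1`.
#' @param width_h width in hours (Gaussian FWHM or pulse duration); ignored for
#'   the cosine shapes.
#' @param mean_level daily mean abundance, `> 0` (arbitrary units).
#' @return an object of class `"tc_waveform"`.
#' @seealso [gen_transcript_profile()]
#' @export
#' @examples
#' w <- waveform_spec("cosine", peak_phase_h = 6, rel_amplitude = 2)
#' waveform_value(w, c(0, 6, 12))
waveform_spec <- function(shape = c("cosine", "clipped_cosine", "gaussian_bump",
                                    "rect_pulse"),
                          peak_phase_h = 0, rel_amplitude = 1.5,
                          width_h = 2, mean_level = 1) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(peak_phase_h), length(peak_phase_h) == 1L,
            peak_phase_h >= 0, peak_phase_h < 24,
            is.numeric(mean_level), mean_level > 0)
  if (!is.numeric(rel_amplitude) || rel_amplitude < 1)
    stop("'rel_amplitude' is a peak/mean ratio and must be >= 1")
  if (shape == "cosine" && rel_amplitude > 2)
    stop("a pure cosine with rel_amplitude > 2 would go negative; ",
         "use shape = 'clipped_cosine'")
  if (shape %in% c("gaussian_bump", "rect_pulse")) {
    stopifnot(is.numeric(width_h), width_h > 0, width_h < 24)
    if (shape == "gaussian_bump" && width_h < 0.5)
      stop("'width_h' below 0.5 h is narrower than the default sampling grid")
  }
  w <- list(shape = shape, peak_phase_h = peak_phase_h,
            rel_amplitude = rel_amplitude, width_h = width_h,
            mean_level = mean_level)
  if (shape == "clipped_cosine") {
    # daily mean of max(0, 1 + a*cos(theta)) relative to 1, used to rescale
    a <- rel_amplitude - 1
    w$clip_mean <- if (a <= 1) 1 else {
      th0 <- acos(-1 / a)
      (th0 + a * sin(th0)) / pi
    }
  }
  class(w) <- "tc_waveform"
  w
}

#' @export
print.tc_waveform <- function(x, ...) {
  cat(sprintf("diel waveform: %s, peak ZT%.2f, peak/mean %.3g, mean %.3g\n",
              x$shape, x$peak_phase_h, x$rel_amplitude, x$mean_level))
  invisible(x)
}

#' Evaluate a waveform at Zeitgeber times
#'
#' @param w a [waveform_spec()] object.
#' @param t numeric vector of times in hours; interpreted modulo 24.
#' @return abundance values, same length as `t`.
#' @export
waveform_value <- function(w, t) {
  stopifnot(inherits(w, "tc_waveform"))
  t <- t %% 24
  a <- w$rel_amplitude - 1
  switch(w$shape,
    cosine = w$mean_level * (1 + a * cos(2 * pi * (t - w$peak_phase_h) / 24)),
    clipped_cosine = {
      raw <- pmax(0, 1 + a * cos(2 * pi * (t - w$peak_phase_h) / 24))
      w$mean_level * raw / w$clip_mean
    },
    gaussian_bump = {
      sigma <- w$width_h / (2 * sqrt(2 * log(2)))
      g <- 0
      for (k in -3:3)
        g <- g + exp(-((t - w$peak_phase_h + 24 * k)^2) / (2 * sigma^2))
      gbar <- sigma * sqrt(2 * pi) / 24    # wrapped Gaussian integrates exactly
      w$mean_level * g / gbar
    },
    rect_pulse = {
      start <- (w$peak_phase_h - w$width_h / 2) %% 24
      end <- start + w$width_h
      h <- 24 * w$mean_level / w$width_h
      inside <- (t >= start & t < end) | (t + 24 >= start & t + 24 < end)
      ifelse(inside, h, 0)
    })
}

#' Exact integral of a waveform over a time interval
#'
#' Computes `\int_a^b m(t) dt` for `0 <= a <= b <= 24` from the closed-form
#' antiderivative of each shape, so that downstream light/dark synthesis
#' integrals carry no quadrature error.
#'
#' @param w a [waveform_spec()] object.
#' @param a,b integration limits in hours, `0 <= a <= b <= 24`.
#' @return the integral (abundance-hours).
#' @export
waveform_integral <- function(w, a, b) {
  stopifnot(inherits(w, "tc_waveform"), a >= 0, b <= 24 + 1e-12, b >= a)
  amp <- w$rel_amplitude - 1
  om <- 2 * pi / 24
  switch(w$shape,
    cosine = {
      w$mean_level * ((b - a) + (amp / om) *
        (sin(om * (b - w$peak_phase_h)) - sin(om * (a - w$peak_phase_h))))
    },
    clipped_cosine = {
      if (amp <= 1) {
        w$mean_level * ((b - a) + (amp / om) *
          (sin(om * (b - w$peak_phase_h)) - sin(om * (a - w$peak_phase_h))))
      } else {
        # positive support is peak +/- th0/om (hours); integrate piecewise
        th0 <- acos(-1 / amp)
        half <- th0 / om
        lo <- w$peak_phase_h - half
        hi <- w$peak_phase_h + half
        seg <- function(x1, x2) {  # integral of (1 + amp*cos) on [x1,x2]
          (x2 - x1) + (amp / om) * (sin(om * (x2 - w$peak_phase_h)) -
                                      sin(om * (x1 - w$peak_phase_h)))
        }
        tot <- 0
        for (k in -1:1) {
          l <- max(a, lo + 24 * k); u <- min(b, hi + 24 * k)
          if (u > l) tot <- tot + seg(l, u)
        }
        w$mean_level * tot / w$clip_mean
      }
    },
    gaussian_bump = {
      sigma <- w$width_h / (2 * sqrt(2 * log(2)))
      gbar <- sigma * sqrt(2 * pi) / 24
      tot <- 0
      for (k in -3:3) {
        mu <- w$peak_phase_h - 24 * k
        tot <- tot + (stats::pnorm(b, mu, sigma) - stats::pnorm(a, mu, sigma))
      }
      w$mean_level * tot * sigma * sqrt(2 * pi) / gbar
    },
    rect_pulse = {
      start <- (w$peak_phase_h - w$width_h / 2) %% 24
      end <- start + w$width_h
      h <- 24 * w$mean_level / w$width_h
      tot <- 0
      for (k in c(-24, 0, 24)) {
        l <- max(a, start + k); u <- min(b, end + k)
        if (u > l) tot <- tot + h * (u - l)
      }
      tot
    })
}

#' Construct a transcript profile on a uniform 24-h grid
#'
#' A `transcript_profile` stores one gene's diel abundance `m(t)` sampled on a
#' uniform grid covering `[0, 24]` with the periodic closure
#' `values[1] == values[n]`. Profiles built by [gen_transcript_profile()] also
#' carry their analytic waveform so that the coincidence model can integrate
#' them exactly; profiles read from tabulated data are integrated by the
#' trapezoidal rule.
#'
#' @param gene_id gene identifier (scalar character).
#' @param times hours, strictly increasing uniform grid on `[0, 24]` (the
#'   closing 24-h point may be omitted and is then appended).
#' @param values non-negative abundances, same length as `times`.
#' @param waveform optional [waveform_spec()] the samples were drawn from.
#' @return an object of class `"transcript_profile"`.
#' @export
transcript_profile <- function(gene_id, times, values, waveform = NULL) {
  stopifnot(length(times) == length(values), length(times) >= 3,
            all(is.finite(times)), all(is.finite(values)))
  o <- order(times)
  times <- times[o]; values <- values[o]
  if (any(values < 0)) stop("transcript abundances must be non-negative")
  step <- diff(times)
  if (max(step) - min(step) > 1e-8)
    stop("'times' must form a uniform grid")
  if (abs(times[1]) > 1e-9) stop("grid must start at 0 h")
  n <- length(times)
  if (abs(times[n] - 24) > 1e-9) {
    if (abs(times[n] + step[1] - 24) > 1e-9)
      stop("grid must cover [0, 24] (directly or up to 24 - step)")
    times <- c(times, 24)
    values <- c(values, values[1])
  } else if (abs(values[n] - values[1]) > 1e-9 * (1 + abs(values[1]))) {
    stop("profile is not 24-h periodic: value at 24 h differs from value at 0 h")
  }
  structure(list(gene_id = as.character(gene_id), times = times,
                 values = values, waveform = waveform),
            class = "transcript_profile")
}

#' @export
print.transcript_profile <- function(x, ...) {
  cat(sprintf("transcript profile '%s': %d points on [0, 24] h, mean %.4g%s\n",
              x$gene_id, length(x$times), daily_mean(x),
              if (is.null(x$waveform)) " (tabulated)"
              else sprintf(" (%s waveform)", x$waveform$shape)))
  invisible(x)
}

#' Daily mean abundance of a transcript profile
#'
#' Periodic trapezoidal mean over one 24-h cycle (exact for the packaged
#' waveform shapes when pulse edges fall on grid nodes).
#'
#' @param profile a [transcript_profile()].
#' @return scalar mean abundance.
#' @export
daily_mean <- function(profile) {
  stopifnot(inherits(profile, "transcript_profile"))
  n <- length(profile$times)
  # with v[1] == v[n], periodic trapezoid reduces to the mean of v[1..n-1]
  mean(profile$values[-n])
}

#' Sample a waveform onto a transcript profile
#'
#' @param spec a [waveform_spec()].
#' @param grid_step grid spacing in hours; must divide 24 evenly.
#' @param gene_id identifier for the resulting profile.
#' @return a [transcript_profile()] carrying `spec` as its analytic waveform.
#' @export
#' @examples
#' p <- gen_transcript_profile(waveform_spec("cosine", 6, 2), grid_step = 0.1)
#' daily_mean(p)
gen_transcript_profile <- function(spec, grid_step = 0.1, gene_id = "gene") {
  stopifnot(inherits(spec, "tc_waveform"), grid_step > 0)
  n_steps <- 24 / grid_step
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("'grid_step' must divide 24 h evenly")
  times <- seq(0, 24, by = grid_step)
  values <- waveform_value(spec, times)
  values[length(values)] <- values[1]  # periodic closure
  transcript_profile(gene_id, times, values, waveform = spec)
}

#' Generate a seeded cohort of rhythmic transcript profiles
#'
#' Samples peak phases and peak/mean amplitudes from user-supplied samplers and
#' returns the profiles together with their ground truth, so downstream
#' recovery tests can compare estimates with the generating parameters.
#'
#' @param n number of genes.
#' @param phase_sampler either a numeric vector of phases recycled over genes,
#'   or a `function(n)` returning `n` phases in `[0, 24)`. Default: uniform.
#' @param amplitude_sampler as `phase_sampler`, for peak/mean amplitudes
#'   (must respect the shape's admissible range). Default: uniform on
#'   `[1.5, 2]`.
#' @param shape waveform shape passed to [waveform_spec()].
#' @param width_h,mean_level passed to [waveform_spec()].
#' @param grid_step sampling grid in hours.
#' @param seed integer seed; the cohort is bit-reproducible given the seed.
#' @return an object of class `"transcript_cohort"`: a list of
#'   [transcript_profile()]s with a `truth` attribute
#'   (`data.frame(gene_id, peak_phase_h, rel_amplitude)`).
#' @export
gen_transcript_cohort <- function(n,
                                  phase_sampler = function(m) stats::runif(m, 0, 24),
                                  amplitude_sampler = function(m) stats::runif(m, 1.5, 2),
                                  shape = "cosine", width_h = 2, mean_level = 1,
                                  grid_step = 0.1, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  draw <- function(sampler, what) {
    x <- if (is.function(sampler)) sampler(n) else rep_len(sampler, n)
    if (length(x) != n || !is.numeric(x))
      stop("invalid ", what, " sampler: must yield ", n, " numeric values")
    x
  }
  phases <- draw(phase_sampler, "phase") %% 24
  amps <- draw(amplitude_sampler, "amplitude")
  if (any(amps < 1)) stop("amplitude sampler produced values < 1")
  ids <- sprintf("g%04d", seq_len(n))
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- waveform_spec(shape, peak_phase_h = phases[i],
                          rel_amplitude = amps[i], width_h = width_h,
                          mean_level = mean_level)
    profiles[[i]] <- gen_transcript_profile(spec, grid_step, gene_id = ids[i])
  }
  names(profiles) <- ids
  structure(profiles,
            truth = data.frame(gene_id = ids, peak_phase_h = phases,
                               rel_amplitude = amps,
                               stringsAsFactors = FALSE),
            class = c("transcript_cohort", "list"))
}

#' @export
print.transcript_cohort <- function(x, ...) {
  cat(sprintf("transcript cohort: %d genes, grid of %d points\n",
              length(x), length(x[[1]]$times)))
  invisible(x)
}

#' Ground truth of a synthetic cohort
#'
#' @param cohort a [gen_transcript_cohort()] result.
#' @return the `data.frame` of generating phases and amplitudes.
#' @export
cohort_truth <- function(cohort) attr(cohort, "truth")
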