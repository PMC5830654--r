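#' @keywords internal
check_dusk <- function(t_dusk) {
  stopifnot(is.numeric(t_dusk), length(t_dusk) == 1L, t_dusk > 0, t_dusk < 24)
  t_dusk
}

#' Entrain a transcript profile to a photoperiod
#'
#' Transcript rhythms are specified at the 12:12 reference photoperiod. Under a
#' different photoperiod the circadian clock shifts their phase according to
#' its dusk sensitivity `s`: a dawn-tracking clock (`s = 0`, the behaviour of
#' the Arabidopsis clock) keeps the dawn-referenced phase fixed, a
#' dusk-tracking clock (`s = 1`) keeps the peak at a fixed offset from dusk,
#' and intermediate values interpolate (`s = 0.5` is noon-tracking).
#' The waveform is shifted rigidly (circularly) by `s * (t_dusk - 12)` hours;
#' shape and daily mean are preserved.
#'
#' @param profile a [transcript_profile()], phased at 12:12.
#' @param t_dusk dusk time of the target photoperiod, hours in `(0, 24)`.
#' @param dusk_sensitivity clock dusk sensitivity `s` in `[0, 1]`.
#' @return the entrained [transcript_profile()].
#' @export
#' @examples
#' p <- gen_transcript_profile(waveform_spec("cosine", 12, 2))
#' peak_phase(entrain_profile(p, t_dusk = 18, dusk_sensitivity = 1))  # 18
entrain_profile <- function(profile, t_dusk, dusk_sensitivity = 0) {
  stopifnot(inherits(profile, "transcript_profile"),
            dusk_sensitivity >= 0, dusk_sensitivity <= 1)
  check_dusk(t_dusk)
  shift <- dusk_sensitivity * (t_dusk - 12)
  if (abs(shift) < 1e-12) return(profile)
  if (!is.null(profile$waveform)) {
    w <- profile$waveform
    w$peak_phase_h <- (w$peak_phase_h + shift) %% 24
    return(gen_transcript_profile(w, grid_step = diff(profile$times[1:2]),
                                  gene_id = profile$gene_id))
  }
  # tabulated profile: circular linear interpolation of the samples
  tq <- (profile$times - shift) %% 24
  vals <- stats::approx(profile$times, profile$values, xout = tq,
                        rule = 2)$y
  vals[length(vals)] <- vals[1]
  transcript_profile(profile$gene_id, profile$times, vals)
}

#' Light-interval and dark-interval transcript integrals
#'
#' Splits the daily transcript integral at dusk: `A = \int_0^{t_dusk} m(t) dt`
#' (light, dawn at ZT0) and `B = \int_{t_dusk}^{24} m(t) dt` (dark). Profiles
#' carrying an analytic waveform are integrated in closed form; tabulated
#' profiles use the trapezoidal rule with a linearly interpolated node
#' inserted at `t_dusk`, so `A + B` always equals the full-day integral to
#' machine precision.
#'
#' @inheritParams entrain_profile
#' @return named numeric vector `c(light = A, dark = B)`.
#' @export
light_dark_integrals <- function(profile, t_dusk) {
  stopifnot(inherits(profile, "transcript_profile"))
  check_dusk(t_dusk)
  if (!is.null(profile$waveform)) {
    total <- waveform_integral(profile$waveform, 0, 24)
    A <- waveform_integral(profile$waveform, 0, t_dusk)
    return(c(light = A, dark = total - A))
  }
  tt <- profile$times; vv <- profile$values
  if (!any(abs(tt - t_dusk) < 1e-12)) {
    vd <- stats::approx(tt, vv, xout = t_dusk)$y
    idx <- findInterval(t_dusk, tt)
    tt <- append(tt, t_dusk, after = idx)
    vv <- append(vv, vd, after = idx)
  }
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  light <- tt <= t_dusk + 1e-12
  A <- trapz(tt[light], vv[light])
  B <- trapz(tt[!light | abs(tt - t_dusk) < 1e-12], vv[!light | abs(tt - t_dusk) < 1e-12])
  c(light = A, dark = B)
}

#' Daily protein synthesis rate from a transcript profile
#'
#' `k_s = T_L * A + T_D * B`, where `A` and `B` are the light- and
#' dark-interval transcript integrals and `T_L`, `T_D` the translation rates
#' per unit mRNA in light and dark.
#'
#' @inheritParams entrain_profile
#' @param T_L,T_D translation rates in light and dark (per unit mRNA per hour).
#' @return scalar daily synthesis `k_s`.
#' @export
daily_synthesis_rate <- function(profile, t_dusk, T_L = 1.4, T_D = 1) {
  stopifnot(T_L > 0, T_D > 0)
  ab <- light_dark_integrals(profile, t_dusk)
  unname(T_L * ab["light"] + T_D * ab["dark"])
}

#' Daily synthesis rate of the reference (arrhythmic, unit-mean) protein
#'
#' The internal standard of relative quantification is represented by an
#' "average" protein whose transcript has no rhythm:
#' `k_s,ref = T_L * t_dusk + T_D * (24 - t_dusk)`.
#'
#' @inheritParams daily_synthesis_rate
#' @return scalar reference synthesis rate.
#' @export
reference_synthesis_rate <- function(t_dusk, T_L = 1.4, T_D = 1) {
  stopifnot(T_L > 0, T_D > 0)
  check_dusk(t_dusk)
  T_L * t_dusk + T_D * (24 - t_dusk)
}

#' Steady-state protein abundance
#'
#' For slowly turning-over proteins, abundance settles where synthesis is
#' balanced by degradation and growth dilution: `P = k_s / (k_d + mu)`.
#'
#' @param k_s daily synthesis rate.
#' @param k_d degradation rate (per day), `>= 0`.
#' @param mu growth dilution rate (per day), `>= 0`; `k_d + mu` must be `> 0`.
#' @return steady-state abundance.
#' @export
steady_state_abundance <- function(k_s, k_d, mu = 0) {
  stopifnot(k_d >= 0, mu >= 0)
  if (k_d + mu <= 0) stop("k_d + mu must be positive")
  k_s / (k_d + mu)
}

#' Normalised steady-state abundance under the coincidence model
#'
#' The model's central quantity, comparable to relative quantitative
#' proteomics:
#' \deqn{P_{norm} = \frac{R \int_0^{t_{dusk}} m(t)\,dt + \int_{t_{dusk}}^{24} m(t)\,dt}
#'                       {(R - 1)\, t_{dusk} + 24}}
#' where `R = T_L / T_D` is the light/dark translation ratio. The protein's
#' turnover is assumed equal to the reference protein's, so turnover and
#' dilution cancel in the ratio.
#'
#' @inheritParams entrain_profile
#' @param R light/dark translation ratio, `> 0` (1.4 for Arabidopsis rosettes).
#' @return scalar normalised abundance (dimensionless; equals the daily mean
#'   of `m` when `R = 1` or when `m` is constant).
#' @export
normalised_abundance <- function(profile, t_dusk, R = 1.4) {
  stopifnot(R > 0)
  ab <- light_dark_integrals(profile, t_dusk)
  unname((R * ab["light"] + ab["dark"]) / ((R - 1) * t_dusk + 24))
}

#' Relative change in abundance between two photoperiods
#'
#' `delta_P = (P2 - P1) / ((P1 + P2)/2)`: the difference normalised to the
#' mean of the pair, antisymmetric and bounded in `(-2, 2)` for positive
#' abundances.
#'
#' @param p1,p2 abundances at the first and second photoperiod (`p1 + p2 > 0`).
#' @return the relative change score.
#' @export
relative_change <- function(p1, p2) {
  if (any(p1 + p2 <= 0)) stop("p1 + p2 must be positive")
  (p2 - p1) / ((p1 + p2) / 2)
}

#' Predict photoperiod responses for a cohort of transcripts
#'
#' For every gene and photoperiod: entrain the 12:12 profile with the clock's
#' dusk sensitivity, evaluate the normalised abundance, and score the change
#' between a photoperiod pair (default 6 h vs 18 h, reported long-minus-short).
#'
#' @param cohort a list of [transcript_profile()]s (e.g. from
#'   [gen_transcript_cohort()]).
#' @param photoperiods dusk times in hours, each in `(0, 24)`.
#' @param R light/dark translation ratio.
#' @param dusk_sensitivity clock dusk sensitivity in `[0, 1]`.
#' @param pair length-2 photoperiod pair `(short, long)` for the change score;
#'   both must be in `photoperiods`.
#' @return list with `predictions` (`data.frame(gene_id, photoperiod_h,
#'   p_normalised)`) and `delta` (`data.frame(gene_id, delta_p)`).
#' @export
predict_response <- function(cohort, photoperiods = c(6, 8, 12, 18), R = 1.4,
                             dusk_sensitivity = 0, pair = c(6, 18)) {
  stopifnot(length(cohort) >= 1, length(photoperiods) >= 1,
            all(photoperiods > 0 & photoperiods < 24))
  if (!all(pair %in% photoperiods))
    stop("'pair' photoperiods must be among 'photoperiods'")
  ids <- vapply(cohort, function(p) p$gene_id, character(1))
  grid <- expand.grid(gene_id = ids, photoperiod_h = photoperiods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pn <- matrix(NA_real_, nrow = length(cohort), ncol = length(photoperiods),
               dimnames = list(ids, as.character(photoperiods)))
  for (j in seq_along(photoperiods)) {
    d <- photoperiods[j]
    for (i in seq_along(cohort)) {
      prof <- entrain_profile(cohort[[i]], d, dusk_sensitivity)
      pn[i, j] <- normalised_abundance(prof, d, R)
    }
  }
  grid$p_normalised <- as.vector(pn)
  delta <- data.frame(
    gene_id = ids,
    delta_p = relative_change(pn[, as.character(pair[1])],
                              pn[, as.character(pair[2])]),
    stringsAsFactors = FALSE, row.names = NULL)
  list(predictions = grid, delta = delta)
}

#' Fit-free translational coincidence model for a transcript cohort
#'
#' Constructs the coincidence model for a set of diel transcript profiles:
#' each gene's normalised protein abundance is predicted at every photoperiod
#' from its transcript rhythm, the light/dark translation ratio `R`, and the
#' clock's dusk sensitivity. The returned object supports `print()`,
#' `summary()`, `coef()`, `predict()`, `plot()` and `simulate()` (the latter
#' draws replicated noisy proteome tables emulating the measurement design).
#'
#' @inheritParams predict_response
#' @return an object of class `"coincidence_model"`.
#' @export
#' @examples
#' coh <- gen_transcript_cohort(20, seed = 1)
#' m <- coincidence_model(coh)
#' head(predict(m))
coincidence_model <- function(cohort, photoperiods = c(6, 8, 12, 18), R = 1.4,
                              dusk_sensitivity = 0, pair = c(6, 18)) {
  res <- predict_response(cohort, photoperiods, R, dusk_sensitivity, pair)
  structure(list(cohort = cohort, photoperiods = photoperiods, R = R,
                 dusk_sensitivity = dusk_sensitivity, pair = pair,
                 predictions = res$predictions, delta = res$delta,
                 call = match.call()),
            class = "coincidence_model")
}

#' @export
print.coincidence_model <- function(x, ...) {
  cat("Translational coincidence model\n")
  cat(sprintf("  genes: %d   photoperiods: %s h\n", length(x$cohort),
              paste(x$photoperiods, collapse = ", ")))
  cat(sprintf("  light/dark translation ratio R = %.3g, dusk sensitivity s = %.2f\n",
              x$R, x$dusk_sensitivity))
  cat(sprintf("  change score pair: %g h -> %g h (long minus short)\n",
              x$pair[1], x$pair[2]))
  invisible(x)
}

#' @export
coef.coincidence_model <- function(object, ...) {
  c(R = object$R, dusk_sensitivity = object$dusk_sensitivity)
}

#' Predicted normalised abundances from a coincidence model
#'
#' @param object a [coincidence_model()].
#' @param photoperiods optional new dusk times; defaults to those the model
#'   was built with.
#' @param type `"abundance"` for per-gene-per-photoperiod normalised
#'   abundances, `"delta"` for the between-pair change scores.
#' @param ... unused.
#' @return a `data.frame`.
#' @export
predict.coincidence_model <- function(object, photoperiods = NULL,
                                      type = c("abundance", "delta"), ...) {
  type <- match.arg(type)
  if (is.null(photoperiods)) {
    if (type == "abundance") return(object$predictions)
    return(object$delta)
  }
  res <- predict_response(object$cohort, photoperiods, object$R,
                          object$dusk_sensitivity,
                          pair = range(photoperiods))
  if (type == "abundance") res$predictions else res$delta
}

#' @export
summary.coincidence_model <- function(object, ...) {
  d <- object$delta$delta_p
  out <- list(model = object,
              delta_summary = summary(d),
              n_up = sum(d > 0), n_down = sum(d < 0))
  class(out) <- "summary.coincidence_model"
  out
}

#' @export
print.summary.coincidence_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("\nPredicted change %g h -> %g h:\n",
              x$model$pair[1], x$model$pair[2]))
  print(x$delta_summary)
  cat(sprintf("genes predicted up: %d, down: %d\n", x$n_up, x$n_down))
  invisible(x)
}

#' Plot predicted photoperiod change against transcript peak phase
#'
#' @param x a [coincidence_model()] built from a cohort with ground truth
#'   (otherwise peak phases are recomputed from the profiles).
#' @param ... passed to [graphics::plot()].
#' @export
plot.coincidence_model <- function(x, ...) {
  truth <- attr(x$cohort, "truth")
  phases <- if (!is.null(truth)) truth$peak_phase_h
            else vapply(x$cohort, peak_phase, numeric(1))
  graphics::plot(phases, x$delta$delta_p,
                 xlab = "transcript peak phase (ZT h)",
                 ylab = sprintf("predicted change, %g h to %g h",
                                x$pair[1], x$pair[2]),
                 ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
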