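#' Study-design scenario configuration
#'
#' Bundles the parameters of the emulated measurement design: four
#' photoperiods (6, 8, 12, 18 h), three biological replicates, multiplicative
#' replicate noise with a coefficient of variation of 0.07 (the observed
#' replicate CVs ranged 0.059-0.074), a light/dark translation ratio of 1.4,
#' and a dawn-tracking clock.
#'
#' @param photoperiods dusk times in hours, each in `(0, 24)`.
#' @param n_replicates biological replicates per photoperiod, `>= 1`.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   replicate noise, `>= 0`.
#' @param R light/dark translation ratio, `> 0`.
#' @param dusk_sensitivity clock dusk sensitivity in `[0, 1]`.
#' @param seed integer seed driving all randomness downstream.
#' @return an object of class `"scenario_config"`.
#' @export
scenario_config <- function(photoperiods = c(6, 8, 12, 18), n_replicates = 3,
                            noise_cv = 0.07, R = 1.4, dusk_sensitivity = 0,
                            seed = 1L) {
  stopifnot(all(photoperiods > 0 & photoperiods < 24),
            n_replicates >= 1, noise_cv >= 0, R > 0,
            dusk_sensitivity >= 0, dusk_sensitivity <= 1)
  structure(list(photoperiods = photoperiods,
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, R = R,
                 dusk_sensitivity = dusk_sensitivity,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# multiplicative lognormal noise with unit mean and the requested CV
# (sigma^2 = log(1 + CV^2); meanlog = -sigma^2/2 keeps E[noise] = 1)
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a replicated proteome relative-abundance table
#'
#' For each gene and photoperiod the replicate abundances are the coincidence
#' model's normalised abundance multiplied by independent lognormal noise with
#' the configured CV (unit mean, so the noiseless limit and the expectation
#' both reproduce the model exactly). The generating model values are returned
#' as ground truth for recovery tests.
#'
#' @param cohort a list of [transcript_profile()]s.
#' @param config a [scenario_config()].
#' @return `data.frame(protein_id, photoperiod_h, replicate, abundance)` with
#'   attributes `truth` (`gene_id, photoperiod_h, p_normalised`) and
#'   `truth_delta` (the model's change scores for the 6->18 h pair when both
#'   are present, otherwise the extreme pair).
#' @export
gen_proteome_table <- function(cohort, config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"), length(cohort) >= 1)
  pair <- if (all(c(6, 18) %in% config$photoperiods)) c(6, 18)
          else range(config$photoperiods)
  res <- predict_response(cohort, config$photoperiods, config$R,
                          config$dusk_sensitivity, pair = pair)
  set.seed(config$seed)
  pred <- res$predictions
  nrep <- config$n_replicates
  tab <- pred[rep(seq_len(nrow(pred)), each = nrep), ]
  tab$replicate <- rep(seq_len(nrep), times = nrow(pred))
  tab$abundance <- tab$p_normalised * lognormal_noise(nrow(tab), config$noise_cv)
  out <- data.frame(protein_id = tab$gene_id,
                    photoperiod_h = tab$photoperiod_h,
                    replicate = tab$replicate,
                    abundance = tab$abundance,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "truth") <- res$predictions
  attr(out, "truth_delta") <- res$delta
  out
}

#' Simulate proteome tables from a coincidence model
#'
#' `simulate()` method drawing `nsim` replicated proteome tables under the
#' model, as [gen_proteome_table()] does for a standalone cohort.
#'
#' @param object a [coincidence_model()].
#' @param nsim number of tables to draw.
#' @param seed integer seed.
#' @param n_replicates,noise_cv measurement design, see [scenario_config()].
#' @param ... unused.
#' @return a list of proteome `data.frame`s (length `nsim`), or a single
#'   `data.frame` when `nsim = 1`.
#' @export
simulate.coincidence_model <- function(object, nsim = 1, seed = 1L,
                                       n_replicates = 3, noise_cv = 0.07, ...) {
  sims <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    cfg <- scenario_config(object$photoperiods, n_replicates, noise_cv,
                           object$R, object$dusk_sensitivity,
                           seed = as.integer(seed) + i - 1L)
    sims[[i]] <- gen_proteome_table(object$cohort, cfg)
  }
  if (nsim == 1) sims[[1]] else sims
}

# hours of light elapsed in [0, t] under a dawn-at-0 schedule with dusk t_dusk
light_hours <- function(t, t_dusk) {
  full <- floor(t / 24)
  rem <- t - 24 * full
  full * t_dusk + pmin(rem, t_dusk)
}

#' Simulate a partial stable-isotope labelling time course
#'
#' Labelled fraction under piecewise-constant turnover:
#' `F(t) = efficiency * (1 - exp(-K(t)))` with
#' `K(t) = k_light * L(t) + k_dark * (t - L(t))`, `L(t)` the light hours
#' elapsed. Multiplicative noise is applied and the result clipped to
#' `[0, efficiency]`, mirroring the bounded nature of isotope incorporation.
#'
#' @param k_light,k_dark labelling/turnover rates per hour in light and dark,
#'   `>= 0`.
#' @param efficiency asymptotic labelled fraction (precursor enrichment), in
#'   `(0, 1]`.
#' @param times sampling times in hours since labelling start, increasing,
#'   first `>= 0`. The default design samples the dark period soon after
#'   labelling starts: interval-based rate estimates lose precision as label
#'   accumulates, so informative light and dark intervals belong early in the
#'   time course.
#' @param t_dusk photoperiod of the labelling schedule (dawn at 0 h).
#' @param noise_cv multiplicative noise CV.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param protein_id identifier.
#' @return an object of class `"labelling_series"`: list with `protein_id`,
#'   `times`, `fraction`, `t_dusk`, plus the noiseless `truth`.
#' @export
gen_labelling_series <- function(k_light, k_dark, efficiency = 0.8,
                                 times = c(0, 3, 6, 12, 18, 48),
                                 t_dusk = 6, noise_cv = 0, seed = NULL,
                                 protein_id = "prot") {
  stopifnot(k_light >= 0, k_dark >= 0, efficiency > 0, efficiency <= 1,
            length(times) >= 1, all(diff(times) > 0), times[1] >= 0,
            noise_cv >= 0)
  check_dusk(t_dusk)
  if (!is.null(seed)) set.seed(as.integer(seed))
  L <- light_hours(times, t_dusk)
  K <- k_light * L + k_dark * (times - L)
  truth <- efficiency * (1 - exp(-K))
  fr <- truth * lognormal_noise(length(times), noise_cv)
  fr <- pmin(pmax(fr, 0), efficiency)
  labelling_series(protein_id, times, fr, t_dusk, truth = truth)
}

#' Construct a labelling time course
#'
#' @param protein_id identifier.
#' @param times hours since labelling start, increasing, first `>= 0`.
#' @param fraction labelled fractions in `[0, 1]`.
#' @param t_dusk photoperiod of the schedule during labelling.
#' @param truth optional noiseless fractions (kept for recovery tests).
#' @return an object of class `"labelling_series"`.
#' @export
labelling_series <- function(protein_id, times, fraction, t_dusk = 12,
                             truth = NULL) {
  stopifnot(length(times) == length(fraction), all(diff(times) > 0),
            times[1] >= 0, all(fraction >= 0), all(fraction <= 1))
  check_dusk(t_dusk)
  structure(list(protein_id = as.character(protein_id), times = times,
                 fraction = fraction, t_dusk = t_dusk, truth = truth),
            class = "labelling_series")
}

#' @export
print.labelling_series <- function(x, ...) {
  cat(sprintf("labelling series '%s': %d timepoints over %g h, max fraction %.3f\n",
              x$protein_id, length(x$times), max(x$times), max(x$fraction)))
  invisible(x)
}

#' Simulate end-of-night / end-of-day transcript snapshots
#'
#' Emulates sampling a transcript just before lights-on (EN, ZT0) and just
#' before lights-off (ED, ZT = dusk) in each photoperiod, the two-point design
#' from which pseudo-time-series and arrhythmicity calls are built.
#'
#' @param cohort a list of [transcript_profile()]s (12:12-phased).
#' @param photoperiods dusk times sampled (default the five-photoperiod
#'   design `{4, 6, 8, 12, 18}`).
#' @param dusk_sensitivity clock dusk sensitivity.
#' @param noise_cv multiplicative replicate noise CV.
#' @param n_replicates replicates per sample.
#' @param seed integer seed.
#' @return `data.frame(gene_id, photoperiod_h, timepoint, replicate,
#'   abundance)` with `timepoint` in `{"EN", "ED"}`; noiseless values in the
#'   `truth` attribute.
#' @export
gen_diel_snapshot_table <- function(cohort, photoperiods = c(4, 6, 8, 12, 18),
                                    dusk_sensitivity = 0, noise_cv = 0.07,
                                    n_replicates = 3, seed = 1L) {
  stopifnot(all(photoperiods > 0 & photoperiods < 24), n_replicates >= 1)
  set.seed(as.integer(seed))
  rows <- vector("list", length(cohort) * length(photoperiods))
  k <- 0
  for (prof in cohort) {
    for (d in photoperiods) {
      ent <- entrain_profile(prof, d, dusk_sensitivity)
      en <- profile_value_at(ent, 0)
      ed <- profile_value_at(ent, d)
      k <- k + 1
      rows[[k]] <- data.frame(gene_id = prof$gene_id, photoperiod_h = d,
                              timepoint = c("EN", "ED"),
                              base = c(en, ed), stringsAsFactors = FALSE)
    }
  }
  base <- do.call(rbind, rows)
  nrep <- n_replicates
  tab <- base[rep(seq_len(nrow(base)), each = nrep), ]
  tab$replicate <- rep(seq_len(nrep), times = nrow(base))
  tab$abundance <- tab$base * lognormal_noise(nrow(tab), noise_cv)
  out <- data.frame(gene_id = tab$gene_id, photoperiod_h = tab$photoperiod_h,
                    timepoint = tab$timepoint, replicate = tab$replicate,
                    abundance = tab$abundance,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "truth") <- base
  out
}

# waveform-exact or interpolated evaluation of a profile at one time
profile_value_at <- function(profile, t) {
  if (!is.null(profile$waveform)) return(waveform_value(profile$waveform, t))
  stats::approx(profile$times, profile$values, xout = t %% 24)$y
}

#' Generate an annotation term-to-gene map with one planted term
#'
#' Random term assignments over a gene universe, optionally with one planted
#' term concentrated on a chosen gene subset, so enrichment machinery can be
#' verified against a known signal.
#'
#' @param gene_ids character vector of genes (the background).
#' @param n_terms number of random terms.
#' @param term_size genes per random term (drawn without replacement).
#' @param planted optional list `list(term = "name", genes = c(...))`; `genes`
#'   must be a subset of `gene_ids`.
#' @param seed integer seed.
#' @return `data.frame(term_id, gene_id)`.
#' @export
gen_annotation_map <- function(gene_ids, n_terms = 10, term_size = 25,
                               planted = NULL, seed = 1L) {
  stopifnot(length(gene_ids) >= 1, n_terms >= 0)
  set.seed(as.integer(seed))
  maps <- list()
  if (n_terms > 0) {
    sz <- min(term_size, length(gene_ids))
    for (i in seq_len(n_terms)) {
      maps[[i]] <- data.frame(term_id = sprintf("T%03d", i),
                              gene_id = sample(gene_ids, sz),
                              stringsAsFactors = FALSE)
    }
  }
  if (!is.null(planted)) {
    if (!all(planted$genes %in% gene_ids))
      stop("planted gene subset must lie within 'gene_ids'")
    maps[[length(maps) + 1L]] <- data.frame(term_id = planted$term,
                                            gene_id = planted$genes,
                                            stringsAsFactors = FALSE)
  }
  if (!length(maps)) return(data.frame(term_id = character(),
                                       gene_id = character(),
                                       stringsAsFactors = FALSE))
  out <- do.call(rbind, maps)
  row.names(out) <- NULL
  out
}
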