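#' Peak phase of a diel transcript profile
#'
#' The profile is linearly interpolated onto a 0.1-h grid over `[0, 24)` and
#' the phase of the maximum is returned; plateau ties are broken by the
#' earliest time.
#'
#' @param profile a [transcript_profile()] (must not be constant).
#' @return peak phase in hours, in `[0, 24)`.
#' @export
peak_phase <- function(profile) {
  stopifnot(inherits(profile, "transcript_profile"))
  grid <- seq(0, 23.9, by = 0.1)
  vals <- stats::approx(profile$times, profile$values, xout = grid)$y
  rng <- max(vals) - min(vals)
  if (rng <= 1e-9 * (1 + max(abs(vals))))
    stop("constant profile has no defined peak phase")
  grid[which(vals >= max(vals) - 1e-9 * (1 + max(vals)))[1]]
}

#' Relative (peak/mean) amplitude of a profile
#'
#' Maximum abundance over the cycle divided by the daily mean; the amplitude
#' convention behind the 1.5 and 1.7 rhythmicity thresholds.
#'
#' @param profile a [transcript_profile()] with positive daily mean.
#' @return the peak/mean ratio (`>= 1`).
#' @export
relative_amplitude <- function(profile) {
  m <- daily_mean(profile)
  if (m <= 0) stop("daily mean must be positive")
  if (!is.null(profile$waveform)) {
    w <- profile$waveform
    # the analytic peak value avoids the slight undershoot of a grid maximum
    return(waveform_value(w, w$peak_phase_h) / w$mean_level)
  }
  max(profile$values) / m
}

#' Assign a 2-h Zeitgeber phase bin
#'
#' @param peak_phase_h phase(s) in `[0, 24)`.
#' @return `data.frame(phase_bin, label)` with `phase_bin = floor(phase/2)`
#'   in `0..11` and labels `"ZT0-2"` ... `"ZT22-24"`.
#' @export
assign_phase_bin <- function(peak_phase_h) {
  if (any(peak_phase_h < 0 | peak_phase_h >= 24))
    stop("phase must lie in [0, 24)")
  b <- floor(peak_phase_h / 2)
  data.frame(phase_bin = as.integer(b),
             label = sprintf("ZT%d-%d", 2L * b, 2L * b + 2L),
             stringsAsFactors = FALSE)
}

#' Build per-gene pseudo-time-series from EN/ED snapshots
#'
#' Reconstructs a coarse diel series from two-point sampling across
#' photoperiods: ZT0 is the mean of all end-of-night samples (the clock is
#' dawn-referenced, so EN approximates ZT0 in every photoperiod), and each
#' end-of-day sample at photoperiod `p` represents ZT`p`.
#'
#' @param snapshots `data.frame(gene_id, photoperiod_h, timepoint, replicate,
#'   abundance)` with `timepoint` in `{"EN", "ED"}`.
#' @param photoperiods the photoperiods that must all be present (default
#'   `{4, 6, 8, 12, 18}`).
#' @return numeric matrix, genes in rows, columns named by the ZT times
#'   `0, 4, 6, 8, 12, 18`.
#' @export
build_pseudo_timeseries <- function(snapshots,
                                    photoperiods = c(4, 6, 8, 12, 18)) {
  need <- c("gene_id", "photoperiod_h", "timepoint", "abundance")
  stopifnot(all(need %in% names(snapshots)))
  genes <- unique(snapshots$gene_id)
  have <- unique(snapshots$photoperiod_h)
  if (!all(photoperiods %in% have))
    stop("missing photoperiod(s): ",
         paste(setdiff(photoperiods, have), collapse = ", "))
  out <- matrix(NA_real_, length(genes), length(photoperiods) + 1L,
                dimnames = list(genes, c("0", as.character(photoperiods))))
  for (g in genes) {
    sub <- snapshots[snapshots$gene_id == g, ]
    en <- sub$abundance[sub$timepoint == "EN" &
                          sub$photoperiod_h %in% photoperiods]
    if (!length(en)) stop("gene ", g, " has no EN samples")
    out[g, "0"] <- mean(en)
    for (p in photoperiods) {
      ed <- sub$abundance[sub$timepoint == "ED" & sub$photoperiod_h == p]
      if (!length(ed)) stop("gene ", g, " has no ED sample at ", p, " h")
      out[g, as.character(p)] <- mean(ed)
    }
  }
  out
}

# vectorised pooled-variance two-sample t-tests of ED vs EN per
# gene x photoperiod on log2 abundances; same statistic as
# t.test(var.equal = TRUE) (cross-checked in the unit tests)
ed_en_tests <- function(snapshots) {
  lg <- log2(snapshots$abundance)
  key <- factor(paste(snapshots$gene_id, snapshots$photoperiod_h,
                      snapshots$timepoint, sep = "\r"))
  n <- tapply(lg, key, length)
  if (any(n < 2)) stop("every gene x photoperiod x timepoint cell needs >= 2 replicates")
  m <- tapply(lg, key, mean)
  v <- tapply(lg, key, stats::var)
  info <- do.call(rbind, strsplit(names(m), "\r", fixed = TRUE))
  df <- data.frame(gene_id = info[, 1], photoperiod_h = info[, 2],
                   timepoint = info[, 3], n = as.vector(n), m = as.vector(m),
                   v = as.vector(v), stringsAsFactors = FALSE)
  ed <- df[df$timepoint == "ED", ]
  en <- df[df$timepoint == "EN", ]
  idx <- match(paste(ed$gene_id, ed$photoperiod_h),
               paste(en$gene_id, en$photoperiod_h))
  en <- en[idx, ]
  dfree <- ed$n + en$n - 2
  sp2 <- ((ed$n - 1) * ed$v + (en$n - 1) * en$v) / dfree
  tstat <- (ed$m - en$m) / sqrt(sp2 * (1 / ed$n + 1 / en$n))
  data.frame(gene_id = ed$gene_id, photoperiod_h = as.numeric(ed$photoperiod_h),
             t = tstat, p = 2 * stats::pt(-abs(tstat), dfree),
             stringsAsFactors = FALSE)
}

#' Select reliably arrhythmic transcripts
#'
#' A transcript is called reliably arrhythmic when (i) it is not diurnally
#' rhythmic in an external diel time-course analysis, and (ii) its end-of-day
#' and end-of-night expression do not differ significantly in any of the
#' sampled photoperiods, by two-tailed two-sample t-tests at `alpha`
#' Bonferroni-corrected across the photoperiods (threshold `alpha / n_pp`,
#' i.e. 0.01 for five photoperiods at `alpha = 0.05`).
#'
#' @param diel_rhythmic per-gene external diel evidence, named by gene:
#'   either a logical vector (`TRUE` = in the diurnally rhythmic set) or
#'   numeric ANOVA p-values (rhythmic when `p < alpha`).
#' @param snapshots EN/ED snapshot table, see [gen_diel_snapshot_table()];
#'   needs `>= 2` replicates per cell.
#' @param alpha significance threshold (default 0.05).
#' @return `data.frame(gene_id, arrhythmic, min_t_p)` where `min_t_p` is the
#'   smallest ED-vs-EN t-test p-value across photoperiods.
#' @export
select_arrhythmic <- function(diel_rhythmic, snapshots, alpha = 0.05) {
  tests <- ed_en_tests(snapshots)
  pps <- unique(tests$photoperiod_h)
  thr <- alpha / length(pps)
  minp <- tapply(tests$p, tests$gene_id, min)
  genes <- names(minp)
  if (is.null(names(diel_rhythmic)))
    stop("'diel_rhythmic' must be named by gene_id")
  missing <- setdiff(genes, names(diel_rhythmic))
  if (length(missing))
    stop("no diel rhythmicity information for: ",
         paste(utils::head(missing, 5), collapse = ", "))
  ext <- diel_rhythmic[genes]
  rhythmic_ext <- if (is.logical(ext)) ext else ext < alpha
  data.frame(gene_id = genes,
             arrhythmic = !rhythmic_ext & as.vector(minp) >= thr,
             min_t_p = as.vector(minp),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Circadian-consistency correlation filter
#'
#' Retains a transcript when the Pearson correlation between two of its
#' expression series (e.g. a diel time course and a photoperiod
#' pseudo-time-series, or a diel and a constant-light series) is at least the
#' threshold; transcripts with `r < 0.75` are filtered out under the default.
#'
#' @param series_a,series_b equal-length numeric series (`>= 3` points, both
#'   with nonzero variance).
#' @param threshold inclusive retention threshold on Pearson's r.
#' @return list with `r` and logical `pass`.
#' @export
correlation_filter <- function(series_a, series_b, threshold = 0.75) {
  stopifnot(length(series_a) == length(series_b), length(series_a) >= 3)
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0)
    stop("correlation undefined for a zero-variance series")
  r <- stats::cor(series_a, series_b)
  # inclusive boundary, robust to floating-point representation of r
  list(r = r, pass = r >= threshold - 1e-12)
}

#' Photoperiod mean-expression change filter
#'
#' Retains a transcript whose mean expression is photoperiod-insensitive:
#' the symmetric relative change `max(m1, m2)/min(m1, m2) - 1` must not
#' exceed the threshold (transcripts with a `> 0.3`-fold change are filtered
#' out under the default; the boundary value is retained).
#'
#' @param mean_spp,mean_lpp mean expression in the short and long photoperiod
#'   (both `> 0`).
#' @param threshold maximum tolerated relative change.
#' @return list with `change` and logical `pass`.
#' @export
mean_change_filter <- function(mean_spp, mean_lpp, threshold = 0.3) {
  if (mean_spp <= 0 || mean_lpp <= 0) stop("means must be positive")
  change <- max(mean_spp, mean_lpp) / min(mean_spp, mean_lpp) - 1
  # inclusive boundary (the 0.3 case is retained), floating-point safe
  list(change = change, pass = change <= threshold + 1e-12)
}
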