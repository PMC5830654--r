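#' Per-protein one-way ANOVA across photoperiods
#'
#' Classic one-way ANOVA on log2-transformed relative abundances, one test per
#' protein, with Benjamini-Hochberg adjustment across proteins to control the
#' global FDR.
#'
#' @param table `data.frame(protein_id, photoperiod_h, replicate, abundance)`
#'   with `>= 2` photoperiods and `>= 2` replicates per cell; abundances must
#'   be positive.
#' @return `data.frame(protein_id, anova_p, anova_q)`.
#' @export
photoperiod_anova <- function(table) {
  need <- c("protein_id", "photoperiod_h", "abundance")
  stopifnot(all(need %in% names(table)), all(table$abundance > 0))
  split_idx <- split(seq_len(nrow(table)), table$protein_id)
  ids <- names(split_idx)
  p <- vapply(split_idx, function(ix) {
    y <- log2(table$abundance[ix])
    g <- factor(table$photoperiod_h[ix])
    if (nlevels(g) < 2 || any(tabulate(g) < 2))
      stop("each protein needs >= 2 photoperiods with >= 2 replicates")
    if (stats::var(y) == 0) return(1)  # identical values: F = 0, p = 1
    stats::oneway.test(y ~ g, var.equal = TRUE)$p.value
  }, numeric(1))
  data.frame(protein_id = ids, anova_p = unname(p),
             anova_q = stats::p.adjust(unname(p), method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tukey HSD pairwise photoperiod contrasts per protein
#'
#' Fits the per-protein one-way model and applies the Tukey honest
#' significant differences post hoc test to all photoperiod pairs, then
#' adjusts each pair's p-values across proteins with Benjamini-Hochberg.
#'
#' @inheritParams photoperiod_anova
#' @return a `data.frame` with one row per protein: `protein_id`, and for
#'   every photoperiod pair `i < j` columns `tukey_p_<i>_<j>` (raw) and
#'   `tukey_q_<i>_<j>` (BH across proteins).
#' @export
pairwise_tukey <- function(table) {
  stopifnot(all(c("protein_id", "photoperiod_h", "abundance") %in% names(table)),
            all(table$abundance > 0))
  split_idx <- split(seq_len(nrow(table)), table$protein_id)
  ids <- names(split_idx)
  rows <- lapply(split_idx, function(ix) {
    y <- log2(table$abundance[ix])
    g <- factor(table$photoperiod_h[ix])
    if (nlevels(g) < 2 || any(tabulate(g) < 2))
      stop("each protein needs >= 2 photoperiods with >= 2 replicates")
    if (stats::var(y) == 0) {
      cmb <- utils::combn(levels(g), 2)
      p <- rep(1, ncol(cmb))
      names(p) <- paste(cmb[2, ], cmb[1, ], sep = "-")
      return(p)
    }
    tk <- stats::TukeyHSD(stats::aov(y ~ g))$g
    stats::setNames(tk[, "p adj"], rownames(tk))
  })
  pm <- do.call(rbind, rows)
  # normalise contrast names "b-a" -> "a_b" with numeric ordering
  pairs <- strsplit(colnames(pm), "-", fixed = TRUE)
  lab <- vapply(pairs, function(pr) {
    ab <- sort(as.numeric(pr))
    sprintf("%g_%g", ab[1], ab[2])
  }, character(1))
  out <- data.frame(protein_id = ids, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (k in seq_along(lab)) {
    out[[paste0("tukey_p_", lab[k])]] <- unname(pm[, k])
    out[[paste0("tukey_q_", lab[k])]] <- stats::p.adjust(pm[, k], method = "BH")
  }
  out
}

#' Maximal fold change across photoperiod means
#'
#' `fc = max(means)/min(means)`; the direction compares the longest- against
#' the shortest-photoperiod mean (`"up"` when strictly greater, `"down"` when
#' strictly smaller, `"none"` on a tie).
#'
#' @param means positive per-photoperiod mean abundances.
#' @param photoperiods the corresponding photoperiods (hours); defaults to
#'   `names(means)` or the index order.
#' @return list with `fc` (`>= 1`) and `direction`.
#' @export
max_fold_change <- function(means, photoperiods = NULL) {
  if (any(means <= 0)) stop("photoperiod means must be positive")
  if (is.null(photoperiods)) {
    photoperiods <- if (!is.null(names(means))) as.numeric(names(means))
                    else seq_along(means)
  }
  stopifnot(length(photoperiods) == length(means))
  long <- means[which.max(photoperiods)]
  short <- means[which.min(photoperiods)]
  dir <- if (long > short) "up" else if (long < short) "down" else "none"
  list(fc = max(means) / min(means), direction = dir)
}

#' Per-protein photoperiod statistics
#'
#' Convenience wrapper combining [photoperiod_anova()], [pairwise_tukey()]
#' and [max_fold_change()] into one table.
#'
#' @inheritParams photoperiod_anova
#' @return a `data.frame` with `protein_id`, `anova_p`, `anova_q`, `max_fc`,
#'   `direction` and the Tukey columns.
#' @export
protein_stats <- function(table) {
  an <- photoperiod_anova(table)
  tk <- pairwise_tukey(table)
  means <- stats::aggregate(abundance ~ protein_id + photoperiod_h,
                            data = table, FUN = mean)
  fc <- do.call(rbind, lapply(split(means, means$protein_id), function(d) {
    m <- max_fold_change(d$abundance, d$photoperiod_h)
    data.frame(protein_id = d$protein_id[1], max_fc = m$fc,
               direction = m$direction, stringsAsFactors = FALSE)
  }))
  out <- merge(an, fc, by = "protein_id")
  out <- merge(out, tk, by = "protein_id")
  out[order(out$protein_id), , drop = FALSE]
}

#' Split significant proteins into up/down sets
#'
#' @param stats a [protein_stats()]-style `data.frame` (needs `protein_id`,
#'   `anova_p`, `direction`, and `max_fc` when filtering on fold change).
#' @param p_threshold significance threshold on the raw ANOVA p (default
#'   0.05, the criterion behind "changed significantly with photoperiod").
#' @param fc_threshold optional minimum maximal fold change.
#' @param use_adjusted use `anova_q` instead of `anova_p`.
#' @return list of character vectors `up` and `down`.
#' @export
select_significant <- function(stats, p_threshold = 0.05, fc_threshold = NULL,
                               use_adjusted = FALSE) {
  if (!nrow(stats)) return(list(up = character(), down = character()))
  p <- if (use_adjusted) stats$anova_q else stats$anova_p
  keep <- p < p_threshold
  if (!is.null(fc_threshold)) keep <- keep & stats$max_fc > fc_threshold
  list(up = stats$protein_id[keep & stats$direction == "up"],
       down = stats$protein_id[keep & stats$direction == "down"])
}

# one-sided (overrepresentation) Fisher p for the 2x2 table
# [in_set&in_term, in_set&!term; !set&term, !set&!term]
fisher_greater <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
}

#' Sliding fold-change-window term enrichment
#'
#' Bins changed proteins into overlapping fold-change windows (width 0.2,
#' step 0.1: 1.0-1.2, 1.1-1.3, ...) and tests each annotation term for
#' overrepresentation inside each window against the background of all
#' quantified proteins, with a one-sided Fisher's exact test. Both raw and
#' BH-adjusted (across term x window pairs) p-values are returned.
#'
#' @param fc named numeric vector of maximal fold changes for the proteins in
#'   the changed set under scrutiny (names are protein ids).
#' @param annotations `data.frame(term_id, gene_id)` term-to-protein map.
#' @param background character vector of all quantified protein ids (must
#'   contain `names(fc)`).
#' @param window_width,window_step window geometry on the fold-change axis.
#' @return `data.frame(term_id, window_lo, window_hi, a, b, c, d, fisher_p,
#'   adjusted_p)` where `a..d` are the contingency counts (window&term,
#'   window only, term only, neither) over the background.
#' @export
fc_window_enrichment <- function(fc, annotations, background,
                                 window_width = 0.2, window_step = 0.1) {
  stopifnot(!is.null(names(fc)), all(names(fc) %in% background),
            length(background) >= 1)
  terms <- split(annotations$gene_id, annotations$term_id)
  terms <- lapply(terms, intersect, background)
  if (!length(terms) || max(fc) < 1)
    return(data.frame(term_id = character(), window_lo = numeric(),
                      window_hi = numeric(), a = integer(), b = integer(),
                      c = integer(), d = integer(), fisher_p = numeric(),
                      adjusted_p = numeric(), stringsAsFactors = FALSE))
  n_win <- max(1L, ceiling((max(fc) - 1 - window_width) / window_step) + 1L)
  lows <- 1 + window_step * (seq_len(n_win) - 1L)
  N <- length(background)
  rows <- list(); k <- 0
  for (w in seq_along(lows)) {
    lo <- lows[w]; hi <- lo + window_width
    inwin <- names(fc)[fc >= lo & fc < hi]
    for (tn in names(terms)) {
      tg <- terms[[tn]]
      a <- length(intersect(inwin, tg))
      b <- length(inwin) - a
      cc <- length(tg) - a
      d <- N - a - b - cc
      k <- k + 1
      rows[[k]] <- data.frame(term_id = tn, window_lo = lo, window_hi = hi,
                              a = a, b = b, c = cc, d = d,
                              fisher_p = fisher_greater(a, b, cc, d),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$fisher_p, method = "BH")
  row.names(out) <- NULL
  out
}

#' Phase-bin enrichment of up- and down-regulated proteins
#'
#' For every 2-h Zeitgeber phase bin, tests whether the up-regulated (and,
#' separately, the down-regulated) set is overrepresented among proteins whose
#' transcripts peak in that bin, by one-sided Fisher's exact tests against the
#' phased background. A signed summary score,
#' `-log10(p_up) + log10(p_down)`, is positive where the up-set concentrates
#' and negative where the down-set does.
#'
#' @param up_set,down_set character vectors of protein ids (subsets of
#'   `names(phase_bins)`).
#' @param phase_bins named integer vector mapping every background protein to
#'   its phase bin `0..11` (see [assign_phase_bin()]).
#' @return `data.frame(phase_bin, label, n_bin, p_up, p_down, q_up, q_down,
#'   signed_score)`.
#' @export
phase_enrichment <- function(up_set, down_set, phase_bins) {
  stopifnot(!is.null(names(phase_bins)))
  background <- names(phase_bins)
  bad <- setdiff(c(up_set, down_set), background)
  if (length(bad)) stop("proteins without a phase bin: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  N <- length(background)
  bins <- 0:11
  res <- lapply(bins, function(b) {
    inbin <- background[phase_bins == b]
    test_set <- function(s) {
      if (!length(s)) return(1)
      a <- length(intersect(s, inbin))
      fisher_greater(a, length(s) - a, length(inbin) - a,
                     N - length(s) - length(inbin) + a)
    }
    data.frame(phase_bin = b, label = sprintf("ZT%d-%d", 2 * b, 2 * b + 2),
               n_bin = length(inbin),
               p_up = test_set(up_set), p_down = test_set(down_set),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_up <- stats::p.adjust(out$p_up, method = "BH")
  out$q_down <- stats::p.adjust(out$p_down, method = "BH")
  out$signed_score <- -log10(out$p_up) + log10(out$p_down)
  out
}

#' Hypergeometric test of set overlap
#'
#' Upper-tail probability of observing at least the realised overlap between
#' two subsets of a common background (e.g. circadian-controlled transcripts
#' vs photoperiod-regulated proteins).
#'
#' @param background_n size of the background universe.
#' @param set1,set2 character vectors, both subsets of the background.
#' @return the p-value `P(X >= |set1 & set2|)`.
#' @export
overlap_hypergeometric <- function(background_n, set1, set2) {
  k <- length(intersect(set1, set2))
  m <- length(unique(set1)); n <- length(unique(set2))
  if (m > background_n || n > background_n)
    stop("sets must fit within the background")
  stats::phyper(k - 1, m, background_n - m, n, lower.tail = FALSE)
}

#' Measured between-photoperiod change scores
#'
#' Computes the same change score as the coincidence model's prediction,
#' `(mean_lpp - mean_spp) / ((mean_spp + mean_lpp)/2)`, from replicate means
#' of a proteome table.
#'
#' @inheritParams photoperiod_anova
#' @param pair length-2 photoperiod pair `(short, long)`.
#' @return `data.frame(protein_id, delta_p)`.
#' @export
measured_delta <- function(table, pair = c(6, 18)) {
  stopifnot(length(pair) == 2, all(pair %in% table$photoperiod_h))
  sub <- table[table$photoperiod_h %in% pair, ]
  means <- stats::aggregate(abundance ~ protein_id + photoperiod_h,
                            data = sub, FUN = mean)
  spp <- means[means$photoperiod_h == pair[1], ]
  lpp <- means[means$photoperiod_h == pair[2], ]
  idx <- match(spp$protein_id, lpp$protein_id)
  data.frame(protein_id = spp$protein_id,
             delta_p = relative_change(spp$abundance, lpp$abundance[idx]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare model-predicted and measured photoperiod changes
#'
#' Pearson correlation (with p-value) between predicted and measured change
#' scores, and the ordinary least-squares fit of measured on predicted
#' (measured is the noisier axis; set `swap = TRUE` for the other
#' orientation).
#'
#' @param predicted,measured paired numeric vectors (`>= 3` values, nonzero
#'   variance).
#' @param swap regress predicted on measured instead.
#' @return list with `pearson_r`, `pearson_p`, `slope`, `intercept`, `n`.
#' @export
evaluate_model <- function(predicted, measured, swap = FALSE) {
  keep <- is.finite(predicted) & is.finite(measured)
  predicted <- predicted[keep]; measured <- measured[keep]
  if (length(predicted) < 3) stop("need >= 3 paired values")
  if (stats::sd(predicted) == 0 || stats::sd(measured) == 0)
    stop("zero variance in predicted or measured changes")
  ct <- stats::cor.test(predicted, measured, method = "pearson")
  fit <- if (swap) stats::lm(predicted ~ measured)
         else stats::lm(measured ~ predicted)
  cf <- stats::coef(fit)
  list(pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
       slope = unname(cf[2]), intercept = unname(cf[1]),
       n = length(predicted))
}
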