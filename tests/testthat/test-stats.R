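make_table <- function(mat, photoperiods = c(6, 8, 12, 18), reps = 3) {
  # mat: proteins x (photoperiods*reps) abundances
  do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
    data.frame(protein_id = rownames(mat)[i],
               photoperiod_h = rep(photoperiods, each = reps),
               replicate = rep(seq_len(reps), times = length(photoperiods)),
               abundance = mat[i, ], stringsAsFactors = FALSE)
  }))
}

test_that("per-protein ANOVA matches stats::aov and degenerates sensibly", {
  set.seed(1)
  m <- matrix(exp(rnorm(24, 0, 0.2)), nrow = 2,
              dimnames = list(c("pA", "pB"), NULL))
  m["pB", ] <- 1.5   # identical values in all groups
  tab <- make_table(m)
  res <- photoperiod_anova(tab)
  ref <- summary(aov(log2(abundance) ~ factor(photoperiod_h),
                     data = tab[tab$protein_id == "pA", ]))[[1]]
  expect_equal(res$anova_p[res$protein_id == "pA"], ref[["Pr(>F)"]][1],
               tolerance = 1e-10)
  expect_equal(res$anova_p[res$protein_id == "pB"], 1)
  expect_equal(res$anova_q, bh_oracle(res$anova_p))
})

test_that("Benjamini-Hochberg follows the step-up formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, method = "BH"), rep(0.04, 4))
  set.seed(2)
  pr <- runif(50)
  expect_equal(p.adjust(pr, method = "BH"), bh_oracle(pr))
})

test_that("Tukey contrasts flag a single shifted photoperiod", {
  set.seed(3)
  base <- exp(rnorm(12, 0, 0.05))
  shifted <- base
  shifted[10:12] <- shifted[10:12] * 4   # 18-h group moved ~ 10 sigma in log2
  m <- rbind(null = base, hit = shifted)
  tab <- make_table(m)
  tk <- pairwise_tukey(tab)
  hit <- tk[tk$protein_id == "hit", ]
  expect_lt(hit$tukey_p_6_18, 0.001)
  expect_lt(hit$tukey_p_8_18, 0.001)
  expect_lt(hit$tukey_p_12_18, 0.001)
  expect_gt(hit$tukey_p_6_12, 0.2)
  # identical groups: all contrasts at 1
  flat <- make_table(matrix(2, 1, 12, dimnames = list("f", NULL)))
  expect_true(all(unlist(pairwise_tukey(flat)[, -1]) == 1))
})

test_that("with two groups Tukey reduces to the pooled t-test", {
  set.seed(4)
  m <- matrix(exp(rnorm(8, 0, 0.1)), 1, dimnames = list("p", NULL))
  tab <- make_table(m, photoperiods = c(6, 18), reps = 4)
  tk <- pairwise_tukey(tab)
  tt <- t.test(log2(abundance) ~ photoperiod_h, data = tab, var.equal = TRUE)
  expect_equal(tk$tukey_p_6_18, tt$p.value, tolerance = 1e-6)
})

test_that("maximal fold change and direction follow the long-vs-short rule", {
  expect_equal(max_fold_change(c(1, 1.1, 1.5, 2), c(6, 8, 12, 18)),
               list(fc = 2, direction = "up"))
  expect_equal(max_fold_change(c(2, 1.5, 1.2, 1), c(6, 8, 12, 18)),
               list(fc = 2, direction = "down"))
  expect_equal(max_fold_change(c(1, 1, 1, 1), c(6, 8, 12, 18)),
               list(fc = 1, direction = "none"))
  # non-monotone profile: extremes define the fold change
  expect_equal(max_fold_change(c(1, 3, 0.5, 1.2), c(6, 8, 12, 18)),
               list(fc = 6, direction = "up"))
  expect_error(max_fold_change(c(1, 0), c(6, 18)), "positive")
})

test_that("significant sets split by direction and optional fold change", {
  st <- data.frame(protein_id = c("a", "b", "c", "d"),
                   anova_p = c(0.04, 0.04, 0.2, 0.01),
                   anova_q = c(0.08, 0.08, 0.3, 0.04),
                   max_fc = c(1.6, 1.4, 2.0, 1.8),
                   direction = c("up", "up", "down", "down"),
                   stringsAsFactors = FALSE)
  s0 <- select_significant(st)
  expect_setequal(s0$up, c("a", "b"))
  expect_setequal(s0$down, "d")
  s1 <- select_significant(st, fc_threshold = 1.5)
  expect_setequal(s1$up, "a")
  expect_setequal(s1$down, "d")
  empty <- select_significant(st[0, ])
  expect_length(empty$up, 0)
})

test_that("hypergeometric overlap matches enumeration and the printed cases", {
  expect_equal(overlap_hypergeometric(10, letters[1:5], letters[1:5]),
               1 / choose(10, 5))
  expect_equal(overlap_hypergeometric(10, letters[1:5], letters[6:10]), 1)
  expect_equal(overlap_hypergeometric(6, letters[1:3], letters[1:3]),
               1 / choose(6, 3))   # the 3/0/0/3 table: p = 0.05
  for (N in c(5, 9, 12)) {
    for (K in 0:N) for (n in 0:N) {
      k <- min(K, n)
      if (k == 0) next
      s1 <- paste0("x", seq_len(K))
      s2 <- paste0("x", c(seq_len(k), if (n > k) K + seq_len(n - k)))
      if (K + (n - k) > N) next
      expect_equal(overlap_hypergeometric(N, s1, s2),
                   hyper_upper_oracle(N, K, n, k), tolerance = 1e-12)
    }
  }
})

test_that("fold-change window enrichment recovers planted structure only", {
  genes <- sprintf("g%03d", 1:80)
  target <- genes[1:10]
  ann <- gen_annotation_map(genes, n_terms = 5, term_size = 15,
                            planted = list(term = "HIT", genes = target),
                            seed = 8)
  fc <- c(setNames(rep(1.25, 10), target),
          setNames(runif(20, 1.5, 2.5), genes[11:30]))
  enr <- fc_window_enrichment(fc, ann, background = genes)
  expect_true(all(enr$a + enr$b + enr$c + enr$d == 80))
  best <- enr[which.min(enr$fisher_p), ]
  expect_equal(best$term_id, "HIT")
  expect_true(best$window_lo <= 1.25 && best$window_hi > 1.25)
})

test_that("uniform annotations yield no adjusted enrichment in most seeds", {
  genes <- sprintf("g%03d", 1:100)
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    ann <- gen_annotation_map(genes, n_terms = 6, term_size = 20,
                              seed = seed)
    fc <- setNames(runif(30, 1, 2), sample(genes, 30))
    enr <- fc_window_enrichment(fc, ann, background = genes)
    if (nrow(enr) && min(enr$adjusted_p) < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 5)
})

test_that("phase enrichment highlights the bins the up-set came from", {
  set.seed(9)
  background <- sprintf("g%03d", 1:240)
  bins <- setNames(rep(0:11, each = 20), background)
  up <- background[bins %in% 5:7]           # drawn only from ZT10-16
  res <- phase_enrichment(up, character(0), bins)
  expect_equal(nrow(res), 12)
  expect_true(all(res$p_up[res$phase_bin %in% 5:7] < 0.01))
  expect_true(all(res$p_down == 1))
  expect_true(all(res$signed_score[res$phase_bin %in% 5:7] > 0))
  expect_error(phase_enrichment("missing", character(0), bins), "phase bin")
})

test_that("random up-sets stay unenriched after adjustment in most seeds", {
  background <- sprintf("g%03d", 1:240)
  bins <- setNames(rep(0:11, each = 20), background)
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    up <- sample(background, 40)
    res <- phase_enrichment(up, character(0), bins)
    if (min(res$q_up) < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 5)
})

test_that("measured change scores mirror the model definition", {
  m <- matrix(c(rep(1, 3), rep(1, 3), rep(1, 3), rep(3, 3)), 1,
              dimnames = list("p", NULL))
  tab <- make_table(m)
  expect_equal(measured_delta(tab, c(6, 18))$delta_p, 1.0)
  expect_equal(measured_delta(tab, c(18, 6))$delta_p, -1.0)
  expect_error(measured_delta(tab, c(6, 20)), "photoperiod")
})

test_that("model evaluation returns exact statistics for exact data", {
  x <- c(-0.3, -0.1, 0, 0.2, 0.5)
  ev <- evaluate_model(x, x)
  expect_equal(ev$pearson_r, 1)
  expect_equal(ev$slope, 1)
  expect_equal(ev$intercept, 0, tolerance = 1e-12)
  ev2 <- evaluate_model(x, 0.75 * x)
  expect_equal(ev2$slope, 0.75)
  expect_equal(ev2$pearson_r, 1)
  ev3 <- evaluate_model(x, 0.75 * x, swap = TRUE)
  expect_equal(ev3$slope, 1 / 0.75)
  expect_error(evaluate_model(x, rep(1, 5)), "variance")
})

test_that("protein_stats assembles ANOVA, Tukey and fold changes", {
  coh <- gen_transcript_cohort(6, seed = 14)
  tab <- gen_proteome_table(coh, scenario_config(seed = 14))
  st <- protein_stats(tab)
  expect_setequal(st$protein_id, unique(tab$protein_id))
  expect_true(all(c("anova_p", "anova_q", "max_fc", "direction",
                    "tukey_p_6_18") %in% names(st)))
  expect_true(all(st$max_fc >= 1))
  expect_true(all(st$anova_q >= 0 & st$anova_q <= 1))
})
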