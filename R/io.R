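tc_schemas <- list(
  transcripts = list(cols = c(gene_id = "character", time_h = "numeric",
                              abundance = "numeric"),
                     key = c("gene_id", "time_h")),
  proteome = list(cols = c(protein_id = "character", photoperiod_h = "numeric",
                           replicate = "numeric", abundance = "numeric"),
                  key = c("protein_id", "photoperiod_h", "replicate")),
  labelling = list(cols = c(protein_id = "character", time_h = "numeric",
                            labelled_fraction = "numeric"),
                   key = c("protein_id", "time_h")),
  annotations = list(cols = c(term_id = "character", gene_id = "character"),
                     key = c("term_id", "gene_id")),
  snapshots = list(cols = c(gene_id = "character", photoperiod_h = "numeric",
                            timepoint = "character", replicate = "numeric",
                            abundance = "numeric"),
                   key = c("gene_id", "photoperiod_h", "timepoint",
                           "replicate")),
  truth = list(cols = c(gene_id = "character", photoperiod_h = "numeric",
                        p_normalised = "numeric"),
               key = c("gene_id", "photoperiod_h")),
  predictions = list(cols = c(gene_id = "character",
                              photoperiod_h = "numeric",
                              p_normalised = "numeric",
                              delta_p_6_18 = "numeric"),
                     key = c("gene_id", "photoperiod_h")))

#' Read a validated TSV interchange table
#'
#' Strict reader for the package's tab-separated interchange formats. The
#' header must contain exactly the schema's columns, numeric columns are
#' parsed locale-independently (dot decimal), and duplicated key rows are
#' rejected with their row number.
#'
#' @param path file path.
#' @param schema one of `"transcripts"`, `"proteome"`, `"labelling"`,
#'   `"annotations"`, `"snapshots"`, `"truth"`, `"predictions"`.
#' @return a typed `data.frame`.
#' @export
read_tc_table <- function(path, schema) {
  schema <- match.arg(schema, names(tc_schemas))
  sc <- tc_schemas[[schema]]
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = NA, stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(names(sc$cols), names(df))
  if (length(missing))
    stop("schema '", schema, "': missing column(s) ",
         paste(missing, collapse = ", "), " in ", path)
  extra <- setdiff(names(df), names(sc$cols))
  if (length(extra))
    stop("schema '", schema, "': unexpected column(s) ",
         paste(extra, collapse = ", "), " in ", path)
  df <- df[names(sc$cols)]
  for (cn in names(sc$cols)) {
    if (sc$cols[[cn]] == "numeric") {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      bad <- which(is.na(v) & !is.na(df[[cn]]))
      if (length(bad))
        stop("non-numeric value in column '", cn, "', data row ", bad[1])
      df[[cn]] <- v
    } else {
      df[[cn]] <- as.character(df[[cn]])
    }
  }
  key <- do.call(paste, c(df[sc$key], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated (", paste(sc$key, collapse = ", "),
         ") at data row ", dup[1])
  message(sprintf("read %d rows from %s [%s]", nrow(df), path, schema))
  df
}

#' Write a TSV interchange table
#'
#' Numbers are formatted with `%.10g`, so identical inputs produce
#' byte-identical files (the determinism contract of the pipeline).
#'
#' @param df `data.frame` to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tc_table <- function(df, path) {
  out <- df
  for (cn in names(out))
    if (is.numeric(out[[cn]])) out[[cn]] <- sprintf("%.10g", out[[cn]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Convert a transcripts table to profile objects
#'
#' @param df `data.frame(gene_id, time_h, abundance)` from
#'   [read_tc_table()].
#' @return a named list of [transcript_profile()]s (tabulated; integrated by
#'   trapezoid downstream).
#' @export
profiles_from_table <- function(df) {
  stopifnot(all(c("gene_id", "time_h", "abundance") %in% names(df)))
  lapply(split(df, df$gene_id), function(d) {
    o <- order(d$time_h)
    transcript_profile(d$gene_id[1], d$time_h[o], d$abundance[o])
  })
}

#' Flatten profiles to a transcripts table
#'
#' @param profiles a list of [transcript_profile()]s.
#' @return `data.frame(gene_id, time_h, abundance)` (the closing 24-h node is
#'   dropped; it duplicates ZT0).
#' @export
profiles_to_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    n <- length(p$times)
    data.frame(gene_id = p$gene_id, time_h = p$times[-n],
               abundance = p$values[-n], stringsAsFactors = FALSE)
  })) -> out
  row.names(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Strictly validated configuration for [run_pipeline()]. Unknown fields are
#' rejected so a typo cannot silently fall back to a default.
#'
#' @param n_genes synthetic cohort size.
#' @param photoperiods dusk times in hours.
#' @param R light/dark translation ratio.
#' @param dusk_sensitivity clock dusk sensitivity in `[0, 1]`.
#' @param n_replicates replicates per photoperiod.
#' @param noise_cv replicate noise CV.
#' @param grid_step transcript sampling grid (hours).
#' @param pair photoperiod pair for change scores.
#' @param p_threshold ANOVA significance threshold.
#' @param fc_threshold fold-change threshold for the significant-set split.
#' @param seed integer seed for all randomness.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_genes = 100, photoperiods = c(6, 8, 12, 18),
                            R = 1.4, dusk_sensitivity = 0, n_replicates = 3,
                            noise_cv = 0.07, grid_step = 0.1,
                            pair = c(6, 18), p_threshold = 0.05,
                            fc_threshold = 1.5, seed = 1L) {
  stopifnot(n_genes >= 2, all(photoperiods > 0 & photoperiods < 24),
            R > 0, dusk_sensitivity >= 0, dusk_sensitivity <= 1,
            n_replicates >= 2, noise_cv >= 0, grid_step > 0,
            length(pair) == 2, all(pair %in% photoperiods),
            p_threshold > 0, fc_threshold > 0)
  structure(list(n_genes = as.integer(n_genes), photoperiods = photoperiods,
                 R = R, dusk_sensitivity = dusk_sensitivity,
                 n_replicates = as.integer(n_replicates), noise_cv = noise_cv,
                 grid_step = grid_step, pair = pair,
                 p_threshold = p_threshold, fc_threshold = fc_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose keys are [pipeline_config()] arguments;
#'   unknown keys are rejected.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

# small deterministic polynomial content hash for the run manifest
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full synthetic coincidence pipeline
#'
#' Simulate a transcript cohort under the configured study design, predict
#' normalised abundances and change scores with the coincidence model,
#' simulate the replicated proteome table, classify rhythms, compute
#' per-protein photoperiod statistics, and evaluate predictions against the
#' simulated measurements. All artefacts are written as TSV/JSON into
#' `out_dir` together with a manifest (config hash, seed, package version);
#' identical config and seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory artefacts (`cohort`, `model`,
#'   `proteome`, `rhythms`, `stats`, `evaluation`) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  cohort <- stage("simulate", gen_transcript_cohort(
    config$n_genes, grid_step = config$grid_step, seed = config$seed))
  model <- stage("predict", coincidence_model(
    cohort, config$photoperiods, config$R, config$dusk_sensitivity,
    config$pair))
  proteome <- stage("proteome", gen_proteome_table(cohort, scenario_config(
    config$photoperiods, config$n_replicates, config$noise_cv, config$R,
    config$dusk_sensitivity, seed = config$seed + 1L)))
  rhythms <- stage("classify", {
    ph <- vapply(cohort, peak_phase, numeric(1))
    amp <- vapply(cohort, relative_amplitude, numeric(1))
    bins <- assign_phase_bin(ph)
    data.frame(gene_id = names(cohort), peak_phase_h = unname(ph),
               phase_bin = bins$phase_bin, phase_label = bins$label,
               rel_amplitude = unname(amp), stringsAsFactors = FALSE,
               row.names = NULL)
  })
  stats_tab <- stage("stats", protein_stats(proteome))
  evaluation <- stage("evaluate", {
    meas <- measured_delta(proteome, config$pair)
    pred <- model$delta
    idx <- match(meas$protein_id, pred$gene_id)
    evaluate_model(pred$delta_p[idx], meas$delta_p)
  })

  stage("write", {
    write_tc_table(profiles_to_table(cohort),
                   file.path(out_dir, "transcripts.tsv"))
    write_tc_table(proteome, file.path(out_dir, "proteome.tsv"))
    truth <- attr(proteome, "truth")
    write_tc_table(data.frame(gene_id = truth$gene_id,
                              photoperiod_h = truth$photoperiod_h,
                              p_normalised = truth$p_normalised,
                              stringsAsFactors = FALSE),
                   file.path(out_dir, "truth.tsv"))
    preds <- model$predictions
    preds$delta_p_6_18 <- model$delta$delta_p[match(preds$gene_id,
                                                    model$delta$gene_id)]
    write_tc_table(preds, file.path(out_dir, "predictions.tsv"))
    write_tc_table(rhythms, file.path(out_dir, "rhythms.tsv"))
    write_tc_table(stats_tab, file.path(out_dir, "stats.tsv"))
    jsonlite::write_json(evaluation, file.path(out_dir, "eval.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg_txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                digits = NA)
    manifest <- list(config = unclass(config),
                     config_hash = fnv1a32(cfg_txt),
                     seed = config$seed,
                     package_version = as.character(
                       utils::packageVersion("transcoin")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    NULL
  })
  invisible(list(cohort = cohort, model = model, proteome = proteome,
                 rhythms = rhythms, stats = stats_tab,
                 evaluation = evaluation, out_dir = out_dir))
}
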