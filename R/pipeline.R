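#' Default end-to-end run configuration
#'
#' Assembles a `run_config`: two cohort configurations (mimic-like and
#' gicu-like at their published sizes by default), the multiple-source
#' split specification, hyperparameter grids, number of repeated splits,
#' feature-set selector, imputation mode and master seed. Cohort seeds not
#' set explicitly are derived deterministically from the master seed.
#'
#' @param n_mimic,n_gicu Cohort sizes.
#' @param n_splits Repeated train/test splits (100 at study scale).
#' @param seed Master seed driving every stage.
#' @param feature_set `"base"` (18 physiological features), `"extended"`
#'   (+ age, sex, BMI, hours since admission) or `"both"` (default): base
#'   runs all four systems, extended adds the two classifier variants.
#' @param imputation `"knn"` or `"complete"` (complete-case drops instances
#'   with any missing base feature).
#' @param knn_k Neighbours for imputation.
#' @param importance_repeats Permutations per feature and split.
#' @param ntree Trees per forest grid point.
#' @return Object of class `run_config` (a named list).
#' @export
default_run_config <- function(n_mimic = 7592, n_gicu = 1870,
                               n_splits = 100, seed = 1,
                               feature_set = c("both", "base", "extended"),
                               imputation = c("knn", "complete"),
                               knn_k = 5, importance_repeats = 5,
                               ntree = 60L) {
  structure(list(
    mimic = mimic_like_config(n_patients = n_mimic, seed = seed + 1L),
    gicu = gicu_like_config(n_patients = n_gicu, seed = seed + 2L),
    split = split_spec(test_fraction = 0.30, primary = "gicu"),
    grids = default_grids(ntree = ntree),
    n_splits = n_splits,
    feature_set = match.arg(feature_set),
    imputation = match.arg(imputation),
    knn_k = knn_k,
    importance_repeats = importance_repeats,
    seed = seed
  ), class = "run_config")
}

#' Read / write a run configuration file
#'
#' Serialises the scalar fields and the two cohort configurations to YAML
#' (default) or JSON, chosen by extension. Grids and the split spec are
#' rebuilt from their serialised fields on read.
#'
#' @param config A `run_config`.
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @export
write_run_config <- function(config, path) {
  ser <- list(
    seed = config$seed, n_splits = config$n_splits,
    feature_set = config$feature_set, imputation = config$imputation,
    knn_k = config$knn_k, importance_repeats = config$importance_repeats,
    split = unclass(config$split),
    mimic = unclass(config$mimic),
    gicu = unclass(config$gicu)
  )
  ser$mimic$outcome_coefficients <- as.list(ser$mimic$outcome_coefficients)
  ser$gicu$outcome_coefficients <- as.list(ser$gicu$outcome_coefficients)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(ser, path)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  cfg <- default_run_config(
    n_splits = raw$n_splits %||% 100,
    seed = raw$seed %||% 1,
    feature_set = raw$feature_set %||% "both",
    imputation = raw$imputation %||% "knn",
    knn_k = raw$knn_k %||% 5,
    importance_repeats = raw$importance_repeats %||% 5
  )
  rebuild <- function(ser) {
    co <- unlist(ser$outcome_coefficients)
    cohort_config(
      name = ser$name, n_patients = ser$n_patients,
      frac_female = ser$frac_female,
      age_median_iqr = unlist(ser$age_median_iqr),
      bmi_median_iqr = unlist(ser$bmi_median_iqr),
      los_median_iqr = unlist(ser$los_median_iqr),
      discharge_delay_median_iqr = unlist(ser$discharge_delay_median_iqr),
      mortality_rate = ser$mortality_rate,
      readmission_rate = ser$readmission_rate,
      negative_rate = ser$negative_rate,
      vitals_cadence = ser$vitals_cadence, labs_cadence = ser$labs_cadence,
      missingness_rate = ser$missingness_rate,
      outcome_coefficients = co[co != 0],
      seed = ser$seed
    )
  }
  if (!is.null(raw$mimic)) cfg$mimic <- rebuild(raw$mimic)
  if (!is.null(raw$gicu)) cfg$gicu <- rebuild(raw$gicu)
  if (!is.null(raw$split)) {
    cfg$split <- split_spec(raw$split$test_fraction, raw$split$primary)
  }
  cfg
}

#' Run the full pipeline and emit the report bundle
#'
#' Orchestrates every stage: generate the two synthetic cohorts, build the
#' class-balanced labelled dataset, extract windowed features, impute (or
#' drop incomplete cases), run the repeated-split experiment for the
#' rule-based and machine-learning systems on the base feature set — and,
#' with `feature_set = "both"`, the two classifiers again on the extended
#' set — then write tidy CSV reports into `out_dir`:
#'
#' * `instances.csv` — the labelled instances (stay, source, reference
#'   time, label, provenance);
#' * `metrics_by_split.csv`, `metrics_summary.csv` — per-split and
#'   mean (SD) metric tables over all systems and cohorts;
#' * `importance_by_split.csv`, `importance_summary.csv` — permutation
#'   importances with dense ranks (0 = most important);
#' * `rank_agreement.csv` — Spearman correlation between the two
#'   classifier families' importance rankings;
#' * `curves_roc.csv`, `curves_prc.csv` — first-split ROC/PRC curves per
#'   system and cohort;
#' * `counts.csv` — structured log of per-stage counts.
#'
#' Identical configuration and seed give a byte-identical bundle. Any stage
#' failure aborts with the stage name; nothing is written on failure.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the experiment results and the report
#'   tables.
#' @export
#' @examples
#' \donttest{
#' cfg <- default_run_config(n_mimic = 150, n_gicu = 80, n_splits = 2)
#' res <- run_pipeline(cfg, tempfile("run"))
#' }
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(config$seed)
  stage <- "setup"
  counts <- list()
  result <- tryCatch({
    stage <- "generate"
    mimic <- generate_cohort(config$mimic)
    gicu <- generate_cohort(config$gicu)
    counts$stays_mimic <- length(mimic)
    counts$stays_gicu <- length(gicu)

    stage <- "build"
    instances <- build_dataset(list(mimic, gicu))
    counts$instances <- nrow(instances)
    counts$instances_augmented <- sum(instances$provenance == "augmented")

    stage <- "features"
    extended_needed <- config$feature_set %in% c("extended", "both")
    X_ext <- build_feature_matrix(instances, extended = TRUE)
    X_base <- X_ext[, .base_features, drop = FALSE]
    y <- as.integer(instances$label == "RFD")
    src <- instances$source

    stage <- "impute"
    if (config$imputation == "complete") {
      keep <- rowSums(is.na(X_base)) == 0
      counts$instances_dropped_incomplete <- sum(!keep)
      instances <- instances[keep, , drop = FALSE]
      X_base <- X_base[keep, , drop = FALSE]
      X_ext <- X_ext[keep, , drop = FALSE]
      y <- y[keep]; src <- src[keep]
    } else {
      counts$imputed_cells <- sum(is.na(X_base))
      X_base <- knn_impute(X_base, k = config$knn_k)
      X_ext[, .base_features] <- X_base
    }

    stage <- "experiment-base"
    systems_base <- if (config$feature_set == "extended") {
      c("logistic", "forest")
    } else {
      c("nld", "nld_weighted", "logistic", "forest")
    }
    exp_base <- if (config$feature_set != "extended") {
      run_experiment(X_base, y, src, systems = systems_base,
                     n_splits = config$n_splits, seed = config$seed,
                     grids = config$grids, spec = config$split,
                     importance_repeats = config$importance_repeats)
    }

    stage <- "experiment-extended"
    exp_ext <- if (extended_needed) {
      run_experiment(X_ext, y, src, systems = c("logistic", "forest"),
                     n_splits = config$n_splits, seed = config$seed,
                     grids = config$grids, spec = config$split,
                     importance_repeats = config$importance_repeats)
    }

    stage <- "report"
    tag_ext <- function(d, col) {
      if (is.null(d)) return(NULL)
      d[[col]] <- paste0(d[[col]], "_extended")
      d
    }
    bind <- function(a, b) {
      if (is.null(a)) return(b)
      if (is.null(b)) return(a)
      rbind(a, b)
    }
    metrics_by_split <- bind(
      if (!is.null(exp_base)) exp_base$per_split,
      tag_ext(if (!is.null(exp_ext)) exp_ext$per_split, "system"))
    metrics_summary <- bind(
      if (!is.null(exp_base)) exp_base$summary,
      tag_ext(if (!is.null(exp_ext)) exp_ext$summary, "system"))
    importance_by_split <- bind(
      if (!is.null(exp_base)) exp_base$importance,
      tag_ext(if (!is.null(exp_ext)) exp_ext$importance, "family"))
    importance_summary <- bind(
      if (!is.null(exp_base)) exp_base$importance_summary,
      tag_ext(if (!is.null(exp_ext)) exp_ext$importance_summary, "family"))
    rank_agreement <- data.frame(
      feature_set = c(if (!is.null(exp_base)) "base",
                      if (!is.null(exp_ext)) "extended"),
      spearman = c(if (!is.null(exp_base)) exp_base$spearman %||% NA_real_,
                   if (!is.null(exp_ext)) exp_ext$spearman %||% NA_real_)
    )

    curve_tables <- .curve_tables(bind(
      if (!is.null(exp_base)) exp_base$first_split_scores,
      tag_ext(if (!is.null(exp_ext)) exp_ext$first_split_scores, "system")))

    list(instances = instances, metrics_by_split = metrics_by_split,
         metrics_summary = metrics_summary,
         importance_by_split = importance_by_split,
         importance_summary = importance_summary,
         rank_agreement = rank_agreement,
         curves = curve_tables, counts = counts,
         exp_base = exp_base, exp_ext = exp_ext)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  # all computation succeeded; emit the bundle
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inst_out <- result$instances[, c("stay_id", "source", "t_ref", "label",
                                   "provenance")]
  names(inst_out)[3] <- "t_ref_minutes"
  data.table::fwrite(inst_out, file.path(out_dir, "instances.csv"))
  data.table::fwrite(result$metrics_by_split,
                     file.path(out_dir, "metrics_by_split.csv"))
  data.table::fwrite(result$metrics_summary,
                     file.path(out_dir, "metrics_summary.csv"))
  if (!is.null(result$importance_by_split)) {
    data.table::fwrite(result$importance_by_split,
                       file.path(out_dir, "importance_by_split.csv"))
    data.table::fwrite(result$importance_summary,
                       file.path(out_dir, "importance_summary.csv"))
  }
  data.table::fwrite(result$rank_agreement,
                     file.path(out_dir, "rank_agreement.csv"))
  data.table::fwrite(result$curves$roc, file.path(out_dir, "curves_roc.csv"))
  data.table::fwrite(result$curves$prc, file.path(out_dir, "curves_prc.csv"))
  data.table::fwrite(
    data.frame(count = names(result$counts),
               value = unlist(result$counts, use.names = FALSE)),
    file.path(out_dir, "counts.csv"))
  invisible(result)
}

.curve_tables <- function(scores) {
  if (!is.null(scores)) scores <- as.data.frame(scores)
  if (is.null(scores) || !nrow(scores)) {
    empty_roc <- data.frame(cohort = character(0), system = character(0),
                            fpr = numeric(0), tpr = numeric(0),
                            threshold = numeric(0))
    empty_prc <- data.frame(cohort = character(0), system = character(0),
                            recall = numeric(0), precision = numeric(0),
                            threshold = numeric(0))
    return(list(roc = empty_roc, prc = empty_prc))
  }
  groups <- unique(scores[, c("cohort", "system")])
  roc_rows <- list(); prc_rows <- list()
  for (g in seq_len(nrow(groups))) {
    sel <- scores$cohort == groups$cohort[g] &
      scores$system == groups$system[g]
    sc <- scores$score[sel]; lb <- scores$label[sel]
    roc <- roc_curve(sc, lb)
    prc <- prc_curve(sc, lb)
    roc_rows[[g]] <- cbind(groups[g, ], roc, row.names = NULL)
    prc_rows[[g]] <- cbind(groups[g, ], prc, row.names = NULL)
  }
  list(roc = do.call(rbind, roc_rows), prc = do.call(rbind, prc_rows))
}
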