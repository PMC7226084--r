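PIPELINE_KEYS <- c("master_seed", "n_subjects", "windows", "algorithms",
                   "generator", "learning_curve", "step2", "comparison",
                   "write_recordings")

#' Default pipeline configuration
#'
#' Three synthetic subjects at the study conditions (5-minute 4-channel
#' 2000 Hz recordings), all three window lengths, all five algorithm
#' families, Nemenyi post-hoc for the window effect and Bergmann-Hommel for
#' the algorithm effect.
#'
#' @return a `pipeline_config` list
#' @export
default_pipeline_config <- function() {
  structure(list(
    master_seed = 1L, n_subjects = 3L,
    windows = WINDOW_CHOICES_MS, algorithms = ALGORITHM_FAMILIES,
    generator = list(),
    learning_curve = list(enabled = TRUE,
                          sizes = c(720, 1440, 2520, 3240)),
    step2 = list(folds = 3L, adasyn_K = 5L, adasyn_beta = 1.0),
    comparison = list(alpha = 0.05, window_posthoc = "nemenyi",
                      algorithm_posthoc = "bergmann_hommel"),
    write_recordings = FALSE), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list; unknown keys are errors, every
#' constraint names the offending key.
#'
#' @param x path to a YAML config file, or a (partial) config list
#' @return a fully defaulted, validated `pipeline_config`
#' @export
validate_config <- function(x = list()) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- yaml::read_yaml(x) %||% list()
  }
  stopifnot(is.list(x))
  unknown <- setdiff(names(x), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- default_pipeline_config()
  for (k in names(x)) {
    if (is.list(cfg[[k]]) && !is.null(names(cfg[[k]]))) {
      sub_unknown <- setdiff(names(x[[k]]), names(cfg[[k]]))
      if (k != "generator" && length(sub_unknown))
        stop("unknown config key(s) in '", k, "': ",
             paste(sub_unknown, collapse = ", "))
      cfg[[k]][names(x[[k]])] <- x[[k]]
    } else cfg[[k]] <- x[[k]]
  }
  if (!is.numeric(cfg$master_seed) || cfg$master_seed < 0)
    stop("config key 'master_seed' must be a non-negative integer")
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 1)
    stop("config key 'n_subjects' must be a positive integer")
  bad <- setdiff(cfg$windows, WINDOW_CHOICES_MS)
  if (length(bad))
    stop("config key 'windows' allows only {",
         paste(WINDOW_CHOICES_MS, collapse = ", "), "} ms; got ",
         paste(bad, collapse = ", "))
  bad <- setdiff(cfg$algorithms, ALGORITHM_FAMILIES)
  if (length(bad))
    stop("config key 'algorithms' allows only {",
         paste(ALGORITHM_FAMILIES, collapse = ", "), "}; got ",
         paste(bad, collapse = ", "))
  if (!cfg$comparison$window_posthoc %in%
        c("nemenyi", "holm", "bergmann_hommel"))
    stop("config key 'comparison$window_posthoc' invalid")
  if (!cfg$comparison$algorithm_posthoc %in%
        c("nemenyi", "holm", "bergmann_hommel"))
    stop("config key 'comparison$algorithm_posthoc' invalid")
  # cross-validate the generator section by constructing it
  do.call(generator_config, c(cfg$generator, list(seed = 1L)))
  cfg$master_seed <- as.integer(cfg$master_seed)
  cfg$n_subjects <- as.integer(cfg$n_subjects)
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_log <- function(state, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  if (!state$quiet) message(line)
  cat(line, "\n", file = state$log_path, append = TRUE)
}

#' Run the full two-step pipeline on synthetic subjects
#'
#' For each synthetic subject (one seeded recording + annotations, its seed
#' derived from the master seed): writes feature tables per window, runs
#' step-1 balanced binary detection per algorithm and window (balance ->
#' 30% tuning holdout -> grid search -> 5-fold CV), learning curves at
#' 10 ms (sizes exceeding the available development rows are dropped with a
#' logged notice), and step-2 three-class classification at 10 ms with
#' ADASYN inside training folds. Then compares window lengths per algorithm
#' and algorithms at 10 ms across subjects with the Friedman test and the
#' configured post-hocs. Metric CSVs are byte-reproducible under a fixed
#' master seed; wall-clock fit times appear only in the learning-curve
#' table.
#'
#' @param config a `pipeline_config`, partial list, or YAML path
#' @param out_dir output directory (created if needed)
#' @param quiet suppress console logging (the run log file is always
#'   written)
#' @return invisibly, a list with step-1/step-2 metric data.frames,
#'   comparison results, and the manifest
#' @export
run_full <- function(config = list(), out_dir, quiet = FALSE) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(quiet = quiet, log_path = file.path(out_dir, "run_log.txt"))
  cat("", file = state$log_path)
  cfg_yaml <- yaml::as.yaml(unclass(cfg))
  cfg_path <- file.path(out_dir, "config.yaml")
  writeLines(cfg_yaml, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  subj_seeds <- derive_seeds(cfg$master_seed, cfg$n_subjects)
  pipeline_log(state, "full-run: %d subject(s), windows {%s} ms, algorithms {%s}",
               cfg$n_subjects, paste(cfg$windows, collapse = ","),
               paste(cfg$algorithms, collapse = ","))
  step1 <- list(); step2 <- list(); lc <- list(); chosen <- list()
  for (s in seq_len(cfg$n_subjects)) {
    sseed <- subj_seeds[s]
    stage_seeds <- derive_seeds(sseed, 6)
    gen_cfg <- do.call(generator_config,
                       c(cfg$generator, list(seed = stage_seeds[1])))
    subj_id <- sprintf("subject%02d", s)
    pipeline_log(state, "[%s] generating recording (seed %d)", subj_id,
                 stage_seeds[1])
    gr <- generate_recording(gen_cfg)
    gr$recording$subject_id <- subj_id
    write_annotations(gr$annotations,
                      file.path(out_dir,
                                sprintf("%s_annotations.csv", subj_id)))
    if (isTRUE(cfg$write_recordings))
      write_recording(gr$recording,
                      file.path(out_dir, sprintf("%s_signal.csv", subj_id)))
    tables <- list()
    for (w in cfg$windows) {
      tbl <- extract_features(gr$recording, gr$annotations, w)
      tables[[as.character(w)]] <- tbl
      write_feature_table(tbl, file.path(
        out_dir, sprintf("%s_features_win%03d.csv", subj_id, w)))
      pipeline_log(state, "[%s] features @ %d ms: %d segments (%d HFO)",
                   subj_id, w, nrow(tbl), sum(tbl$label != "noHFO"))
    }
    algo_seeds <- derive_seeds(stage_seeds[2],
                               length(cfg$algorithms) * length(cfg$windows))
    ai <- 0
    for (algo in cfg$algorithms) for (w in cfg$windows) {
      ai <- ai + 1
      tbl <- tables[[as.character(w)]]
      seeds <- derive_seeds(algo_seeds[ai], 4)
      bal <- balance_binary(tbl, seeds[1])
      sp <- split_tuning_holdout(bal, 0.30, seeds[2])
      spec <- algorithm_spec(algo)
      Xt <- as.matrix(sp$tuning[, feature_columns()])
      yt <- factor(ifelse(sp$tuning$label %in% HFO_LABELS, "HFO", "noHFO"),
                   levels = c("noHFO", "HFO"))
      tuned <- tune(spec, Xt, yt, seed = seeds[3])
      mets <- crossval_detect(sp$development, spec, tuned$params,
                              folds = 5, seed = seeds[4])
      chosen[[sprintf("%s_%s_win%d", subj_id, algo, w)]] <-
        as.list(tuned$params)
      pf <- mets$per_fold[, c("fold", "auc", "sensitivity", "specificity")]
      step1[[length(step1) + 1]] <- cbind(
        data.frame(subject = subj_id, algorithm = algo, window = w), pf)
      pipeline_log(state,
                   "[%s] step1 %s @ %dms: AUC %.3f sens %.3f spec %.3f",
                   subj_id, algo, w, mets$mean["auc"],
                   mets$mean["sensitivity"], mets$mean["specificity"])
      if (w == 10 && isTRUE(cfg$learning_curve$enabled)) {
        sizes <- cfg$learning_curve$sizes
        feas <- sizes[sizes <= nrow(sp$development)]
        if (length(feas) < length(sizes))
          pipeline_log(state,
            "[%s] learning curve %s: dropping infeasible size(s) %s (> %d rows)",
            subj_id, algo,
            paste(setdiff(sizes, feas), collapse = ","),
            nrow(sp$development))
        if (length(feas)) {
          lc_tbl <- learning_curve(sp$development, spec, tuned$params,
                                   sizes = feas, seed = seeds[4])
          lc[[length(lc) + 1]] <- cbind(
            data.frame(subject = subj_id, algorithm = algo), lc_tbl)
        }
      }
    }
    # step 2: three-class classification at 10 ms on ground-truth HFO rows
    if (10 %in% cfg$windows) {
      hfo_tbl <- tables[["10"]]
      hfo_tbl <- hfo_tbl[hfo_tbl$label %in% HFO_LABELS, , drop = FALSE]
      counts <- table(factor(hfo_tbl$label, levels = HFO_LABELS))
      if (min(counts) < 10) {
        pipeline_log(state,
          "[%s] step2 skipped: class counts %s too small (need >= 10 each)",
          subj_id, paste(sprintf("%s=%d", names(counts), counts),
                         collapse = " "))
      } else {
        s2_seeds <- derive_seeds(stage_seeds[3], length(cfg$algorithms))
        for (j in seq_along(cfg$algorithms)) {
          algo <- cfg$algorithms[j]
          mm <- crossval_classify(
            hfo_tbl, algo, folds = cfg$step2$folds, seed = s2_seeds[j],
            adasyn = adasyn_config(cfg$step2$adasyn_K,
                                   cfg$step2$adasyn_beta, s2_seeds[j]))
          pf <- mm$per_fold[, c("class", "fold", "sensitivity",
                                "specificity")]
          step2[[length(step2) + 1]] <- cbind(
            data.frame(subject = subj_id, algorithm = algo), pf)
          pipeline_log(state,
                       "[%s] step2 %s: mean sens %s", subj_id, algo,
                       paste(sprintf("%s=%.2f", mm$mean$class,
                                     mm$mean$sensitivity), collapse = " "))
        }
      }
    }
  }
  step1 <- do.call(rbind, step1)
  data.table::fwrite(step1, file.path(out_dir, "step1_metrics.csv"))
  if (length(lc))
    data.table::fwrite(do.call(rbind, lc),
                       file.path(out_dir, "learning_curves.csv"))
  if (length(step2)) {
    step2 <- do.call(rbind, step2)
    data.table::fwrite(step2, file.path(out_dir, "step2_metrics.csv"))
  } else step2 <- NULL
  comparisons <- run_comparisons(cfg, step1, out_dir, state)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("hfopipe")),
                   config_hash = config_hash,
                   master_seed = cfg$master_seed,
                   subject_seeds = subj_seeds,
                   chosen_hyperparameters = chosen)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_summary(cfg, step1, step2, comparisons, out_dir)
  pipeline_log(state, "full-run complete: outputs in %s", out_dir)
  invisible(list(config = cfg, step1 = step1, step2 = step2,
                 learning_curves = if (length(lc)) do.call(rbind, lc),
                 comparisons = comparisons, manifest = manifest))
}

# subject x condition mean-AUC matrices -> Friedman + post-hoc reports
run_comparisons <- function(cfg, step1, out_dir, state) {
  out <- list()
  agg <- stats::aggregate(auc ~ subject + algorithm + window, step1, mean)
  if (length(cfg$windows) >= 2 && cfg$n_subjects >= 2) {
    for (algo in cfg$algorithms) {
      sub <- agg[agg$algorithm == algo, ]
      M <- stats::reshape(sub[, c("subject", "window", "auc")],
                          idvar = "subject", timevar = "window",
                          direction = "wide")
      vals <- as.matrix(M[, -1])
      colnames(vals) <- sub("auc.", "win", colnames(vals), fixed = TRUE)
      rownames(vals) <- M$subject
      cmp <- compare_conditions(
        performance_matrix(vals), cfg$comparison$window_posthoc,
        cfg$comparison$alpha,
        file.path(out_dir, sprintf("window_effect_%s.json", algo)))
      out[[paste0("window_effect_", algo)]] <- cmp
      pipeline_log(state,
                   "compare windows (%s): chi2 %.2f p %.3g", algo,
                   cmp$friedman$chi2, cmp$friedman$p)
    }
  } else pipeline_log(state,
    "window-effect comparison skipped: needs >= 2 windows and >= 2 subjects")
  if (length(cfg$algorithms) >= 2 && cfg$n_subjects >= 2 &&
        10 %in% cfg$windows) {
    sub <- agg[agg$window == 10, ]
    M <- stats::reshape(sub[, c("subject", "algorithm", "auc")],
                        idvar = "subject", timevar = "algorithm",
                        direction = "wide")
    vals <- as.matrix(M[, -1])
    colnames(vals) <- sub("auc.", "", colnames(vals), fixed = TRUE)
    rownames(vals) <- M$subject
    posthoc <- cfg$comparison$algorithm_posthoc
    if (posthoc == "bergmann_hommel" && length(cfg$algorithms) > 6)
      posthoc <- "holm"
    cmp <- compare_conditions(
      performance_matrix(vals), posthoc, cfg$comparison$alpha,
      file.path(out_dir, "algorithm_effect_10ms.json"))
    out$algorithm_effect_10ms <- cmp
    pipeline_log(state, "compare algorithms @10ms: chi2 %.2f p %.3g",
                 cmp$friedman$chi2, cmp$friedman$p)
  } else pipeline_log(state,
    "algorithm-effect comparison skipped: needs >= 2 algorithms, >= 2 subjects and the 10 ms window")
  out
}

write_summary <- function(cfg, step1, step2, comparisons, out_dir) {
  path <- file.path(out_dir, "summary.txt")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(sprintf(...), "\n", file = con, sep = "")
  w("hfopipe full-run summary")
  w("========================")
  w("subjects: %d   windows: %s ms   algorithms: %s", cfg$n_subjects,
    paste(cfg$windows, collapse = ","),
    paste(cfg$algorithms, collapse = ","))
  w("")
  w("step 1 (HFO vs noHFO), mean over folds and subjects:")
  agg <- stats::aggregate(cbind(auc, sensitivity, specificity) ~
                            algorithm + window, step1, mean)
  for (i in seq_len(nrow(agg)))
    w("  %-4s @ %3d ms  AUC %.3f  sens %.3f  spec %.3f",
      agg$algorithm[i], agg$window[i], agg$auc[i], agg$sensitivity[i],
      agg$specificity[i])
  if (!is.null(step2)) {
    w("")
    w("step 2 (R / FR / FRonR at 10 ms), mean over folds and subjects:")
    agg2 <- stats::aggregate(cbind(sensitivity, specificity) ~
                               algorithm + class, step2, mean)
    for (i in seq_len(nrow(agg2)))
      w("  %-4s %-6s  sens %.3f  spec %.3f", agg2$algorithm[i],
        agg2$class[i], agg2$sensitivity[i], agg2$specificity[i])
  }
  if (length(comparisons)) {
    w("")
    w("comparisons (Friedman + post-hoc):")
    for (nm in names(comparisons)) {
      fr <- comparisons[[nm]]$friedman
      w("  %s: chi2 = %.3f, df = %d, p = %.3g", nm, fr$chi2, fr$df, fr$p)
    }
  }
  invisible(path)
}
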