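# End-to-end orchestration: generate -> prep -> split -> train -> predict ->
# evaluate from one config, with logging, a manifest, and a summary report
# comparing single- vs multi-output models per assay.

#' Default run configuration
#'
#' Returns the full nested configuration consumed by [run_experiment()], at
#' desk scale. Any part can be overridden by supplying a (partial) list via
#' `overrides` or by editing the returned list; a YAML file with the same
#' structure can be loaded with [load_config()].
#'
#' @param overrides Optional named list merged over the defaults
#'   (recursively).
#' @return Named nested list.
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1,
    generator = list(
      n_chem = 800, d = 60, n_blocks = 10, rho = 0.5,
      prevalence_range = c(0.05, 0.5),
      n_assays = 4, sparsity = 5, effect_size = 2, share_fraction = 0.5,
      target_prevalence = 0.08, missing_rate = 0.2,
      dup_fraction = 0.1, flip_prob = 0.1,
      reliability = list(error_range = c(0.02, 0.04),
                         hard_fraction = 0.05, hard_error = 0.12,
                         shape = c(8, 2))
    ),
    filters = list(freq_cut = 19, unique_cut = 10, correlation_cutoff = 0.9),
    partition = list(K_split = 5, K_cv = 10, max_sweeps = 10),
    models = list(algorithm = "random_forest", resample = "none", grid = NULL),
    net = list(hidden = c(32, 32), dropout = 0.1, l2 = 1e-4,
               batch_norm = FALSE, epochs = 120, learning_rate = 3e-3,
               patience = 15, val_fraction = 0.1),
    mc = list(N = 2000, N_grid = c(100, 1000, 2000), class_threshold = 0.5),
    evaluation = list(tpr_target = 0.9)
  )
  merge_config(cfg, overrides)
}

merge_config <- function(base, over) {
  if (is.null(over)) return(base)
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) && !is.null(names(over[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with (a subset of) the [default_config()] structure.
#' @return Full configuration with defaults filled in.
#' @export
load_config <- function(path) {
  default_config(yaml::read_yaml(path))
}

validate_config <- function(cfg) {
  g <- cfg$generator
  stopifnot(g$n_chem >= 50, g$d >= 4, g$sparsity <= g$d,
            cfg$partition$K_split >= 2, cfg$mc$N >= 10,
            cfg$filters$correlation_cutoff > 0, cfg$filters$correlation_cutoff < 1)
  stopifnot(cfg$models$algorithm %in% c("logistic", "random_forest", "gradient_boosting"),
            cfg$models$resample %in% c("none", "down", "up", "smote"))
  invisible(cfg)
}

stage_log <- function(con, stage, t0, ...) {
  msg <- sprintf("[%s] %s (%.1fs) %s", format(Sys.time(), "%H:%M:%S"), stage,
                 as.numeric(Sys.time()) - t0, paste(..., collapse = " "))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full synthetic-panel experiment
#'
#' Executes every stage from one configuration: fingerprint generation,
#' toxicophore planting and label simulation, duplicate injection and
#' deduplication, feature filtering, anticlustered train/test split and CV
#' folds, single-output training per assay plus a masked-loss multi-output
#' network, probabilistic-fingerprint emulation for the test set, Monte
#' Carlo and naive prediction, and evaluation. Every intermediate table is
#' written to `out_dir` as TSV, the ground truth as JSON, and a summary
#' report (JSON + Markdown) compares single- vs multi-output FPR at the
#' recall target per assay, with disagreement rates and convergence flips.
#' Re-running with the same config reproduces the deterministic artifacts
#' bit-identically.
#'
#' @param config Configuration list from [default_config()] or
#'   [load_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the report, per-stage objects and artifact
#'   paths.
#' @export
run_experiment <- function(config = default_config(), out_dir = tempfile("fingertox_run_")) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  con <- file(logfile, open = "wt")
  on.exit(close(con), add = TRUE)
  seed <- cfg$seed
  g <- cfg$generator
  art <- function(x) file.path(out_dir, x)
  run_stage <- function(stage, expr) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s (artifacts in %s)",
                   stage, conditionMessage(e), out_dir), call. = FALSE))
    stage_log(con, stage, t0)
    res
  }

  # -- generate ---------------------------------------------------------
  fp <- run_stage("generate_fingerprints", generate_fingerprints(
    g$n_chem, g$d, g$n_blocks, g$rho, g$prevalence_range,
    seed = child_seed(seed, "gen")))
  truth <- run_stage("plant_toxicophores", plant_toxicophores(
    fp, g$n_assays, g$sparsity, g$effect_size, g$share_fraction,
    g$target_prevalence, seed = child_seed(seed, "plant")))
  labels0 <- run_stage("simulate_labels", simulate_labels(
    fp, truth, g$missing_rate, seed = child_seed(seed, "labels")))
  records <- run_stage("inject_duplicates", inject_duplicates(
    labels0, g$dup_fraction, g$flip_prob, seed = child_seed(seed, "dup")))
  write_table_tsv(fp, art("fingerprints.tsv"))
  write_truth_json(truth, art("truth.json"))

  # -- prep -------------------------------------------------------------
  labels <- run_stage("deduplicate", deduplicate(records))
  write_table_tsv(labels, art("labels.tsv"))
  nzv <- run_stage("filter_near_zero_variance", filter_near_zero_variance(
    fp, cfg$filters$freq_cut, cfg$filters$unique_cut))
  fc <- run_stage("filter_correlated", filter_correlated(
    nzv$table, cfg$filters$correlation_cutoff))
  x <- fc$table

  # -- split ------------------------------------------------------------
  sp <- run_stage("split_train_test", split_train_test(
    labels, K = cfg$partition$K_split, seed = child_seed(seed, "split"),
    max_sweeps = cfg$partition$max_sweeps))
  write_assignment_tsv(sp$assignment, art("anticlusters.tsv"))
  train_ids <- sp$train_ids; test_ids <- sp$test_ids
  folds <- run_stage("make_cv_folds", make_cv_folds(
    labels[train_ids, , drop = FALSE], K = cfg$partition$K_cv,
    seed = child_seed(seed, "folds"), max_sweeps = cfg$partition$max_sweeps))

  # -- train ------------------------------------------------------------
  xtr <- x[train_ids, , drop = FALSE]
  single <- run_stage("train_single_output", lapply(colnames(labels), function(a) {
    train_single_output(xtr, labels[train_ids, a],
                        algorithm = cfg$models$algorithm,
                        grid = cfg$models$grid,
                        folds = folds[train_ids],
                        resample = cfg$models$resample,
                        seed = child_seed(seed, paste0("single_", a)))
  }))
  names(single) <- colnames(labels)
  net <- run_stage("train_multi_output", train_multi_output(
    xtr, labels[train_ids, , drop = FALSE],
    hidden = cfg$net$hidden, dropout = cfg$net$dropout, l2 = cfg$net$l2,
    batch_norm = cfg$net$batch_norm, epochs = cfg$net$epochs,
    learning_rate = cfg$net$learning_rate, patience = cfg$net$patience,
    val_fraction = cfg$net$val_fraction, seed = child_seed(seed, "net")))

  # -- probabilistic fingerprints for the test set ----------------------
  rspec <- reliability_spec(colnames(fp),
                            error_range = g$reliability$error_range,
                            hard_fraction = g$reliability$hard_fraction,
                            hard_error = g$reliability$hard_error,
                            shape = g$reliability$shape,
                            seed = child_seed(seed, "reliability"))
  probs <- run_stage("emulate_probabilistic_fingerprints",
                     emulate_probabilistic_fingerprints(
                       fp[test_ids, , drop = FALSE], rspec,
                       seed = child_seed(seed, "probs")))
  write_table_tsv(probs, art("probs.tsv"))

  # -- predict ----------------------------------------------------------
  A <- ncol(labels)
  thr <- cfg$mc$class_threshold
  pred <- run_stage("predict", {
    mc_s <- matrix(NA_real_, length(test_ids), A,
                   dimnames = list(test_ids, colnames(labels)))
    mc_m <- nv_s <- nv_m <- mc_s
    for (i in seq_along(test_ids)) {
      pvec <- probs[test_ids[i], ]
      cs <- child_seed(seed, paste0("mc_", test_ids[i]))
      for (a in seq_len(A)) {
        mc_s[i, a] <- predict_monte_carlo(single[[a]], pvec, N = cfg$mc$N,
                                          class_threshold = thr,
                                          seed = cs)$mean_score
        nv_s[i, a] <- predict_naive(single[[a]], pvec)$score
      }
      mc_m[i, ] <- predict_monte_carlo(net, pvec, N = cfg$mc$N,
                                       class_threshold = thr,
                                       seed = cs)$mean_score
      nv_m[i, ] <- predict_naive(net, pvec)$score
    }
    list(mc_single = mc_s, naive_single = nv_s,
         mc_multi = mc_m, naive_multi = nv_m)
  })
  write_table_tsv(pred$mc_single, art("predictions_mc_single.tsv"))
  write_table_tsv(pred$mc_multi, art("predictions_mc_multi.tsv"))
  write_table_tsv(pred$naive_single, art("predictions_naive_single.tsv"))
  write_table_tsv(pred$naive_multi, art("predictions_naive_multi.tsv"))

  # -- convergence (multi-output, shared samples) -----------------------
  conv <- run_stage("convergence_analysis", convergence_analysis(
    net, probs, N_grid = cfg$mc$N_grid, class_threshold = thr,
    seed = child_seed(seed, "conv")))
  flips <- stats::aggregate(flipped ~ assay, conv, sum)

  # -- evaluate ---------------------------------------------------------
  ytest <- labels[test_ids, , drop = FALSE]
  tt <- cfg$evaluation$tpr_target
  rep_single <- eval_report(pred$mc_single, ytest, tpr_target = tt)
  rep_multi <- eval_report(pred$mc_multi, ytest, tpr_target = tt)
  disag <- data.frame(
    assay = colnames(labels),
    single = disagreement_rate(pred$mc_single >= thr, pred$naive_single >= thr),
    multi = disagreement_rate(pred$mc_multi >= thr, pred$naive_multi >= thr),
    row.names = NULL)

  report <- list(
    config = cfg,
    n_chemicals = nrow(fp),
    n_features_surviving = ncol(x),
    feature_filter = list(near_zero = nzv$report$removed_near_zero,
                          correlated = fc$report$removed_correlated),
    split = list(n_train = length(train_ids), n_test = length(test_ids)),
    single_output = rep_single,
    multi_output = rep_multi,
    disagreement = disag,
    convergence_flips = flips)
  jsonlite::write_json(report, art("report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  write_report_md(report, art("report.md"))

  # -- manifest ---------------------------------------------------------
  yaml::write_yaml(cfg, art("config.yaml"))
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    config_hash = unname(tools::md5sum(art("config.yaml"))),
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("fingertox")))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(report = report, models = list(single = single, net = net),
                 truth = truth, out_dir = out_dir,
                 data = list(fingerprints = fp, labels = labels, probs = probs,
                             train_ids = train_ids, test_ids = test_ids)))
}

write_report_md <- function(report, path) {
  s <- report$single_output; m <- report$multi_output
  lines <- c(
    "# Synthetic-panel run summary", "",
    sprintf("- chemicals: %d (train %d / test %d)", report$n_chemicals,
            report$split$n_train, report$split$n_test),
    sprintf("- surviving features: %d", report$n_features_surviving), "",
    sprintf("## FPR at TPR >= %.2f (Monte Carlo predictions)", s$tpr_target[1]), "",
    "| assay | single-output | multi-output | ROC-AUC single | ROC-AUC multi |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.3f | %.3f | %.3f | %.3f |", s$assay, s$fpr_at_tpr,
            m$fpr_at_tpr, s$roc_auc, m$roc_auc),
    "", "## Monte Carlo vs naive disagreement", "",
    "| assay | single | multi |", "|---|---|---|",
    sprintf("| %s | %.3f | %.3f |", report$disagreement$assay,
            report$disagreement$single, report$disagreement$multi),
    "", "## Convergence flips (multi-output)", "",
    "| assay | flipped chemicals |", "|---|---|",
    sprintf("| %s | %d |", report$convergence_flips$assay,
            report$convergence_flips$flipped))
  writeLines(lines, path)
  invisible(path)
}
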