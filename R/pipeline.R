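#' Pipeline run configuration
#'
#' One object driving the whole workflow: generate (or accept) segments,
#' decompose, extract entropy features, and classify overall and lobe-wise.
#' A single top-level seed deterministically derives every stage seed, so
#' identical configurations reproduce identical report tables.
#'
#' @param synth a [synth_config()] describing the data to generate, or
#'   `NULL` when `segments` are supplied directly.
#' @param segments optional pre-built list of `eeg_segment` objects.
#' @param montage_id lobe montage; defaults to the synth config's montage.
#' @param n_modes modes per channel for the decomposition.
#' @param entropy an [entropy_params()].
#' @param classifiers character vector of [model_spec()] family names.
#' @param optimize_budget if > 0, additionally run Bayesian optimization
#'   of the boosted ensemble with this evaluation budget and report it as
#'   `optimized_ensemble`.
#' @param k cross-validation folds.
#' @param group_by_subject grouped (subject-level) cross-validation.
#' @param lobes lobe names to evaluate, or `"all"` for every lobe in the
#'   montage.
#' @param permutations permutation-test iterations (0 = skip).
#' @param learning_fractions training fractions for a learning curve
#'   (`NULL` = skip).
#' @param seed top-level integer seed.
#' @param outdir directory for report tables and the run manifest
#'   (`NULL` = in-memory only).
#' @return list of class `run_config`.
#' @export
run_config <- function(synth = synth_preset("strong"), segments = NULL,
                       montage_id = NULL, n_modes = 5L,
                       entropy = entropy_params(),
                       classifiers = "boosted_trees",
                       optimize_budget = 0L, k = 10L,
                       group_by_subject = FALSE, lobes = "all",
                       permutations = 0L, learning_fractions = NULL,
                       seed = 1L, outdir = NULL) {
  if (is.null(synth) && is.null(segments))
    stop("either a synth config or segments must be supplied")
  montage_id <- montage_id %||% synth$montage_id
  bad <- setdiff(classifiers, .families)
  if (length(bad)) stop("unknown classifier family: ", paste(bad, collapse = ", "))
  structure(list(synth = synth, segments = segments, montage_id = montage_id,
                 n_modes = as.integer(n_modes), entropy = entropy,
                 classifiers = classifiers,
                 optimize_budget = as.integer(optimize_budget),
                 k = as.integer(k), group_by_subject = group_by_subject,
                 lobes = lobes, permutations = as.integer(permutations),
                 learning_fractions = learning_fractions,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the [run_config()] arguments; `synth` is a block
#' of [synth_config()] arguments, or the string `"strong"`/`"null"` for a
#' preset.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth <- if (is.character(y$synth)) synth_preset(y$synth, seed = y$seed %||% 1L)
  else if (is.list(y$synth)) do.call(synth_config, y$synth)
  else synth_preset("strong", seed = y$seed %||% 1L)
  ep <- if (is.list(y$entropy)) do.call(entropy_params, y$entropy)
  else entropy_params()
  run_config(synth = synth, montage_id = y$montage_id,
             n_modes = y$n_modes %||% 5L, entropy = ep,
             classifiers = y$classifiers %||% "boosted_trees",
             optimize_budget = y$optimize_budget %||% 0L,
             k = y$k %||% 10L,
             group_by_subject = y$group_by_subject %||% FALSE,
             lobes = y$lobes %||% "all",
             permutations = y$permutations %||% 0L,
             learning_fractions = y$learning_fractions,
             seed = y$seed %||% 1L, outdir = y$outdir)
}

metrics_row <- function(cv) {
  data.frame(Ac = cv$metrics["Ac"], Se = cv$metrics["Se"],
             Sp = cv$metrics["Sp"], Pr = cv$metrics["Pr"],
             Fs = cv$metrics["Fs"], AUC = cv$auc,
             mean_fold_Ac = cv$mean_accuracy, sd_fold_Ac = cv$sd_accuracy,
             ci_lo = cv$ci95[1], ci_hi = cv$ci95[2], row.names = NULL)
}

#' Run the full cognitive-load detection pipeline
#'
#' Preprocess/generate -> decompose -> entropy features -> overall and
#' lobe-wise cross-validated classification, with optional permutation
#' test and learning curve. Any stage failure aborts with the stage named;
#' completed outputs are kept on disk when `outdir` is set.
#'
#' @param config a [run_config()].
#' @param verbose log stage progress and row/column counts.
#' @return object of class `cogload_run` with elements `overall`
#'   (one row per classifier), `lobewise` (one row per classifier x lobe),
#'   `roc` (pooled out-of-fold ROC points per classifier), `cv` (the raw
#'   `cv_result` objects), `permutation`, `learning_curve`, `features`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  segments <- stage("data", {
    s <- config$segments %||% generate_dataset(config$synth)
    if (!length(s)) stop("no segments available")
    s
  })
  log_msg("data: %d segments of %d channels x %d samples", length(segments),
          ncol(segments[[1]]$data), nrow(segments[[1]]$data))
  feats <- stage("features",
                 extract_features(segments, n_modes = config$n_modes,
                                  params = config$entropy, verbose = verbose))
  log_msg("features: %d rows x %d feature columns",
          nrow(feats), length(feature_cols(feats)))
  montage <- stage("montage", build_montage(config$montage_id))
  lobes <- if (identical(config$lobes, "all")) names(montage$mapping)
  else config$lobes
  specs <- lapply(config$classifiers, function(f)
    model_spec(f, seed = derive_seed(config$seed, paste0("spec-", f))))
  names(specs) <- config$classifiers
  if (config$optimize_budget > 0L) {
    log_msg("optimizing boosted ensemble (budget %d)", config$optimize_budget)
    bo <- stage("optimize",
                bayesian_optimize("boosted_trees", feats,
                                  budget = config$optimize_budget,
                                  seed = derive_seed(config$seed, "bo")))
    specs$optimized_ensemble <- bo$best
  }
  cvs <- list(); overall <- NULL; lobewise <- NULL; roc <- list()
  for (nm in names(specs)) {
    cv <- stage(paste0("cv-", nm),
                stratified_kfold_cv(specs[[nm]], feats, k = config$k,
                                    seed = derive_seed(config$seed, paste0("cv-", nm)),
                                    group_by_subject = config$group_by_subject))
    cvs[[nm]] <- list(overall = cv)
    overall <- rbind(overall, cbind(classifier = nm, lobe = "overall",
                                    metrics_row(cv)))
    roc[[nm]] <- cv$roc
    log_msg("cv %s overall: Ac %.2f%%", nm, cv$mean_accuracy)
    for (lb in lobes) {
      fl <- select_lobe_features(feats, montage, lb)
      cvl <- stage(paste0("cv-", nm, "-", lb),
                   stratified_kfold_cv(specs[[nm]], fl, k = config$k,
                                       seed = derive_seed(config$seed,
                                                          paste0("cv-", nm, "-", lb)),
                                       group_by_subject = config$group_by_subject))
      cvs[[nm]][[lb]] <- cvl
      lobewise <- rbind(lobewise, cbind(classifier = nm, lobe = lb,
                                        metrics_row(cvl)))
      log_msg("cv %s %s: Ac %.2f%%", nm, lb, cvl$mean_accuracy)
    }
  }
  perm <- NULL
  if (config$permutations > 0L) {
    perm <- stage("permutation",
                  permutation_test(specs[[1L]], feats,
                                   n_perm = config$permutations, k = config$k,
                                   seed = derive_seed(config$seed, "perm")))
    log_msg("permutation: p = %.4f", perm$p_value)
  }
  lc <- NULL
  if (!is.null(config$learning_fractions)) {
    lc <- stage("learning_curve",
                learning_curve(specs[[1L]], feats,
                               fractions = config$learning_fractions,
                               seed = derive_seed(config$seed, "lc")))
  }
  cfg_for_hash <- config[setdiff(names(config), c("segments", "outdir"))]
  manifest <- list(seed = config$seed,
                   config_hash = derive_seed(0L, paste(deparse(cfg_for_hash),
                                                       collapse = "")),
                   n_segments = length(segments),
                   n_features = length(feature_cols(feats)),
                   n_modes = config$n_modes, k = config$k,
                   classifiers = names(specs), lobes = lobes,
                   montage = config$montage_id,
                   group_by_subject = config$group_by_subject)
  out <- structure(list(overall = overall, lobewise = lobewise, roc = roc,
                        cv = cvs, permutation = perm, learning_curve = lc,
                        features = feats, manifest = manifest,
                        config = config),
                   class = "cogload_run")
  if (!is.null(config$outdir)) write_run(out, config$outdir)
  out
}

# Deterministic fixed-precision table formatting so identical runs write
# byte-identical report files.
format_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.4f", v))
  df
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(format_table(run$overall),
                     file.path(outdir, "overall_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(format_table(run$lobewise),
                     file.path(outdir, "lobewise_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(run$roc))
    utils::write.table(format_table(run$roc[[nm]]),
                       file.path(outdir, paste0("roc_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(run$permutation))
    jsonlite::write_json(run$permutation[c("observed", "p_value", "n_perm",
                                           "permuted")],
                         file.path(outdir, "permutation.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(run$learning_curve))
    utils::write.table(format_table(run$learning_curve),
                       file.path(outdir, "learning_curve.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.cogload_run <- function(x, ...) {
  cat("Cognitive-load pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  cat(sprintf("  %d segments -> %d features (%d modes, montage %s)\n",
              x$manifest$n_segments, x$manifest$n_features,
              x$manifest$n_modes, x$manifest$montage))
  cat("  overall results:\n")
  ov <- x$overall
  for (i in seq_len(nrow(ov)))
    cat(sprintf("    %-20s Ac %.2f%%  Se %.2f%%  Sp %.2f%%  AUC %.3f\n",
                ov$classifier[i], ov$Ac[i], ov$Se[i], ov$Sp[i], ov$AUC[i]))
  if (!is.null(x$lobewise)) {
    best <- x$lobewise[order(-x$lobewise$mean_fold_Ac), ]
    cat(sprintf("  best lobe: %s (%s, Ac %.2f%%)\n",
                best$lobe[1], best$classifier[1], best$mean_fold_Ac[1]))
  }
  if (!is.null(x$permutation))
    cat(sprintf("  permutation test: p = %.4f (%d iterations)\n",
                x$permutation$p_value, x$permutation$n_perm))
  invisible(x)
}
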