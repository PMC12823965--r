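.families <- c("boosted_trees", "bagged_trees", "subspace_knn",
               "subspace_discriminant", "svm_linear", "svm_quadratic",
               "svm_cubic", "svm_rbf", "knn", "naive_bayes", "lda", "qda",
               "logistic", "tree")

#' Classifier specification
#'
#' Names one of the supported classifier families together with its
#' hyperparameters and a seed. Families: gradient-boosted trees
#' (`boosted_trees`, the boosted-ensemble workhorse), `bagged_trees`,
#' random-subspace ensembles over k-NN or LDA base learners
#' (`subspace_knn`, `subspace_discriminant`), SVMs with linear, quadratic,
#' cubic or RBF kernels, `knn`, Gaussian `naive_bayes`, `lda`, `qda`,
#' `logistic`, and a single CART `tree`.
#'
#' @param family one of the family names above.
#' @param params named list of hyperparameters (defaults filled in).
#' @param seed integer seed used for any stochastic fitting step.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family, params = list(), seed = 1L) {
  family <- match.arg(family, .families)
  defaults <- switch(family,
    boosted_trees = list(nrounds = 60L, max_depth = 3L, eta = 0.3,
                         subsample = 1.0),
    bagged_trees = list(ntree = 100L, nodesize = 1L),
    subspace_knn = list(k = 5L, n_learners = 30L, subspace_frac = 0.5),
    subspace_discriminant = list(n_learners = 30L, subspace_frac = 0.5),
    svm_linear = list(cost = 1),
    svm_quadratic = list(cost = 1),
    svm_cubic = list(cost = 1),
    svm_rbf = list(cost = 1, gamma = NA_real_),  # NA: e1071 default 1/p
    knn = list(k = 5L),
    naive_bayes = list(),
    lda = list(), qda = list(), logistic = list(),
    tree = list(cp = 0.01, minsplit = 20L))
  bad <- setdiff(names(params), names(defaults))
  if (length(bad))
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(bad, collapse = ", "))
  defaults[names(params)] <- params
  structure(list(family = family, params = defaults, seed = as.integer(seed)),
            class = "model_spec")
}

# Fit one model on (X, y). X numeric matrix; y factor with levels
# c("rest", "task"); "task" is the positive class throughout.
fit_model <- function(spec, X, y) {
  p <- spec$params
  set.seed(spec$seed)
  fit <- switch(spec$family,
    boosted_trees = {
      d <- xgboost::xgb.DMatrix(X, label = as.numeric(y == "task"))
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       max_depth = p$max_depth, eta = p$eta,
                                       subsample = p$subsample, nthread = 1,
                                       seed = spec$seed),
                         d, nrounds = p$nrounds, verbose = 0)
    },
    bagged_trees = randomForest::randomForest(
      X, y, ntree = p$ntree, mtry = ncol(X), nodesize = p$nodesize),
    subspace_knn = fit_subspace(X, y, p, base = "knn", seed = spec$seed),
    subspace_discriminant = fit_subspace(X, y, p, base = "lda",
                                         seed = spec$seed),
    svm_linear = e1071::svm(X, y, kernel = "linear", cost = p$cost,
                            scale = FALSE),
    svm_quadratic = e1071::svm(X, y, kernel = "polynomial", degree = 2,
                               coef0 = 1, cost = p$cost, scale = FALSE),
    svm_cubic = e1071::svm(X, y, kernel = "polynomial", degree = 3,
                           coef0 = 1, cost = p$cost, scale = FALSE),
    svm_rbf = e1071::svm(X, y, kernel = "radial", cost = p$cost,
                         gamma = if (is.na(p$gamma)) 1 / ncol(X) else p$gamma,
                         scale = FALSE),
    knn = list(X = X, y = y, k = p$k),
    naive_bayes = e1071::naiveBayes(X, y),
    lda = MASS::lda(X, grouping = y),
    qda = MASS::qda(X, grouping = y),
    logistic = {
      df <- as.data.frame(X); df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    tree = {
      df <- as.data.frame(X); df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = p$cp,
                                                  minsplit = p$minsplit))
    })
  structure(list(fit = fit, spec = spec, columns = colnames(X)),
            class = "emfdeeg_fit")
}

# Random-subspace ensemble over k-NN or LDA base learners.  Scores are
# the mean positive-class votes/posteriors across learners.
fit_subspace <- function(X, y, p, base, seed) {
  d <- max(1L, floor(p$subspace_frac * ncol(X)))
  subs <- lapply(seq_len(p$n_learners), function(i) {
    set.seed(derive_seed(seed, paste0("subspace", i)))
    sort(sample.int(ncol(X), d))
  })
  learners <- lapply(subs, function(cols) {
    if (base == "lda") {
      Xi <- X[, cols, drop = FALSE]
      ok <- apply(Xi, 2L, stats::sd) > 1e-10
      if (!any(ok)) return(NULL)
      tryCatch(MASS::lda(Xi[, ok, drop = FALSE], grouping = y),
               error = function(e) NULL)
    } else NULL  # knn is lazy: training rows stored once below
  })
  list(base = base, subs = subs, learners = learners, X = X, y = y, k = p$k)
}

# Continuous positive-class score per row of X (probability-like where
# available; oriented decision values for SVMs) plus hard predictions.
predict_model <- function(model, X) {
  spec <- model$spec
  X <- X[, model$columns, drop = FALSE]
  svm_pred <- NULL   # SVM branch supplies its own hard labels
  score <- switch(spec$family,
    boosted_trees = predict(model$fit, xgboost::xgb.DMatrix(X)),
    bagged_trees = predict(model$fit, X, type = "prob")[, "task"],
    subspace_knn = , subspace_discriminant = {
      en <- model$fit
      acc <- numeric(nrow(X))
      nused <- 0L
      for (i in seq_along(en$subs)) {
        cols <- en$subs[[i]]
        if (en$base == "knn") {
          set.seed(1L)  # class::knn breaks distance ties at random
          pr <- class::knn(en$X[, cols, drop = FALSE],
                           X[, cols, drop = FALSE], en$y, k = en$k,
                           prob = TRUE)
          pp <- attr(pr, "prob")
          acc <- acc + ifelse(pr == "task", pp, 1 - pp)
          nused <- nused + 1L
        } else if (!is.null(en$learners[[i]])) {
          keep <- colnames(en$X[, cols, drop = FALSE]) %in%
            rownames(en$learners[[i]]$scaling)
          po <- predict(en$learners[[i]],
                        X[, cols[keep], drop = FALSE])$posterior[, "task"]
          acc <- acc + po
          nused <- nused + 1L
        }
      }
      if (nused == 0L) rep(0.5, nrow(X)) else acc / nused
    },
    svm_linear = , svm_quadratic = , svm_cubic = , svm_rbf = {
      pr <- predict(model$fit, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # the decision column is named "<A>/<B>": positive values favour A
      if (!startsWith(colnames(dv)[1L], "task/")) dv <- -dv
      svm_pred <<- factor(as.character(pr), levels = c("rest", "task"))
      as.numeric(dv[, 1L])
    },
    knn = {
      set.seed(1L)
      pr <- class::knn(model$fit$X, X, model$fit$y, k = model$fit$k,
                       prob = TRUE)
      pp <- attr(pr, "prob")
      ifelse(pr == "task", pp, 1 - pp)
    },
    naive_bayes = predict(model$fit, X, type = "raw")[, "task"],
    lda = , qda = predict(model$fit, X)$posterior[, "task"],
    logistic = {
      df <- as.data.frame(X)
      as.numeric(predict(model$fit, newdata = df, type = "response"))
    },
    tree = {
      df <- as.data.frame(X)
      predict(model$fit, newdata = df, type = "prob")[, "task"]
    })
  pred <- svm_pred %||% factor(ifelse(score > 0.5, "task", "rest"),
                               levels = c("rest", "task"))
  list(score = as.numeric(score), pred = pred)
}

# ---------------------------------------------------------------------------

#' Confusion metrics in percent
#'
#' Accuracy, sensitivity (task recall), specificity, precision and
#' F-score from confusion counts, with `task` the positive class.
#' Undefined ratios (empty denominator) are reported as `NA`, never as 0.
#'
#' @param tp,fn,tn,fp confusion counts (non-negative, total > 0).
#' @return named numeric vector `c(Ac, Se, Sp, Pr, Fs)` in percent.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  tp <- unname(tp); fn <- unname(fn); tn <- unname(tn); fp <- unname(fp)
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  total <- sum(counts)
  if (total == 0) stop("all confusion counts are zero")
  safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  Se <- safe(tp, tp + fn)
  Sp <- safe(tn, tn + fp)
  Pr <- safe(tp, tp + fp)
  Fs <- if (!is.na(Se) && !is.na(Pr) && (Se + Pr) > 0)
    2 * Pr * Se / (Pr + Se) else NA_real_
  c(Ac = 100 * (tp + tn) / total, Se = Se, Sp = Sp, Pr = Pr, Fs = Fs)
}

#' ROC curve and AUC from continuous scores
#'
#' Threshold sweep over the unique scores (ties grouped, i.e.
#' rank-averaged); AUC by the trapezoid rule.
#'
#' @param scores continuous scores, larger favouring `task`.
#' @param y labels, factor or character with both `rest` and `task`.
#' @return list with `curve` (`data.frame(fpr, tpr, threshold)`) and `auc`.
#' @export
roc_auc <- function(scores, y) {
  y <- factor(as.character(y), levels = c("rest", "task"))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  np <- sum(y == "task"); nn <- sum(y == "rest")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; lab <- y[ord] == "task"
  grp <- cumsum(!duplicated(s))                 # tie groups
  tp <- cumsum(lab); fp <- cumsum(!lab)
  last <- !duplicated(grp, fromLast = TRUE)     # last row of each tie group
  curve <- data.frame(fpr = c(0, fp[last] / nn), tpr = c(0, tp[last] / np),
                      threshold = c(Inf, s[last]))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  list(curve = curve, auc = auc)
}

# Stratified fold assignment: shuffled indices of each class dealt
# round-robin, so per-fold class proportions are within one sample of the
# global proportions.  With `groups`, whole groups (subjects) are dealt to
# folds instead, keeping each subject's segments together.
assign_folds <- function(y, k, seed, groups = NULL) {
  set.seed(seed)
  fold <- integer(length(y))
  if (is.null(groups)) {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    gu <- sample(unique(groups))
    if (length(gu) < k) stop("need at least k distinct groups for grouped CV")
    gf <- rep_len(seq_len(k), length(gu))
    fold <- gf[match(groups, gu)]
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Every row is scored exactly once out-of-fold. Min-max normalization
#' (and optional variance/correlation feature reduction) is fitted inside
#' each training fold only, so no statistics leak from held-out rows.
#' Reports per-fold confusion counts, pooled Ac/Se/Sp/Pr/Fs, the ROC over
#' pooled out-of-fold scores, and mean/SD/95% CI of the fold accuracies
#' (CI from the t distribution on k - 1 degrees of freedom).
#'
#' @param spec a [model_spec()].
#' @param x an `eeg_features` data frame with a `condition` column, or any
#'   data frame of numeric features plus `condition`.
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment and model fits.
#' @param group_by_subject keep each subject's segments in one fold
#'   (requires a `subject_id` column with at least `k` subjects).
#' @param normalize fit-and-apply min-max scaling per training fold.
#' @param reduce apply [reduce_features()] per training fold.
#' @return object of class `cv_result`.
#' @export
stratified_kfold_cv <- function(spec, x, k = 10L, seed = 1L,
                                group_by_subject = FALSE, normalize = TRUE,
                                reduce = FALSE) {
  stopifnot(k >= 2)
  y <- factor(as.character(x$condition), levels = c("rest", "task"))
  if (any(is.na(y))) stop("condition column must contain only rest/task")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (min(table(y)) < k && !group_by_subject)
    stop("k exceeds the size of the smaller class")
  groups <- if (group_by_subject) x$subject_id else NULL
  fold <- assign_folds(y, k, derive_seed(seed, "folds"), groups)
  fc <- feature_cols(x)
  scores <- numeric(nrow(x))
  preds <- factor(rep("rest", nrow(x)), levels = c("rest", "task"))
  per_fold <- matrix(0L, nrow = k, ncol = 4L,
                     dimnames = list(NULL, c("tp", "fn", "tn", "fp")))
  norm_ranges <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(y[tr])) < 2L)
      stop("degenerate single-class training fold; reduce k or regroup")
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    if (reduce) {
      xtr <- reduce_features(xtr)
      xte <- xte[, colnames(xtr), drop = FALSE]
    }
    if (normalize) {
      norm_ranges[[f]] <- vapply(xtr[feature_cols(xtr)], range, numeric(2))
      xte <- fit_apply_minmax(xtr, xte)
      xtr <- fit_apply_minmax(xtr)
    }
    Xtr <- as.matrix(xtr[feature_cols(xtr)])
    Xte <- as.matrix(xte[feature_cols(xte)])
    sp <- spec; sp$seed <- derive_seed(seed, paste0("fit", f))
    model <- fit_model(sp, Xtr, y[tr])
    out <- predict_model(model, Xte)
    scores[te] <- out$score
    preds[te] <- out$pred
    per_fold[f, ] <- c(sum(out$pred == "task" & y[te] == "task"),
                       sum(out$pred == "rest" & y[te] == "task"),
                       sum(out$pred == "rest" & y[te] == "rest"),
                       sum(out$pred == "task" & y[te] == "rest"))
  }
  fold_acc <- 100 * (per_fold[, "tp"] + per_fold[, "tn"]) / rowSums(per_fold)
  pooled <- colSums(per_fold)
  roc <- roc_auc(scores, y)
  ci <- mean(fold_acc) + c(-1, 1) * stats::qt(0.975, k - 1) *
    stats::sd(fold_acc) / sqrt(k)
  structure(list(
    per_fold = as.data.frame(per_fold), fold = fold,
    metrics = confusion_metrics(pooled["tp"], pooled["fn"],
                                pooled["tn"], pooled["fp"]),
    fold_accuracy = fold_acc, mean_accuracy = mean(fold_acc),
    sd_accuracy = stats::sd(fold_acc), ci95 = ci,
    scores = scores, predictions = preds, truth = y,
    roc = roc$curve, auc = roc$auc,
    norm_ranges = norm_ranges,
    spec = spec, k = k, seed = seed,
    group_by_subject = group_by_subject),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV, %s (seed %d%s)\n", x$k, x$spec$family, x$seed,
              if (x$group_by_subject) ", grouped by subject" else ""))
  m <- x$metrics
  cat(sprintf("  pooled: Ac %.2f%%  Se %.2f%%  Sp %.2f%%  Pr %.2f%%  Fs %.2f%%  AUC %.3f\n",
              m["Ac"], m["Se"], m["Sp"], m["Pr"], m["Fs"], x$auc))
  cat(sprintf("  fold accuracy: mean %.2f%%, SD %.2f, 95%% CI [%.2f, %.2f]\n",
              x$mean_accuracy, x$sd_accuracy, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  print(object)
  cat("  per-fold confusion counts:\n")
  print(object$per_fold)
  invisible(object)
}

#' Permutation test of classifier performance
#'
#' The observed statistic is the mean cross-validated accuracy; each
#' iteration permutes the condition labels wholesale and re-runs the full
#' cross-validation. The p-value uses the add-one rule
#' `p = (1 + #{permuted >= observed}) / (n_perm + 1)`, so it is never 0.
#'
#' @inheritParams stratified_kfold_cv
#' @param n_perm number of permutations (100 is the conventional choice).
#' @return list of class `permutation_result`: `observed`, `permuted`,
#'   `p_value`, `n_perm`.
#' @export
permutation_test <- function(spec, x, n_perm = 100L, k = 10L, seed = 1L,
                             normalize = TRUE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- stratified_kfold_cv(spec, x, k = k, seed = derive_seed(seed, "obs"),
                             normalize = normalize)$mean_accuracy
  permuted <- vapply(seq_len(n_perm), function(i) {
    xi <- x
    set.seed(derive_seed(seed, paste0("perm", i)))
    xi$condition <- sample(xi$condition)
    stratified_kfold_cv(spec, xi, k = k,
                        seed = derive_seed(seed, paste0("permcv", i)),
                        normalize = normalize)$mean_accuracy
  }, numeric(1))
  p <- (1 + sum(permuted >= obs)) / (n_perm + 1)
  structure(list(observed = obs, permuted = permuted, p_value = p,
                 n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: observed accuracy %.2f%%, %d permutations, p = %.4f\n",
              x$observed, x$n_perm, x$p_value))
  invisible(x)
}

#' Learning curve over training-set fractions
#'
#' For each fraction the training folds are stratified-subsampled, the
#' model refitted, and both training accuracy (on the subsample) and
#' validation accuracy (on the held-out fold) recorded, averaged over
#' folds and repeats.
#'
#' @inheritParams stratified_kfold_cv
#' @param fractions training fractions in (0, 1].
#' @param repeats number of repetitions with different subsample seeds.
#' @return `data.frame` with `fraction`, `train_accuracy`,
#'   `validation_accuracy`.
#' @export
learning_curve <- function(spec, x, fractions = c(0.1, 0.25, 0.5, 0.75, 1),
                           k = 5L, seed = 1L, repeats = 3L,
                           normalize = TRUE) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  y <- factor(as.character(x$condition), levels = c("rest", "task"))
  out <- lapply(fractions, function(f) {
    tr_acc <- va_acc <- numeric(0)
    for (rep_i in seq_len(repeats)) {
      fold <- assign_folds(y, k, derive_seed(seed, paste0("lc", rep_i)))
      for (fd in seq_len(k)) {
        tr <- which(fold != fd); te <- which(fold == fd)
        sub <- unlist(lapply(levels(y), function(cl) {
          ci <- tr[y[tr] == cl]
          set.seed(derive_seed(seed, paste0("sub", rep_i, fd, cl, f)))
          sample(ci, max(1L, round(f * length(ci))))
        }))
        if (length(unique(y[sub])) < 2L)
          stop("fraction ", f, " yields a single-class subsample")
        xtr <- x[sub, , drop = FALSE]; xte <- x[te, , drop = FALSE]
        if (normalize) {
          xte <- fit_apply_minmax(xtr, xte)
          xtr <- fit_apply_minmax(xtr)
        }
        sp <- spec; sp$seed <- derive_seed(seed, paste0("lcfit", rep_i, fd, f))
        model <- fit_model(sp, as.matrix(xtr[feature_cols(xtr)]), y[sub])
        tr_acc <- c(tr_acc, mean(predict_model(
          model, as.matrix(xtr[feature_cols(xtr)]))$pred == y[sub]))
        va_acc <- c(va_acc, mean(predict_model(
          model, as.matrix(xte[feature_cols(xte)]))$pred == y[te]))
      }
    }
    c(train = 100 * mean(tr_acc), validation = 100 * mean(va_acc))
  })
  data.frame(fraction = fractions,
             train_accuracy = vapply(out, `[[`, numeric(1), "train"),
             validation_accuracy = vapply(out, `[[`, numeric(1), "validation"))
}

# ---------------------------------------------------------------------------
# Bayesian hyperparameter optimization (sequential model-based search with
# a Gaussian-process surrogate and expected improvement)

.search_spaces <- list(
  boosted_trees = list(
    nrounds = list(lo = 20, hi = 200, log = FALSE, int = TRUE),
    max_depth = list(lo = 1, hi = 8, log = FALSE, int = TRUE),
    eta = list(lo = 0.01, hi = 0.5, log = TRUE, int = FALSE),
    subsample = list(lo = 0.5, hi = 1, log = FALSE, int = FALSE)),
  bagged_trees = list(
    ntree = list(lo = 50, hi = 300, log = FALSE, int = TRUE),
    nodesize = list(lo = 1, hi = 10, log = FALSE, int = TRUE)),
  subspace_knn = list(
    k = list(lo = 1, hi = 15, log = FALSE, int = TRUE),
    n_learners = list(lo = 10, hi = 50, log = FALSE, int = TRUE),
    subspace_frac = list(lo = 0.2, hi = 0.8, log = FALSE, int = FALSE)),
  svm_rbf = list(
    cost = list(lo = 1e-2, hi = 1e2, log = TRUE, int = FALSE),
    gamma = list(lo = 1e-4, hi = 1, log = TRUE, int = FALSE)),
  knn = list(
    k = list(lo = 1, hi = 25, log = FALSE, int = TRUE)),
  tree = list(
    cp = list(lo = 1e-4, hi = 0.1, log = TRUE, int = FALSE),
    minsplit = list(lo = 2, hi = 40, log = FALSE, int = TRUE)))

space_to_params <- function(space, u) {
  out <- list()
  for (i in seq_along(space)) {
    s <- space[[i]]
    v <- if (s$log) exp(log(s$lo) + u[i] * (log(s$hi) - log(s$lo)))
    else s$lo + u[i] * (s$hi - s$lo)
    if (s$int) v <- as.integer(round(v))
    out[[names(space)[i]]] <- v
  }
  out
}

# Expected improvement for maximization under a simple GP surrogate
# (squared-exponential kernel on the unit cube, fixed length-scale 0.25,
# nugget 1e-6, zero-mean on standardized objectives).
gp_ei <- function(U, yst, cand, ls = 0.25, nugget = 1e-6) {
  sq <- function(A, B) outer(rowSums(A^2), rowSums(B^2), `+`) -
    2 * tcrossprod(A, B)
  K <- exp(-pmax(sq(U, U), 0) / (2 * ls^2)) + diag(nugget, nrow(U))
  Kc <- exp(-pmax(sq(cand, U), 0) / (2 * ls^2))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yst))
  mu <- as.numeric(Kc %*% alpha)
  v <- forwardsolve(t(L), t(Kc))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  best <- max(yst)
  z <- (mu - best) / s
  (mu - best) * stats::pnorm(z) + s * stats::dnorm(z)
}

#' Bayesian hyperparameter optimization
#'
#' Sequential model-based search over a family's declared hyperparameter
#' box: an initial random design followed by expected-improvement
#' proposals from a Gaussian-process surrogate. The objective is mean
#' accuracy of an inner stratified cross-validation.
#'
#' @param family family name with a declared search space
#'   (`boosted_trees`, `bagged_trees`, `subspace_knn`, `svm_rbf`, `knn`,
#'   `tree`).
#' @param x feature data frame with a `condition` column.
#' @param budget total number of objective evaluations (default 30).
#' @param seed integer seed.
#' @param k_inner folds of the inner cross-validation objective.
#' @return list with `best` (a [model_spec()]), `best_objective`, and
#'   `history` (one row per evaluation, in order, with the objective and a
#'   monotone `running_best`).
#' @export
#' @importFrom stats dnorm
bayesian_optimize <- function(family, x, budget = 30L, seed = 1L,
                              k_inner = 5L) {
  if (!family %in% names(.search_spaces))
    stop("no search space declared for family '", family, "'")
  if (budget < 1) stop("budget must be >= 1")
  space <- .search_spaces[[family]]
  d <- length(space)
  objective <- function(u, i) {
    sp <- model_spec(family, space_to_params(space, u),
                     seed = derive_seed(seed, paste0("bo-eval", i)))
    stratified_kfold_cv(sp, x, k = k_inner,
                        seed = derive_seed(seed, "bo-inner"))$mean_accuracy
  }
  n0 <- min(budget, max(4L, d + 1L))
  set.seed(derive_seed(seed, "bo-init"))
  U <- matrix(stats::runif(n0 * d), ncol = d)
  ys <- vapply(seq_len(n0), function(i) objective(U[i, ], i), numeric(1))
  while (nrow(U) < budget) {
    i <- nrow(U) + 1L
    set.seed(derive_seed(seed, paste0("bo-cand", i)))
    cand <- matrix(stats::runif(500L * d), ncol = d)
    ysd <- if (stats::sd(ys) > 0) stats::sd(ys) else 1
    ei <- gp_ei(U, (ys - mean(ys)) / ysd, cand)
    u <- cand[which.max(ei), , drop = FALSE]
    U <- rbind(U, u)
    ys <- c(ys, objective(as.numeric(u), i))
  }
  hist_params <- do.call(rbind, lapply(seq_len(nrow(U)), function(i)
    as.data.frame(space_to_params(space, U[i, ]))))
  history <- cbind(hist_params, objective = ys, running_best = cummax(ys))
  best_i <- which.max(ys)
  list(best = model_spec(family, space_to_params(space, U[best_i, ]),
                         seed = seed),
       best_objective = ys[best_i], history = history)
}
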