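#' Stratified k-fold assignment
#'
#' Participants are randomly split into `k` folds for cross-validation,
#' stratified by class: members of each class are shuffled and dealt
#' cyclically across folds (the second class continuing the deal where
#' the first stopped), so per-fold class counts are within one of the
#' cohort proportion and fold sizes differ by at most one. Deterministic
#' given `split_seed`.
#'
#' @param labels Integer class labels in `{0, 1}`, one per participant.
#' @param k Number of folds (default 5).
#' @param split_seed Integer seed for the shuffle.
#' @param ids Optional participant ids used to name the assignment.
#' @return Object of class `fold_assignment`: list with `fold` (integer
#'   vector in `1..k`, one per participant), `k`, `split_seed`.
#' @examples
#' f <- make_folds(rep(c(0, 1), c(11, 17)), k = 5, split_seed = 1)
#' table(f$fold)
#' @export
make_folds <- function(labels, k = 5L, split_seed = 0L, ids = NULL) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  n <- length(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("both classes must be present")
  if (n < 2L * k) stop("need at least 2k participants for ", k, " folds")
  counts <- table(labels)
  if (any(counts < k)) {
    stop("class too small to stratify: every class needs >= k members")
  }
  fold <- integer(n)
  withr_seed(split_seed, {
    # larger classes dealt first; the deal position carries across classes
    pos <- 0L
    for (cl in classes[order(-counts[as.character(classes)])]) {
      members <- which(labels == cl)
      members <- members[sample.int(length(members))]
      fold[members] <- ((pos + seq_along(members) - 1L) %% k) + 1L
      pos <- pos + length(members)
    }
  })
  if (!is.null(ids)) names(fold) <- ids
  structure(list(fold = fold, k = k, split_seed = as.integer(split_seed)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("Fold assignment: k =", x$k, ", split seed", x$split_seed,
      ", sizes", paste(tabulate(x$fold, x$k), collapse = "/"), "\n")
  invisible(x)
}

# Seeds for per-fold weight initialization, derived from the experiment's
# init seed so each fold's network differs but the whole CV run is a pure
# function of (data, folds, init_seed, config).
derive_fold_seeds <- function(init_seed, k) {
  withr_seed(init_seed, sample.int(.Machine$integer.max, k))
}

#' One 5-fold cross-validation experiment
#'
#' For each fold, a freshly initialized network (seeded from `init_seed`)
#' is trained on the out-of-fold participants and predicts the held-out
#' fold, so every participant is predicted exactly once as a test case.
#' Pooled accuracy is the fraction of all `N` held-out predictions that
#' match the true label — an exact rational `m/N`.
#'
#' @param X Design matrix of normalized edge vectors (rows=participants).
#' @param y Integer labels in `{0, 1}`.
#' @param folds A [make_folds()] assignment.
#' @param init_seed Seed of this experiment's initial network weights.
#' @param config A [train_config()].
#' @param hidden Hidden-layer widths of the network.
#' @param keep_models Keep the k trained per-fold models (needed for
#'   gradient collection; sizeable for the full 3486-input network).
#' @return Object of class `cv_result`: `prediction` (0-based predicted
#'   class per participant), `correct` (logical), `pooled_accuracy`,
#'   `init_seed`, `folds`, and `models` (list of k trained `mlp`s, or
#'   `NULL`).
#' @export
run_cv <- function(X, y, folds, init_seed, config = train_config(),
                   hidden = c(1024L, 256L, 64L), keep_models = TRUE) {
  stopifnot(inherits(folds, "fold_assignment"))
  y <- as.integer(y)
  n <- nrow(X)
  if (length(folds$fold) != n || length(y) != n) {
    stop("X, y and fold assignment disagree on cohort size")
  }
  fold_seeds <- derive_fold_seeds(init_seed, folds$k)
  prediction <- integer(n)
  models <- if (keep_models) vector("list", folds$k) else NULL
  for (f in seq_len(folds$k)) {
    test <- folds$fold == f
    model <- mlp_init(ncol(X), hidden = hidden, init_seed = fold_seeds[f])
    model <- tryCatch(
      mlp_train(model, X[!test, , drop = FALSE], y[!test], config),
      error = function(e) stop("training failed in fold ", f, ": ",
                               conditionMessage(e)))
    prediction[test] <- mlp_forward(model, X[test, , drop = FALSE])$class
    if (keep_models) models[[f]] <- model
  }
  correct <- prediction == y
  structure(list(prediction = prediction, correct = correct,
                 pooled_accuracy = sum(correct) / n,
                 init_seed = as.integer(init_seed), folds = folds,
                 models = models),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV experiment (init seed %d): pooled accuracy %.2f%% (%d/%d)\n",
              x$init_seed, 100 * x$pooled_accuracy, sum(x$correct),
              length(x$correct)))
  invisible(x)
}

#' Repeated-seed cross-validation experiments
#'
#' Runs [run_cv()] once per init seed (default seeds `0..n_seeds-1`) with
#' the fold assignment held fixed — only the initial network weights are
#' re-randomized across experiments. The best model is the seed with
#' maximal pooled held-out accuracy, ties broken by the lowest seed.
#' Optionally re-randomizes folds per seed (`refold_per_seed`), deriving
#' each seed's split from `folds$split_seed` and the init seed.
#'
#' Input gradients can be collected on the fly (`gradients = TRUE`): after
#' each experiment, every correctly predicted held-out participant
#' contributes the gradient of its true class under its fold's model, and
#' per-class running sums are kept so the per-fold models can be released
#' — memory stays flat in `n_seeds`.
#'
#' @inheritParams run_cv
#' @param n_seeds Number of experiments; init seeds are `seeds`.
#' @param seeds Init seeds to run (default `0:(n_seeds-1)`).
#' @param gradients Collect true-class input gradients of correctly
#'   predicted held-out participants (see [collect_gradients()]).
#' @param gradient_mode Gradient target: `"probability"` (default),
#'   `"logit"` or `"margin"`.
#' @param keep_models Retain all per-fold models of every seed (memory!).
#' @param refold_per_seed Re-randomize the fold split for every seed.
#' @param progress Print one line per completed seed.
#' @return Object of class `repeated_run`: `results` (list of slim
#'   `cv_result`s), `accuracies`, `seeds`, `best_seed`, `best_accuracy`,
#'   and `gradient_samples` (a `grad_samples` accumulator, or `NULL`).
#' @export
run_repeated <- function(X, y, folds, n_seeds, config = train_config(),
                         hidden = c(1024L, 256L, 64L),
                         seeds = seq_len(n_seeds) - 1L,
                         gradients = TRUE,
                         gradient_mode = "probability",
                         keep_models = FALSE,
                         refold_per_seed = FALSE,
                         progress = FALSE) {
  stopifnot(length(seeds) >= 1)
  y <- as.integer(y)
  results <- vector("list", length(seeds))
  gs <- NULL
  for (s in seq_along(seeds)) {
    folds_s <- if (refold_per_seed) {
      make_folds(y, k = folds$k,
                 split_seed = folds$split_seed + seeds[s] + 1L)
    } else folds
    cv <- run_cv(X, y, folds_s, init_seed = seeds[s], config = config,
                 hidden = hidden, keep_models = TRUE)
    if (gradients) {
      gs_s <- collect_gradients(cv, X, y, mode = gradient_mode,
                                keep_samples = FALSE)
      gs <- if (is.null(gs)) gs_s else combine_grad_samples(gs, gs_s)
    }
    if (!keep_models) cv$models <- NULL
    results[[s]] <- cv
    if (progress) {
      message(sprintf("seed %d: pooled accuracy %.2f%%", seeds[s],
                      100 * cv$pooled_accuracy))
    }
  }
  accuracies <- vapply(results, `[[`, numeric(1), "pooled_accuracy")
  best <- which.max(accuracies)  # first max = lowest seed on ties
  structure(list(results = results, accuracies = accuracies,
                 seeds = as.integer(seeds),
                 best_seed = as.integer(seeds[best]),
                 best_accuracy = accuracies[best],
                 gradient_samples = gs,
                 folds = folds, config = config, hidden = hidden),
            class = "repeated_run")
}

#' @export
print.repeated_run <- function(x, ...) {
  cat(sprintf(
    "Repeated CV: %d experiments, best seed %d at %.2f%% pooled accuracy (mean %.2f%%)\n",
    length(x$seeds), x$best_seed, 100 * x$best_accuracy,
    100 * mean(x$accuracies)))
  invisible(x)
}
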