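#' Fisher's z transformation of a correlation
#'
#' `z = 0.5 * ln((1 + r) / (1 - r)) = atanh(r)`; variance-stabilizes
#' accuracies before ANOVA. `|r| = 1` returns an infinite sentinel with a
#' warning.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  stopifnot(all(abs(r) <= 1 + 1e-12))
  if (any(abs(r) >= 1)) {
    warning("|r| = 1: Fisher z is infinite")
  }
  atanh(pmin(pmax(r, -1), 1))
}

# fit one model on a training design and score it against observed
# phenotypes of `eval_ids`; NA (with warning) when the accuracy is undefined
fit_and_score <- function(model, panel, A, y_all, train_ids, eval_ids,
                          mcmc = c(n_iter = 5000, burn_in = 2500),
                          seed = NULL) {
  y_tr <- y_all[train_ids]
  fit <- switch(model,
    GBLUP = gblup_fit_predict(A, y_tr, predict_ids = eval_ids),
    RKHS = rkhs_fit_predict(panel, y_tr, predict_ids = eval_ids),
    BAYESC = bayesc_fit_predict(panel, y_tr, predict_ids = eval_ids,
                                n_iter = mcmc[["n_iter"]],
                                burn_in = mcmc[["burn_in"]], seed = seed),
    stop("unknown model: ", model))
  tryCatch(accuracy(fit, y_all[eval_ids]),
           error = function(e) {
             warning("undefined accuracy recorded as NA: ",
                     conditionMessage(e))
             NA_real_
           })
}

sample_training <- function(method, ids, n, strata, similarity, A, seed,
                            h2_cdmean, target_ids = NULL,
                            cdmean_control = list()) {
  switch(method,
    SRS = srs_sample(ids, n, seed = seed),
    STRAT = stratified_sample(ids, strata, n, seed = seed),
    GD = gd_sample(similarity, ids, n, seed = seed),
    CDMEAN = do.call(cdmean_select,
                     c(list(A = A, candidates = ids, n = n, h2 = h2_cdmean,
                            target_ids = target_ids, seed = seed),
                       cdmean_control)),
    stop("unknown method: ", method))
}

#' Training-validation (TV) evaluation scheme
#'
#' For each training-set size and replicate, samples a training set from the
#' whole panel by each method, fits each model on it, and predicts the
#' complement (the validation set). Sampler inputs (relationship matrix,
#' similarity matrix, strata) are computed once per panel. Replicates are
#' independently seeded from `seed` by a counter, so any subset of cells is
#' reproducible in isolation.
#'
#' @param panel a [dosage_panel] (with strata if `"STRAT"` is requested).
#' @param trait a `trait_set` (or named phenotype vector).
#' @param methods subset of `c("SRS", "STRAT", "GD", "CDMEAN")`.
#' @param models subset of `c("GBLUP", "RKHS", "BAYESC")`.
#' @param sizes training-set sizes (default `c(50, 75, 100, 125, 150)`).
#' @param reps sampling replicates per size (default 100).
#' @param seed base RNG seed.
#' @param h2_cdmean heritability fed to CDmean (default 0.5, trait-agnostic).
#' @param mcmc named vector with `n_iter`, `burn_in` for BayesC.
#' @param cdmean_control extra arguments for [cdmean_select]
#'   (e.g. `max_stall`, `n_starts`).
#' @param gd_measure distance measure for GD sampling (default
#'   `"euclidean"`, converted to similarity by `1 - D / max(D)`).
#' @return data.frame of accuracy records: one row per
#'   (size, rep, method, model) with `accuracy` and `fisher_z`.
#' @export
run_tv_scheme <- function(panel, trait,
                          methods = c("SRS", "STRAT", "GD", "CDMEAN"),
                          models = c("GBLUP", "RKHS", "BAYESC"),
                          sizes = c(50, 75, 100, 125, 150), reps = 100,
                          seed = 1, h2_cdmean = 0.5,
                          mcmc = c(n_iter = 5000, burn_in = 2500),
                          cdmean_control = list(),
                          gd_measure = c("euclidean", "nei", "jaccard",
                                         "kosman")) {
  validate_panel(panel)
  gd_measure <- match.arg(gd_measure)
  y_all <- if (inherits(trait, "trait_set")) trait$values else trait
  ids <- panel_ids(panel)
  stopifnot(all(sizes < length(ids)))
  A <- vanraden_A(panel)
  S <- if ("GD" %in% methods) panel_similarity(panel, gd_measure) else NULL
  out <- vector("list", length(sizes) * reps * length(methods) *
                  length(models))
  row <- 0L
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    for (rep_i in seq_len(reps)) {
      for (mi in seq_along(methods)) {
        method <- methods[mi]
        s_seed <- child_seed(seed, (si * 1000L + rep_i) * 10L + mi)
        design <- sample_training(method, ids, n, panel$strata, S, A,
                                  s_seed, h2_cdmean,
                                  cdmean_control = cdmean_control)
        val_ids <- setdiff(ids, design$training_ids)
        for (ki in seq_along(models)) {
          acc <- fit_and_score(models[ki], panel, A, y_all,
                               design$training_ids, val_ids, mcmc = mcmc,
                               seed = child_seed(s_seed, 7000L + ki))
          row <- row + 1L
          out[[row]] <- data.frame(
            scheme = "TV", method = method, model = models[ki],
            train_size = n, test_size = length(val_ids), rep = rep_i,
            accuracy = acc,
            fisher_z = if (is.na(acc)) NA_real_ else fisher_z(acc),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out[seq_len(row)])
}

panel_similarity <- function(panel, measure) {
  m <- switch(measure,
              euclidean = euclidean_distance(panel),
              nei = nei_distance(panel),
              jaccard = jaccard_similarity(panel),
              kosman = kosman_leonard_similarity(panel))
  to_similarity(m)
}

#' Admissible training-set sizes for a given test-set size
#'
#' The evaluation menus pair a test set of 40 or 70 with training sizes
#' 25/50/75/100, and a test set of 95 with 30/45/60/75 (so that training
#' plus test never exceeds a 190-line panel).
#'
#' @param test_size test-set size.
#' @return integer vector of training sizes.
#' @export
tt_train_size_menu <- function(test_size) {
  if (test_size >= 95) c(30L, 45L, 60L, 75L) else c(25L, 50L, 75L, 100L)
}

#' Training-test (TT) evaluation scheme
#'
#' For each test-set replicate a test set is drawn uniformly from the panel;
#' the remainder forms the candidate pool. Every method then samples
#' `n_sampling_reps` training sets of each size from the pool, each model is
#' fitted, and the common test set is predicted — so within one test-set
#' replicate all methods, sizes and models predict the identical test set.
#' CDmean uses targeted contrasts (the test individuals). Realization
#' accuracy is the mean over sampling replicates; the returned records keep
#' both replicate indices so either level can be analyzed.
#'
#' @inheritParams run_tv_scheme
#' @param test_size number of held-out test individuals (default 40).
#' @param train_sizes training sizes; defaults to [tt_train_size_menu].
#' @param n_test_sets test-set replicates (default 50).
#' @param n_sampling_reps training-set draws per test set (default 50).
#' @return data.frame of accuracy records with `test_rep` and `samp_rep`.
#' @export
run_tt_scheme <- function(panel, trait,
                          methods = c("SRS", "STRAT", "GD", "CDMEAN"),
                          models = c("GBLUP", "RKHS", "BAYESC"),
                          test_size = 40, train_sizes = NULL,
                          n_test_sets = 50, n_sampling_reps = 50, seed = 1,
                          h2_cdmean = 0.5,
                          mcmc = c(n_iter = 5000, burn_in = 2500),
                          cdmean_control = list(),
                          gd_measure = c("euclidean", "nei", "jaccard",
                                         "kosman")) {
  validate_panel(panel)
  gd_measure <- match.arg(gd_measure)
  y_all <- if (inherits(trait, "trait_set")) trait$values else trait
  ids <- panel_ids(panel)
  N <- length(ids)
  train_sizes <- train_sizes %||% tt_train_size_menu(test_size)
  if (test_size + max(train_sizes) > N) {
    stop(sprintf(paste0("training size %d is not admissible with a test set",
                        " of %d in a panel of %d"),
                 max(train_sizes), test_size, N))
  }
  A <- vanraden_A(panel)
  S <- if ("GD" %in% methods) panel_similarity(panel, gd_measure) else NULL
  out <- list()
  row <- 0L
  for (tr in seq_len(n_test_sets)) {
    t_seed <- child_seed(seed, 500000L + tr)
    test_ids <- local_seed(t_seed, sample_ids(ids, test_size))
    pool <- setdiff(ids, test_ids)
    for (si in seq_along(train_sizes)) {
      n <- train_sizes[si]
      for (mi in seq_along(methods)) {
        method <- methods[mi]
        for (sr in seq_len(n_sampling_reps)) {
          s_seed <- child_seed(t_seed, (si * 1000L + sr) * 10L + mi)
          design <- sample_training(method, pool, n, panel$strata, S, A,
                                    s_seed, h2_cdmean,
                                    target_ids = test_ids,
                                    cdmean_control = cdmean_control)
          for (ki in seq_along(models)) {
            acc <- fit_and_score(models[ki], panel, A, y_all,
                                 design$training_ids, test_ids,
                                 mcmc = mcmc,
                                 seed = child_seed(s_seed, 7000L + ki))
            row <- row + 1L
            out[[row]] <- data.frame(
              scheme = "TT", method = method, model = models[ki],
              train_size = n, test_size = test_size, test_rep = tr,
              samp_rep = sr, accuracy = acc,
              fisher_z = if (is.na(acc)) NA_real_ else fisher_z(acc),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Full-factorial ANOVA of prediction accuracies
#'
#' Aggregates accuracy records to one cell mean per
#' (method, size, model), Fisher-z transforms the cell means, and fits the
#' fixed-effects model `z ~ method * size * model` with size as a numeric
#' covariate and sequential (Type I) sums of squares in the term order
#' method, size, model, method:size, method:model, size:model, three-way.
#' With a complete `a x s x k` grid the degrees of freedom are
#' `(a-1, 1, k-1, a-1, (a-1)(k-1), k-1, (a-1)(k-1))` with
#' `as k - 1 - sum(df)` residual degrees of freedom (e.g. 36 for a
#' 4 x 5 x 3 grid and 24 for 4 x 4 x 3).
#'
#' @param records data.frame with columns `method`, `model`, `train_size`,
#'   `accuracy` (e.g. from [run_tv_scheme] / [run_tt_scheme]).
#' @param type `"I"` (sequential, default) or `"II"`.
#' @return data.frame with columns term, df, SS, MS, F, p; attribute
#'   `"cells"` holds the cell means used.
#' @export
anova_accuracy <- function(records, type = c("I", "II")) {
  type <- match.arg(type)
  need <- c("method", "model", "train_size", "accuracy")
  stopifnot(all(need %in% names(records)))
  records <- records[!is.na(records$accuracy), , drop = FALSE]
  cells <- aggregate(accuracy ~ method + train_size + model, data = records,
                     FUN = mean)
  full <- expand.grid(method = unique(records$method),
                      train_size = unique(records$train_size),
                      model = unique(records$model),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$method, d$train_size, d$model, sep = "|")
  missing_cells <- setdiff(key(full), key(cells))
  if (length(missing_cells)) {
    stop("incomplete method x size x model grid; missing cells: ",
         paste(missing_cells, collapse = ", "))
  }
  cells$z <- fisher_z(cells$accuracy)
  cells$method <- factor(cells$method)
  cells$model <- factor(cells$model)
  cells$size <- as.numeric(cells$train_size)
  fit <- lm(z ~ method * size * model, data = cells)
  if (type == "I") {
    a <- anova(fit)
    tab <- data.frame(term = rownames(a), df = a$Df, SS = a$`Sum Sq`,
                      MS = a$`Mean Sq`, F = a$`F value`, p = a$`Pr(>F)`,
                      stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("car", quietly = TRUE)) {
      stop("type II ANOVA requires the car package")
    }
    a <- car::Anova(fit, type = "II")
    tab <- data.frame(term = rownames(a), df = a$Df, SS = a$`Sum Sq`,
                      MS = a$`Sum Sq` / a$Df, F = a$`F value`,
                      p = a$`Pr(>F)`, stringsAsFactors = FALSE)
  }
  rownames(tab) <- NULL
  attr(tab, "cells") <- cells
  tab
}
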