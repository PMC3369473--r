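# Experiment orchestration: extract -> aggregate -> cross-validate ->
# report, over the 5-variant x 3-classifier x 2-region grid, plus the
# selected-vs-whole-feature comparison.

.CLASSIFIERS <- c("adaboost", "svm", "mlp")

#' Configure an experiment grid
#'
#' @param regions Region kinds to evaluate (`"entire"`, `"middle"`).
#' @param variants Aggregation variants to evaluate (any of `"mean"`,
#'   `"median"`, `"std"`, `"mean_std"`, `"median_std"`).
#' @param classifiers Classifiers to evaluate (any of `"adaboost"`,
#'   `"svm"`, `"mlp"`).
#' @param folds Cross-validation folds.
#' @param seed Seed for fold assignment and classifier initialization.
#' @param middle_fractions Middle-region rectangle fractions, see
#'   [region_spec()].
#' @param adaboost,svm,mlp Named lists of hyperparameter overrides passed
#'   to the respective trainers.
#' @param selection Logical: also run best-first feature selection in
#'   [run_selection_comparison()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(regions = c("entire", "middle"),
                              variants = .AGG_VARIANTS,
                              classifiers = .CLASSIFIERS,
                              folds = 3L, seed = 1L,
                              middle_fractions = c(0.35, 0.65, 0.30, 0.70),
                              adaboost = list(), svm = list(), mlp = list(),
                              selection = TRUE) {
  regions <- match.arg(regions, c("entire", "middle"), several.ok = TRUE)
  variants <- match.arg(variants, .AGG_VARIANTS, several.ok = TRUE)
  classifiers <- match.arg(classifiers, .CLASSIFIERS, several.ok = TRUE)
  structure(list(regions = regions, variants = variants,
                 classifiers = classifiers, folds = as.integer(folds),
                 seed = as.integer(seed), middle_fractions = middle_fractions,
                 adaboost = adaboost, svm = svm, mlp = mlp,
                 selection = isTRUE(selection)),
            class = "experiment_config")
}

.make_trainer <- function(classifier, config) {
  overrides <- config[[classifier]]
  fn <- switch(classifier,
               adaboost = train_adaboost, svm = train_svm, mlp = train_mlp)
  function(x, y) do.call(fn, c(list(x = x, y = y),
                               overrides,
                               if (is.null(overrides$seed)) list(seed = config$seed)))
}

#' Run the full experiment grid on a cohort
#'
#' For every (region, variant) cell, builds the aggregate feature matrix
#' and cross-validates every configured classifier, reporting weighted
#' F-measure and classification accuracy — the shape of the published
#' results tables. Deterministic given the cohort and `config$seed`.
#'
#' @param cohort A `tongue_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; if given, writes `grid.csv` and
#'   `grid.json`.
#' @return An object of class `experiment_grid`: a data frame with columns
#'   `region`, `variant`, `classifier`, `weighted_f`, `ca`, plus the full
#'   `evaluation_report`s in `attr(, "reports")`.
#' @export
run_experiment <- function(cohort, config = experiment_config(),
                           out_dir = NULL) {
  stopifnot(inherits(cohort, "tongue_cohort"),
            inherits(config, "experiment_config"))
  rows <- list()
  reports <- list()
  for (region in config$regions) {
    spec <- region_spec(region, config$middle_fractions)
    for (variant in config$variants) {
      X <- cohort_features(cohort$images, spec, variant)
      for (classifier in config$classifiers) {
        trainer <- .make_trainer(classifier, config)
        rep <- cross_validate(X, cohort$labels, trainer,
                              k = config$folds, seed = config$seed)
        key <- paste(region, variant, classifier, sep = ".")
        reports[[key]] <- rep
        rows[[key]] <- data.frame(region = region, variant = variant,
                                  classifier = classifier,
                                  weighted_f = rep$weighted_f, ca = rep$ca)
      }
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  res <- structure(grid, reports = reports, config = config,
                   class = c("experiment_grid", "data.frame"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(grid, file.path(out_dir, "grid.csv"), row.names = FALSE)
    jsonlite::write_json(grid, file.path(out_dir, "grid.json"),
                         digits = NA, dataframe = "rows")
  }
  res
}

# best cell of a grid: max weighted F, ties toward svm, then mlp, then
# adaboost
.best_cell <- function(grid) {
  pref <- match(grid$classifier, c("svm", "mlp", "adaboost"))
  ord <- order(-grid$weighted_f, pref)
  grid[ord[1], , drop = FALSE]
}

#' Compare selected-feature and whole-feature performance
#'
#' For each (region, variant) cell the best-first-selected feature subset
#' (CFS merit) is used to retrain the grid, and the best (weighted F, CA)
#' cell over the grid is reported with and without selection — the shape of
#' the published selected-vs-whole comparison. With `config$selection =
#' FALSE` the selection pass is skipped and both columns are identical.
#'
#' @inheritParams run_experiment
#' @param stale_limit Best-first search patience, see
#'   [best_first_select()].
#' @return A one-row data frame: best whole-feature `(weighted_f, ca)` and
#'   best selected-feature `(weighted_f_sel, ca_sel)`, with the winning
#'   grid cells as attributes.
#' @export
run_selection_comparison <- function(cohort, config = experiment_config(),
                                     stale_limit = 5L) {
  whole <- run_experiment(cohort, config)
  best_whole <- .best_cell(whole)
  if (!config$selection) {
    best_sel <- best_whole
  } else {
    rows <- list()
    for (region in config$regions) {
      spec <- region_spec(region, config$middle_fractions)
      for (variant in config$variants) {
        X <- cohort_features(cohort$images, spec, variant)
        sel <- best_first_select(X, cohort$labels, stale_limit = stale_limit)
        idx <- if (length(sel$indices) >= 1L) sel$indices else seq_len(ncol(X))
        Xs <- X[, idx, drop = FALSE]
        if (ncol(Xs) < 1L) Xs <- X
        for (classifier in config$classifiers) {
          trainer <- .make_trainer(classifier, config)
          rep <- cross_validate(Xs, cohort$labels, trainer,
                                k = config$folds, seed = config$seed)
          rows[[paste(region, variant, classifier, sep = ".")]] <-
            data.frame(region = region, variant = variant,
                       classifier = classifier,
                       weighted_f = rep$weighted_f, ca = rep$ca)
        }
      }
    }
    best_sel <- .best_cell(do.call(rbind, rows))
  }
  out <- data.frame(weighted_f = best_whole$weighted_f, ca = best_whole$ca,
                    weighted_f_sel = best_sel$weighted_f, ca_sel = best_sel$ca)
  attr(out, "best_whole") <- best_whole
  attr(out, "best_selected") <- best_sel
  out
}
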