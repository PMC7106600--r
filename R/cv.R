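# Cross-validated evaluation of the full pipeline:
# transform fitting -> structure search -> CPT fitting -> risk prediction.
#
# Pipeline hygiene: everything fitted from data (PCA, discretizer edges,
# structure, CPTs) is fitted inside each training fold, never on held-out
# cases. The fixed-structure mode relaxes only the structure step.

#' Declared state sets for the network feature variables
#'
#' States come from the schema, not from observed data, so a training fold
#' missing a rare state still yields a network in which that state is legal
#' (it receives the smoothing prior in its CPT rows).
#'
#' @param schema Schema from [pvq_schema()].
#' @param k Discretization levels of the composites.
#' @return Named list of character state vectors for every feature-level
#'   variable including `sb_group`.
#' @export
feature_states <- function(schema = pvq_schema(), k = 3) {
  c(
    list(
      oq_level = as.character(seq_len(k)),
      oq8 = as.character(0:4),
      rfl_level = as.character(seq_len(k)),
      rfl25 = as.character(1:6),
      deq_quadrant = c("00", "01", "10", "11")
    ),
    schema$demographics,
    list(sb_group = c("with_sb", "without_sb"))
  )
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline so cross-validation is
#' reproducible from one object.
#'
#' @param nodes Feature variables entering the network (default: the five
#'   questionnaire-derived variables plus the eight demographics and
#'   `sb_group`).
#' @param k Discretization levels for the OQ/RFL composites (default 3).
#' @param algorithm `"tabu"` (default) or `"hill_climbing"`.
#' @param score A `pvq_score_spec` (default BIC).
#' @param constraints A `pvq_constraints` or `NULL`.
#' @param ess Equivalent sample size of the CPT Dirichlet prior.
#' @param threshold Classification threshold on the posterior.
#' @param structure_mode `"per_fold"` (honest: structure re-learned inside
#'   every fold; default) or `"fixed"` (structure learned once on the full
#'   cohort, only CPTs refitted per fold).
#' @param schema Questionnaire schema.
#' @param tabu_length,max_iter,max_tabu_escapes Search controls.
#' @return An object of class `pvq_config`.
#' @export
pipeline_config <- function(nodes = NULL, k = 3, algorithm = "tabu",
                            score = score_spec(), constraints = NULL,
                            ess = 1, threshold = 0.5,
                            structure_mode = c("per_fold", "fixed"),
                            schema = pvq_schema(),
                            tabu_length = 10L, max_iter = 200L,
                            max_tabu_escapes = 10L) {
  structure_mode <- match.arg(structure_mode)
  states <- feature_states(schema, k)
  if (is.null(nodes)) nodes <- names(states)
  bad <- setdiff(nodes, names(states))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown feature node(s): ", paste(bad, collapse = ", ")),
                 class = "pvq_config_error")
  }
  if (!"sb_group" %in% nodes) nodes <- c(nodes, "sb_group")
  search_algorithm(algorithm)  # errors early on unsupported names
  structure(list(nodes = nodes, states = states[nodes], k = k,
                 algorithm = algorithm, score = score,
                 constraints = constraints, ess = ess, threshold = threshold,
                 structure_mode = structure_mode, schema = schema,
                 tabu_length = tabu_length, max_iter = max_iter,
                 max_tabu_escapes = max_tabu_escapes),
            class = "pvq_config")
}

#' Fit the full pipeline on a training cohort
#'
#' Fits the feature transforms, runs the constrained structure search and
#' estimates the CPTs, all on the supplied records only.
#'
#' @param train Validated cohort tibble.
#' @param config A `pvq_config`.
#' @param fixed_dag Optional `pvq_dag` that short-circuits the structure
#'   search (used by the fixed-structure cross-validation mode).
#' @return A list with `transforms` (`pvq_transforms`), `dag` (`pvq_dag`)
#'   and `bn` (fitted `pvq_bn`).
#' @export
fit_pipeline <- function(train, config, fixed_dag = NULL) {
  transforms <- fit_feature_transforms(train, k = config$k)
  ft <- build_feature_table(train, transforms)
  fdata <- ft[, config$nodes]
  fdata[] <- lapply(fdata, as.character)
  enc <- encode_discrete(fdata, config$states)
  dag <- fixed_dag %||% run_search(enc, config)
  bn <- fit_cpts(dag, enc, ess = config$ess)
  list(transforms = transforms, dag = dag, bn = bn)
}

run_search <- function(enc, config) {
  if (config$algorithm == "tabu") {
    tabu_search(enc, config$states, config$constraints, config$score,
                tabu_length = config$tabu_length, max_iter = config$max_iter,
                max_tabu_escapes = config$max_tabu_escapes)
  } else {
    search_algorithm(config$algorithm)(enc, config$states, config$constraints,
                                       config$score, max_iter = config$max_iter)
  }
}

#' Predict held-out records with a fitted pipeline
#'
#' @param fitted Result of [fit_pipeline()].
#' @param newdata Cohort tibble of records to score.
#' @param config The `pvq_config` used to fit.
#' @return A tibble with one row per record: `patient_id`, `truth`,
#'   `probability`, `predicted`.
#' @export
predict_pipeline <- function(fitted, newdata, config) {
  ft <- build_feature_table(newdata, fitted$transforms)
  ev_nodes <- setdiff(config$nodes, "sb_group")
  out <- vector("list", nrow(ft))
  for (i in seq_len(nrow(ft))) {
    ev <- vapply(ev_nodes, function(v) as.character(ft[[v]][i]), character(1))
    pr <- predict_risk(fitted$bn, stats::setNames(ev, ev_nodes),
                       threshold = config$threshold)
    out[[i]] <- tibble::tibble(patient_id = ft$patient_id[i],
                               truth = ft$sb_group[i],
                               probability = pr$probability,
                               predicted = pr$predicted)
  }
  dplyr::bind_rows(out)
}

#' Leave-one-out cross-validation of the pipeline
#'
#' For each case i the transforms (PCA, discretizers), the network
#' structure (unless `structure_mode = "fixed"`) and the CPTs are fitted on
#' the other N-1 cases and case i is predicted; all N predictions are
#' aggregated into one confusion matrix. Deterministic given the
#' configuration.
#'
#' @param cohort Validated cohort tibble (>= 10 cases, both groups present).
#' @param config A `pvq_config`.
#' @return A list of class `pvq_cv`: `metrics` (one-row tibble),
#'   `predictions` (per-case tibble), `confusion`.
#' @export
loocv <- function(cohort, config = pipeline_config()) {
  cohort <- tibble::as_tibble(cohort)
  n <- nrow(cohort)
  if (n < 10) rlang::abort("need at least 10 cases", class = "pvq_cv_error")
  groups <- derive_sb_group(cohort$sb_status)
  if (length(unique(groups)) < 2) {
    rlang::abort("cohort must contain both groups", class = "pvq_cv_error")
  }
  fixed_dag <- NULL
  if (config$structure_mode == "fixed") {
    fixed_dag <- fit_pipeline(cohort, config)$dag
  }
  preds <- vector("list", n)
  for (i in seq_len(n)) {
    train <- cohort[-i, ]
    if (length(unique(groups[-i])) < 2) {
      rlang::abort(sprintf("training fold for case %d has a single class", i),
                   class = "pvq_cv_error")
    }
    fitted <- fit_pipeline(train, config, fixed_dag = fixed_dag)
    preds[[i]] <- predict_pipeline(fitted, cohort[i, ], config)
  }
  preds <- dplyr::bind_rows(preds)
  cm <- confusion_matrix(preds$truth, preds$predicted)
  structure(list(metrics = metrics(cm), predictions = preds, confusion = cm,
                 scheme = "loocv"),
            class = "pvq_cv")
}

#' Repeated stratified k-fold cross-validation
#'
#' Fold assignment is stratified by group and drawn from a seeded
#' generator, so the full accuracy distribution is reproducible. Per-repeat
#' accuracy is pooled over the k folds: (tp + tn) / N.
#'
#' @param cohort Validated cohort tibble.
#' @param k Number of folds (default 10).
#' @param repeats Number of repetitions (default 100).
#' @param seed Integer seed for the fold generator.
#' @param config A `pvq_config`.
#' @return A list of class `pvq_cv_repeated`: `per_repeat` (tibble with
#'   accuracy and balanced accuracy per repeat), `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
repeated_kfold <- function(cohort, k = 10, repeats = 100, seed = 1,
                           config = pipeline_config()) {
  cohort <- tibble::as_tibble(cohort)
  n <- nrow(cohort)
  if (k > n) rlang::abort("k exceeds the number of cases", class = "pvq_cv_error")
  groups <- derive_sb_group(cohort$sb_status)
  set.seed(as.integer(seed))
  fixed_dag <- NULL
  if (config$structure_mode == "fixed") {
    fixed_dag <- fit_pipeline(cohort, config)$dag
  }
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(groups, k)
    preds <- vector("list", k)
    for (f in seq_len(k)) {
      test_idx <- which(fold == f)
      fitted <- fit_pipeline(cohort[-test_idx, ], config, fixed_dag = fixed_dag)
      preds[[f]] <- predict_pipeline(fitted, cohort[test_idx, ], config)
    }
    preds <- dplyr::bind_rows(preds)
    cm <- confusion_matrix(preds$truth, preds$predicted)
    m <- metrics(cm)
    rows[[r]] <- tibble::tibble(repeat_id = r, accuracy = m$accuracy,
                                balanced_accuracy = m$balanced_accuracy)
  }
  per_repeat <- dplyr::bind_rows(rows)
  structure(list(per_repeat = per_repeat,
                 mean_accuracy = mean(per_repeat$accuracy),
                 sd_accuracy = stats::sd(per_repeat$accuracy),
                 k = k, repeats = repeats, seed = seed),
            class = "pvq_cv_repeated")
}

# Stratified fold labels: within each group, a random permutation is dealt
# round-robin into k folds.
stratified_folds <- function(groups, k) {
  fold <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Compare structure-search algorithms by cross-validated error
#'
#' Runs [repeated_kfold()] once per supported algorithm with a shared fold
#' assignment (same seed) and ranks algorithms by mean classification
#' error, ties broken by error variance. Unsupported algorithm names are
#' reported in the result, never silently skipped.
#'
#' @param cohort Validated cohort tibble.
#' @param algorithms Character vector of algorithm names.
#' @param config A `pvq_config` (its `algorithm` field is overridden).
#' @param k,repeats,seed Cross-validation controls.
#' @return A tibble with one row per requested algorithm: `algorithm`,
#'   `supported`, `mean_error`, `error_variance`, `rank` (NA for
#'   unsupported names).
#' @export
select_algorithm <- function(cohort, algorithms, config = pipeline_config(),
                             k = 10, repeats = 10, seed = 1) {
  supported <- vapply(algorithms, function(a) {
    tryCatch({ search_algorithm(a); TRUE },
             pvq_unsupported_algorithm = function(e) FALSE)
  }, logical(1))
  if (!any(supported)) {
    rlang::abort("no supported algorithm in the list",
                 class = "pvq_unsupported_algorithm")
  }
  rows <- lapply(seq_along(algorithms), function(i) {
    a <- algorithms[i]
    if (!supported[i]) {
      return(tibble::tibble(algorithm = a, supported = FALSE,
                            mean_error = NA_real_, error_variance = NA_real_))
    }
    cfg <- config
    cfg$algorithm <- a
    res <- repeated_kfold(cohort, k = k, repeats = repeats, seed = seed,
                          config = cfg)
    err <- 1 - res$per_repeat$accuracy
    tibble::tibble(algorithm = a, supported = TRUE,
                   mean_error = mean(err), error_variance = stats::var(err))
  })
  out <- dplyr::bind_rows(rows)
  ranked <- order(out$mean_error, out$error_variance)
  out$rank <- NA_integer_
  out$rank[ranked[seq_len(sum(supported))]] <-
    seq_len(sum(supported))
  out[order(is.na(out$rank), out$rank), ]
}

#' @export
print.pvq_cv <- function(x, ...) {
  cat("Cross-validated pipeline evaluation (", x$scheme, ")\n", sep = "")
  print(as.data.frame(round(x$metrics, 4)))
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x A `pvq_cv`.
#' @param ... Unused.
#' @return The per-case prediction tibble.
#' @export
tidy.pvq_cv <- function(x, ...) x$predictions

#' One-row summary of a cross-validation result
#'
#' @param x A `pvq_cv`.
#' @param ... Unused.
#' @return The metric tibble.
#' @export
glance.pvq_cv <- function(x, ...) x$metrics
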