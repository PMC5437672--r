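#' Experiment configuration
#'
#' Bundles the cohort, discovery, consensus and classifier settings for
#' the two end-to-end experiments: all-comers with a training/holdout
#' split, and receptor-group-specific cross-validation (with majority
#' downsampling for the heavily imbalanced HR+HER2- group).
#'
#' Cohort sizes default to the study composition: 24/54 pCR/non-pCR in
#' training plus 12/27 held out for the all-comers experiment; 10/60
#' for HR+HER2-; 26/21 for TN/HER2+.
#'
#' @param experiment one of `"all_comers"`, `"HR+HER2-"`, `"TN/HER2+"`.
#' @param n_pcr_train,n_non_pcr_train,n_pcr_test,n_non_pcr_test cohort
#'   sizes (test sizes ignored outside `all_comers`).
#' @param phantom template [phantom_config()].
#' @param discovery a [discovery_config()]; for `"HR+HER2-"` the
#'   majority class is downsampled to 20 per iteration by default.
#' @param consensus a [consensus_config()].
#' @param classifiers classifier kinds to evaluate.
#' @param cv_repeats,cv_folds classifier cross-validation scheme.
#' @param max_prefix deepest sequential feature prefix.
#' @param seed master seed; every stage derives its own stream from it.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("all_comers", "HR+HER2-",
                                             "TN/HER2+"),
                              n_pcr_train = NULL, n_non_pcr_train = NULL,
                              n_pcr_test = 12, n_non_pcr_test = 27,
                              phantom = phantom_config(),
                              discovery = NULL,
                              consensus = consensus_config(),
                              classifiers = classifier_kinds(),
                              cv_repeats = 50, cv_folds = 3,
                              max_prefix = 10,
                              seed = 1L) {
  experiment <- match.arg(experiment)
  defaults <- switch(experiment,
                     all_comers = c(24, 54),
                     `HR+HER2-` = c(10, 60),
                     `TN/HER2+` = c(26, 21))
  if (is.null(n_pcr_train)) n_pcr_train <- defaults[1]
  if (is.null(n_non_pcr_train)) n_non_pcr_train <- defaults[2]
  if (is.null(discovery)) {
    discovery <- discovery_config(
      downsample_majority_to = if (experiment == "HR+HER2-") 20 else NULL
    )
  }
  structure(list(experiment = experiment,
                 n_pcr_train = n_pcr_train,
                 n_non_pcr_train = n_non_pcr_train,
                 n_pcr_test = n_pcr_test, n_non_pcr_test = n_non_pcr_test,
                 phantom = phantom, discovery = discovery,
                 consensus = consensus, classifiers = classifiers,
                 cv_repeats = cv_repeats, cv_folds = cv_folds,
                 max_prefix = max_prefix, seed = as.integer(seed)),
            class = "experiment_config")
}

# Column subsets for the four consensus feature sets of experiment 1.
region_feature_sets <- function(ids) {
  list(
    combined = which(ids$family != "PK"),
    intratumoral = which(ids$region == "intratumoral"),
    peritumoral = which(ids$region == "peritumoral"),
    pk = which(ids$family == "PK")
  )
}

#' All-comers experiment: discovery, clustering, CV and holdout
#'
#' Generates a synthetic training cohort and an independent holdout
#' cohort, extracts and normalizes features (holdout scaled by frozen
#' training statistics), discovers top features on the training set
#' only, runs consensus clustering on the training set for the
#' combined, intratumoral-only, peritumoral-only and PK feature sets,
#' cross-validates the classifiers on the training set, and evaluates
#' the holdout with sequential top-1..k feature inclusion.  An audit
#' record proves that holdout patients never enter normalization,
#' discovery or training.
#'
#' @param config an [experiment_config()] with
#'   `experiment = "all_comers"`.
#' @param features optional precomputed list with `train` and `test`
#'   raw (unnormalized) `feature_table`s, to reuse extractions.
#' @return report bundle: list with `features`, `discovery` (per
#'   feature set), `consensus` (four `consensus_matrix` objects plus
#'   per-class accuracies), `cv`, `holdout`, and `audit`.
#' @export
run_experiment1 <- function(config = experiment_config("all_comers"),
                            features = NULL) {
  stopifnot(config$experiment == "all_comers")
  if (is.null(features)) {
    train_cohort <- generate_cohort(
      cohort_spec(config$n_pcr_train, config$n_non_pcr_train,
                  seed = config$seed),
      config$phantom
    )
    test_cohort <- generate_cohort(
      cohort_spec(config$n_pcr_test, config$n_non_pcr_test,
                  seed = config$seed + 100000L),
      config$phantom
    )
    for (i in seq_along(test_cohort)) {
      test_cohort[[i]]$patient_id <- paste0("holdout_",
                                            test_cohort[[i]]$patient_id)
    }
    features <- list(train = build_feature_table(train_cohort),
                     test = build_feature_table(test_cohort))
  }
  train_raw <- features$train
  test_raw <- features$test
  stopifnot(!any(train_raw$meta$patient_id %in% test_raw$meta$patient_id))
  train <- normalize_features(train_raw)
  test <- normalize_features(test_raw, reference = train_raw)
  ids <- train$ids
  sets <- region_feature_sets(ids)
  y_train <- train$meta$label
  y_test <- test$meta$label

  # discovery per feature set (training patients only); the PK set is
  # used whole (15 features)
  disc_cfg <- config$discovery
  discovery <- list()
  for (s in c("combined", "intratumoral", "peritumoral")) {
    cfg_s <- disc_cfg
    cfg_s$seed <- disc_cfg$seed + match(s, names(sets))
    discovery[[s]] <- discovery_protocol(
      train$values[, sets[[s]], drop = FALSE], y_train, cfg_s
    )
  }

  consensus <- list()
  cons_sets <- list(
    combined = discovery$combined$top_features,
    intratumoral = discovery$intratumoral$top_features,
    peritumoral = discovery$peritumoral$top_features,
    pk = ids$name[sets$pk]
  )
  for (s in names(cons_sets)) {
    cfg_c <- config$consensus
    cfg_c$seed <- config$consensus$seed + match(s, names(cons_sets))
    cm <- consensus_cluster(train$values[, cons_sets[[s]], drop = FALSE],
                            cfg_c)
    consensus[[s]] <- list(
      matrix = cm,
      accuracy = cluster_label_accuracy(cm$final_assignment, y_train)
    )
  }

  top <- discovery$combined$top_features
  cv <- do.call(rbind, lapply(config$classifiers, function(kind) {
    sequential_feature_eval(train$values, y_train, top, kind, mode = "cv",
                            max_prefix = config$max_prefix,
                            n_repeats = config$cv_repeats,
                            n_folds = config$cv_folds,
                            seed = config$seed + 7L)
  }))
  holdout <- do.call(rbind, lapply(config$classifiers, function(kind) {
    sequential_feature_eval(train$values, y_train, top, kind,
                            mode = "holdout", test_x = test$values,
                            test_labels = y_test,
                            max_prefix = config$max_prefix)
  }))

  audit <- list(
    train_ids = train$meta$patient_id,
    test_ids = test$meta$patient_id,
    disjoint = !any(train$meta$patient_id %in% test$meta$patient_id),
    normalization_reference = "train",
    normalization_params_from = nrow(train_raw$values),
    discovery_n_patients = nrow(train$values),
    holdout_used_for = "evaluation only"
  )
  list(features = list(train = train, test = test),
       discovery = discovery, consensus = consensus,
       cv = cv, holdout = holdout, audit = audit, config = config)
}

#' Receptor-group experiment: downsampled discovery plus CV
#'
#' Generates the receptor-group cohort, runs group-restricted feature
#' discovery (downsampling the majority class to 20 per iteration for
#' the imbalanced HR+HER2- group, none for TN/HER2+), and evaluates all
#' classifiers over the top-1..k feature prefixes with repeated
#' stratified cross-validation.  Discovery and evaluation share the
#' patient pool (there is no holdout), which makes the resulting CV
#' estimates optimistic; the bundle records this.
#'
#' @param config an [experiment_config()] with a receptor-group
#'   `experiment`.
#' @param features optional precomputed raw `feature_table` for the
#'   group.
#' @return report bundle: list with `features`, `discovery`, `cv` and
#'   `notes`.
#' @export
run_experiment2 <- function(config, features = NULL) {
  stopifnot(config$experiment %in% c("HR+HER2-", "TN/HER2+"))
  grp <- if (config$experiment == "HR+HER2-") "HR+HER2-" else "TN/HER2+"
  if (is.null(features)) {
    cohort <- generate_cohort(
      cohort_spec(config$n_pcr_train, config$n_non_pcr_train, group = grp,
                  seed = config$seed),
      config$phantom
    )
    features <- build_feature_table(cohort)
  }
  if (nrow(features$values) < 6L) stop("group too small (< 6 patients)")
  tab <- normalize_features(features)
  y <- tab$meta$label
  disc <- discovery_protocol(tab$values, y, config$discovery)
  cv <- do.call(rbind, lapply(config$classifiers, function(kind) {
    sequential_feature_eval(tab$values, y, disc$top_features, kind,
                            mode = "cv", max_prefix = config$max_prefix,
                            n_repeats = config$cv_repeats,
                            n_folds = config$cv_folds,
                            seed = config$seed + 7L)
  }))
  list(features = tab, discovery = disc, cv = cv,
       notes = paste("discovery and evaluation share the patient pool;",
                     "CV estimates are optimistic"),
       config = config)
}

#' Leakage audit of an experiment-1 bundle
#'
#' Asserts that holdout patients are disjoint from the training set and
#' that normalization was referenced to training statistics only.
#'
#' @param bundle output of [run_experiment1()].
#' @return `TRUE` invisibly; stops on a violated guarantee.
#' @export
audit_leakage <- function(bundle) {
  a <- bundle$audit
  if (!a$disjoint) stop("holdout and training patients overlap")
  if (a$normalization_reference != "train") {
    stop("holdout statistics leaked into normalization")
  }
  if (a$normalization_params_from != length(a$train_ids)) {
    stop("normalization reference size mismatch")
  }
  invisible(TRUE)
}
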