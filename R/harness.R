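#' Nested cross-validation plan with permutations
#'
#' Mirrors a sevenfold nested design: per permutation the cohort is split
#' into `folds` disjoint, exhaustive, diagnosis-stratified test folds; the
#' remaining subjects of each fold are split into training and validation
#' sets at the requested proportions (validation is used for model selection
#' only). Assignments are deterministic in the master seed.
#'
#' @param diagnoses Named character vector (subject id -> class).
#' @param folds Number of outer folds (default 7).
#' @param proportions Length-3 train/val/test proportions (default mirrors a
#'   100/20/20 split).
#' @param n_permutations Number of independent permutations.
#' @param seed Master seed.
#' @return A `cv_plan`.
#' @export
make_cv_plan <- function(diagnoses, folds = 7,
                         proportions = c(100, 20, 20) / 140,
                         n_permutations = 5, seed = 1) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8, all(proportions > 0))
  ids <- names(diagnoses)
  classes <- unique(diagnoses)
  if (length(classes) != 2) stop("make_cv_plan expects exactly two classes")
  if (min(table(diagnoses)) < folds)
    stop("class too small to stratify over ", folds, " folds")
  val_frac <- proportions[2] / (proportions[1] + proportions[2])
  perms <- lapply(seq_len(n_permutations), function(p) {
    with_seed(derive_seed(seed, p), {
      fold_of <- stats::setNames(rep(NA_integer_, length(ids)), ids)
      counts <- rep(0L, folds)
      # stratified, size-balanced assignment: each subject goes to the
      # currently smallest fold, cycling within class, so fold sizes differ
      # by at most one overall (e.g. 140 subjects -> 7 folds of 20)
      for (cl in classes) {
        members <- sample(ids[diagnoses == cl])
        for (m in members) {
          f <- which.min(counts)
          fold_of[m] <- f
          counts[f] <- counts[f] + 1L
        }
      }
      lapply(seq_len(folds), function(f) {
        test <- ids[fold_of == f]
        rest <- ids[fold_of != f]
        val <- unlist(lapply(classes, function(cl) {
          m <- sample(rest[diagnoses[rest] == cl])
          m[seq_len(max(1, round(length(m) * val_frac)))]
        }))
        train <- setdiff(rest, val)
        if (length(unique(diagnoses[train])) < 2 ||
            length(unique(diagnoses[test])) < 2)
          stop("stratification failed: single-class split")
        list(train = train, val = val, test = test)
      })
    })
  })
  structure(list(folds = folds, n_permutations = n_permutations,
                 proportions = proportions, seed = seed,
                 assignments = perms, diagnoses = diagnoses),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  sz <- lengths(x$assignments[[1]][[1]])
  cat("<cv_plan>", x$n_permutations, "permutations x", x$folds,
      "folds; split sizes", paste(sz, collapse = "/"), "\n")
  invisible(x)
}

plan_splits <- function(plan) {
  out <- list()
  for (p in seq_len(plan$n_permutations))
    for (f in seq_len(plan$folds))
      out[[length(out) + 1]] <- c(plan$assignments[[p]][[f]],
                                  list(perm = p, fold = f))
  out
}

# Precompute per-level feature tables once (features depend only on the
# subject and the label source, not on the split).
precompute_feature_tables <- function(cohort, series) {
  lapply(stats::setNames(nm = level_sources(series)), function(src)
    feature_table(cohort, series_masks(series, src)))
}

# Radiomics arm for one split: ICC screen on the training subjects across
# all perturbed levels (a feature survives only if it passes every pairing
# with the reference), then RFE-logistic on the reference-label features.
fit_radiomics_arm <- function(tables, diagnoses, split, n_final = 10,
                              lambda = 0.1) {
  ref_src <- names(tables)[1]
  train <- split$train
  screen_in <- lapply(tables, function(tb) tb[train, , drop = FALSE])
  scr <- icc_screen(screen_in)
  kept <- scr$kept_names
  if (length(kept) < 2) {
    # degenerate screen: fall back to the most label-stable features so the
    # arm stays defined; flagged on the returned object
    ord <- order(scr$min_icc, decreasing = TRUE, na.last = TRUE)
    kept <- rownames(scr$icc_values)[ord][seq_len(min(5,
                                                      nrow(scr$icc_values)))]
  }
  X <- tables[[ref_src]][train, kept, drop = FALSE]
  model <- rfe_train(X, diagnoses[train], n_final = min(n_final, ncol(X)),
                     lambda = lambda)
  list(model = model, screen = scr)
}

#' Population-level classification stability experiment
#'
#' Per permutation and fold, a model is trained on the reference labels and
#' tested once per Dice level of the label series; metric panels are
#' aggregated per level over all test splits — models trained on the
#' reference labeling, tested under gradually deviating labels.
#'
#' @param cohort An `sn_cohort`.
#' @param series A `label_series` (reference level included).
#' @param model_kind `"radiomics-lr"` or `"pdnet-masked"`.
#' @param plan A `cv_plan`.
#' @param cfg For the CNN arm, a [pdnet_train_cfg()]; for the radiomics arm
#'   a list with optional `n_final`, `lambda`.
#' @return List with `predictions` (a `prediction_table`), `per_split`
#'   (per level x split metric panels), and `summary` (per-level mean/sd).
#' @export
run_population_stability <- function(cohort, series,
                                     model_kind = c("radiomics-lr",
                                                    "pdnet-masked"),
                                     plan, cfg = NULL) {
  model_kind <- match.arg(model_kind)
  dx <- cohort_diagnoses(cohort)
  sources <- level_sources(series)
  splits <- plan_splits(plan)
  preds <- list()
  if (model_kind == "radiomics-lr") {
    cfg <- cfg %||% list()
    tables <- precompute_feature_tables(cohort, series)
    for (sp in splits) {
      arm <- fit_radiomics_arm(tables, dx, sp,
                               n_final = cfg$n_final %||% 10,
                               lambda = cfg$lambda %||% 0.1)
      for (src in sources) {
        sc <- predict_scores(arm$model, tables[[src]][sp$test, , drop = FALSE])
        preds[[length(preds) + 1]] <- data.frame(
          subject_id = sp$test, label_source = src,
          true_class = unname(dx[sp$test]),
          predicted_class = ifelse(sc >= 0.5, "PD", "HC"), score = sc,
          perm = sp$perm, fold = sp$fold, stringsAsFactors = FALSE)
      }
    }
  } else {
    cfg <- cfg %||% pdnet_train_cfg()
    ref_masks <- series_masks(series, sources[1])
    # ROI tensors depend only on (subject, level); cache across splits
    inputs_by_src <- lapply(stats::setNames(nm = sources), function(src)
      prepare_inputs(cohort, series_masks(series, src), cfg, "masked"))
    for (sp in splits) {
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(cfg$seed, sp$perm * 100 + sp$fold)
      model <- train_classifier(cohort, ref_masks, "masked",
                                split = sp, cfg = cfg_i)
      for (src in sources) {
        pr <- predict(model, cohort, ids = sp$test,
                      inputs = inputs_by_src[[src]])
        pr$label_source <- src
        pr$perm <- sp$perm
        pr$fold <- sp$fold
        preds[[length(preds) + 1]] <- pr
      }
    }
  }
  predictions <- do.call(rbind, preds)
  class(predictions) <- c("prediction_table", class(predictions))
  per_split <- do.call(rbind, lapply(sources, function(src) {
    sub <- predictions[predictions$label_source == src, ]
    do.call(rbind, lapply(split(sub, list(sub$perm, sub$fold)), function(s) {
      data.frame(label_source = src, perm = s$perm[1], fold = s$fold[1],
                 t(classification_panel(s)))
    }))
  }))
  rownames(per_split) <- NULL
  summary <- do.call(rbind, lapply(sources, function(src) {
    m <- per_split[per_split$label_source == src,
                   c("accuracy", "auc", "bac", "sensitivity", "specificity")]
    data.frame(label_source = src,
               metric = colnames(m), mean = colMeans(m),
               sd = apply(m, 2, stats::sd), row.names = NULL)
  }))
  list(model_kind = model_kind, predictions = predictions,
       per_split = per_split, summary = summary)
}

# Helper: pooled CCI matrix over (perm, fold, subject) prediction instances.
cci_matrix <- function(predictions, sources) {
  key <- function(df) paste(df$perm, df$fold, df$subject_id, sep = "|")
  M <- matrix(1, length(sources), length(sources),
              dimnames = list(sources, sources))
  for (i in seq_along(sources)) for (j in seq_along(sources)) {
    if (i == j) next
    a <- predictions[predictions$label_source == sources[i], ]
    b <- predictions[predictions$label_source == sources[j], ]
    a$subject_id <- key(a)
    b$subject_id <- key(b)
    M[i, j] <- cci(a, b)
  }
  M
}

#' Intrasubject classification-consistency (CCI) experiment
#'
#' Trains the masked-input and gated-pooling classifiers on the reference
#' labels per split, tests every label level, pools the test predictions
#' across permutations and folds, and computes the pairwise CCI matrix per
#' model for every pair of label sources.
#'
#' @param cohort,series,plan As in [run_population_stability()].
#' @param cfg A [pdnet_train_cfg()].
#' @return List with per-model `predictions`, `cci` matrices, and the mean
#'   off-diagonal CCI per model.
#' @export
run_cci_experiment <- function(cohort, series, plan, cfg = pdnet_train_cfg()) {
  dx <- cohort_diagnoses(cohort)
  sources <- level_sources(series)
  ref_masks <- series_masks(series, sources[1])
  splits <- plan_splits(plan)
  inputs <- list(
    masked = lapply(stats::setNames(nm = sources), function(src)
      prepare_inputs(cohort, series_masks(series, src), cfg, "masked")),
    gated = lapply(stats::setNames(nm = sources), function(src)
      prepare_inputs(cohort, series_masks(series, src), cfg, "gated")))
  out <- list()
  for (mode in c("masked", "gated")) {
    preds <- list()
    for (sp in splits) {
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(cfg$seed, sp$perm * 100 + sp$fold)
      model <- train_classifier(cohort, ref_masks, mode, split = sp,
                                cfg = cfg_i)
      for (src in sources) {
        pr <- predict(model, cohort, ids = sp$test,
                      inputs = inputs[[mode]][[src]])
        pr$label_source <- src
        pr$perm <- sp$perm
        pr$fold <- sp$fold
        preds[[length(preds) + 1]] <- pr
      }
    }
    predictions <- do.call(rbind, preds)
    M <- cci_matrix(predictions, sources)
    out[[mode]] <- list(predictions = predictions, cci = M,
                        mean_offdiag = mean(M[upper.tri(M) | lower.tri(M)]))
  }
  out
}

#' Four-configuration joint-model comparison
#'
#' Evaluates, on byte-identical test splits: (1) the gated classifier
#' trained and tested on reference labels; (2) the same trained model tested
#' on automatic (SN2) labels; (3) the gated classifier trained and tested on
#' automatic labels; (4) the joint end-to-end model, which needs no
#' test-time labels. Paired matched-samples t-tests on per-split accuracy
#' with Bonferroni correction compare the designated configuration pairs.
#'
#' @param cohort An `sn_cohort`.
#' @param series A `label_series` (its reference level supplies training
#'   labels).
#' @param plan A `cv_plan`.
#' @param cfg A [pdnet_train_cfg()] for the gated classifiers.
#' @param sn2_cfg An [sn2_config()] for the segmentation/joint branches.
#' @param sn2_epochs,joint_epochs,joint_warmup,lr_seg Optimization knobs.
#' @return List with `per_split` accuracy/AUC per configuration, `summary`,
#'   paired `tests`, and the mean automatic-label Dice.
#' @export
run_joint_comparison <- function(cohort, series, plan,
                                 cfg = pdnet_train_cfg(),
                                 sn2_cfg = sn2_config(),
                                 sn2_epochs = 10, joint_epochs = 8,
                                 joint_warmup = 3, lr_seg = 2e-3) {
  dx <- cohort_diagnoses(cohort)
  ref_masks <- series_masks(series, level_sources(series)[1])
  splits <- plan_splits(plan)
  rows <- list()
  auto_dice <- c()
  config_names <- c("ref_ref", "ref_auto", "auto_auto", "joint_none")
  grid_dim <- dim(cohort$subjects[[1]]$volume$values)
  for (sp in splits) {
    seed_i <- derive_seed(cfg$seed, sp$perm * 100 + sp$fold)
    cfg_i <- cfg
    cfg_i$seed <- seed_i
    # all four configurations share one population ROI box per fold so they
    # see byte-identical input volumes; only labels / gates differ
    cfg_i$box <- population_box(ref_masks[sp$train], cfg$margin, grid_dim)
    # automatic labeling: SN2 trained on the reference labels of this split
    sn2 <- train_sn2(cohort, ref_masks, split = sp, cfg = sn2_cfg,
                     epochs = sn2_epochs, lr = lr_seg, seed = seed_i)
    auto_masks <- lapply(cohort$subjects, function(s)
      sn2_segment(sn2, s$volume)$mask)
    auto_dice <- c(auto_dice, mean(vapply(sp$test, function(id)
      dice_coefficient(auto_masks[[id]], ref_masks[[id]]), numeric(1))))
    m_ref <- train_classifier(cohort, ref_masks, "gated", split = sp,
                              cfg = cfg_i)
    m_auto <- train_classifier(cohort, auto_masks, "gated", split = sp,
                               cfg = cfg_i)
    m_joint <- train_joint(cohort, ref_masks, split = sp, cfg = sn2_cfg,
                           extractor = cfg$extractor, epochs = joint_epochs,
                           warmup_epochs = joint_warmup, lr = lr_seg,
                           head_hidden = cfg$head_hidden, seed = seed_i,
                           init = list(sn2 = sn2, classifier = m_ref))
    pred_sets <- list(
      ref_ref = predict(m_ref, cohort, ref_masks, ids = sp$test),
      ref_auto = predict(m_ref, cohort, auto_masks, ids = sp$test),
      auto_auto = predict(m_auto, cohort, auto_masks, ids = sp$test),
      joint_none = predict(m_joint, cohort, ids = sp$test))
    for (cn in config_names) {
      pan <- classification_panel(pred_sets[[cn]])
      rows[[length(rows) + 1]] <- data.frame(config = cn, perm = sp$perm,
                                             fold = sp$fold, t(pan))
    }
  }
  per_split <- do.call(rbind, rows)
  rownames(per_split) <- NULL
  summary <- do.call(rbind, lapply(config_names, function(cn) {
    m <- per_split[per_split$config == cn,
                   c("accuracy", "auc", "bac", "sensitivity", "specificity")]
    data.frame(config = cn, metric = colnames(m), mean = colMeans(m),
               sd = apply(m, 2, stats::sd), row.names = NULL)
  }))
  acc <- function(cn) per_split$accuracy[per_split$config == cn]
  comparisons <- list(ref_ref_vs_ref_auto = c("ref_ref", "ref_auto"),
                      joint_vs_ref_auto = c("joint_none", "ref_auto"),
                      auto_auto_vs_ref_ref = c("auto_auto", "ref_ref"),
                      joint_vs_ref_ref = c("joint_none", "ref_ref"))
  tests <- lapply(comparisons, function(pair)
    paired_comparison(acc(pair[1]), acc(pair[2]),
                      n_comparisons = length(comparisons)))
  list(per_split = per_split, summary = summary, tests = tests,
       auto_dice_mean = mean(auto_dice))
}

#' Write stability reports to CSV and JSON files
#'
#' @param report Output of one of the `run_*` experiment functions.
#' @param out_dir Output directory.
#' @param name File-name stem.
#' @return Vector of written paths, invisibly.
#' @export
render_reports <- function(report, out_dir, name = "report") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  wr <- function(df, suffix) {
    p <- file.path(out_dir, paste0(name, "_", suffix, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(report$summary)) wr(report$summary, "summary")
  if (!is.null(report$per_split)) wr(report$per_split, "per_split")
  for (mode in intersect(names(report), c("masked", "gated")))
    wr(as.data.frame(report[[mode]]$cci), paste0("cci_", mode))
  jp <- file.path(out_dir, paste0(name, ".json"))
  drop_heavy <- function(x) {
    if (is.list(x)) lapply(x[setdiff(names(x), "predictions")], drop_heavy)
    else x
  }
  jsonlite::write_json(drop_heavy(report), jp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(paths, jp))
}
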