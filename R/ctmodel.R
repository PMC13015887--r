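# Ct-prediction harness: feature extraction, grouped splitting, stacked
# ensemble regression, evaluation and interpretability.

.FEATURE_COLS <- c("temperature", "time", "length", "gc", "last_base",
                   "dG", "Tm", "binding_prob", "tag")

#' Featurize amplification records
#'
#' Maps records (primer sequence, tag flag, reaction conditions, observed
#' Ct) to the fixed feature set used by the Ct model: reaction parameters
#' (temperature, extension time), primer properties (length, GC fraction,
#' 3'-terminal base) and thermodynamic stability (dG, Tm, average binding
#' probability), plus the binary tag flag.  Thermodynamics are delegated
#' to [duplex_thermo()] at each record's own temperature; the average
#' binding probability is the two-state bound template fraction at the
#' annealing temperature (see the methods vignette for why this stands in
#' for an otherwise underdefined quantity).
#'
#' @param records data.frame with columns `sequence`, `tag` (logical),
#'   `temperature`, `time`, and optionally `ct`, `id`, `censored`,
#'   `tag_dG`.
#' @param monovalent_salt Salt concentration used for thermodynamics,
#'   mol/L.
#' @param primer_conc Primer concentration for Tm / binding probability,
#'   mol/L.
#' @param params NN parameter set.
#' @return data.frame of features (one row per record), carrying `ct`,
#'   `id` and `censored` through when present.  Feature columns are
#'   listed in `attr(, "feature_cols")`.
#' @export
featurize <- function(records, monovalent_salt = 0.18, primer_conc = 4e-7,
                      params = nn_params()) {
  need <- c("sequence", "tag", "temperature", "time")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  n <- nrow(records)
  out <- data.frame(
    temperature = as.numeric(records$temperature),
    time = as.numeric(records$time),
    length = NA_real_, gc = NA_real_,
    last_base = factor(rep("A", n), levels = .BASES),
    dG = NA_real_, Tm = NA_real_, binding_prob = NA_real_,
    tag = as.numeric(records$tag)
  )
  for (i in seq_len(n)) {
    s <- .clean_seq(records$sequence[i], sprintf("record %d sequence", i))
    conds <- reaction_conditions(
      temperature = records$temperature[i],
      monovalent_salt = monovalent_salt,
      extension_time = records$time[i],
      primer_conc = primer_conc
    )
    th <- duplex_thermo(s, conds, params)
    bases <- strsplit(s, "")[[1]]
    out$length[i] <- nchar(s)
    out$gc[i] <- mean(bases %in% c("G", "C"))
    out$last_base[i] <- bases[length(bases)]
    out$dG[i] <- th$dG
    out$Tm[i] <- th$Tm
    out$binding_prob[i] <- binding_probability(
      th$dG, records$temperature[i], primer_conc)
  }
  for (extra in c("ct", "censored")) {
    if (extra %in% names(records)) out[[extra]] <- records[[extra]]
  }
  out$id <- if ("id" %in% names(records)) records$id else records$sequence
  attr(out, "feature_cols") <- .FEATURE_COLS
  out
}

#' Split a dataset by primer identity
#'
#' Partitions records into training and validation sets such that all
#' records of a given primer land in exactly one partition (leakage
#' guard).  The split is over identities, not rows, and is invariant to
#' the input row order at a fixed seed.
#'
#' @param data data.frame with an `id` column (primer identity; falls
#'   back to `sequence`).
#' @param fraction Fraction of identities assigned to training.
#' @param seed Integer seed.
#' @return List with `train` and `validation` data.frames.
#' @export
split_by_group <- function(data, fraction = 0.7, seed = 1) {
  idcol <- if ("id" %in% names(data)) "id" else "sequence"
  ids <- sort(unique(as.character(data[[idcol]])))
  if (length(ids) < 2) stop("need >= 2 primer identities to split")
  n_train <- round(fraction * length(ids))
  n_train <- min(max(n_train, 1), length(ids) - 1)
  train_ids <- .with_seed(seed, sample(ids, n_train))
  in_train <- as.character(data[[idcol]]) %in% train_ids
  list(train = data[in_train, , drop = FALSE],
       validation = data[!in_train, , drop = FALSE])
}

# fixed design matrix over the feature columns
.feat_matrix <- function(features) {
  df <- features[, .FEATURE_COLS, drop = FALSE]
  df$last_base <- factor(df$last_base, levels = .BASES)
  stats::model.matrix(~ . , data = df)[, -1, drop = FALSE]
}

.fit_base <- function(name, X, y, seed) {
  switch(name,
    lm = {
      df <- as.data.frame(X); df$.y <- y
      stats::lm(.y ~ ., data = df)
    },
    ranger = ranger::ranger(
      x = X, y = y, num.trees = 300, seed = seed, num.threads = 1
    ),
    xgboost = xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = 0.1,
                    max_depth = 4, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = 150, verbose = 0
    ),
    stop("unknown base learner: ", name)
  )
}

.predict_base <- function(name, fit, X) {
  switch(name,
    # rank-deficiency warnings arise when a condition grid is degenerate
    # (e.g. a single temperature level); predictions are still valid there
    lm = suppressWarnings(
      as.numeric(stats::predict(fit, newdata = as.data.frame(X)))),
    ranger = as.numeric(stats::predict(fit, data = X)$predictions),
    xgboost = as.numeric(stats::predict(fit,
                                        newdata = xgboost::xgb.DMatrix(X)))
  )
}

#' Train a stacked ensemble Ct model
#'
#' First tier: distinct base regressors (linear model, random forest,
#' gradient-boosted trees) fitted with grouped k-fold cross-validation so
#' every training record receives an out-of-fold prediction from each
#' learner.  Second tier: a linear meta-learner fitted ONLY on those
#' out-of-fold predictions (no leakage).  Base learners are then refitted
#' on the full training set for deployment.  Deterministic given `seed`.
#'
#' @param train Featurized training data (from [featurize()], with `ct`).
#' @param learners Character vector of base learners among `"lm"`,
#'   `"ranger"`, `"xgboost"`.
#' @param seed Integer seed (folds, forests, boosting).
#' @param k Number of grouped folds (>= 2; 5 recommended).
#' @param exclude_censored Drop records flagged `censored` (Ct at the
#'   cap) instead of keeping them at the cap value.
#' @return An object of class `pa_stack` with the fitted tiers and a
#'   training manifest (seed, folds, learner set, group membership).
#' @export
train_stack <- function(train, learners = c("lm", "ranger", "xgboost"),
                        seed = 1, k = 5, exclude_censored = FALSE) {
  if (!"ct" %in% names(train)) stop("training data needs a 'ct' column")
  if (exclude_censored && "censored" %in% names(train)) {
    train <- train[!train$censored, , drop = FALSE]
  }
  if (nrow(train) < length(learners) + 2) stop("training set too small")
  y <- train$ct
  if (stats::sd(y) < 1e-12) {
    warning("constant-target training set: falling back to a mean predictor")
    obj <- list(constant = mean(y), learners = character(0),
                manifest = list(seed = seed, k = k, n = nrow(train)))
    class(obj) <- "pa_stack"
    return(obj)
  }
  X <- .feat_matrix(train)
  ids <- as.character(train$id)
  groups <- sort(unique(ids))
  k <- min(k, length(groups))
  fold_of_group <- .with_seed(seed, {
    stats::setNames(sample(rep_len(seq_len(k), length(groups))), groups)
  })
  fold <- fold_of_group[ids]
  oof <- matrix(NA_real_, nrow(train), length(learners),
                dimnames = list(NULL, learners))
  for (j in seq_len(k)) {
    hold <- fold == j
    if (!any(hold) || all(hold)) next
    for (ln in learners) {
      fit <- .fit_base(ln, X[!hold, , drop = FALSE], y[!hold], seed + j)
      oof[hold, ln] <- .predict_base(ln, fit, X[hold, , drop = FALSE])
    }
  }
  ok <- stats::complete.cases(oof)
  meta_df <- as.data.frame(oof[ok, , drop = FALSE])
  meta_df$.y <- y[ok]
  meta <- stats::lm(.y ~ ., data = meta_df)
  base_fits <- lapply(stats::setNames(learners, learners),
                      function(ln) .fit_base(ln, X, y, seed))
  obj <- list(
    base = base_fits, meta = meta, learners = learners,
    oof = oof, oof_y = y,
    manifest = list(seed = seed, k = k, learners = learners,
                    n = nrow(train), groups = fold_of_group)
  )
  class(obj) <- "pa_stack"
  obj
}

#' Predict Ct values from a stacked model
#'
#' @param object A `pa_stack` from [train_stack()].
#' @param newdata Featurized data (from [featurize()]).
#' @param ... Unused.
#' @return Numeric vector of predicted Ct values.
#' @export
predict.pa_stack <- function(object, newdata, ...) {
  if (!is.null(object$constant)) {
    return(rep(object$constant, nrow(newdata)))
  }
  X <- .feat_matrix(newdata)
  preds <- vapply(object$learners,
                  function(ln) .predict_base(ln, object$base[[ln]], X),
                  numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1,
                                           dimnames = list(NULL, object$learners))
  as.numeric(stats::predict(object$meta, newdata = as.data.frame(preds)))
}

#' Evaluate a Ct model on held-out data
#'
#' @param model A `pa_stack`.
#' @param validation Featurized validation data with `ct`.
#' @return An object of class `pa_eval`: list with `r2`, `rmse`,
#'   `residual_quantiles`, `interval80` (empirical 10th-90th residual
#'   percentiles) and `interval80_half_width`, plus the predictions.
#' @export
evaluate_model <- function(model, validation) {
  if (!nrow(validation)) stop("validation set is empty")
  pred <- predict(model, validation)
  y <- validation$ct
  resid <- y - pred
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  q <- stats::quantile(resid, c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95),
                       names = TRUE)
  i80 <- unname(stats::quantile(resid, c(0.1, 0.9)))
  obj <- list(
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    rmse = sqrt(mean(resid^2)),
    residual_quantiles = q,
    interval80 = i80,
    interval80_half_width = diff(i80) / 2,
    predictions = pred, observed = y
  )
  class(obj) <- "pa_eval"
  obj
}

#' @export
print.pa_eval <- function(x, ...) {
  cat(sprintf(
    "Ct model evaluation: R2 = %.3f  RMSE = %.2f cycles\n 80%% residual interval: [%.2f, %.2f] cycles\n",
    x$r2, x$rmse, x$interval80[1], x$interval80[2]))
  invisible(x)
}

#' Permutation feature importance
#'
#' Model-agnostic global importance: each feature column is shuffled
#' `n_shuffles` times and the mean validation RMSE inflation relative to
#' the unshuffled baseline is recorded, then features are ranked
#' descending.
#'
#' @param model A `pa_stack`.
#' @param validation Featurized validation data with `ct`.
#' @param n_shuffles Shuffles per feature (>= 10 recommended).
#' @param seed Integer seed.
#' @return data.frame with `feature` and `importance` (RMSE inflation,
#'   cycles), sorted descending.
#' @export
permutation_importance <- function(model, validation, n_shuffles = 10,
                                   seed = 1) {
  base_rmse <- sqrt(mean((validation$ct - predict(model, validation))^2))
  .with_seed(seed, {
    imp <- vapply(.FEATURE_COLS, function(f) {
      infl <- vapply(seq_len(n_shuffles), function(i) {
        shuffled <- validation
        shuffled[[f]] <- sample(shuffled[[f]])
        sqrt(mean((shuffled$ct - predict(model, shuffled))^2)) - base_rmse
      }, numeric(1))
      mean(infl)
    }, numeric(1))
    out <- data.frame(feature = names(imp), importance = unname(imp))
    out[order(-out$importance), , drop = FALSE]
  })
}

#' Partial dependence of predicted Ct on one feature
#'
#' Mean prediction over the data with one feature clamped to each grid
#' value in turn.
#'
#' @param model A `pa_stack`.
#' @param data Featurized data.
#' @param feature Feature name.
#' @param grid Values to clamp the feature to.
#' @return data.frame with `value` and `prediction`.
#' @export
partial_dependence <- function(model, data, feature, grid) {
  pred <- vapply(grid, function(v) {
    d <- data
    d[[feature]] <- if (is.factor(d[[feature]])) {
      factor(rep(v, nrow(d)), levels = levels(d[[feature]]))
    } else rep(v, nrow(d))
    mean(predict(model, d))
  }, numeric(1))
  data.frame(value = grid, prediction = pred)
}
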