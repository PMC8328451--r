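#' Build a calibration table from reference-covered coarse cells
#'
#' Pairs the coarse predictors (mean NDSI across scenes, TPI) with the
#' reference snow-free fraction, keeping only cells with full fine-grid
#' reference coverage (e.g. inside surveyed transects).
#'
#' @param ndsi_mean coarse grid: scene-mean NDSI.
#' @param tpi_coarse coarse grid: TPI (m).
#' @param reference coarse grid: reference snow-free fraction in \[0, 1\]
#'   (`NA` outside the reference coverage).
#' @param coverage optional binary coarse grid restricting rows further
#'   (1 = usable reference cell).
#' @return data.frame with columns `cell` (linear index), `ndsi`, `tpi`, `y`.
#' @export
make_calibration_set <- function(ndsi_mean, tpi_coarse, reference,
                                 coverage = NULL) {
  stop_if_misaligned(ndsi_mean, tpi_coarse, reference,
                     what = "calibration grids")
  keep <- !is.na(reference$values) & !is.na(ndsi_mean$values) &
    !is.na(tpi_coarse$values)
  if (!is.null(coverage)) {
    stop_if_misaligned(ndsi_mean, coverage, what = "coverage grid")
    keep <- keep & !is.na(coverage$values) & coverage$values == 1
  }
  idx <- which(keep)
  if (!length(idx)) stop("no usable calibration cells")
  data.frame(cell = idx,
             ndsi = ndsi_mean$values[idx],
             tpi = tpi_coarse$values[idx],
             y = reference$values[idx])
}

#' Balanced sampling across snow-fraction bins
#'
#' Reference data are typically skewed towards snow-covered cells; to avoid
#' training on that skew, rows are sampled so that each 10%-wide fraction bin
#' (\[0, 0.1), ..., \[0.9, 1.0\]) contributes about the same number of points.
#'
#' @param cal calibration data.frame from [make_calibration_set()].
#' @param quota_per_bin rows drawn per bin (bins smaller than the quota are
#'   kept whole).
#' @param seed RNG seed for the draw.
#' @return subset of `cal`, row-bound over bins.
#' @export
balanced_sample <- function(cal, quota_per_bin, seed = 1L) {
  if (!nrow(cal)) stop("empty calibration set")
  if (quota_per_bin < 1) stop("`quota_per_bin` must be >= 1")
  bin <- pmin(floor(cal$y * 10), 9)
  with_seed(seed, {
    keep <- unlist(lapply(0:9, function(b) {
      rows <- which(bin == b)
      if (length(rows) <= quota_per_bin) rows
      else sample(rows, quota_per_bin)
    }), use.names = FALSE)
  })
  cal[sort(keep), , drop = FALSE]
}

#' Built-in learners for the snow-fraction model
#'
#' Learners honor a fit/predict contract: `fit(data)` returns an opaque model,
#' `predict(model, newdata)` returns numeric predictions; `n_hyper` counts
#' tunable hyperparameters (used to break ranking ties towards simpler
#' learners). The snow-fraction response is curvilinear in both predictors
#' with a threshold effect in TPI, so both built-ins are flexible:
#' a penalized thin-plate spline regression and gradient-boosted stumps.
#'
#' @param k spline basis dimension per smooth.
#' @param nrounds,eta boosting rounds and learning rate.
#' @return a `snowsel_learner` list with `name`, `n_hyper`, `fit`, `predict`.
#' @export
learner_pspline <- function(k = 10) {
  structure(list(
    name = "penalized_spline", n_hyper = 1L,
    fit = function(data) {
      kk <- max(3, min(k, floor(nrow(data) / 3)))
      mgcv::gam(y ~ s(ndsi, k = kk) + s(tpi, k = kk), data = data,
                method = "REML")
    },
    predict = function(model, newdata)
      as.numeric(mgcv::predict.gam(model, newdata = newdata))
  ), class = "snowsel_learner")
}

#' @rdname learner_pspline
#' @export
learner_gbstumps <- function(nrounds = 150, eta = 0.1) {
  structure(list(
    name = "boosted_stumps", n_hyper = 2L,
    fit = function(data) {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(data[, c("ndsi", "tpi")]),
                                     label = data$y, nthread = 1)
      xgboost::xgb.train(
        params = list(max_depth = 1, eta = eta,
                      objective = "reg:squarederror", nthread = 1),
        data = dtrain, nrounds = nrounds, verbose = 0)
    },
    predict = function(model, newdata)
      as.numeric(predict(model, xgboost::xgb.DMatrix(
        as.matrix(newdata[, c("ndsi", "tpi")]), nthread = 1)))
  ), class = "snowsel_learner")
}

#' @rdname learner_pspline
#' @export
learner_linear <- function() {
  structure(list(
    name = "linear", n_hyper = 0L,
    fit = function(data) stats::lm(y ~ ndsi + tpi, data = data),
    predict = function(model, newdata)
      as.numeric(stats::predict(model, newdata = newdata))
  ), class = "snowsel_learner")
}

# Seeded fold assignment, stratified on y deciles so every fold sees the full
# fraction range (mirrors the balanced calibration design).
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    bin <- pmin(floor(y * 10), 9)
    fold <- integer(length(y))
    for (b in unique(bin)) {
      rows <- which(bin == b)
      fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
    fold
  })
}

#' Repeated k-fold cross-validation of one learner
#'
#' Five folds repeated five times gives 25 resamples by default; each
#' resample's score is out-of-fold R-squared, `1 - SSE/SST`, with SST about
#' the held-out mean.
#'
#' @param learner a `snowsel_learner`.
#' @param data calibration data.frame.
#' @param k folds per repeat.
#' @param repeats repeats.
#' @param seed RNG seed controlling fold assignment.
#' @return numeric vector of `k * repeats` out-of-fold R-squared values;
#'   resamples whose held-out responses are constant (SST = 0) are `NA` with
#'   a warning.
#' @export
cv_score <- function(learner, data, k = 5, repeats = 5, seed = 1L) {
  if (nrow(data) < 2 * k)
    stop("need at least 2k rows for ", k, "-fold cross-validation")
  scores <- numeric(0)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(data$y, k, stage_seed(seed, 100L + r))
    for (f in seq_len(k)) {
      test <- fold == f
      model <- learner$fit(data[!test, , drop = FALSE])
      pred <- learner$predict(model, data[test, , drop = FALSE])
      yt <- data$y[test]
      sst <- sum((yt - mean(yt))^2)
      if (sst == 0) {
        warning("degenerate resample: held-out responses are constant")
        scores <- c(scores, NA_real_)
      } else {
        scores <- c(scores, 1 - sum((yt - pred)^2) / sst)
      }
    }
  }
  scores
}

#' Cross-validate, rank, and average the two best learners
#'
#' Learners are ranked by mean cross-validated R-squared (ties broken towards
#' fewer hyperparameters); the top two are refit on all rows and their
#' predictions averaged (unweighted) and clipped to \[0, 1\].
#'
#' @param data calibration data.frame.
#' @param learners list of >= 2 `snowsel_learner`s.
#' @param k,repeats,seed cross-validation controls, see [cv_score()].
#' @return a `snowsel_calibration` list: `cv` (data.frame of learner name,
#'   mean and sd of CV R-squared, n_hyper), `chosen` (two names),
#'   `models` (refit top two), `predictor_cor` (Pearson r of `ndsi` and `tpi`
#'   vs `y`), and `predict(newdata)`.
#' @export
fit_ensemble <- function(data, learners, k = 5, repeats = 5, seed = 1L) {
  if (length(learners) < 2) stop("need at least two learners to ensemble")
  cv <- lapply(learners, cv_score, data = data, k = k, repeats = repeats,
               seed = seed)
  tab <- data.frame(
    name = vapply(learners, `[[`, "", "name"),
    mean_r2 = vapply(cv, function(s) mean(s, na.rm = TRUE), 0),
    sd_r2 = vapply(cv, function(s) stats::sd(s, na.rm = TRUE), 0),
    n_resamples = lengths(cv),
    n_hyper = vapply(learners, function(l) as.integer(l$n_hyper), 0L)
  )
  ord <- order(-tab$mean_r2, tab$n_hyper)
  top <- ord[1:2]
  models <- lapply(learners[top], function(l) l$fit(data))
  preds <- learners[top]
  predict_fun <- function(newdata) {
    p <- (preds[[1]]$predict(models[[1]], newdata) +
          preds[[2]]$predict(models[[2]], newdata)) / 2
    pmin(pmax(p, 0), 1)
  }
  structure(list(
    cv = tab[ord, , drop = FALSE],
    resamples = stats::setNames(cv, tab$name),
    chosen = tab$name[top],
    models = models,
    predictor_cor = c(ndsi = stats::cor(data$ndsi, data$y),
                      tpi = stats::cor(data$tpi, data$y)),
    predict = predict_fun
  ), class = "snowsel_calibration")
}

#' Predict the snow-free fraction area-wide
#'
#' Applies the calibrated ensemble to every coarse cell with valid predictors.
#'
#' @param result a `snowsel_calibration` from [fit_ensemble()].
#' @param ndsi_mean,tpi_coarse aligned coarse predictor grids.
#' @return snow-free-fraction grid in \[0, 1\]; `NA` where any predictor is
#'   `NA`.
#' @export
predict_fraction <- function(result, ndsi_mean, tpi_coarse) {
  stop_if_misaligned(ndsi_mean, tpi_coarse, what = "predictor grids")
  ok <- !is.na(ndsi_mean$values) & !is.na(tpi_coarse$values)
  out <- matrix(NA_real_, nrow(ndsi_mean$values), ncol(ndsi_mean$values))
  if (any(ok)) {
    nd <- data.frame(ndsi = ndsi_mean$values[ok], tpi = tpi_coarse$values[ok])
    out[ok] <- result$predict(nd)
  }
  grid_like(ndsi_mean, out)
}
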