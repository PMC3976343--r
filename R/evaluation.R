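# Performance criteria and the 9-model x 4-potential benchmark matrix.

#' Scaled error rate
#'
#' The median over samples of the prediction error normalised by the
#' experimental value, `median(|y_pred - y_true| / y_true)`; lower is
#' better and 0 is perfect. Samples whose experimental value is 0 (e.g.
#' fully collapsed late-passage staining) are excluded with a warning.
#'
#' @param y_true Experimentally determined values.
#' @param y_pred Predicted values.
#' @param method `"relative"` (default): median of per-sample relative
#'   errors. `"pooled"`: alternative reading, median absolute error
#'   divided by the median experimental value.
#' @return Non-negative scalar.
#' @export
scaled_error_rate <- function(y_true, y_pred,
                              method = c("relative", "pooled")) {
  method <- match.arg(method)
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1)
  if (all(y_true == 0)) stop("all experimental values are zero")
  if (method == "pooled")
    return(median(abs(y_pred - y_true)) / median(y_true))
  zero <- y_true == 0
  if (any(zero))
    warning(sum(zero), " sample(s) with zero experimental value excluded")
  median(abs(y_pred[!zero] - y_true[!zero]) / y_true[!zero])
}

#' Correlation coefficient between experimental and predicted values
#'
#' Pearson correlation pooled across all samples (all lots and passages
#' together, one number per benchmark cell).
#'
#' @param y_true,y_pred Numeric vectors, `n >= 3`, neither constant.
#' @return Scalar in `[-1, 1]`.
#' @export
correlation_coefficient <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 3)
  if (sd(y_true) == 0 || sd(y_pred) == 0)
    stop("correlation undefined for a constant vector")
  cor(y_true, y_pred)
}

# The nine input-feature configurations.
MODEL_SPECS <- data.frame(
  model_id = 1:9,
  inputs = c("null", "genes", "genes+mp1", paste0("mp", 1:6)),
  label = c("NULL (mean predictor)", "genes only", "genes + M-pattern 1",
            paste("M-pattern", 1:6)),
  stringsAsFactors = FALSE
)

#' Ranked table of nonzero model weights
#'
#' @param fit A [lasso_fit()] object.
#' @return Data frame of nonzero weights on the original feature scale,
#'   sorted by absolute weight (descending), with provenance columns
#'   (morphology feature / gene / count, statistic, time point).
#' @export
weight_report <- function(fit) {
  stopifnot(inherits(fit, "lasso_fit"))
  nz <- which(fit$beta != 0)
  out <- data.frame(feature = names(fit$beta)[nz],
                    weight = unname(fit$beta[nz]),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$weight)), , drop = FALSE]
  rownames(out) <- NULL
  cbind(out, parse_feature_provenance(out$feature)[, c("source", "statistic",
                                                       "hours")])
}

#' Run the full 36-model prediction benchmark
#'
#' Evaluates every input configuration (NULL; genes; genes + M-pattern 1;
#' M-patterns 1-6) against every potential (osteogenic, adipogenic,
#' chondrogenic differentiation rate and PDT): 9 x 4 = 36 cells. Each
#' non-NULL cell is scored on out-of-fold predictions from
#' [nested_loocv_predict()]; its ranked nonzero-weight table comes from a
#' full-data fit at the LOOCV-selected penalty. The NULL cell predicts the
#' mean teacher value for every sample (its correlation is undefined and
#' reported as `NA`).
#'
#' @param bundle A list with `features` (named list `mp1` ... `mp6` of
#'   sample x feature matrices), `genes` (genes x samples matrix) and
#'   `potentials` (data frame with `sample_id` and the four potential
#'   columns), e.g. from [simulate_feature_bundle()].
#' @param models Subset of model ids to run (default all nine).
#' @param potential_types Subset of potentials (default all four).
#' @param nested Use nested LOOCV for out-of-fold predictions.
#' @return A `benchmark_matrix`: list with `results` (one row per cell:
#'   `model_id`, `inputs`, `potential_type`, `scaled_error_rate`,
#'   `correlation`, `fold_vs_null`, `n_selected`) and `cells` (per-cell
#'   predictions and weight tables).
#' @export
run_benchmark <- function(bundle, models = 1:9,
                          potential_types = POTENTIAL_TYPES,
                          nested = TRUE) {
  stopifnot(all(models %in% 1:9),
            all(potential_types %in% POTENTIAL_TYPES))
  for (el in c("features", "genes", "potentials"))
    if (is.null(bundle[[el]])) stop("benchmark bundle is missing '", el, "'")
  results <- list()
  cells <- list()
  for (p in potential_types) {
    y <- setNames(bundle$potentials[[p]], bundle$potentials$sample_id)
    null_ser <- scaled_error_rate(y, null_model(y))
    for (m in models) {
      spec <- MODEL_SPECS[MODEL_SPECS$model_id == m, ]
      key <- sprintf("model%d_%s", m, p)
      if (spec$inputs == "null") {
        pred <- null_model(y)
        cell <- list(y_true = y, y_pred = pred, weights = NULL,
                     lambda = NA_real_)
        ser <- null_ser
        cc <- NA_real_
        nsel <- 0L
      } else {
        ds <- assemble_dataset(bundle$features, bundle$potentials, p,
                               spec$inputs, genes = bundle$genes)
        cvp <- nested_loocv_predict(ds$X, ds$y, nested = nested)
        pred <- cvp$predictions
        sel <- loocv_select_lambda(ds$X, ds$y)
        fit <- lasso_fit(ds$X, ds$y, sel$lambda)
        cell <- list(y_true = ds$y, y_pred = pred,
                     weights = weight_report(fit), lambda = sel$lambda,
                     fold_lambda = cvp$lambda)
        ser <- scaled_error_rate(ds$y, pred)
        cc <- correlation_coefficient(ds$y, pred)
        nsel <- length(fit$selected_features)
      }
      results[[key]] <- data.frame(
        model_id = m, inputs = spec$inputs, label = spec$label,
        potential_type = p, scaled_error_rate = ser, correlation = cc,
        fold_vs_null = null_ser / ser, n_selected = nsel,
        stringsAsFactors = FALSE)
      cells[[key]] <- cell
    }
  }
  res <- do.call(rbind, results)
  rownames(res) <- NULL
  structure(list(results = res, cells = cells,
                 models = models, potential_types = potential_types),
            class = "benchmark_matrix")
}

#' @export
print.benchmark_matrix <- function(x, ...) {
  cat(sprintf("Prediction benchmark: %d cells (%d models x %d potentials)\n",
              nrow(x$results), length(x$models), length(x$potential_types)))
  df <- x$results
  df$scaled_error_rate <- signif(df$scaled_error_rate, 3)
  df$correlation <- signif(df$correlation, 3)
  df$fold_vs_null <- signif(df$fold_vs_null, 3)
  print(df[, c("model_id", "label", "potential_type", "scaled_error_rate",
               "correlation", "fold_vs_null", "n_selected")])
  invisible(x)
}
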