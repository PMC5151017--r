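#' Fit the confound residualizer
#'
#' Fits, for every morphometric feature independently, the ordinary
#' least-squares regression `feature ~ 1 + age + sex` on the chosen fit rows.
#' Downstream models see the residuals from these fits, so that age and sex
#' differences between diagnostic groups cannot masquerade as disease effects.
#'
#' @param table A `morph_table`.
#' @param fit_rows Row indices used to estimate the coefficients. The default
#'   (all rows) reproduces the conventional across-all-subjects correction; a
#'   training-fold subset gives a leakage-free variant.
#' @return An object of class `preprocess_model` holding per-feature
#'   coefficients `(intercept, beta_age, beta_sex)`; z-scoring statistics are
#'   added by [fit_zscore()].
#' @export
fit_residualizer <- function(table, fit_rows = seq_len(n_subjects(table))) {
  stopifnot(inherits(table, "morph_table"))
  fit_rows <- normalize_rows(fit_rows, n_subjects(table))
  if (length(fit_rows) < 3) stop("need at least 3 fit rows")
  age <- table$age[fit_rows]
  sex <- table$sex[fit_rows]
  if (stats::var(age) == 0) stop("age is constant on the fit rows")
  X <- cbind(intercept = 1, age = age, sex = sex)
  qx <- qr(X)
  if (qx$rank < max(2L, length(unique(sex)) + 1L)) {
    stop("rank-deficient confound design on the fit rows")
  }
  # single-sex cohorts: drop the sex column rather than fail
  drop_sex <- qx$rank < 3L
  if (drop_sex) {
    X <- X[, 1:2, drop = FALSE]
    qx <- qr(X)
  }
  Y <- table$features[fit_rows, , drop = FALSE]
  beta <- qr.coef(qx, Y)
  if (drop_sex) beta <- rbind(beta, sex = 0)
  rownames(beta) <- c("intercept", "age", "sex")
  structure(
    list(coefficients = beta, fit_rows = fit_rows,
         schema = table$schema, zscore = NULL),
    class = "preprocess_model"
  )
}

normalize_rows <- function(rows, n) {
  if (is.logical(rows)) rows <- which(rows)
  rows <- as.integer(rows)
  if (any(rows < 1 | rows > n)) stop("fit_rows out of range")
  rows
}

#' @export
print.preprocess_model <- function(x, ...) {
  cat("<preprocess_model> ", ncol(x$coefficients), " features, fitted on ",
      length(x$fit_rows), " rows",
      if (!is.null(x$zscore)) ", with z-scoring stats", "\n", sep = "")
  invisible(x)
}

#' Apply the confound residualizer
#'
#' Replaces each feature by `feature - (intercept + beta_age * age +
#' beta_sex * sex)`. Covariates are retained unchanged.
#'
#' @param model A `preprocess_model` from [fit_residualizer()].
#' @param table A `morph_table` with schema-matching columns.
#' @return A `morph_table` with provenance `"residualized"`.
#' @export
apply_residualizer <- function(model, table) {
  check_schema_match(model, table)
  X <- cbind(1, table$age, table$sex)
  resid <- table$features - X %*% model$coefficients
  morph_table(table$subject_id, table$label, table$age, table$sex, resid,
              provenance = "residualized", schema = table$schema)
}

check_schema_match <- function(model, table) {
  if (!identical(colnames(model$coefficients), colnames(table$features))) {
    stop("table feature columns do not match the fitted model's schema")
  }
}

#' Fit z-scoring statistics
#'
#' Records, per feature, the mean and standard deviation (n-1 denominator)
#' on the fit rows, to be applied by [apply_zscore()].
#'
#' @param model A `preprocess_model` (typically after [apply_residualizer()]
#'   produced the table being standardized).
#' @param table The table whose fit rows supply the statistics.
#' @param fit_rows Rows used for the statistics; defaults to the rows the
#'   residualizer was fitted on.
#' @return The model augmented with a `zscore` component.
#' @export
fit_zscore <- function(model, table, fit_rows = model$fit_rows) {
  check_schema_match(model, table)
  fit_rows <- normalize_rows(fit_rows, n_subjects(table))
  X <- table$features[fit_rows, , drop = FALSE]
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  if (any(sdev <= 0)) {
    stop("zero-variance feature(s) on fit rows: ",
         paste(utils::head(colnames(X)[sdev <= 0], 5), collapse = ", "))
  }
  model$zscore <- list(mean = mu, sd = sdev)
  model
}

#' Apply z-scoring
#'
#' @param model A `preprocess_model` carrying z-score statistics.
#' @param table A schema-matching `morph_table`.
#' @return A `morph_table` with provenance `"zscored"`.
#' @export
apply_zscore <- function(model, table) {
  if (is.null(model$zscore)) stop("model carries no z-score statistics; call fit_zscore() first")
  check_schema_match(model, table)
  Z <- sweep(sweep(table$features, 2, model$zscore$mean), 2, model$zscore$sd, "/")
  morph_table(table$subject_id, table$label, table$age, table$sex, Z,
              provenance = "zscored", schema = table$schema)
}

#' One-call preprocessing: residualize then z-score
#'
#' Convenience wrapper running [fit_residualizer()], [apply_residualizer()],
#' [fit_zscore()] and [apply_zscore()] in sequence.
#'
#' @inheritParams fit_residualizer
#' @return List with `table` (provenance `"zscored"`) and `model`.
#' @export
preprocess_table <- function(table, fit_rows = seq_len(n_subjects(table))) {
  model <- fit_residualizer(table, fit_rows)
  resid <- apply_residualizer(model, table)
  model <- fit_zscore(model, resid, fit_rows)
  list(table = apply_zscore(model, resid), model = model)
}

#' Serialize / restore a preprocessing model as JSON
#'
#' @param model A `preprocess_model`.
#' @param path File path.
#' @return `read_preprocess_model()` returns the model; the writer returns
#'   `path` invisibly.
#' @export
write_preprocess_model <- function(model, path) {
  obj <- list(
    coefficients = as.data.frame(t(model$coefficients)),
    fit_rows = model$fit_rows,
    zscore = if (!is.null(model$zscore)) {
      list(mean = unname(model$zscore$mean), sd = unname(model$zscore$sd))
    }
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_preprocess_model
#' @export
read_preprocess_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- t(as.matrix(obj$coefficients))
  sch <- feature_schema()
  colnames(beta) <- sch$feature_names
  zs <- NULL
  if (!is.null(obj$zscore)) {
    zs <- list(mean = stats::setNames(obj$zscore$mean, sch$feature_names),
               sd = stats::setNames(obj$zscore$sd, sch$feature_names))
  }
  structure(list(coefficients = beta, fit_rows = obj$fit_rows,
                 schema = sch, zscore = zs),
            class = "preprocess_model")
}
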