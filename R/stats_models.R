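#' Cognitive composite score
#'
#' Arithmetic mean of component z-scores (e.g. the executive-functioning
#' composite averaging word fluency, Stroop interference and concept-shift
#' z-scores). A subject missing any component gets a missing composite with
#' a warning; nothing is imputed.
#'
#' @param table A data frame of per-subject z-scores, one test per column.
#' @param components Character vector of column names to average.
#' @param domain Name under which the composite is stored.
#' @return `table` with an added `domain` column.
#' @export
composite_score <- function(table, components, domain) {
  miss <- setdiff(components, names(table))
  if (length(miss)) {
    stop("missing component column(s): ", paste(miss, collapse = ", "))
  }
  comp <- as.matrix(table[, components, drop = FALSE])
  out <- rowMeans(comp)
  if (anyNA(out)) {
    warning(sum(is.na(out)), " subject(s) missing a component of '", domain,
            "'; composite set to NA")
  }
  table[[domain]] <- out
  table
}

#' Collinearity diagnostics (tolerance and VIF)
#'
#' For each predictor `j`, regresses it on all other predictors; the
#' variance inflation factor is `VIF_j = 1 / (1 - R2_j)` and the tolerance
#' is its reciprocal `1 - R2_j`. Predictors with tolerance below 0.2 are
#' flagged.
#'
#' @param X A data frame or matrix of predictors (>= 2 columns, more rows
#'   than predictors).
#' @param threshold Tolerance flag threshold (default 0.2).
#' @return A data frame with columns `predictor`, `r_squared`, `tolerance`,
#'   `vif`, `flagged`, `singular`.
#' @export
collinearity <- function(X, threshold = 0.2) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 predictors")
  if (nrow(X) <= p) stop("need more rows than predictors")
  out <- lapply(seq_len(p), function(j) {
    fit <- lm(reformulate(names(X)[-j], response = names(X)[j]), data = X)
    r2 <- summary(fit)$r.squared
    singular <- r2 >= 1 - 1e-10
    tol <- max(1 - r2, 0)
    data.frame(predictor = names(X)[j], r_squared = r2,
               tolerance = if (singular) 0 else tol,
               vif = if (singular) Inf else 1 / tol,
               flagged = (if (singular) 0 else tol) < threshold,
               singular = singular, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

std_betas <- function(fit, data, response) {
  cf <- coef(fit)[-1L]
  if (!length(cf)) return(numeric(0))
  sy <- sd(data[[response]])
  vapply(names(cf), function(v) cf[[v]] * sd(data[[v]]) / sy, numeric(1))
}

model_record <- function(fit, data, response, step, note = "") {
  sm <- summary(fit)
  fstat <- sm$fstatistic
  preds <- attr(terms(fit), "term.labels")
  list(
    step = step,
    predictors = preds,
    coefficients = coef(fit),
    std_beta = std_betas(fit, data, response),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_statistic = if (!is.null(fstat)) unname(fstat[1L]) else NA_real_,
    df = if (!is.null(fstat)) unname(fstat[2:3]) else c(NA_real_, NA_real_),
    p = if (!is.null(fstat)) {
      unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
    } else NA_real_,
    observed = data[[response]],
    fitted = unname(fitted(fit)),
    note = note
  )
}

fit_ols <- function(response, predictors, data) {
  f <- if (length(predictors)) {
    reformulate(predictors, response = response)
  } else {
    reformulate("1", response = response)
  }
  fit <- lm(f, data = data)
  if (fit$rank < length(predictors) + 1L) {
    stop("rank-deficient design: predictors ",
         paste(predictors, collapse = ", "))
  }
  fit
}

drop_p_values <- function(fit, candidates) {
  if (!length(candidates)) return(numeric(0))
  d1 <- drop1(fit, scope = reformulate(candidates), test = "F")
  stats::setNames(d1[["Pr(>F)"]][-1L], rownames(d1)[-1L])
}

add_p_values <- function(fit, candidates, data) {
  if (!length(candidates)) return(numeric(0))
  a1 <- add1(fit, scope = reformulate(c(".", candidates)), test = "F")
  stats::setNames(a1[["Pr(>F)"]][-1L], rownames(a1)[-1L])
}

#' Blockwise stepwise ordinary least squares regression
#'
#' Stepwise selection over a first block of predictors with a second block
#' of forced predictors, as used to relate single-layer FPN centralities
#' (block 1) plus the multilayer FPN centrality (block 2, never removed) to
#' cognition. Backward elimination starts from all block-1 predictors and
#' repeatedly removes the block-1 predictor with the largest partial-F
#' p-value exceeding `p_remove` (default 0.10); forward selection repeatedly
#' adds the block-1 predictor with the smallest partial-F p-value below
#' `p_enter` (default 0.05). By default the forced block enters the working
#' model before selection runs (`block2_entry = "before"`); with
#' `"after"` block-1 selection runs alone and the forced block is added to
#' the final model.
#'
#' @param data A complete-case data frame.
#' @param response Response column name.
#' @param block1 Character vector of selectable predictors.
#' @param block2 Character vector of forced predictors (may be empty).
#' @param direction `"backward"` or `"forward"`.
#' @param p_remove,p_enter F-probability thresholds for removal / entry.
#' @param block2_entry Whether the forced block is present during selection
#'   (`"before"`, default) or appended afterwards (`"after"`).
#' @return An object of class `stepwise_fit`: `models` (one
#'   record per step with R2, adjusted R2, F, df, p, standardized betas,
#'   observed/fitted values), `removal_history`, `final` (the final `lm`),
#'   `delta` (R2 change and F-change between consecutive models),
#'   `collinearity` (diagnostics for the starting design), `direction`.
#' @export
stepwise_blockwise <- function(data, response, block1, block2 = character(),
                               direction = c("backward", "forward"),
                               p_remove = 0.10, p_enter = 0.05,
                               block2_entry = c("before", "after")) {
  direction <- match.arg(direction)
  block2_entry <- match.arg(block2_entry)
  data <- as.data.frame(data)
  all_pred <- c(block1, block2)
  if (!length(all_pred)) stop("empty predictor sets")
  miss <- setdiff(c(response, all_pred), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[, c(response, all_pred)])
  data <- data[cc, , drop = FALSE]
  if (nrow(data) <= length(all_pred) + 1L) {
    stop("need more rows than predictors + 1")
  }

  coll <- if (length(all_pred) >= 2L) {
    collinearity(data[, all_pred, drop = FALSE])
  } else NULL
  forced <- if (block2_entry == "before") block2 else character(0)
  removal_history <- list()
  models <- list()
  step <- 0L

  if (direction == "backward") {
    current <- block1
    fit <- fit_ols(response, c(current, forced), data)
    models[[length(models) + 1L]] <- model_record(fit, data, response, step)
    repeat {
      pv <- drop_p_values(fit, current)
      if (!length(pv) || max(pv) <= p_remove) break
      worst <- names(pv)[which.max(pv)]
      step <- step + 1L
      removal_history[[step]] <- list(step = step, predictor = worst,
                                      p_at_removal = unname(max(pv)))
      current <- setdiff(current, worst)
      fit <- fit_ols(response, c(current, forced), data)
      models[[length(models) + 1L]] <- model_record(fit, data, response, step)
    }
  } else {
    current <- character(0)
    fit <- fit_ols(response, forced, data)
    models[[length(models) + 1L]] <- model_record(fit, data, response, step)
    repeat {
      candidates <- setdiff(block1, current)
      pv <- add_p_values(fit, candidates, data)
      if (!length(pv) || min(pv) >= p_enter) break
      best <- names(pv)[which.min(pv)]
      step <- step + 1L
      removal_history[[step]] <- list(step = step, predictor = best,
                                      p_at_entry = unname(min(pv)))
      current <- c(current, best)
      fit <- fit_ols(response, c(current, forced), data)
      models[[length(models) + 1L]] <- model_record(fit, data, response, step)
    }
  }
  if (block2_entry == "after" && length(block2)) {
    fit <- fit_ols(response, c(current, block2), data)
    models[[length(models) + 1L]] <- model_record(fit, data, response,
                                                  step + 1L,
                                                  note = "block 2 entered")
  }
  delta <- NULL
  if (length(models) >= 2L) {
    delta <- do.call(rbind, lapply(seq_len(length(models) - 1L), function(k) {
      m1 <- models[[k]]; m2 <- models[[k + 1L]]
      f1 <- fit_ols(response, m1$predictors, data)
      f2 <- fit_ols(response, m2$predictors, data)
      an <- anova(f1, f2)
      data.frame(from = k, to = k + 1L,
                 delta_r2 = m2$r_squared - m1$r_squared,
                 f_change = an$F[2L], p_change = an[["Pr(>F)"]][2L])
    }))
  }
  structure(
    list(models = models, removal_history = removal_history,
         final = fit, delta = delta, collinearity = coll,
         direction = direction, response = response,
         block1 = block1, block2 = block2, n = nrow(data)),
    class = "stepwise_fit"
  )
}

#' @export
print.stepwise_fit <- function(x, ...) {
  last <- x$models[[length(x$models)]]
  cat("<stepwise_fit> ", x$direction, " selection, n = ", x$n, "\n", sep = "")
  cat("  final model: ", x$response, " ~ ",
      if (length(last$predictors)) paste(last$predictors, collapse = " + ")
      else "1", "\n", sep = "")
  cat(sprintf("  R2 = %.3f, adj R2 = %.3f, F(%g, %g) = %.3f, p = %.4f\n",
              last$r_squared, last$adj_r_squared, last$df[1L], last$df[2L],
              last$f_statistic, last$p))
  invisible(x)
}

#' Tidy summary of a stepwise fit
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return A data frame with one row per predictor per model step
#'   (`model_step`, `predictor`, `beta`, `std_beta`, `R2`, `adjR2`, `F`,
#'   `df1`, `df2`, `p`).
#' @export
as.data.frame.stepwise_fit <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$models), function(k) {
    m <- x$models[[k]]
    preds <- if (length(m$predictors)) m$predictors else "(intercept only)"
    data.frame(model_step = k, predictor = preds,
               beta = if (length(m$predictors))
                 unname(m$coefficients[m$predictors]) else NA_real_,
               std_beta = if (length(m$predictors))
                 unname(m$std_beta[m$predictors]) else NA_real_,
               R2 = m$r_squared, adjR2 = m$adj_r_squared,
               F = m$f_statistic, df1 = m$df[1L], df2 = m$df[2L], p = m$p,
               stringsAsFactors = FALSE)
  }))
}

#' Hierarchical quadratic age model
#'
#' Fits `y ~ age` and `y ~ age + age^2` and reports the R-squared change and
#' F-change test for the quadratic term, testing an inverted-U (or U-shaped)
#' relation of a network measure with age.
#'
#' @param age Numeric age vector.
#' @param y Numeric response vector of equal length.
#' @return A list with `model1`, `model2` (model records), `fits` (the two
#'   `lm` objects), `delta_r2`, `f_change`, `df_change`, `p_change`.
#' @export
hierarchical_quadratic <- function(age, y) {
  if (length(age) != length(y)) stop("age and y must have equal length")
  if (length(age) < 5L) stop("need at least 5 observations")
  if (sd(age) == 0) stop("constant age vector")
  d <- data.frame(age = age, age2 = age^2, y = y)
  f1 <- lm(y ~ age, data = d)
  f2 <- lm(y ~ age + age2, data = d)
  an <- anova(f1, f2)
  m1 <- model_record(f1, d, "y", 1L)
  m2 <- model_record(f2, d, "y", 2L)
  list(model1 = m1, model2 = m2, fits = list(f1, f2),
       delta_r2 = m2$r_squared - m1$r_squared,
       f_change = an$F[2L], df_change = c(an$Df[2L], an$Res.Df[2L]),
       p_change = an[["Pr(>F)"]][2L])
}

#' Leave-one-out cross-validated coefficient of determination
#'
#' For each observation, fits the linear model on the remaining `n - 1`
#' rows and predicts the held-out response; the cross-validated R-squared
#' (percent scale) is `100 * (1 - sum((y - yhat)^2) / sum(y^2))` with the
#' uncentered denominator. Perfect prediction yields 100; an all-zero
#' predictor yields 0.
#'
#' @param X A data frame or matrix of predictors.
#' @param y Numeric response vector.
#' @return The cross-validated R-squared on the percent scale.
#' @export
loocv_r2 <- function(X, y) {
  X <- as.data.frame(X)
  n <- nrow(X)
  if (length(y) != n) stop("X and y must have matching rows")
  if (n < 3L) stop("need at least 3 observations")
  d <- cbind(X, .y = y)
  preds <- names(X)
  yhat <- numeric(n)
  for (i in seq_len(n)) {
    fit <- lm(reformulate(preds, response = ".y"), data = d[-i, , drop = FALSE])
    if (fit$rank < length(preds) + 1L) {
      stop("singular leave-one-out design at fold ", i)
    }
    yhat[i] <- predict(fit, newdata = d[i, , drop = FALSE])
  }
  100 * (1 - sum((y - yhat)^2) / sum(y^2))
}
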