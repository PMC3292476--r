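# Logistic regression scoring and the training machinery: maximum-likelihood
# fitting (IRLS via stats::glm), AIC-guided stepwise selection, likelihood-
# ratio-guided dropping of non-significant terms, case-resampling bootstrap
# confidence intervals, and repeated split-half cross-validation.

#' Construct a logistic model
#'
#' @param variables character vector of covariate names.
#' @param intercept intercept term.
#' @param coefficients numeric vector, one per variable.
#' @param platform free-text platform tag.
#' @param provenance free-text training provenance.
#' @return a `logistic_model`.
#' @export
logistic_model <- function(variables, intercept, coefficients,
                           platform = "generic", provenance = "") {
  variables <- as.character(variables)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != length(variables)) {
    stop("coefficients and variables differ in length")
  }
  if (!all(is.finite(c(intercept, coefficients)))) {
    stop("model terms must all be finite")
  }
  structure(list(variables = variables, intercept = as.numeric(intercept),
                 coefficients = coefficients, platform = platform,
                 provenance = provenance),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("logistic_model (", x$platform, "): intercept ",
      format(x$intercept, digits = 4), "\n", sep = "")
  for (i in seq_along(x$variables)) {
    cat("  ", format(x$variables[i], width = 24),
        format(x$coefficients[i], digits = 4), "\n")
  }
  invisible(x)
}

#' Score candidates with a logistic model
#'
#' p = 1 / (1 + exp(-(intercept + sum beta_i x_i))): the modeled probability
#' that the candidate is a true variant.
#'
#' @param model a [logistic_model()].
#' @param features data.frame/data.table (one row per candidate) or a named
#'   numeric vector providing every model variable.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
lr_score <- function(model, features) {
  stopifnot(inherits(model, "logistic_model"))
  if (is.numeric(features) && !is.null(names(features))) {
    features <- as.data.frame(as.list(features))
  }
  missing <- setdiff(model$variables, names(features))
  if (length(missing)) {
    stop("features missing model variable(s): ", paste(missing, collapse = ", "))
  }
  x <- as.matrix(as.data.frame(features)[, model$variables, drop = FALSE])
  drop(plogis(model$intercept + x %*% model$coefficients))
}

.label_to_binary <- function(label) {
  if (is.character(label) || is.factor(label)) {
    label <- as.character(label)
    if (!all(label %in% c("TP", "FP"))) stop("labels must be TP/FP")
    return(as.integer(label == "TP"))
  }
  as.integer(label)
}

.glm_formula <- function(variables, df, label_col = ".y") {
  f <- if (!length(variables)) {
    as.formula(paste(label_col, "~ 1"))
  } else {
    as.formula(paste(label_col, "~",
                     paste(sprintf("`%s`", variables), collapse = " + ")))
  }
  # step()/drop1() re-evaluate the glm call later; the formula environment
  # must keep the data alive
  e <- new.env(parent = globalenv())
  e$df <- df
  environment(f) <- e
  f
}

.check_fit_health <- function(fit, y) {
  cf <- coef(fit)
  if (any(is.na(cf))) {
    stop("singular design: collinear variable(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  mu <- fit$fitted.values
  if (length(unique(y)) == 2L &&
      min(mu[y == 1L]) > 1 - 1e-8 && max(mu[y == 0L]) < 1e-8) {
    stop("perfect separation: the classes are linearly separable; ",
         "maximum-likelihood coefficients diverge")
  }
  invisible(fit)
}

#' Fit a logistic regression model by maximum likelihood
#'
#' Iteratively reweighted least squares (log-likelihood tolerance 1e-8,
#' at most 100 iterations), reporting Wald z and two-sided p per coefficient.
#' Perfectly separated data and singular designs are rejected with a
#' diagnostic.
#'
#' @param data data.frame/data.table holding the variables and a label
#'   column ("TP"/"FP" or 0/1).
#' @param variables covariates to fit.
#' @param label_col name of the label column.
#' @param platform,provenance stored in the resulting model.
#' @return an `lr_fit`: list(model, summary (term/estimate/z/p), aic, n,
#'   glm).
#' @export
lr_fit <- function(data, variables, label_col = "label",
                   platform = "generic", provenance = "fit on user data") {
  data <- as.data.frame(data)
  y <- .label_to_binary(data[[label_col]])
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    stop("need at least 2 examples of each class")
  }
  for (v in variables) {
    if (length(unique(data[[v]])) < 2L) stop("constant variable: ", v)
  }
  df <- data.frame(.y = y, data[, variables, drop = FALSE], check.names = FALSE)
  fit <- suppressWarnings(glm(.glm_formula(variables, df),
                              family = binomial(), data = df,
                              control = list(epsilon = 1e-8, maxit = 100L)))
  .check_fit_health(fit, y)
  cf <- summary(fit)$coefficients
  terms_ <- setdiff(rownames(cf), "(Intercept)")
  terms_clean <- gsub("`", "", terms_)
  model <- logistic_model(terms_clean, cf["(Intercept)", 1L],
                          cf[terms_, 1L], platform, provenance)
  structure(list(model = model,
                 summary = data.table::data.table(
                   term = c("(Intercept)", terms_clean),
                   estimate = cf[, 1L], z = cf[, 3L], p = cf[, 4L]),
                 aic = fit$aic, n = nrow(df), glm = fit),
            class = "lr_fit")
}

#' @export
print.lr_fit <- function(x, ...) {
  cat("lr_fit on n =", x$n, " AIC =", format(x$aic, digits = 6), "\n")
  print(x$summary)
  invisible(x)
}

#' AIC-guided bidirectional stepwise variable selection
#'
#' Starts from the full model over `candidate_variables` and applies
#' bidirectional stepwise search, returning the AIC-minimal model visited.
#' Deterministic for a given input.
#'
#' @inheritParams lr_fit
#' @param candidate_variables variables to search over (>= 2).
#' @return an `lr_fit` on the selected variables.
#' @export
stepwise_select <- function(data, candidate_variables, label_col = "label",
                            platform = "generic",
                            provenance = "stepwise-selected") {
  if (length(candidate_variables) < 2L) stop("need >= 2 candidate variables")
  data <- as.data.frame(data)
  y <- .label_to_binary(data[[label_col]])
  df <- data.frame(.y = y, data[, candidate_variables, drop = FALSE],
                   check.names = FALSE)
  full <- suppressWarnings(glm(.glm_formula(candidate_variables, df),
                               family = binomial(), data = df,
                               control = list(epsilon = 1e-8, maxit = 100L)))
  sel <- suppressWarnings(step(full, direction = "both", trace = 0))
  kept <- gsub("`", "", attr(stats::terms(sel), "term.labels"))
  if (!length(kept)) {
    cf <- coef(sel)
    return(structure(list(
      model = logistic_model(character(), cf[["(Intercept)"]], numeric(),
                             platform, provenance),
      summary = data.table::data.table(term = "(Intercept)",
                                       estimate = cf[["(Intercept)"]],
                                       z = NA_real_, p = NA_real_),
      aic = sel$aic, n = nrow(df), glm = sel), class = "lr_fit"))
  }
  lr_fit(data, kept, label_col, platform, provenance)
}

#' Drop variables lacking likelihood-ratio significance
#'
#' Repeatedly removes the term with the largest likelihood-ratio p-value
#' while that p-value exceeds `alpha`, refitting after each removal.
#' Idempotent: a model whose every term is significant is returned unchanged.
#'
#' @param fit an `lr_fit`.
#' @param data the training data the fit was computed on.
#' @param alpha significance threshold.
#' @param label_col name of the label column.
#' @return an `lr_fit` on the retained variables.
#' @export
drop_nonsignificant <- function(fit, data, alpha = 0.05,
                                label_col = "label") {
  stopifnot(inherits(fit, "lr_fit"))
  vars <- fit$model$variables
  current <- fit
  repeat {
    if (!length(vars)) break
    d1 <- suppressWarnings(drop1(current$glm, test = "LRT"))
    p <- d1[["Pr(>Chi)"]][-1L]
    names(p) <- gsub("`", "", rownames(d1)[-1L])
    if (!length(p) || all(p <= alpha, na.rm = TRUE)) break
    worst <- names(p)[which.max(p)]
    vars <- setdiff(vars, worst)
    if (!length(vars)) {
      y <- .label_to_binary(as.data.frame(data)[[label_col]])
      df <- data.frame(.y = y)
      g <- glm(.y ~ 1, family = binomial(), data = df)
      return(structure(list(
        model = logistic_model(character(), coef(g)[[1L]], numeric(),
                               fit$model$platform, "all terms dropped"),
        summary = data.table::data.table(term = "(Intercept)",
                                         estimate = coef(g)[[1L]],
                                         z = NA_real_, p = NA_real_),
        aic = g$aic, n = nrow(df), glm = g), class = "lr_fit"))
    }
    current <- lr_fit(data, vars, label_col, fit$model$platform,
                      fit$model$provenance)
  }
  current
}

.curve_at_cutoffs <- function(p, y, cutoffs) {
  # precision/sensitivity at each cutoff; precision is NA when nothing is
  # called positive
  prec <- sens <- numeric(length(cutoffs))
  npos <- sum(y == 1L)
  for (k in seq_along(cutoffs)) {
    call <- p >= cutoffs[k]
    tp <- sum(call & y == 1L)
    prec[k] <- if (any(call)) tp / sum(call) else NA_real_
    sens[k] <- if (npos) tp / npos else NA_real_
  }
  list(precision = prec, sensitivity = sens)
}

#' Repeated split-half cross-validation of a logistic model
#'
#' Per replicate: sample half the rows, refit on that half, score the
#' held-out half, and record precision TP/(TP+FP) and sensitivity
#' TP/(TP+FN) at every cutoff in the grid. The mean curve is the pointwise
#' mean over replicates; the full-data curve fits and evaluates on all rows.
#' An overfit model shows high replicate dispersion and a mean curve far
#' from the full-data curve; a well-specified one matches it closely.
#'
#' @inheritParams lr_fit
#' @param reps number of replicates (>= 2).
#' @param split training fraction per replicate.
#' @param cutoff_grid probability cutoffs for the curves.
#' @param seed RNG seed.
#' @return a `cv_result`: cutoffs, per-replicate precision/sensitivity
#'   matrices, mean and full-data curves, n_replicates, seed.
#' @export
cross_validate <- function(data, variables, reps = 100L, split = 0.5,
                           cutoff_grid = seq(0, 1, by = 0.01), seed = 1L,
                           label_col = "label") {
  if (reps < 2L) stop("reps must be >= 2")
  data <- as.data.frame(data)
  y <- .label_to_binary(data[[label_col]])
  n <- nrow(data)
  x <- as.matrix(data[, variables, drop = FALSE])
  set.seed(seed)
  K <- length(cutoff_grid)
  prec <- matrix(NA_real_, reps, K)
  sens <- matrix(NA_real_, reps, K)
  n_train <- max(2L, floor(n * split))
  for (r in seq_len(reps)) {
    repeat {
      idx <- sample.int(n, n_train)
      y_tr <- y[idx]; y_te <- y[-idx]
      if (length(unique(y_tr)) == 2L && length(unique(y_te)) == 2L) break
    }
    g <- suppressWarnings(glm.fit(cbind(1, x[idx, , drop = FALSE]), y_tr,
                                  family = binomial(),
                                  control = list(epsilon = 1e-8, maxit = 100L)))
    cf <- ifelse(is.na(g$coefficients), 0, g$coefficients)
    p_te <- drop(plogis(cbind(1, x[-idx, , drop = FALSE]) %*% cf))
    cur <- .curve_at_cutoffs(p_te, y_te, cutoff_grid)
    prec[r, ] <- cur$precision
    sens[r, ] <- cur$sensitivity
  }
  full <- suppressWarnings(glm.fit(cbind(1, x), y, family = binomial(),
                                   control = list(epsilon = 1e-8, maxit = 100L)))
  cf <- ifelse(is.na(full$coefficients), 0, full$coefficients)
  p_all <- drop(plogis(cbind(1, x) %*% cf))
  fc <- .curve_at_cutoffs(p_all, y, cutoff_grid)
  structure(list(cutoffs = cutoff_grid,
                 replicate_precision = prec, replicate_sensitivity = sens,
                 mean_precision = colMeans(prec, na.rm = TRUE),
                 mean_sensitivity = colMeans(sens, na.rm = TRUE),
                 full_precision = fc$precision,
                 full_sensitivity = fc$sensitivity,
                 n_replicates = as.integer(reps), seed = as.integer(seed)),
            class = "cv_result")
}

#' Bootstrap confidence intervals for model coefficients
#'
#' Case-resampling bootstrap with percentile intervals (via boot/boot.ci).
#' Fails loudly when more than 10% of replicates do not converge —
#' unreasonably wide or unstable intervals are an overfitting signal and are
#' surfaced, never hidden.
#'
#' @inheritParams lr_fit
#' @param reps bootstrap replicates.
#' @param level confidence level.
#' @param seed RNG seed.
#' @return data.table: term, estimate, lower, upper; attribute
#'   `n_failed` gives the number of non-converged replicates.
#' @export
bootstrap_ci <- function(data, variables, reps = 1000L, level = 0.95,
                         seed = 1L, label_col = "label") {
  data <- as.data.frame(data)
  y <- .label_to_binary(data[[label_col]])
  x <- cbind(`(Intercept)` = 1, as.matrix(data[, variables, drop = FALSE]))
  point <- lr_fit(data, variables, label_col)  # errors if the full fit fails
  stat <- function(d, i) {
    out <- tryCatch({
      g <- suppressWarnings(glm.fit(x[i, , drop = FALSE], y[i],
                                    family = binomial(),
                                    control = list(epsilon = 1e-8,
                                                   maxit = 100L)))
      if (!g$converged || any(is.na(g$coefficients))) rep(NA_real_, ncol(x))
      else g$coefficients
    }, error = function(e) rep(NA_real_, ncol(x)))
    out
  }
  set.seed(seed)
  bo <- boot::boot(data.frame(i = seq_along(y)), statistic = stat, R = reps)
  failed <- sum(!stats::complete.cases(bo$t))
  if (failed > 0.1 * reps) {
    stop(failed, "/", reps, " bootstrap replicates failed to converge; ",
         "the model is likely overfit (expect unreasonably wide intervals)")
  }
  est <- c(point$model$intercept, point$model$coefficients)
  terms_ <- c("(Intercept)", variables)
  lower <- upper <- numeric(length(terms_))
  ok <- stats::complete.cases(bo$t)
  for (j in seq_along(terms_)) {
    if (failed == 0L) {
      ci <- boot::boot.ci(bo, conf = level, type = "perc", index = j)
      lower[j] <- ci$percent[4L]; upper[j] <- ci$percent[5L]
    } else {
      qs <- quantile(bo$t[ok, j], c((1 - level) / 2, 1 - (1 - level) / 2),
                     type = 6, names = FALSE)
      lower[j] <- qs[1L]; upper[j] <- qs[2L]
    }
  }
  out <- data.table::data.table(term = terms_, estimate = est,
                                lower = lower, upper = upper)
  viol <- out$estimate < out$lower | out$estimate > out$upper
  if (any(viol)) {
    warning("bootstrap interval excludes the point estimate for: ",
            paste(out$term[viol], collapse = ", "))
  }
  data.table::setattr(out, "n_failed", failed)
  out
}

#' Save / load a logistic model as JSON
#'
#' The JSON schema is \{variables, intercept, coefficients, platform,
#' provenance\}; loading validates lengths and finiteness, and a loaded
#' model scores bit-identically to the saved one.
#'
#' @param model a [logistic_model()].
#' @param path JSON file path.
#' @return `path` / the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "logistic_model"))
  jsonlite::write_json(
    list(variables = model$variables, intercept = model$intercept,
         coefficients = model$coefficients, platform = model$platform,
         provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("variables", "intercept", "coefficients")
  if (!all(need %in% names(x))) {
    stop("model file missing field(s): ",
         paste(setdiff(need, names(x)), collapse = ", "))
  }
  logistic_model(as.character(x$variables), x$intercept,
                 as.numeric(x$coefficients),
                 platform = x$platform %||% "generic",
                 provenance = x$provenance %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
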