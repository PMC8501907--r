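# FitResult container and the multi-start nonlinear least-squares engine.
#
# All fitting functions in the package return a "photofit_fit" object: model
# id, parameter estimates with standard errors, goodness-of-fit statistics
# (SSR, AIC, BIC), the observation and fitted-value table, and a plot
# builder. broom-style tidy()/glance()/augment() methods and a ggplot2
# autoplot() method are provided.

new_fit_result <- function(model, coefs, data = NULL, fitted = NULL,
                           stats = list(), extra = list(), fit = NULL,
                           plot_builder = NULL) {
  structure(
    list(model = model, coefs = coefs, data = data, fitted = fitted,
         stats = stats, extra = extra, fit = fit,
         plot_builder = plot_builder),
    class = "photofit_fit"
  )
}

failed_fit_result <- function(model, message, data = NULL, diagnostics = NULL) {
  new_fit_result(
    model = model,
    coefs = tibble(term = character(), estimate = double(),
                   std.error = double()),
    data = data,
    stats = list(converged = FALSE, failed = TRUE, message = message,
                 diagnostics = diagnostics)
  )
}

#' @export
print.photofit_fit <- function(x, ...) {
  cat("<photofit fit: ", x$model, ">\n", sep = "")
  if (isTRUE(x$stats$failed)) {
    cat("FAILED: ", x$stats$message, "\n", sep = "")
    return(invisible(x))
  }
  print(x$coefs)
  cat(sprintf("SSR = %.6g, AIC = %.6g, BIC = %.6g, n = %d\n",
              x$stats$ssr %||% NA_real_, x$stats$aic %||% NA_real_,
              x$stats$bic %||% NA_real_, x$stats$n %||% NA_integer_))
  if (length(x$stats$flags)) {
    cat("flags:", paste(x$stats$flags, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Tidy the parameter estimates of a photofit fit
#'
#' @param x a `photofit_fit` object.
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `std.error` (and any
#'   model-specific extras such as derived parameters).
#' @export
tidy.photofit_fit <- function(x, ...) {
  x$coefs
}

#' One-row goodness-of-fit summary of a photofit fit
#'
#' @param x a `photofit_fit` object.
#' @param ... unused.
#' @return A one-row tibble: `model`, `ssr`, `aic`, `bic`, `n`, `converged`.
#' @export
glance.photofit_fit <- function(x, ...) {
  tibble(
    model = x$model,
    ssr = x$stats$ssr %||% NA_real_,
    aic = x$stats$aic %||% NA_real_,
    bic = x$stats$bic %||% NA_real_,
    n = x$stats$n %||% NA_integer_,
    converged = isTRUE(x$stats$converged)
  )
}

#' Observation-level fitted values and residuals
#'
#' @param x a `photofit_fit` object.
#' @param ... unused.
#' @return The observation table with `.fitted` and `.resid` columns.
#' @export
augment.photofit_fit <- function(x, ...) {
  x$fitted
}

#' Plot a photofit fit
#'
#' Each fit type draws its standard diagnostic figure: data with the fitted
#' curve (and a standard-error band where available), the limitation-state
#' overlay for CO2-response fits, or the reliability scatter for variable-J
#' mesophyll-conductance output.
#'
#' @param object a `photofit_fit` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.photofit_fit <- function(object, ...) {
  if (!is.null(object$plot_builder)) return(object$plot_builder(object))
  stopifnot(!is.null(object$fitted))
  ggplot(object$fitted, aes(x = .data$.fitted, y = .data$.fitted + .data$.resid)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    geom_point() +
    labs(x = "fitted", y = "observed", title = object$model) +
    theme_bw()
}

coef_table <- function(fit) {
  # nls/lm summary can fail on singular gradients; keep estimates, NA the SEs
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  tibble(term = names(est), estimate = unname(est),
         std.error = unname(se[names(est)]))
}

fit_stats <- function(fit, n) {
  list(ssr = deviance(fit), aic = AIC(fit), bic = BIC(fit), n = n,
       converged = TRUE, failed = FALSE)
}

flag_large_se <- function(coefs) {
  # very large standard errors usually indicate an unreliable fit
  bad <- is.finite(coefs$std.error) & is.finite(coefs$estimate) &
    abs(coefs$estimate) > 0 & coefs$std.error / abs(coefs$estimate) > 1
  if (any(bad)) {
    terms <- coefs$term[bad]
    warn(paste0("parameter(s) ", paste(terms, collapse = ", "),
                " have standard errors larger than their estimates; ",
                "the fit is likely unreliable or unidentifiable"))
    paste0("large_se:", paste(terms, collapse = ","))
  } else {
    character(0)
  }
}

#' Build a grid of starting values around a central guess
#'
#' Multi-start nonlinear fitting needs a spread of starting values per
#' parameter. For each parameter this spans `n` multiplicative (log-spaced)
#' steps around the central guess for positive parameters, or additive steps
#' for signed/zero-valued ones, and crosses them into a grid capped at
#' `max_starts` rows.
#'
#' @param center named list/vector of central guesses.
#' @param n points per parameter (default 5).
#' @param span multiplicative half-range (default 4: guesses from center/4 to
#'   center*4).
#' @param max_starts cap on the number of starting points (default 500).
#' @param shuffle_seed optional integer; when given, start order is shuffled
#'   reproducibly before capping.
#' @return A data frame of starting values, one row per start.
#' @export
make_start_grid <- function(center, n = 5, span = 4, max_starts = 500,
                            shuffle_seed = NULL) {
  axes <- lapply(center, function(v) {
    if (is.finite(v) && v > 0) {
      exp(seq(log(v / span), log(v * span), length.out = n))
    } else if (is.finite(v) && v < 0) {
      -exp(seq(log(abs(v) / span), log(abs(v) * span), length.out = n))
    } else {
      seq(-1, 1, length.out = n)
    }
  })
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(center)
  if (!is.null(shuffle_seed)) {
    grid <- grid[sample_order(nrow(grid), shuffle_seed), , drop = FALSE]
  }
  utils::head(grid, max_starts)
}

# permutation of 1..n reproducible from a seed, without touching the global RNG
sample_order <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(n)
}

#' Nonlinear least squares with looped starting values
#'
#' Fits `formula` to `data` by Levenberg-Marquardt least squares
#' ([minpack.lm::nlsLM()]), restarted from every row of `start_grid`, and
#' keeps the converged fit with the lowest sum of squared residuals. Looping
#' the starting values makes the nonlinear fits robust to the local minima
#' and flat regions typical of photosynthetic response surfaces.
#'
#' @param formula model formula for `nlsLM`.
#' @param data data frame of observations.
#' @param start_grid data frame of starting values (one row per start), e.g.
#'   from [make_start_grid()].
#' @param lower,upper optional parameter bounds (named, recycled by position).
#' @param max_iter maximum iterations per start (default 1000).
#' @param ftol relative SSR convergence tolerance (default 1e-8).
#' @return The best `nls` fit with attributes `n_tried`/`n_converged`, or
#'   `NULL` if no start converged.
#' @export
fit_nls_multistart <- function(formula, data, start_grid, lower = NULL,
                               upper = NULL, max_iter = 1000, ftol = 1e-8) {
  best <- NULL
  best_ssr <- Inf
  n_conv <- 0L
  ctrl <- minpack.lm::nls.lm.control(maxiter = min(max_iter, 1024),
                                     ftol = ftol)
  p <- ncol(start_grid)
  pars <- names(start_grid)
  expand_bound <- function(b, default) {
    if (is.null(b)) return(rep(default, p))
    if (is.null(names(b))) return(rep_len(b, p))
    out <- rep(default, p)
    out[match(names(b), pars)] <- b
    out
  }
  lower <- expand_bound(lower, -Inf)
  upper <- expand_bound(upper, Inf)
  for (i in seq_len(nrow(start_grid))) {
    start <- as.list(start_grid[i, , drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = data, start = start,
        lower = lower, upper = upper, control = ctrl)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      n_conv <- n_conv + 1L
      ssr <- deviance(fit)
      if (is.finite(ssr) && ssr < best_ssr) {
        best <- fit
        best_ssr <- ssr
      }
    }
  }
  if (!is.null(best)) {
    attr(best, "n_tried") <- nrow(start_grid)
    attr(best, "n_converged") <- n_conv
  }
  best
}

# standard-error band for a fitted curve by the delta method
predict_se_band <- function(predict_fn, est, vc, newdata) {
  pred <- predict_fn(est, newdata)
  if (is.null(vc) || any(!is.finite(vc))) {
    return(tibble(fit = pred, se = NA_real_))
  }
  p <- length(est)
  se <- vapply(seq_along(pred), function(i) {
    g <- vapply(seq_len(p), function(j) {
      h <- max(abs(est[j]) * 1e-6, 1e-8)
      e2 <- est; e2[j] <- e2[j] + h
      (predict_fn(e2, newdata)[i] - pred[i]) / h
    }, numeric(1))
    v <- drop(t(g) %*% vc %*% g)
    if (v < 0) NA_real_ else sqrt(v)
  }, numeric(1))
  tibble(fit = pred, se = se)
}
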