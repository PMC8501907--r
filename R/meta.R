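# Meta-functions: group-wise batch fitting, output compilation, and local
# one/two-factor sensitivity analysis of any fitting function. These are
# deliberately generic - any function with the (data, ...) -> fit contract
# can be scaled across groups or re-run across a grid of assumed inputs.

#' Fit a function once per group
#'
#' Splits `data` by the grouping columns and applies `fit_fn` independently
#' to each group. A group whose fit errors is recorded as a failure (with
#' its message) and does not stop the remaining groups.
#'
#' @param data data frame.
#' @param group_by character vector of grouping column names.
#' @param fit_fn a fitting function with signature `fit_fn(data, ...)` (any
#'   `fit_*` in this package, or compatible user code).
#' @param ... passed on to `fit_fn`.
#' @return An object of class `photofit_grouped`: `$fits` (named list, one
#'   entry per group, either the fit or `NULL`), `$groups` (key tibble with
#'   a `failed` flag), `$failures` (named list of error messages).
#' @examples
#' d <- generate_synthetic_curve(curve_design("aq", seed = 1, n_curves = 3))
#' fits <- fit_many(d, "curve_id", fit_aq_response)
#' compile_data(fits, "parameters")
#' @export
fit_many <- function(data, group_by, fit_fn, ...) {
  stopifnot(is.data.frame(data), length(group_by) >= 1)
  miss <- setdiff(group_by, names(data))
  if (length(miss)) {
    abort(paste0("grouping column(s) absent: ", paste(miss, collapse = ", ")))
  }
  keys <- distinct(data[, group_by, drop = FALSE])
  if (nrow(keys) == 0) abort("no groups to fit")
  key_label <- function(row) paste(unlist(row), collapse = ".")
  fits <- list()
  failures <- list()
  failed <- logical(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- rep(TRUE, nrow(data))
    for (g in group_by) sel <- sel & data[[g]] == keys[[g]][i]
    lbl <- key_label(keys[i, ])
    res <- tryCatch(fit_fn(data[sel, , drop = FALSE], ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[lbl]] <- conditionMessage(res)
      fits[lbl] <- list(NULL)
      failed[i] <- TRUE
    } else {
      fits[[lbl]] <- res
    }
  }
  structure(list(fits = fits, groups = mutate(keys, failed = failed),
                 group_by = group_by, failures = failures),
            class = "photofit_grouped")
}

#' @export
print.photofit_grouped <- function(x, ...) {
  cat("<photofit grouped fits: ", nrow(x$groups), " group(s), ",
      length(x$failures), " failure(s)>\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' Compile grouped fits into one table (or list) per selector
#'
#' @param fits a `photofit_grouped` from [fit_many()].
#' @param selector `"parameters"` (tidy coefficient rows per group),
#'   `"fitted"` (observation-level fitted values per group), `"glance"`
#'   (one goodness-of-fit row per group) or `"graphs"` (named list of
#'   ggplot objects for [print_graphs()]).
#' @return A keyed tibble, or a named list of plots for `"graphs"`.
#' @export
compile_data <- function(fits, selector = c("parameters", "fitted",
                                            "glance", "graphs")) {
  if (!is.character(selector) || !selector[1] %in%
        c("parameters", "fitted", "glance", "graphs")) {
    abort(paste0("unknown selector '", selector[1],
                 "'; options: parameters, fitted, glance, graphs"))
  }
  selector <- selector[1]
  ok <- !vapply(fits$fits, is.null, TRUE)
  keyed <- function(extract) {
    rows <- lapply(which(ok), function(i) {
      bind_cols(fits$groups[i, fits$group_by, drop = FALSE],
                extract(fits$fits[[i]]))
    })
    bind_rows(rows)
  }
  flatten_fit <- function(f, extract) {
    # single fits and multi-model collections both compile
    if (inherits(f, "photofit_fits")) {
      bind_rows(lapply(f, extract))
    } else extract(f)
  }
  switch(selector,
    parameters = keyed(function(f) flatten_fit(f, function(g) {
      mutate(tidy(g), model = g$model, .before = 1)
    })),
    fitted = keyed(function(f) flatten_fit(f, function(g) {
      if (is.null(g$fitted)) tibble() else mutate(g$fitted, model = g$model)
    })),
    glance = keyed(function(f) flatten_fit(f, glance)),
    graphs = {
      plots <- lapply(fits$fits[ok], function(f) {
        if (inherits(f, "photofit_fits")) lapply(f, autoplot)
        else autoplot(f)
      })
      # flatten one level for multi-model fits
      out <- list()
      for (nm in names(plots)) {
        p <- plots[[nm]]
        if (inherits(p, "ggplot")) out[[nm]] <- p
        else for (m in names(p)) out[[paste(nm, m, sep = ".")]] <- p[[m]]
      }
      out
    }
  )
}

# pull a one-row wide tibble of outputs from whatever a fit function returns
.sensitivity_outputs <- function(res) {
  if (is.numeric(res) && length(res) == 1 && is.null(dim(res))) {
    return(tibble(value = unname(res)))
  }
  if (inherits(res, "photofit_fits")) {
    res <- res[[1]]
  }
  if (inherits(res, "photofit_fit")) {
    td <- tidy(res)
    return(tibble::as_tibble(as.list(setNames(td$estimate, td$term))))
  }
  if (is.list(res) && !is.null(res$coefs)) {
    return(tibble::as_tibble(as.list(setNames(res$coefs$estimate,
                                              res$coefs$term))))
  }
  abort("cannot extract outputs from the fit function's return value")
}

#' Re-run a fitting function over a grid of assumed inputs
#'
#' Varies one or two assumed-input arguments of `fit_fn` (e.g. the fixed
#' mesophyll conductance or Gamma* in A-Ci fitting) over the Cartesian
#' product of the supplied levels, refitting at every grid point and
#' recording the fitted outputs. A failed grid-point fit is recorded (NA
#' outputs plus message) and the grid completes.
#'
#' @param data data frame passed to `fit_fn`.
#' @param fit_fn fitting function with signature `fit_fn(data, ...)`.
#' @param factors named list of 1 or 2 numeric vectors; the names must be
#'   argument names of `fit_fn`.
#' @param ... further fixed arguments for `fit_fn`.
#' @return A `photofit_sensitivity` tibble: one row per grid point, the
#'   factor columns first, then one column per fitted output, plus
#'   `fit_failed`/`fail_message`.
#' @export
analyze_sensitivity <- function(data, fit_fn, factors, ...) {
  if (length(factors) < 1 || length(factors) > 2) {
    abort("sensitivity analysis takes 1 or 2 factors")
  }
  if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
    abort("`factors` must be a named list of value vectors")
  }
  grid <- tibble::as_tibble(expand.grid(factors, KEEP.OUT.ATTRS = FALSE))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    args <- c(list(data), as.list(grid[i, , drop = FALSE]), list(...))
    res <- tryCatch(do.call(fit_fn, args), error = function(e) e)
    if (inherits(res, "error")) {
      bind_cols(grid[i, , drop = FALSE],
                tibble(fit_failed = TRUE,
                       fail_message = conditionMessage(res)))
    } else {
      bind_cols(grid[i, , drop = FALSE], .sensitivity_outputs(res),
                tibble(fit_failed = FALSE, fail_message = NA_character_))
    }
  })
  out <- bind_rows(rows)
  attr(out, "factors") <- names(factors)
  class(out) <- c("photofit_sensitivity", class(out))
  out
}

#' Local sensitivity measures against a reference grid point
#'
#' Adds two reference-normalized local sensitivity measures to a grid from
#' [analyze_sensitivity()]: the parameter effect
#' `PE_i = (m_i - m_ref) / m_ref`, the relative change of the fitted output
#' against its value at the user-defined reference inputs; and, per varied
#' factor `p`, the control coefficient
#' `CE_i = PE_i / ((p_i - p_ref) / p_ref)`, the finite-difference
#' elasticity of the output to that input. The reference row has `PE = 0`
#' and an undefined (NA) control coefficient.
#'
#' @param table a `photofit_sensitivity` grid.
#' @param ref named list of reference values, one per factor; every value
#'   must appear among that factor's grid levels.
#' @param output name of the output column to analyze (default: the first
#'   output column).
#' @return The grid with added columns `parameter_effect`,
#'   `control_coefficient_<factor>` (one per factor) and `is_reference`.
#' @export
compute_sensitivity <- function(table, ref, output = NULL) {
  factors <- attr(table, "factors")
  if (is.null(factors)) abort("`table` must come from analyze_sensitivity()")
  if (!setequal(names(ref), factors)) {
    abort(paste0("`ref` must name exactly the varied factors: ",
                 paste(factors, collapse = ", ")))
  }
  for (f in factors) {
    if (!any(abs(table[[f]] - ref[[f]]) < 1e-12)) {
      abort(paste0("reference value ", ref[[f]], " for '", f,
                   "' is not on the grid"))
    }
  }
  out_cols <- setdiff(names(table),
                      c(factors, "fit_failed", "fail_message"))
  out_cols <- out_cols[vapply(table[out_cols], is.numeric, TRUE)]
  if (is.null(output)) output <- out_cols[1]
  if (!output %in% names(table)) {
    abort(paste0("no output column '", output, "'; available: ",
                 paste(out_cols, collapse = ", ")))
  }
  is_ref <- rep(TRUE, nrow(table))
  for (f in factors) is_ref <- is_ref & abs(table[[f]] - ref[[f]]) < 1e-12
  if (sum(is_ref) != 1) {
    abort("expected exactly one reference row on the grid")
  }
  m_ref <- table[[output]][is_ref]
  tb <- table
  if (!is.finite(m_ref) || m_ref == 0) {
    warn("fitted output is zero or missing at the reference point: parameter effect undefined")
    tb$parameter_effect <- NA_real_
  } else {
    tb$parameter_effect <- (tb[[output]] - m_ref) / m_ref
  }
  for (f in factors) {
    rel_step <- (tb[[f]] - ref[[f]]) / ref[[f]]
    ce <- tb$parameter_effect / rel_step
    ce[abs(rel_step) < 1e-15] <- NA_real_
    tb[[paste0("control_coefficient_", f)]] <- ce
  }
  tb$is_reference <- is_ref
  attr(tb, "factors") <- factors
  attr(tb, "output") <- output
  tb
}

#' Heat map of control coefficients over a two-factor sensitivity grid
#'
#' @param table output of [compute_sensitivity()] on a two-factor grid.
#' @param factor which factor's control coefficient to map (default the
#'   first).
#' @return A ggplot tile map.
#' @export
plot_sensitivity <- function(table, factor = NULL) {
  factors <- attr(table, "factors")
  stopifnot(length(factors) == 2)
  if (is.null(factor)) factor <- factors[1]
  col <- paste0("control_coefficient_", factor)
  ggplot(table, aes(x = .data[[factors[1]]], y = .data[[factors[2]]],
                    fill = .data[[col]])) +
    geom_tile() + theme_bw()
}
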