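#' Carbon-use efficiency of ensemble members
#'
#' Carbon-use efficiency (CUE) is the ratio of net to gross primary
#' production, NPP/GPP, computed per model and year.
#'
#' @param members Tibble with `model`, `year`, `gpp`, `npp`.
#' @return Tibble `model, year, cue`.
#' @export
carbon_use_efficiency <- function(members) {
  assert_columns(members, c("model", "year", "gpp", "npp"), "members")
  if (any(members$gpp <= 0)) abort("GPP must be > 0 in every year.")
  dplyr::transmute(members, model = .data$model, year = .data$year,
                   cue = .data$npp / .data$gpp)
}

#' Down-regulated NPP scenario
#'
#' Rebuilds an NPP trajectory in which each year's relative NPP increase is
#' a damped fraction of the concurrent relative GPP increase:
#' `NPP'(t) = NPP'(t-1) * (1 + damping * r(t))` with
#' `r(t) = GPP(t)/GPP(t-1) - 1`. With `damping = 1` NPP tracks GPP's
#' relative path exactly (constant CUE); with `damping = 0` NPP stays at
#' its initial value. A damping of 0.5 emulates the observed halving of the
#' growth response relative to photosynthesis under CO2 enrichment.
#'
#' @param gpp GPP series, Pg C/yr (> 0).
#' @param npp_initial NPP in the first year, Pg C/yr.
#' @param damping Fraction in \[0, 1\] of the relative GPP increase passed
#'   on to NPP.
#' @return Numeric NPP series of the same length as `gpp`.
#' @export
downregulate_npp <- function(gpp, npp_initial, damping = 0.5) {
  if (any(gpp <= 0)) abort("GPP must be > 0.")
  if (damping < 0 || damping > 1) abort("`damping` must lie in [0, 1].")
  n <- length(gpp)
  out <- numeric(n)
  out[1] <- npp_initial
  if (n > 1) {
    r <- gpp[-1] / gpp[-n] - 1
    out[-1] <- npp_initial * cumprod(1 + damping * r)
  }
  out
}

#' Multimodel bias statistics against a reference value
#'
#' Summarizes per-model scalars (e.g. each member's global vegetation
#' carbon change) as a multimodel mean with an n-1 standard deviation, and
#' the percent bias of the mean relative to an observational reference.
#'
#' @param values Per-model scalar values (length >= 2).
#' @param reference Reference value (e.g. a remote-sensing estimate).
#' @param statistic Optional name stored with the summary.
#' @return Object of class `ensemble_summary`; `tidy()`/`glance()` methods
#'   available.
#' @examples
#' # bias of the ensemble mean itself can be read off glance():
#' glance(ensemble_bias_stats(c(10, 15, 22), reference = 10.1))
#' @export
ensemble_bias_stats <- function(values, reference, statistic = NULL) {
  if (length(values) < 2) abort("Need at least two models.")
  if (reference == 0) abort("`reference` must be nonzero.")
  structure(
    list(values = values, mean = mean(values), sd = sd(values),
         n = length(values), reference = reference,
         bias_pct = 100 * (mean(values) - reference) / reference,
         statistic = statistic),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble%s: %.2f +/- %.2f (n = %d); reference %.2f; bias %+.1f%%\n",
              if (is.null(x$statistic)) "" else paste0(" ", x$statistic),
              x$mean, x$sd, x$n, x$reference, x$bias_pct))
  invisible(x)
}

r_squared <- function(x, y) cor(x, y)^2

#' Variance explained between paired diagnostics
#'
#' Squared Pearson correlation between paired values. In `cross_model` mode
#' the pairs are per-model scalars (e.g. each member's vegetation carbon
#' change against its cumulative NBP) and a seeded permutation test
#' supplies a p-value. In `within_model_spatial` mode the data hold
#' per-model grid-cell pairs; R-squared is computed per model and averaged
#' across members.
#'
#' @param data Tibble. For `cross_model`: one row per model with columns
#'   `x` and `y` (names via the `x`/`y` arguments). For
#'   `within_model_spatial`: columns `model` plus the two cell-level
#'   variables.
#' @param x,y Names of the paired columns.
#' @param mode `"cross_model"` or `"within_model_spatial"`.
#' @param n_perm Number of permutations for the p-value.
#' @param seed Integer seed for the permutation test.
#' @return One-row tibble. `cross_model`: `r_squared, p_value, n`.
#'   `within_model_spatial`: `r_squared_mean, r_squared_sd, n_models`,
#'   with per-model values in the `per_model` attribute.
#' @export
variance_explained <- function(data, x = "delta_cveg", y = "cum_nbp",
                               mode = c("cross_model",
                                        "within_model_spatial"),
                               n_perm = 1e4, seed = 1) {
  mode <- match.arg(mode)
  assert_columns(data, c(x, y), "data")
  check_var <- function(v, name) {
    if (length(v) < 3) abort("Need at least three pairs.")
    if (var(v) == 0) abort(sprintf("Zero variance in `%s`.", name))
    v
  }
  if (mode == "cross_model") {
    xv <- check_var(data[[x]], x)
    yv <- check_var(data[[y]], y)
    obs <- r_squared(xv, yv)
    set.seed(child_seed(seed, "variance_explained"))
    perm <- purrr::map_dbl(seq_len(n_perm),
                           function(i) r_squared(xv, sample(yv)))
    tibble::tibble(r_squared = obs,
                   p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
                   n = length(xv))
  } else {
    assert_columns(data, "model", "data")
    per_model <- data |>
      dplyr::group_by(.data$model) |>
      dplyr::summarise(
        r_squared = r_squared(check_var(.data[[x]], x),
                              check_var(.data[[y]], y)),
        .groups = "drop"
      )
    out <- tibble::tibble(
      r_squared_mean = mean(per_model$r_squared),
      r_squared_sd = if (nrow(per_model) > 1) sd(per_model$r_squared) else 0,
      n_models = nrow(per_model)
    )
    attr(out, "per_model") <- per_model
    out
  }
}
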