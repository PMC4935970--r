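#' Boltzmann's constant in electron-volts per kelvin
#'
#' @format Length-one numeric, 8.617e-5 eV/K.
#' @export
boltzmann_ev <- 8.617e-5

#' Build Arrhenius coordinates from richness and temperature
#'
#' The metabolic theory of ecology predicts that richness grows exponentially
#' with temperature: \eqn{\ln S = a - E_a / (kT)}. This function maps per-unit
#' richness estimates and mean annual temperatures (Celsius) onto the
#' coordinates of that line: `inv_kt` \eqn{= 1/(kT)} in 1/eV (with
#' \eqn{T} in kelvin, \eqn{k} = 8.617e-5 eV/K) and `log_richness`
#' \eqn{= \ln S}.
#'
#' @param data Data frame with one row per unit (sample or site).
#' @param richness Column of `data` holding richness estimates (>= 1), e.g.
#'   Chao1; tidy-eval.
#' @param temperature Column holding temperatures in degrees Celsius;
#'   tidy-eval.
#' @param unit Optional column of unit labels; tidy-eval.
#' @return Tibble with columns `unit`, `temperature_k`, `inv_kt`,
#'   `log_richness`.
#' @examples
#' d <- data.frame(site = c("a", "b"), chao1 = c(300, 500), temp = c(2.5, 25.7))
#' arrhenius_points(d, chao1, temp, unit = site)
#' @export
arrhenius_points <- function(data, richness, temperature, unit = NULL) {
  s <- dplyr::pull(data, {{ richness }})
  tc <- dplyr::pull(data, {{ temperature }})
  u <- tryCatch(dplyr::pull(data, {{ unit }}), error = function(e) NULL)
  if (is.null(u)) u <- as.character(seq_along(s))
  if (any(!is.finite(tc))) stop("temperatures must be finite", call. = FALSE)
  if (any(!is.finite(s)) || any(s < 1)) {
    stop("richness must be finite and >= 1 (log of smaller values is negative)",
      call. = FALSE
    )
  }
  tk <- tc + 273.15
  tibble::tibble(
    unit = as.character(u),
    temperature_k = tk,
    inv_kt = 1 / (boltzmann_ev * tk),
    log_richness = log(s)
  )
}

# Gaussian log-likelihood at the MLE residual variance (SS_res / n). Exact
# fits would send log(sigma2) to -Inf, so the variance is floored at machine
# precision relative to the response scale; numerically-exact fits of nested
# models then share one likelihood and differ only in the AIC penalty.
gaussian_loglik <- function(ss_res, n, y_scale = 1) {
  sigma2 <- max(ss_res / n, .Machine$double.eps * max(1, y_scale))
  -n / 2 * (log(2 * pi) + log(sigma2) + 1)
}

new_mte_fit <- function(form, coefficients, ea, points, fitted, n_params,
                        breakpoint = NA_real_) {
  y <- points$log_richness
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  ll <- gaussian_loglik(ss_res, length(y), mean(y^2))
  structure(
    list(
      form = form,
      coefficients = coefficients,
      ea = ea,
      breakpoint = breakpoint,
      r2 = r2,
      ss_res = ss_res,
      ss_tot = ss_tot,
      log_lik = ll,
      aic = -2 * ll + 2 * n_params,
      n_obs = length(y),
      n_params = n_params,
      data = points,
      fitted = fitted
    ),
    class = "mte_fit"
  )
}

#' Fit diversity-temperature models on Arrhenius coordinates
#'
#' Fits `log_richness` against `inv_kt` by ordinary least squares under one of
#' three forms:
#' \describe{
#'   \item{linear}{\eqn{y = a + b x}; the activation energy is the slope with
#'     sign reversed, \eqn{E_a = -b} (eV). 3 parameters (intercept, slope,
#'     residual variance).}
#'   \item{quadratic}{\eqn{y = a + b x + c x^2}; 4 parameters; no single
#'     activation energy is reported.}
#'   \item{piecewise}{continuous two-segment (hinge) model
#'     \eqn{y = a + b_1 x + b_2 (x - x_0)_+} with the breakpoint \eqn{x_0}
#'     chosen by grid search over interior x values (each candidate keeps at
#'     least two points per side) minimising the residual sum of squares;
#'     5 parameters.}
#' }
#' The AIC is \eqn{-2 \ln L + 2 n_{par}} with a Gaussian likelihood evaluated
#' at the maximum-likelihood residual variance; the residual variance counts
#' as a parameter, which shifts all fits on the same data equally and leaves
#' AIC differences untouched.
#'
#' @param points Tibble from [arrhenius_points()] (columns `inv_kt`,
#'   `log_richness`); minimum 3, 4 and 6 points for the three forms.
#' @param form One of `"linear"`, `"quadratic"`, `"piecewise"`.
#' @return An object of class `mte_fit`; see [tidy.mte_fit()] and
#'   [glance.mte_fit()].
#' @examples
#' pts <- tibble::tibble(inv_kt = 38:43, log_richness = 30 - 0.5 * (38:43))
#' fit <- fit_arrhenius(pts, "linear")
#' fit$ea # 0.5
#' @export
fit_arrhenius <- function(points, form = c("linear", "quadratic", "piecewise")) {
  form <- match.arg(form)
  stopifnot(all(c("inv_kt", "log_richness") %in% names(points)))
  x <- points$inv_kt
  y <- points$log_richness
  if (stats::sd(x) == 0) stop("inv_kt is constant: slope undefined", call. = FALSE)
  switch(form,
    linear = {
      if (length(x) < 3) stop("linear fit needs >= 3 points", call. = FALSE)
      fit <- stats::lm(y ~ x)
      cf <- stats::coef(fit)
      new_mte_fit(
        form, c(intercept = unname(cf[1]), slope = unname(cf[2])),
        ea = -unname(cf[2]), points = points, fitted = stats::fitted(fit),
        n_params = 3
      )
    },
    quadratic = {
      if (length(x) < 4) stop("quadratic fit needs >= 4 points", call. = FALSE)
      fit <- stats::lm(y ~ x + I(x^2))
      cf <- stats::coef(fit)
      if (anyNA(cf)) stop("rank-deficient design for quadratic fit", call. = FALSE)
      new_mte_fit(
        form, c(intercept = unname(cf[1]), b = unname(cf[2]), c = unname(cf[3])),
        ea = NA_real_, points = points, fitted = stats::fitted(fit),
        n_params = 4
      )
    },
    piecewise = {
      if (length(x) < 6) stop("piecewise fit needs >= 6 points", call. = FALSE)
      ux <- sort(unique(x))
      mids <- (ux[-1] + ux[-length(ux)]) / 2
      cand <- sort(unique(c(ux, mids)))
      cand <- cand[vapply(cand, function(b) {
        sum(x <= b) >= 2 && sum(x >= b) >= 2 && b > min(x) && b < max(x)
      }, logical(1))]
      if (length(cand) == 0) {
        stop("no breakpoint candidate leaves two points per side", call. = FALSE)
      }
      best <- NULL
      best_ss <- Inf
      for (b in cand) {
        hinge <- pmax(x - b, 0)
        fit <- stats::lm(y ~ x + hinge)
        ss <- sum(stats::resid(fit)^2)
        if (ss < best_ss - 1e-12) {
          best_ss <- ss
          best <- list(b = b, fit = fit)
        }
      }
      cf <- stats::coef(best$fit)
      cf[is.na(cf)] <- 0 # hinge collinear with x when data are a single line
      new_mte_fit(
        form,
        c(
          intercept = unname(cf[1]), slope_left = unname(cf[2]),
          slope_right = unname(cf[2] + cf[3])
        ),
        ea = NA_real_, points = points, fitted = unname(stats::fitted(best$fit)),
        n_params = 5, breakpoint = best$b
      )
    }
  )
}

#' @export
print.mte_fit <- function(x, ...) {
  cat("<mte_fit> form:", x$form, "\n")
  if (x$form == "linear") cat("  E_a =", format(x$ea, digits = 4), "eV\n")
  if (x$form == "piecewise") cat("  breakpoint =", format(x$breakpoint, digits = 4), "1/eV\n")
  cat(
    "  r2 =", format(x$r2, digits = 4), " AIC =", format(x$aic, digits = 5),
    " n =", x$n_obs, "\n"
  )
  invisible(x)
}

#' Tidy an Arrhenius model fit
#'
#' @param x An `mte_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term` and `estimate`.
#' @export
tidy.mte_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' One-row summary of an Arrhenius model fit
#'
#' @param x An `mte_fit`.
#' @param ... Unused.
#' @return Tibble with `form`, `ea`, `breakpoint`, `r2`, `aic`, `log_lik`,
#'   `n_obs`, `n_params`.
#' @export
glance.mte_fit <- function(x, ...) {
  tibble::tibble(
    form = x$form, ea = x$ea, breakpoint = x$breakpoint, r2 = x$r2,
    aic = x$aic, log_lik = x$log_lik, n_obs = x$n_obs, n_params = x$n_params
  )
}

#' Predicted log-richness of a fitted Arrhenius model
#'
#' @param object An `mte_fit`.
#' @param newdata Optional data frame with an `inv_kt` column; defaults to the
#'   training points.
#' @param ... Unused.
#' @return Numeric vector of predicted `log_richness`.
#' @export
predict.mte_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$inv_kt else newdata$inv_kt
  cf <- object$coefficients
  switch(object$form,
    linear = cf[["intercept"]] + cf[["slope"]] * x,
    quadratic = cf[["intercept"]] + cf[["b"]] * x + cf[["c"]] * x^2,
    piecewise = cf[["intercept"]] + cf[["slope_left"]] * x +
      (cf[["slope_right"]] - cf[["slope_left"]]) * pmax(x - object$breakpoint, 0)
  )
}

#' Rank competing Arrhenius fits by AIC
#'
#' Models within 2 AIC units of the best are flagged competitive; ties are
#' broken by higher r-squared, then fewer parameters. All fits must be over
#' the same points.
#'
#' @param fits List of `mte_fit` objects (>= 2) fitted to identical data.
#' @return Tibble with one row per fit: `form`, `n_params`, `log_lik`, `aic`,
#'   `delta_aic`, `r2`, `competitive`, `rank`.
#' @export
select_model <- function(fits) {
  if (!is.list(fits) || length(fits) < 2) {
    stop("select_model() needs at least two fits", call. = FALSE)
  }
  if (!all(vapply(fits, inherits, logical(1), "mte_fit"))) {
    stop("all elements must be mte_fit objects", call. = FALSE)
  }
  ref <- fits[[1]]$data[, c("inv_kt", "log_richness")]
  same <- vapply(fits[-1], function(f) {
    isTRUE(all.equal(f$data[, c("inv_kt", "log_richness")], ref, tolerance = 1e-12))
  }, logical(1))
  if (!all(same)) stop("fits are over different data", call. = FALSE)
  tab <- dplyr::bind_rows(lapply(fits, glance.mte_fit))
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$competitive <- tab$delta_aic < 2
  tab <- tab |>
    dplyr::arrange(.data$aic, dplyr::desc(.data$r2), .data$n_params) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select(
      "form", "n_params", "log_lik", "aic", "delta_aic", "r2",
      "competitive", "rank"
    )
  tab
}

#' Q10 implied by an activation energy
#'
#' \eqn{Q = \exp(E_a (T_2 - T_1) / (k T_1 T_2))}: the factor by which a
#' Boltzmann-Arrhenius rate grows from `t1` to `t2`. With `t2 - t1 = 10` K
#' this is the Q10; e.g. 0.65 eV corresponds to a Q10 of about 2.5.
#'
#' @param ea Activation energy in eV (>= 0 for rates that increase with
#'   temperature).
#' @param t1,t2 Temperatures in kelvin with `t2 > t1 > 0`.
#' @return The rate ratio.
#' @examples
#' q10_from_ea(0.65, 280, 290) # about 2.5
#' @export
q10_from_ea <- function(ea, t1, t2) {
  if (any(c(t1, t2) <= 0)) stop("temperatures must be positive kelvin", call. = FALSE)
  if (t2 <= t1) stop("t2 must exceed t1", call. = FALSE)
  exp(ea * (t2 - t1) / (boltzmann_ev * t1 * t2))
}

#' Arrhenius plot of a fitted model
#'
#' Scatter of `log_richness` against `inv_kt` with the fitted curve overlaid.
#'
#' @param object An `mte_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mte_fit <- function(object, ...) {
  grid <- tibble::tibble(
    inv_kt = seq(min(object$data$inv_kt), max(object$data$inv_kt), length.out = 200)
  )
  grid$log_richness <- predict.mte_fit(object, grid)
  lab <- if (object$form == "linear") {
    sprintf("E[a] == %.3f~eV~~r^2 == %.2f", object$ea, object$r2)
  } else {
    sprintf("r^2 == %.2f", object$r2)
  }
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$inv_kt, y = .data$log_richness)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::annotate("text",
      x = max(object$data$inv_kt), y = max(object$data$log_richness),
      hjust = 1, vjust = 1, label = lab, parse = TRUE
    ) +
    ggplot2::labs(
      x = expression(1 / (kT) ~ (eV^-1)),
      y = expression(ln ~ "(estimated richness)"),
      title = paste("Boltzmann-Arrhenius fit:", object$form)
    ) +
    ggplot2::theme_minimal()
}
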