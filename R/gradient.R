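#' Bin valid pixels along the mean-annual-precipitation gradient
#'
#' Bins are half-open intervals `[lo, lo + width)` anchored at multiples
#' of `width` from 0 mm (default 50 mm). Each retained bin carries the
#' unweighted mean and standard deviation of the response over the valid
#' pixels it contains; bins with fewer than `n_min` pixels are dropped
#' (mirroring gradient figures that omit bins with no sites).
#'
#' @param pixels A `pixel_metrics` object or its [as.data.frame()] table.
#' @param response Column to average: `"resistance"`, `"resilience"`,
#'   `"rain_reduction"`, `"ndvi_reduction"`, ...
#' @param width Bin width in mm (default 50).
#' @param n_min Minimum pixels per retained bin (default 10).
#' @return A `data.frame` of class `binned_profile` with columns
#'   `bin_lo`, `bin_hi`, `bin_mid`, `n`, `mean`, `sd`. Attribute
#'   `n_valid` records the number of valid input pixels and `all_bins`
#'   the pre-drop table.
#' @export
bin_by_map <- function(pixels, response = "resistance", width = 50,
                       n_min = 10L) {
  stopifnot(width > 0, n_min >= 0)
  df <- if (inherits(pixels, "pixel_metrics")) as.data.frame(pixels)
        else as.data.frame(pixels)
  if (!response %in% names(df)) stop_("no column '%s' in pixel table",
                                      response)
  df <- df[df$valid & !is.na(df[[response]]) & !is.na(df$map_mm), ,
           drop = FALSE]
  if (!nrow(df)) stop_("zero valid pixels to bin")
  bin <- floor(df$map_mm / width)
  y <- df[[response]]
  agg <- aggregate(y, by = list(bin = bin),
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       sd = sd(v)))
  all_bins <- data.frame(bin_lo = agg$bin * width,
                         bin_hi = (agg$bin + 1) * width,
                         bin_mid = (agg$bin + 0.5) * width,
                         n = as.integer(agg$x[, "n"]),
                         mean = agg$x[, "mean"],
                         sd = agg$x[, "sd"])
  all_bins <- all_bins[order(all_bins$bin_lo), , drop = FALSE]
  rownames(all_bins) <- NULL
  out <- all_bins[all_bins$n >= n_min, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "response") <- response
  attr(out, "width") <- width
  attr(out, "n_min") <- n_min
  attr(out, "n_valid") <- nrow(df)
  attr(out, "all_bins") <- all_bins
  class(out) <- c("binned_profile", "data.frame")
  out
}

#' Subset pixels by the rain reduction they experienced
#'
#' Retains valid pixels whose rain-reduction fraction lies in the closed
#' interval `[lo, hi]` (defaults 0.05-0.10), so gradient profiles compare
#' sites that experienced a similar degree of precipitation reduction.
#'
#' @param pixels A `pixel_metrics` object or its pixel table.
#' @param lo,hi Closed-interval bounds on the rain-reduction fraction.
#' @return The filtered pixel table (all rows valid).
#' @export
subset_by_rain_reduction <- function(pixels, lo = 0.05, hi = 0.10) {
  if (!(lo < hi)) stop_("lo must be < hi")
  df <- if (inherits(pixels, "pixel_metrics")) as.data.frame(pixels)
        else as.data.frame(pixels)
  df[df$valid & !is.na(df$rain_reduction) &
       df$rain_reduction >= lo & df$rain_reduction <= hi, , drop = FALSE]
}

#' Fit candidate curves to a binned gradient profile
#'
#' Implements the gradient model-selection rule: an ordinary least-squares
#' linear fit on `(bin_mid, mean)` is tried first and selected if its
#' slope is significant (`p <= p_gate`, default 0.05). Otherwise the
#' exponential (`y = a e^{bx}`, nonlinear least squares with log-linear
#' initialization), quadratic, and cubic candidates are fitted and the
#' candidate with the highest coefficient of determination
#' (`R^2 = 1 - SSE/SST`, computed identically for every family) is
#' selected; near-ties (within `1e-9`) go to the family with fewer
#' parameters. A non-converging exponential fit is excluded with a
#' warning.
#'
#' @param profile A [bin_by_map()] result with at least 5 retained bins.
#' @param p_gate Significance gate for the linear fit (default 0.05).
#' @return An object of class `gradient_fit_set`: a list of
#'   `gradient_fit` candidates (`fits`), the name of the selected family
#'   (`selected`), the linear gate p-value and the profile. Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`, [peak_of_fit()].
#' @export
fit_candidates <- function(profile, p_gate = 0.05) {
  stopifnot(inherits(profile, "binned_profile") || is.data.frame(profile))
  x <- profile$bin_mid; y <- profile$mean
  n <- length(x)
  if (n < 5L) stop_("insufficient bins: %d retained, need >= 5", n)
  sst <- sum((y - mean(y))^2)
  r2_of <- function(residuals) {
    sse <- sum(residuals^2)
    if (sst <= 0) return(if (sse < 1e-12) 1 else NA_real_)
    1 - sse / sst
  }
  fits <- list()

  lin <- lm(y ~ x)
  p_lin <- summary(lin)$coefficients["x", "Pr(>|t|)"]
  fits$linear <- new_gradient_fit("linear", lin, coef(lin),
                                  r2_of(resid(lin)), p_lin, n,
                                  profile = profile)

  make_poly <- function(deg, name) {
    m <- lm(y ~ poly(x, deg, raw = TRUE))
    cf <- setNames(coef(m), c("a0", paste0("a", seq_len(deg))))
    s <- summary(m)
    p_overall <- pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                    lower.tail = FALSE)
    new_gradient_fit(name, m, cf, r2_of(resid(m)), unname(p_overall), n,
                     profile = profile)
  }
  fits$exponential <- tryCatch({
    start <- if (all(y > 0)) {
      ll <- lm(log(y) ~ x)
      list(a = exp(unname(coef(ll)[1])), b = unname(coef(ll)[2]))
    } else list(a = mean(y), b = 0)
    m <- minpack.lm::nlsLM(y ~ a * exp(b * x), start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    new_gradient_fit("exponential", m, coef(m), r2_of(resid(m)),
                     NA_real_, n, profile = profile)
  }, error = function(e) {
    warning(sprintf("exponential fit did not converge (%s); excluded",
                    conditionMessage(e)), call. = FALSE)
    NULL
  })
  fits$quadratic <- make_poly(2L, "quadratic")
  fits$cubic <- make_poly(3L, "cubic")
  fits <- Filter(Negate(is.null), fits)

  selected <- if (is.finite(p_lin) && p_lin <= p_gate) "linear" else {
    r2 <- vapply(fits, `[[`, numeric(1), "r2")
    npar <- vapply(fits, `[[`, numeric(1), "n_par")
    ord <- order(-r2, npar)
    top <- ord[1]
    ## near-tie in R2: prefer fewer parameters (order() above already
    ## does, given the 1e-9 rounding here)
    ties <- which(abs(r2 - r2[top]) < 1e-9)
    names(fits)[ties[which.min(npar[ties])]]
  }
  for (nm in names(fits)) fits[[nm]]$selected <- nm == selected
  structure(list(fits = fits, selected = selected, gate_p = p_lin,
                 profile = profile, p_gate = p_gate),
            class = "gradient_fit_set")
}

new_gradient_fit <- function(family, model, coefficients, r2, p_value, n,
                             profile = NULL) {
  n_par <- switch(family, linear = 2L, exponential = 2L, quadratic = 3L,
                  cubic = 4L)
  structure(list(family = family, model = model,
                 coefficients = coefficients, r2 = r2, p_value = p_value,
                 n_bins = n, n_par = n_par, selected = FALSE,
                 profile = profile),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("<gradient_fit> %s%s: R2 = %.4f%s, %d bins\n", x$family,
              if (x$selected) " (selected)" else "", x$r2,
              if (is.finite(x$p_value)) sprintf(", p = %.3g", x$p_value)
              else "", x$n_bins))
  cat("  coefficients:", paste(sprintf("%s = %.6g",
                                       names(x$coefficients) %||%
                                         seq_along(x$coefficients),
                                       x$coefficients), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.gradient_fit_set <- function(x, ...) {
  cat(sprintf("<gradient_fit_set> response '%s', %d bins; linear gate p = %.3g\n",
              attr(x$profile, "response") %||% "?", nrow(x$profile),
              x$gate_p))
  for (f in x$fits) print(f)
  invisible(x)
}

#' @export
summary.gradient_fit_set <- function(object, ...) {
  data.frame(family = vapply(object$fits, `[[`, character(1), "family"),
             r2 = vapply(object$fits, `[[`, numeric(1), "r2"),
             p_value = vapply(object$fits, `[[`, numeric(1), "p_value"),
             n_par = vapply(object$fits, `[[`, integer(1), "n_par"),
             selected = vapply(object$fits, `[[`, logical(1), "selected"),
             row.names = NULL)
}

#' @export
coef.gradient_fit <- function(object, ...) object$coefficients

#' @export
coef.gradient_fit_set <- function(object, ...)
  coef(object$fits[[object$selected]])

#' Evaluate a fitted gradient curve
#'
#' @param object A `gradient_fit` (or `gradient_fit_set`, which delegates
#'   to its selected fit).
#' @param newdata Numeric vector of MAP values (mm); defaults to the bin
#'   midpoints.
#' @param interval `"none"` or `"confidence"` for a 95% band on the
#'   fitted mean. Polynomial families use the analytic OLS interval; the
#'   exponential family uses a seeded parametric bootstrap.
#' @param level Confidence level (default 0.95).
#' @param nboot Bootstrap resamples for the exponential band (default
#'   1000).
#' @param seed Seed for the bootstrap (default 1).
#' @param ... Unused.
#' @return A numeric vector, or a matrix with columns `fit`, `lwr`,
#'   `upr` when `interval = "confidence"`.
#' @export
predict.gradient_fit <- function(object, newdata = NULL,
                                 interval = c("none", "confidence"),
                                 level = 0.95, nboot = 1000L, seed = 1L,
                                 ...) {
  interval <- match.arg(interval)
  x <- newdata %||% object$profile$bin_mid
  if (object$family %in% c("linear", "quadratic", "cubic")) {
    nd <- data.frame(x = x)
    if (interval == "none")
      return(as.numeric(predict(object$model, newdata = nd)))
    p <- predict(object$model, newdata = nd, interval = "confidence",
                 level = level)
    return(p[, c("fit", "lwr", "upr"), drop = FALSE])
  }
  ## exponential
  cf <- object$coefficients
  fit <- cf[["a"]] * exp(cf[["b"]] * x)
  if (interval == "none") return(fit)
  xb <- object$profile$bin_mid
  yb <- fitted(object$model)
  sigma <- sqrt(sum(resid(object$model)^2) /
                  max(1L, length(xb) - object$n_par))
  curves <- with_seed(seed, {
    vapply(seq_len(nboot), function(i) {
      ys <- yb + rnorm(length(yb), 0, sigma)
      m <- tryCatch(minpack.lm::nlsLM(ys ~ a * exp(b * xb),
                                      start = as.list(cf)),
                    error = function(e) NULL)
      if (is.null(m)) return(rep(NA_real_, length(x)))
      cc <- coef(m)
      cc[["a"]] * exp(cc[["b"]] * x)
    }, numeric(length(x)))
  })
  alpha <- (1 - level) / 2
  lwr <- apply(curves, 1, quantile, probs = alpha, na.rm = TRUE)
  upr <- apply(curves, 1, quantile, probs = 1 - alpha, na.rm = TRUE)
  cbind(fit = fit, lwr = lwr, upr = upr)
}

#' @export
predict.gradient_fit_set <- function(object, ...)
  predict(object$fits[[object$selected]], ...)

#' Location of the fitted curve's maximum along the gradient
#'
#' Closed-form argmax of a quadratic or cubic gradient fit over a MAP
#' domain: the real roots of the derivative inside the domain and the
#' domain endpoints are compared. Linear and exponential fits have no
#' interior peak and error. If the maximum sits on a domain endpoint the
#' result carries attribute `boundary = TRUE`.
#'
#' @param fit A `gradient_fit` (quadratic or cubic family) or a
#'   `gradient_fit_set` (its selected fit is used).
#' @param domain Length-2 MAP interval (mm); defaults to the fitted bin
#'   midpoint range.
#' @return Peak location in mm (attribute `boundary`).
#' @export
peak_of_fit <- function(fit, domain = NULL) {
  if (inherits(fit, "gradient_fit_set")) fit <- fit$fits[[fit$selected]]
  stopifnot(inherits(fit, "gradient_fit"))
  if (!fit$family %in% c("quadratic", "cubic"))
    stop_("no interior peak for family '%s'", fit$family)
  domain <- domain %||% range(fit$profile$bin_mid)
  cf <- fit$coefficients
  crit <- if (fit$family == "quadratic") {
    if (cf[["a2"]] == 0) numeric(0) else -cf[["a1"]] / (2 * cf[["a2"]])
  } else {
    ## derivative a1 + 2 a2 x + 3 a3 x^2
    a <- 3 * cf[["a3"]]; b <- 2 * cf[["a2"]]; c0 <- cf[["a1"]]
    if (a == 0) {
      if (b == 0) numeric(0) else -c0 / b
    } else {
      disc <- b^2 - 4 * a * c0
      if (disc < 0) numeric(0)
      else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    }
  }
  cand <- sort(unique(c(domain, crit[crit > domain[1] & crit < domain[2]])))
  vals <- predict(fit, newdata = cand)
  peak <- cand[which.max(vals)]
  attr(peak, "boundary") <- peak %in% domain & !(peak %in% crit)
  peak
}

#' Plot a binned gradient profile and its fitted curves
#'
#' Base-graphics rendering of a gradient panel: bin means with +-1 sd
#' bars, the selected curve with its 95% confidence band, and other
#' converged candidates as thin lines.
#'
#' @param x A `gradient_fit_set`.
#' @param band Draw the confidence band (default TRUE).
#' @param ... Passed to [plot()].
#' @export
plot.gradient_fit_set <- function(x, band = TRUE, ...) {
  pr <- x$profile
  xx <- seq(min(pr$bin_mid), max(pr$bin_mid), length.out = 200)
  sel <- x$fits[[x$selected]]
  ylim <- range(c(pr$mean - pr$sd, pr$mean + pr$sd), na.rm = TRUE)
  plot(pr$bin_mid, pr$mean, pch = 19, xlab = "MAP (mm)",
       ylab = attr(pr, "response") %||% "response", ylim = ylim, ...)
  segments(pr$bin_mid, pr$mean - pr$sd, pr$bin_mid, pr$mean + pr$sd,
           col = "grey60")
  if (band) {
    ci <- predict(sel, newdata = xx, interval = "confidence")
    polygon(c(xx, rev(xx)), c(ci[, "lwr"], rev(ci[, "upr"])),
            col = adjustcolor("steelblue", 0.25), border = NA)
  }
  for (nm in names(x$fits))
    if (nm != x$selected)
      lines(xx, predict(x$fits[[nm]], newdata = xx), col = "grey70",
            lty = 3)
  lines(xx, predict(sel, newdata = xx), col = "steelblue", lwd = 2)
  legend("topleft", bty = "n",
         legend = sprintf("%s (R2 = %.2f)", sel$family, sel$r2))
  invisible(x)
}

#' Serialize a fit set to JSON / a profile to CSV
#'
#' @param fitset A `gradient_fit_set`.
#' @param path Output file.
#' @export
write_fit_json <- function(fitset, path) {
  s <- summary(fitset)
  sel <- fitset$fits[[fitset$selected]]
  pk <- if (sel$family %in% c("quadratic", "cubic"))
    as.numeric(peak_of_fit(fitset)) else NULL
  obj <- list(response = attr(fitset$profile, "response"),
              selected = fitset$selected,
              gate_p = fitset$gate_p,
              peak_map_mm = pk,
              candidates = lapply(fitset$fits, function(f)
                list(family = f$family,
                     coefficients = as.list(f$coefficients),
                     r2 = f$r2,
                     p_value = if (is.finite(f$p_value)) f$p_value else NULL,
                     selected = f$selected)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @param profile A `binned_profile`.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
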