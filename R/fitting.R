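# Strain-life curve fitting and Monte-Carlo calibration of the Weibull
# scatter parameters.

#' Fit the strain-life power law to cycles-to-failure data
#'
#' Least-squares fit of `log N_f` on `log strain` over the non-runout rows
#' (`N_f = C * strain^-n`). Runout specimens, which survived the test's
#' cycle limit without failing, are excluded from the fit by convention.
#'
#' @param table data frame with columns `strain` (in `(0, 1)`),
#'   `cycles_to_failure` (>= 1), and optionally `runout` (logical; treated
#'   as all-`FALSE` when absent)
#' @return object of class `strainlife_fit` with elements `C`, `n`, `fit`
#'   (the underlying `lm`), `data`; supports `coef()`, `print()` and
#'   `predict(fit, strain = ...)`
#' @export
#' @examples
#' tab <- data.frame(strain = c(0.30, 0.40),
#'                   cycles_to_failure = 1.0 * c(0.30, 0.40)^-12.9)
#' coef(fit_power_law(tab))
fit_power_law <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("strain", "cycles_to_failure") %in% names(table)))
  if (is.null(table$runout)) table$runout <- FALSE
  stopifnot(all(table$strain > 0 & table$strain < 1),
            all(table$cycles_to_failure >= 1))
  use <- table[!table$runout, , drop = FALSE]
  if (nrow(use) < 2) stop("need at least 2 non-runout rows")
  if (length(unique(use$strain)) < 2) stop("zero strain variance among non-runout rows")
  fit <- lm(log(cycles_to_failure) ~ log(strain), data = use)
  co <- coef(fit)
  structure(list(C = exp(unname(co[1])), n = -unname(co[2]),
                 fit = fit, data = table),
            class = "strainlife_fit")
}

#' @export
coef.strainlife_fit <- function(object, ...) c(C = object$C, n = object$n)

#' @export
print.strainlife_fit <- function(x, ...) {
  cat(sprintf("Strain-life power law N_f = C * strain^-n: C = %.4g, n = %.3f\n",
              x$C, x$n))
  cat(sprintf("  fitted on %d specimens (%d runouts excluded)\n",
              sum(!x$data$runout), sum(x$data$runout)))
  invisible(x)
}

#' Predicted cycles to failure at given strains
#' @param object a `strainlife_fit`
#' @param strain strains in `(0, 1)`
#' @param ... unused
#' @return predicted cycles to failure
#' @export
predict.strainlife_fit <- function(object, strain, ...) {
  stopifnot(all(strain > 0 & strain < 1))
  object$C * strain^(-object$n)
}

#' Calibrate the Weibull scatter parameters by Monte Carlo
#'
#' Reproduces the four-step calibration of the Weibull coefficient `b` and
#' exponent `m` from the fitted power law:
#' (i) compute the strain `eps*` giving failure at `N_target` cycles,
#' `eps* = (N_target / C)^(-1/n)`;
#' (ii)-(iii) draw `n_samples` failure strains from
#' `Normal(eps*, strain_sd)` (truncated to `(0, 1)`), the scatter observed
#' at other cycle numbers in the source fatigue data (~0.025 strains);
#' (iv) fit a Weibull cumulative distribution to the empirical CDF of the
#' drawn failure strains. The Weibull scale is expressed as `b * eps*`, so
#' `b = scale / eps*`, and the shape is `m`.
#'
#' @param C,n power-law constants (see [fit_power_law()])
#' @param N_target loading cycles relevant to a human lifespan (1e7)
#' @param strain_sd scatter of failure strains (0.025)
#' @param n_samples Monte-Carlo draws (>= 100)
#' @param seed optional integer seed
#' @param method `"cdf"` (default): nonlinear least squares on the
#'   empirical CDF; `"mle"`: maximum likelihood
#' @return object of class `weibull_calibration` with elements `b`, `m`,
#'   `scale`, `eps_star`, `method`, `samples`
#' @export
#' @examples
#' cal <- calibrate_weibull(n_samples = 2000, seed = 1)
#' c(cal$b, cal$m)
calibrate_weibull <- function(C = 1.0, n = 12.9, N_target = 1e7,
                              strain_sd = 0.025, n_samples = 10000,
                              seed = NULL, method = c("cdf", "mle")) {
  method <- match.arg(method)
  stopifnot(C > 0, n > 1, N_target > 1, n_samples >= 100)
  if (strain_sd <= 0) stop("degenerate strain SD")
  eps_star <- (N_target / C)^(-1 / n)

  draws <- with_seed(seed, {
    x <- rnorm(n_samples, eps_star, strain_sd)
    while (any(bad <- x <= 0 | x >= 1)) x[bad] <- rnorm(sum(bad), eps_star, strain_sd)
    x
  })

  # moment-based starting values: Weibull cv ~ 1.2/shape for large shapes
  cv <- sd(draws) / mean(draws)
  k0 <- max(1.2 / cv, 1.5)
  l0 <- mean(draws) / gamma(1 + 1 / k0)

  if (method == "cdf") {
    xs <- sort(draws)
    p_emp <- (seq_along(xs) - 0.5) / length(xs)
    df <- data.frame(x = xs, p = p_emp)
    fit <- nls(p ~ 1 - exp(-(x / lambda)^k), data = df,
               start = list(lambda = l0, k = k0),
               control = list(maxiter = 200, warnOnly = FALSE))
    est <- coef(fit)
    lambda <- unname(est["lambda"]); k <- unname(est["k"])
  } else {
    nll <- function(par) {
      lambda <- exp(par[1]); k <- exp(par[2])
      -sum(log(k / lambda) + (k - 1) * log(draws / lambda) - (draws / lambda)^k)
    }
    opt <- optim(c(log(l0), log(k0)), nll)
    lambda <- exp(opt$par[1]); k <- exp(opt$par[2])
  }

  structure(list(b = lambda / eps_star, m = k, scale = lambda,
                 eps_star = eps_star, method = method, samples = draws),
            class = "weibull_calibration")
}

#' @export
print.weibull_calibration <- function(x, ...) {
  cat(sprintf("Weibull calibration (%s fit on %d draws): b = %.3f, m = %.2f\n",
              x$method, length(x$samples), x$b, x$m))
  cat(sprintf("  eps* = %.4f at the target cycle count; scale = %.4f\n",
              x$eps_star, x$scale))
  invisible(x)
}

#' Read a strain-life table from CSV
#'
#' Columns: `strain`, `cycles_to_failure`, optional `runout` (0/1 or
#' logical). A small synthetic example table is shipped at
#' `system.file("extdata", "strain_life_synthetic.csv", package = "kneefatigue")`.
#'
#' @param path CSV file path
#' @return data frame suitable for [fit_power_law()]
#' @export
read_strain_life <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(tab$runout)) tab$runout <- as.logical(tab$runout)
  tab
}
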