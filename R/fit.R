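#' @title Nonlinear least-squares fits for covalent-inhibition kinetics
#' @description Fits reproducing the standard workflow: Michaelis-Menten fits
#'   of initial rates, first-order (optionally plateaued) fits of
#'   residual-activity traces, and the kobs-vs-[I] fit with automatic
#'   linear/hyperbolic model selection.
#' @name kinetics-fitting
NULL

fit_result <- function(model, estimates, se, residuals, converged, aic,
                       flags = character(0)) {
  structure(list(model = model, estimates = estimates, se = se,
                 residuals = residuals, converged = converged, AIC = aic,
                 flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit:", x$model, if (!x$converged) "(NOT converged)", "\n")
  est <- data.frame(estimate = x$estimates,
                    std.error = x$se[names(x$estimates)])
  print(signif(est, 4))
  cat(sprintf("AIC = %.2f, n = %d\n", x$AIC, length(x$residuals)))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# Unweighted (or 1/sigma^2-weighted) Levenberg-Marquardt wrapper with
# Jacobian-based standard errors, Prism-style.
nls_fit <- function(formula, data, start, weights = NULL) {
  fit <- if (is.null(weights)) {
    minpack.lm::nlsLM(formula, data = data, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(formula, data = data, start = start, weights = weights,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit
}

#' Fit the Michaelis-Menten equation to initial rates
#'
#' `v = Vmax * S / (Km + S)` by unweighted nonlinear least squares
#' (Levenberg-Marquardt), optionally weighted by `1/sigma^2`. Reports `kcat =
#' Vmax / E0` when the enzyme concentration is supplied.
#'
#' @param data data.frame with columns `S` (substrate, M) and `v` (initial
#'   rate) and optionally `sigma`; an [assay_dataset()] works directly.
#' @param E0 enzyme concentration (M), optional.
#' @param weighted use `1/sigma^2` weights (requires a `sigma` column).
#' @return a `fit_result` with estimates `Vmax`, `Km` (and `kcat` when `E0`
#'   given). A `"Km poorly determined"` flag is raised when the fitted Km
#'   falls outside 100x the design range (no curvature in the data).
#' @export
#' @examples
#' S <- make_mm_design(Km = 1e-4)
#' d <- data.frame(S = S, v = 2 * S / (1e-4 + S))
#' fit_michaelis_menten(d)
fit_michaelis_menten <- function(data, E0 = NULL, weighted = FALSE) {
  data <- as.data.frame(data)
  stopifnot(all(c("S", "v") %in% names(data)))
  if (length(unique(data$S)) < 4)
    stop("need >= 4 distinct substrate concentrations")
  if (any(data$v < 0)) stop("rates must be >= 0")
  w <- if (weighted) {
    if (is.null(data$sigma)) stop("weighted fit requires a sigma column")
    1 / data$sigma^2
  } else NULL
  start <- list(Vmax = max(data$v) * 1.2, Km = stats::median(data$S))
  fit <- nls_fit(v ~ Vmax * S / (Km + S), data, start, weights = w)
  sm <- summary(fit)
  est <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  flags <- character(0)
  if (est[["Km"]] > max(data$S) * 100 || est[["Km"]] < min(data$S) / 100)
    flags <- "Km poorly determined"
  if (!is.null(E0)) {
    est <- c(est, kcat = unname(est[["Vmax"]]) / E0)
    se <- c(se, kcat = unname(se[["Vmax"]]) / E0)
  }
  fit_result("michaelis-menten", est, se, stats::resid(fit),
             fit$convInfo$isConv, stats::AIC(fit), flags)
}

#' Fit a first-order decay to a residual-activity trace
#'
#' Without a plateau: `F = exp(-kobs * t)`. With a plateau (reactivating
#' covalent inhibitor): `F = F_ss + (1 - F_ss) * exp(-kobs_total * t)`, which
#' is then decomposed into the inactivation and reactivation components
#' \deqn{k_{obs} = k_{tot} (1 - F_{ss}), \qquad k_5 = k_{tot} F_{ss}.}
#'
#' @param trace an [assay_trace()] or data.frame with columns `time` and `F`.
#' @param with_plateau fit the reactivation plateau and decompose it.
#' @return a `fit_result`. With plateau: estimates `kobs_total`, `F_ss`,
#'   `kobs`, `k5`; without: `kobs`. A `"non-monotone trace"` flag is raised
#'   when the trace rises by more than ~3 noise SDs between points.
#' @export
fit_first_order_decay <- function(trace, with_plateau = FALSE) {
  df <- as.data.frame(trace)
  if (!"F" %in% names(df)) names(df)[2] <- "F"
  if (nrow(df) < 5) stop("need >= 5 time points")
  flags <- character(0)
  rough_sd <- stats::mad(diff(df$F)) + 1e-12
  if (any(diff(df$F) > 3 * rough_sd + 1e-9))
    flags <- "non-monotone trace"
  t_half_guess <- df$time[which.min(abs(df$F - (max(df$F) + min(df$F)) / 2))]
  k_guess <- log(2) / max(t_half_guess, diff(range(df$time)) / 20)
  if (with_plateau) {
    start <- list(ktot = k_guess, F_ss = max(min(df$F), 1e-3))
    fit <- nls_fit(F ~ F_ss + (1 - F_ss) * exp(-ktot * time), df, start)
    est <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    ktot <- est[["ktot"]]; F_ss <- est[["F_ss"]]
    out_est <- c(kobs_total = ktot, F_ss = F_ss,
                 kobs = ktot * (1 - F_ss), k5 = ktot * F_ss)
    # first-order error propagation for the derived pair
    out_se <- c(kobs_total = se[["ktot"]], F_ss = se[["F_ss"]],
                kobs = sqrt((se[["ktot"]] * (1 - F_ss))^2 + (ktot * se[["F_ss"]])^2),
                k5 = sqrt((se[["ktot"]] * F_ss)^2 + (ktot * se[["F_ss"]])^2))
    fit_result("first-order+plateau", out_est, out_se, stats::resid(fit),
               fit$convInfo$isConv, stats::AIC(fit), flags)
  } else {
    fit <- nls_fit(F ~ exp(-kobs * time), df, list(kobs = k_guess))
    est <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    fit_result("first-order", est, se, stats::resid(fit),
               fit$convInfo$isConv, stats::AIC(fit), flags)
  }
}

#' Fit kobs versus inhibitor concentration
#'
#' Saturating (hyperbolic) model `kobs = kinact * I / (Ki + I)`; linear model
#' `kobs = (kinact/Ki) * I` when no curvature is discernible. In `"auto"`
#' mode the hyperbolic fit is kept only when AIC favors it and the fitted Ki
#' lies within 10x the largest assayed concentration; otherwise only the
#' second-order slope `kinact/Ki` is reported (the individual constants are
#' indeterminable, as happens when `[I] << Ki` throughout).
#'
#' @param I inhibitor concentrations (M), >= 3 distinct values.
#' @param kobs fitted pseudo-first-order rate constants (s^-1).
#' @param model `"auto"`, `"linear"` or `"hyperbolic"`.
#' @param aic_margin the hyperbolic model must beat the linear one by at
#'   least this much AIC to be kept in `"auto"` mode (default 2, the usual
#'   threshold below which models are considered indistinguishable, in which
#'   case the more parsimonious linear form wins).
#' @return a `fit_result`; hyperbolic estimates `kinact`, `Ki`,
#'   `kinact_over_Ki`; linear estimate `kinact_over_Ki` only, with flag
#'   `"kinact and Ki indeterminable"`.
#' @export
fit_inactivation <- function(I, kobs, model = c("auto", "linear", "hyperbolic"),
                             aic_margin = 2) {
  model <- match.arg(model)
  if (length(unique(I)) < 3) stop("need >= 3 inhibitor concentrations")
  df <- data.frame(I = I, kobs = kobs)

  fit_lin <- function() {
    fit <- stats::lm(kobs ~ 0 + I, data = df)
    est <- c(kinact_over_Ki = unname(stats::coef(fit)[["I"]]))
    se <- c(kinact_over_Ki = unname(
      suppressWarnings(summary(fit))$coefficients[, "Std. Error"]))
    fit_result("linear", est, se, stats::resid(fit), TRUE, stats::AIC(fit),
               "kinact and Ki indeterminable")
  }
  fit_hyp <- function() {
    start <- list(kinact = max(df$kobs) * 1.5, Ki = stats::median(df$I))
    fit <- nls_fit(kobs ~ kinact * I / (Ki + I), df, start)
    est <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    est <- c(est, kinact_over_Ki = unname(est[["kinact"]] / est[["Ki"]]))
    se <- c(se, kinact_over_Ki = unname(
      est[["kinact_over_Ki"]] *
        sqrt((se[["kinact"]] / est[["kinact"]])^2 + (se[["Ki"]] / est[["Ki"]])^2)))
    fit_result("hyperbolic", est, se, stats::resid(fit),
               fit$convInfo$isConv, stats::AIC(fit))
  }

  if (model == "linear") return(fit_lin())
  if (model == "hyperbolic") return(fit_hyp())
  lin <- fit_lin()
  hyp <- tryCatch(fit_hyp(), error = function(e) NULL)
  if (is.null(hyp) || !hyp$converged) return(lin)
  if (hyp$AIC > lin$AIC - aic_margin ||
      hyp$estimates[["Ki"]] > 10 * max(df$I)) lin else hyp
}

#' Classify a compound's mechanism-based behavior
#'
#' Three functionally distinct outcomes of the covalent cycle:
#' * **substrate** — glycosylation is rate-determining (`k3 < k5`); the
#'   covalent intermediate never accumulates and no time-dependent activity
#'   loss is seen.
#' * **covalent inhibitor** — the intermediate accumulates (`k3 >> k5`) but
#'   is hydrolyzed (`k5 > 0`): activity is lost and later fully recovers.
#' * **covalent inactivator** — no reactivation on the observation timescale
#'   (`k5 ~ 0`): irreversible loss.
#'
#' @param params a `steady_state_params` (from [derive_steady_state()]) or a
#'   [rate_scheme()].
#' @param reactivation_observed was recovery of activity observed over the
#'   experiment window? `NA` (default) defers to `k5 > 0` in the scheme when
#'   available.
#' @return one of `"substrate"`, `"covalent inhibitor"`,
#'   `"covalent inactivator"`, `"undetermined"`.
#' @export
classify_compound <- function(params, reactivation_observed = NA) {
  if (inherits(params, "rate_scheme"))
    params <- derive_steady_state(params)
  if (!inherits(params, "steady_state_params")) return("undetermined")
  reactivates <- if (is.na(reactivation_observed))
    params$kinact > 0 && params$kcat > 0 && !isTRUE(all.equal(params$kcat, 0))
  else reactivation_observed
  if (!params$intermediate_accumulates) return("substrate")
  if (params$kcat == 0 || isFALSE(reactivates)) return("covalent inactivator")
  "covalent inhibitor"
}
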