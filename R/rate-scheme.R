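#' Microscopic rate scheme for the covalent-inhibition cycle
#'
#' The minimal catalytic cycle for mechanism-based covalent inhibition of a
#' glycoside hydrolase is
#'
#' \deqn{E + I \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} E{:}I
#'       \overset{k_3}{\rightarrow} E{-}I
#'       \overset{k_5}{\rightarrow} E + P}
#'
#' where `E:I` is the non-covalent Michaelis complex, `E-I` the covalent
#' glycosyl-enzyme intermediate, `k3` the pseudo-glycosylation (covalent bond
#' formation) rate and `k5` the hydrolysis (reactivation) rate of the covalent
#' intermediate.
#'
#' @param k1 bimolecular association rate constant (M^-1 s^-1); must be > 0
#'   whenever the dissociation constant is needed.
#' @param k_minus1 dissociation rate constant of the Michaelis complex (s^-1).
#' @param k3 pseudo-glycosylation rate constant (s^-1).
#' @param k5 hydrolysis/reactivation rate constant of the covalent
#'   intermediate (s^-1); 0 for a true inactivator.
#'
#' @return An object of class `rate_scheme`: a list with the four rate
#'   constants. The dissociation constant `Kd = k_minus1/k1` is available via
#'   [dissociation_constant()].
#' @seealso [derive_steady_state()], [simulate_cycle()]
#' @export
#' @examples
#' sch <- rate_scheme(k1 = 1e5, k_minus1 = 70, k3 = 0.1, k5 = 5.9e-4)
#' dissociation_constant(sch)
rate_scheme <- function(k1, k_minus1, k3, k5) {
  rates <- c(k1 = k1, k_minus1 = k_minus1, k3 = k3, k5 = k5)
  if (any(!is.finite(rates))) stop("all rate constants must be finite")
  if (any(rates < 0)) stop("all rate constants must be >= 0")
  structure(as.list(rates), class = "rate_scheme")
}

#' @rdname rate_scheme
#' @param scheme a `rate_scheme` object.
#' @export
dissociation_constant <- function(scheme) {
  stopifnot(inherits(scheme, "rate_scheme"))
  if (scheme$k1 == 0) stop("Kd undefined: k1 = 0")
  scheme$k_minus1 / scheme$k1
}

#' @export
print.rate_scheme <- function(x, ...) {
  cat("Covalent-inhibition rate scheme\n")
  cat(sprintf("  k1       = %g M^-1 s^-1\n", x$k1))
  cat(sprintf("  k_minus1 = %g s^-1\n", x$k_minus1))
  cat(sprintf("  k3       = %g s^-1 (pseudo-glycosylation)\n", x$k3))
  cat(sprintf("  k5       = %g s^-1 (reactivation)\n", x$k5))
  if (x$k1 > 0)
    cat(sprintf("  Kd       = %g M\n", x$k_minus1 / x$k1))
  invisible(x)
}

#' Steady-state observables of the covalent-inhibition scheme
#'
#' Derives the observable Michaelis-Menten and inactivation parameters from
#' the microscopic rate constants under rapid-equilibrium binding:
#' \deqn{k_{cat} = \frac{k_3 k_5}{k_3 + k_5}, \quad
#'       K_m = K_d \frac{k_5}{k_3 + k_5}, \quad
#'       k_{cat}/K_m = k_3/K_d}
#' and, for the time-dependent loss of activity measured when the covalent
#' intermediate accumulates (\eqn{k_3 \gg k_5}),
#' \deqn{k_{inact} = k_3, \quad K_i = K_d, \quad k_{inact}/K_i = k_3/K_d.}
#' The second-order rate constants for turnover and inactivation are therefore
#' identical for any scheme: \eqn{k_{cat}/K_m \equiv k_{inact}/K_i}.
#'
#' @param scheme a [rate_scheme()].
#' @param binding `"rapid-equilibrium"` (default; `Kd = k_minus1/k1`) or
#'   `"steady-state"` (`Kd -> (k_minus1 + k3)/k1`).
#' @param accumulation_factor the covalent intermediate is flagged as
#'   accumulating when `k3/k5` exceeds this factor (default 10).
#'
#' @return An object of class `steady_state_params`: list with `kcat`, `Km`,
#'   `kcat_over_Km`, `kinact`, `Ki_app`, `kinact_over_Ki` (all SI: s^-1, M,
#'   M^-1 s^-1) and the logical flag `intermediate_accumulates`.
#' @export
#' @examples
#' sch <- rate_scheme(k1 = 1e5, k_minus1 = 70, k3 = 0.1, k5 = 5.9e-4)
#' derive_steady_state(sch)
derive_steady_state <- function(scheme,
                                binding = c("rapid-equilibrium", "steady-state"),
                                accumulation_factor = 10) {
  stopifnot(inherits(scheme, "rate_scheme"))
  binding <- match.arg(binding)
  k3 <- scheme$k3
  k5 <- scheme$k5
  if (k3 + k5 <= 0) stop("no turnover: k3 and k5 are both zero")
  if (scheme$k1 == 0) stop("Kd undefined: k1 = 0")
  Kd <- switch(binding,
    "rapid-equilibrium" = scheme$k_minus1 / scheme$k1,
    "steady-state"      = (scheme$k_minus1 + k3) / scheme$k1
  )
  kcat <- k3 * k5 / (k3 + k5)
  Km <- Kd * k5 / (k3 + k5)
  out <- list(
    kcat = kcat,
    Km = Km,
    kcat_over_Km = k3 / Kd,
    kinact = k3,
    Ki_app = Kd,
    kinact_over_Ki = k3 / Kd,
    intermediate_accumulates = k5 > 0 && (k3 / k5) > accumulation_factor || k5 == 0,
    binding = binding
  )
  class(out) <- "steady_state_params"
  out
}

#' @export
print.steady_state_params <- function(x, ...) {
  cat("Steady-state kinetic parameters (", x$binding, " binding)\n", sep = "")
  cat(sprintf("  kcat      = %.4g s^-1\n", x$kcat))
  cat(sprintf("  Km        = %.4g M\n", x$Km))
  cat(sprintf("  kcat/Km   = %.4g M^-1 s^-1\n", x$kcat_over_Km))
  cat(sprintf("  kinact    = %.4g s^-1\n", x$kinact))
  cat(sprintf("  Ki(app)   = %.4g M\n", x$Ki_app))
  cat(sprintf("  kinact/Ki = %.4g M^-1 s^-1\n", x$kinact_over_Ki))
  cat(sprintf("  covalent intermediate accumulates: %s\n",
              x$intermediate_accumulates))
  invisible(x)
}

#' Half-life of a first-order process
#'
#' `t_1/2 = ln(2)/k`. Used for the lifetime of the covalent glycosyl-enzyme
#' intermediate, whose decay rate is `k5` (or `kcat` when `kcat ~ k5`).
#'
#' @param k first-order rate constant (s^-1), > 0.
#' @return half-life in seconds.
#' @export
#' @examples
#' half_life(5.9e-4) / 60 # minutes
half_life <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0))
    stop("half_life requires k > 0")
  log(2) / k
}

#' Active-fraction correction of an observed kcat
#'
#' Continuous turnover assays report `kcat_obs = f * kcat_true` where `f` is
#' the fraction of enzyme that is catalytically active. When an independent
#' reference compound is known to satisfy `kcat_true = k5` (rate-limiting
#' hydrolysis of the covalent intermediate, with k5 measured from inactivation
#' data that does not assume full activity), the active fraction is
#' `f = kcat_obs_ref / k5_ref`, and any other observed kcat measured on the
#' same enzyme preparation can be corrected as `kcat_obs_target / f`.
#'
#' @param kcat_obs_ref observed kcat of the reference compound (s^-1).
#' @param k5_ref reactivation rate constant of the reference compound from
#'   inactivation data (s^-1).
#' @param kcat_obs_target observed kcat to correct (s^-1).
#' @return list with `active_fraction` (f) and `kcat_corrected` (s^-1).
#' @export
#' @examples
#' # f from the 2-fluoro reference, applied to the parent carbasugar
#' active_fraction_correction(2.29e-4, 5.9e-4, 3.78e-2)
active_fraction_correction <- function(kcat_obs_ref, k5_ref, kcat_obs_target) {
  if (kcat_obs_ref <= 0 || k5_ref <= 0)
    stop("reference rates must be positive")
  f <- kcat_obs_ref / k5_ref
  if (f > 1)
    stop("observed kcat exceeds k5; correction invalid")
  list(active_fraction = f, kcat_corrected = kcat_obs_target / f)
}

#' Fold ratio of two rate constants
#'
#' @param a,b rate constants (same units); `b > 0`.
#' @param sig_figs significant figures for the rounded ratio (default 1, the
#'   precision at which fold-changes are usually quoted).
#' @return list with `raw` (a/b) and `rounded` (signif to `sig_figs`).
#' @export
#' @examples
#' fold_ratio(2.25e4, 56)$rounded # 400
fold_ratio <- function(a, b, sig_figs = 1) {
  if (b <= 0) stop("fold_ratio requires b > 0")
  raw <- a / b
  list(raw = raw, rounded = signif(raw, sig_figs))
}
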