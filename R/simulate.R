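#' Simulate the full covalent-inhibition cycle by mass action
#'
#' Integrates the mass-action ODE system for
#' `E + I <-> E:I -> E-I -> E + P`:
#' \deqn{dE/dt    = -k_1 E I + k_{-1} EI + k_5 EcovI}
#' \deqn{dEI/dt   =  k_1 E I - (k_{-1} + k_3) EI}
#' \deqn{dEcovI/dt = k_3 EI - k_5 EcovI}
#' \deqn{dI/dt    = -k_1 E I + k_{-1} EI}
#' \deqn{dP/dt    =  k_5 EcovI}
#' with a stiff adaptive solver ([deSolve::lsoda()]). Enzyme
#' (`E + E:I + E-I = E0`) and inhibitor (`I + E:I + E-I + P = I0`) mass are
#' conserved and checked at every output time.
#'
#' @param scheme a [rate_scheme()].
#' @param E0,I0 total enzyme and inhibitor concentrations (M), > 0.
#' @param times strictly increasing time grid (s); should start at 0.
#' @param atol,rtol absolute (M) and relative solver tolerances. The absolute
#'   tolerance defaults to `1e-12 * min(E0, I0)` so that accuracy scales with
#'   the concentrations in play (assays here span nM enzyme to mM inhibitor).
#' @return data.frame of class `simulation_state` with columns `time`, `E`,
#'   `EI` (Michaelis complex), `EcovI` (covalent intermediate), `I`, `P`
#'   (hydrolyzed carbasugar product; the aglycone is released stoichiometrically
#'   with `EcovI + P`, returned as column `aglycone`).
#' @export
#' @examples
#' sch <- rate_scheme(1e5, 70, 0.1, 5.9e-4)
#' out <- simulate_cycle(sch, E0 = 1e-8, I0 = 1e-5, times = seq(0, 600, 10))
#' head(out)
simulate_cycle <- function(scheme, E0, I0, times, atol = NULL, rtol = 1e-10) {
  stopifnot(inherits(scheme, "rate_scheme"))
  if (E0 <= 0 || I0 <= 0) stop("E0 and I0 must be > 0")
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  if (is.null(atol)) atol <- 1e-12 * min(E0, I0)

  # integrate the three independent pools; free E and I follow from the
  # conservation laws, which therefore hold to machine precision
  y0 <- c(EI = 0, EcovI = 0, P = 0)
  p <- unlist(scheme[c("k1", "k_minus1", "k3", "k5")])
  deriv <- function(t, y, p) {
    E <- E0 - y[["EI"]] - y[["EcovI"]]
    I <- I0 - y[["EI"]] - y[["EcovI"]] - y[["P"]]
    bind <- p[["k1"]] * E * I
    diss <- p[["k_minus1"]] * y[["EI"]]
    gly  <- p[["k3"]] * y[["EI"]]
    hyd  <- p[["k5"]] * y[["EcovI"]]
    list(c(EI = bind - diss - gly, EcovI = gly - hyd, P = hyd))
  }
  sol <- deSolve::lsoda(y0, times, deriv, p, atol = atol, rtol = rtol)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff solver failed: istate = ", attr(sol, "istate")[1],
         " at t = ", max(sol[, "time"]))
  out <- as.data.frame(sol)
  out$E <- E0 - out$EI - out$EcovI
  out$I <- I0 - out$EI - out$EcovI - out$P
  out <- out[, c("time", "E", "EI", "EcovI", "I", "P")]

  neg <- out[c("E", "EI", "EcovI", "I", "P")] < -1e5 * atol
  if (any(neg)) stop("negative concentration beyond tolerance in ODE solution")
  # conservation holds by construction; verify before clipping solver noise
  cons_E <- abs(out$E + out$EI + out$EcovI - E0) / E0
  cons_I <- abs(out$I + out$EI + out$EcovI + out$P - I0) / I0
  if (max(cons_E) > 1e-9 || max(cons_I) > 1e-9)
    stop("mass conservation violated beyond solver tolerance")
  out[c("E", "EI", "EcovI", "I", "P")] <-
    lapply(out[c("E", "EI", "EcovI", "I", "P")], pmax, 0)

  out$aglycone <- out$EcovI + out$P
  attr(out, "E0") <- E0
  attr(out, "I0") <- I0
  attr(out, "scheme") <- scheme
  class(out) <- c("simulation_state", "data.frame")
  out
}

#' Two-state residual-activity model
#'
#' Reduction of the covalent-inhibition cycle to active (E + E:I) and
#' inactive (E-I) enzyme: at inhibitor excess and rapid binding
#' pre-equilibrium, the remaining activity fraction follows
#' \deqn{F(t) = F_{ss} + (1 - F_{ss}) e^{-(k_{obs} + k_5) t}, \qquad
#'       F_{ss} = \frac{k_5}{k_{obs} + k_5}}
#' where \eqn{k_{obs} = k_{inact} [I] / (K_i + [I])} is the pseudo-first-order
#' inactivation rate at the given inhibitor concentration. With `k5 = 0`
#' (a true inactivator) this reduces to a single exponential
#' `F(t) = exp(-kobs t)`.
#'
#' @param kobs pseudo-first-order inactivation rate constant (s^-1), >= 0.
#' @param k5 reactivation rate constant (s^-1), >= 0; not both zero.
#' @param t time or vector of times (s).
#' @return activity fraction(s) F in `[0, 1]`.
#' @export
#' @examples
#' activity_fraction(2e-3, 5.9e-4, c(0, 300, 3000))
activity_fraction <- function(kobs, k5, t) {
  if (kobs < 0 || k5 < 0) stop("rates must be >= 0")
  if (kobs + k5 == 0) stop("kobs and k5 must not both be zero")
  F_ss <- k5 / (kobs + k5)
  F_ss + (1 - F_ss) * exp(-(kobs + k5) * t)
}

#' Sequential-mixing stopped-flow / dilution inactivation assay
#'
#' Emulates the two-stage residual-activity experiment: enzyme and inhibitor
#' are mixed and incubated (phase 1, full mass-action kinetics), then an
#' aliquot is diluted into saturating reporter substrate (phase 2) where the
#' remaining activity is read. Because the dilution drops the inhibitor far
#' below its Kd, the Michaelis complex `E:I` dissociates on the assay
#' timescale while the covalent `E-I` does not; residual activity is therefore
#' `F(t_inc) = ([E] + [E:I]) / E0` at the end of incubation.
#'
#' @param scheme a [rate_scheme()].
#' @param E0 enzyme concentration during incubation (M).
#' @param I_concs inhibitor concentrations (M), one trace each.
#' @param incubation_times incubation times (s), >= 0.
#' @param dilution_factor fold dilution into the reporter mix (default 50,
#'   i.e. a 10 uL aliquot into 500 uL); recorded as trace metadata.
#' @param reporter optional list `(S0, kcat_S, Km_S)` describing the reporter
#'   substrate (chromogenic aryl galactoside read at 400 nm); recorded as
#'   metadata. `Km_S` must be > 0 when given.
#' @return list of [assay_trace()] objects (one per inhibitor concentration),
#'   each with columns `time` and `F`.
#' @export
#' @examples
#' sch <- rate_scheme(1e5, 70, 0.1, 5.9e-4)
#' tr <- simulate_stopped_flow(sch, 1e-8, I_concs = 2e-5,
#'                             incubation_times = seq(0, 1200, 60))
#' tr[[1]]
simulate_stopped_flow <- function(scheme, E0, I_concs, incubation_times,
                                  dilution_factor = 50, reporter = NULL) {
  stopifnot(inherits(scheme, "rate_scheme"))
  if (any(incubation_times < 0)) stop("incubation times must be >= 0")
  if (!is.null(reporter) && (is.null(reporter$Km_S) || reporter$Km_S <= 0))
    stop("reporter Km_S must be > 0")
  incubation_times <- sort(unique(incubation_times))
  lapply(I_concs, function(I0) {
    tt <- incubation_times
    run_t <- if (tt[1] > 0) c(0, tt) else tt
    if (length(run_t) < 2) run_t <- c(run_t, run_t + 1) # degenerate single point
    sim <- simulate_cycle(scheme, E0, I0, run_t)
    keep <- match(tt, sim$time)
    F <- (sim$E[keep] + sim$EI[keep]) / E0
    assay_trace(time = tt, value = F, kind = "activity_fraction",
                meta = list(inhibitor_M = I0, E0_M = E0,
                            dilution_factor = dilution_factor,
                            reporter_S0_M = reporter$S0,
                            reporter_kcat_S = reporter$kcat_S,
                            reporter_Km_S = reporter$Km_S))
  })
}

#' Beer-Lambert conversions for the 400 nm reporter signal
#'
#' Release of 4-nitrophenolate from the reporter substrate is followed at
#' 400 nm; `A = epsilon * l * P`.
#'
#' @param P product concentration (M).
#' @param A absorbance (AU).
#' @param epsilon400 molar extinction coefficient at 400 nm (M^-1 cm^-1).
#'   Default 1.0e4, an assumption for 4-nitrophenolate at pH 7.4 — configure
#'   to the calibrated value of your instrument/buffer.
#' @param path optical path length (cm).
#' @return absorbance (AU) or concentration (M).
#' @export
absorbance_from_product <- function(P, epsilon400 = 1e4, path = 1) {
  if (any(P < 0) || epsilon400 < 0 || path < 0) stop("inputs must be >= 0")
  epsilon400 * path * P
}

#' @rdname absorbance_from_product
#' @export
concentration_from_absorbance <- function(A, epsilon400 = 1e4, path = 1) {
  if (any(A < 0)) stop("inputs must be >= 0")
  if (epsilon400 * path <= 0) stop("epsilon * path must be > 0")
  A / (epsilon400 * path)
}

#' Assay trace container
#'
#' A time series from one kinetic experiment: absorbance (AU) or residual
#' activity fraction (dimensionless), with assay metadata.
#'
#' @param time strictly increasing time grid (s).
#' @param value observable series.
#' @param kind `"activity_fraction"` or `"absorbance"`.
#' @param meta named list of metadata (inhibitor concentration, dilution
#'   factor, reporter parameters, noise settings, ...).
#' @return data.frame of class `assay_trace` with columns `time` and `F` (or
#'   `A` for absorbance); metadata in `attr(, "meta")`.
#' @export
assay_trace <- function(time, value, kind = c("activity_fraction", "absorbance"),
                        meta = list()) {
  kind <- match.arg(kind)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (length(time) != length(value)) stop("time and value lengths differ")
  col <- if (kind == "activity_fraction") "F" else "A"
  out <- data.frame(time = time, value = value)
  names(out)[2] <- col
  attr(out, "kind") <- kind
  attr(out, "meta") <- meta[!vapply(meta, is.null, logical(1))]
  class(out) <- c("assay_trace", "data.frame")
  out
}

#' Read and write assay traces as annotated CSV
#'
#' CSV with `# key=value` comment header lines carrying the trace metadata,
#' then a `time,<observable>` table.
#'
#' @param trace an [assay_trace()].
#' @param path file path.
#' @return `write_assay_trace` returns `path` invisibly; `read_assay_trace`
#'   returns an [assay_trace()].
#' @export
write_assay_trace <- function(trace, path) {
  stopifnot(inherits(trace, "assay_trace"))
  meta <- attr(trace, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s", attr(trace, "kind")), con)
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, format(meta[[k]], digits = 15)), con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assay_trace
#' @export
read_assay_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- as.list(vals)
  names(meta) <- keys
  num <- suppressWarnings(as.numeric(vals))
  meta[!is.na(num)] <- num[!is.na(num)]
  kind <- if (!is.null(meta$kind)) meta$kind else "activity_fraction"
  meta$kind <- NULL
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  assay_trace(df$time, df[[2]], kind = kind, meta = meta)
}
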