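#' Published kinetic parameters for TmGalA and its carbasugar ligands
#'
#' The reference kinetic constants (SI units) for the Thermotoga maritima
#' GH36 alpha-galactosidase acting on the cyclohexene carbagalactose analogs
#' and control compounds, as determined at 37 C in 50 mM HEPES pH 7.4:
#' turnover parameters (kcat, kcat/Km, Km) for the dinitrophenyl carbasugar
#' (`"3b"`), its 2-deoxy-2-fluoro analog (`"4"`), the 2-deoxy-2-fluoro
#' galactoside substrate (`"7"`) and 4-nitrophenyl galactoside on the D387A
#' acid/base mutant (`"4NPG_D387A"`) plus the wild-type reference
#' (`"4NPG_WT"`); and inactivation parameters (kinact, kinact/Ki, Ki) for
#' `"4"` (slope only; kinact and Ki individually indeterminable) and the
#' cyclophellitol analog (`"8"`). The corrected kcat values derived from the
#' inactivation data (active-fraction correction) are carried in
#' `kcat_corrected`.
#'
#' @return data.frame, one row per compound, columns `compound`, `kcat`,
#'   `kcat_over_Km`, `Km`, `kinact`, `kinact_over_Ki`, `Ki`,
#'   `kcat_corrected` (NA where not applicable/printed). Units s^-1, M,
#'   M^-1 s^-1.
#' @export
#' @examples
#' tmgala_parameters()
tmgala_parameters <- function() {
  data.frame(
    compound       = c("3b", "4", "7", "4NPG_D387A", "4NPG_WT", "8"),
    kcat           = c(3.78e-2, 2.29e-4, 3.04, 3.60e-2, 33, NA),
    kcat_over_Km   = c(2.25e4, 56, 1200, 196, 6.2e5, NA),
    Km             = c(1.68e-6, 4.1e-6, 253e-6, 184e-6, NA, NA),
    kinact         = c(NA, NA, NA, NA, NA, 1.38e-4),
    kinact_over_Ki = c(NA, 143, NA, NA, NA, 0.86),
    Ki             = c(NA, NA, NA, NA, NA, 161e-6),
    kcat_corrected = c(9.7e-2, 5.9e-4, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Reference microscopic rate schemes per compound class
#'
#' Builds a [rate_scheme()] consistent with the measured observables for the
#' three mechanistic regimes:
#' * `"4"` (covalent inhibitor, k3 >> k5 > 0): k5 = 5.9e-4 s^-1 from the
#'   inactivation data; k3 = 0.1 s^-1 (well into the accumulating regime);
#'   Kd = k3 / (kinact/Ki) with kinact/Ki = 143 M^-1 s^-1, which reproduces
#'   Km = 4.1 uM.
#' * `"7"` (substrate, k3 < k5): kcat = 3.04 s^-1 with k5 = 10 k3 so that
#'   glycosylation is rate-determining; Kd from kcat/Km = 1200 M^-1 s^-1.
#' * `"8"` (covalent inactivator, k5 = 0): k3 = kinact = 1.38e-4 s^-1,
#'   Kd = Ki = 161 uM.
#'
#' The association rate `k1` is not an observable of any of the assays; the
#' default 1e5 M^-1 s^-1 keeps `k_minus1 >> k3` so rapid-equilibrium binding
#' holds.
#'
#' @param compound `"4"`, `"7"` or `"8"`.
#' @param k1 bimolecular association rate constant (M^-1 s^-1).
#' @return a [rate_scheme()].
#' @export
#' @examples
#' derive_steady_state(scheme_for_compound("4"))
scheme_for_compound <- function(compound = c("4", "7", "8"), k1 = 1e5) {
  compound <- match.arg(compound)
  switch(compound,
    "4" = {
      k3 <- 0.1
      k5 <- 5.9e-4
      Kd <- k3 / 143
      rate_scheme(k1, k1 * Kd, k3, k5)
    },
    "7" = {
      kcat <- 3.04
      k3 <- kcat * 11 / 10   # kcat = k3*k5/(k3+k5) with k5 = 10*k3
      k5 <- 10 * k3
      Kd <- k3 / 1200
      rate_scheme(k1, k1 * Kd, k3, k5)
    },
    "8" = {
      Kd <- 161e-6
      rate_scheme(k1, k1 * Kd, 1.38e-4, 0)
    }
  )
}

#' Multiplicative + additive noise model for synthetic assays
#'
#' Observations are generated as `y = mu * (1 + cv * z) + floor * x` with
#' independent standard-normal `z`, `x`. Identical seeds give identical data
#' (R's default Mersenne-Twister RNG).
#'
#' @param cv multiplicative coefficient of variation (fraction, >= 0).
#'   Defaults: 2% for initial rates, 3% for activity traces.
#' @param floor additive noise SD in the observable's units (default 0).
#' @param seed integer RNG seed.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.02, floor = 0, seed = 1L) {
  if (cv < 0 || floor < 0) stop("cv and floor must be >= 0")
  structure(list(cv = cv, floor = floor, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(mu, noise) {
  set.seed(noise$seed)
  mu * (1 + noise$cv * stats::rnorm(length(mu))) +
    noise$floor * stats::rnorm(length(mu))
}

#' Log-spaced Michaelis-Menten substrate design
#'
#' At least six concentrations spanning Km/4 to 4 Km (inclusive endpoints),
#' log-spaced.
#'
#' @param Km Michaelis constant (M), > 0.
#' @param n number of concentrations (>= 4; default 6).
#' @param span two-element range (M); default `c(Km/4, 4*Km)`.
#' @return numeric vector of substrate concentrations (M).
#' @export
#' @examples
#' make_mm_design(Km = 184e-6)
make_mm_design <- function(Km, n = 6, span = c(Km / 4, 4 * Km)) {
  if (Km <= 0) stop("Km must be > 0")
  if (n < 4) stop("need n >= 4 concentrations")
  if (length(span) != 2 || any(span <= 0) || span[2] <= span[1])
    stop("span must be an increasing positive range")
  exp(seq(log(span[1]), log(span[2]), length.out = n))
}

#' Synthetic initial-rate dataset
#'
#' Generates noisy Michaelis-Menten initial rates over a substrate design.
#'
#' @param design substrate concentrations (M), e.g. from [make_mm_design()].
#' @param params list with `kcat` (s^-1) and `Km` (M), or a [rate_scheme()]
#'   (observables derived via [derive_steady_state()]).
#' @param E0 enzyme concentration (M).
#' @param noise a [noise_model()].
#' @return an `assay_dataset` data.frame with columns `S`, `v`, `sigma` and
#'   attribute `truth`.
#' @export
#' @examples
#' d <- generate_rates(make_mm_design(184e-6),
#'                     list(kcat = 3.60e-2, Km = 184e-6),
#'                     E0 = 1e-8, noise = noise_model(0.02, seed = 42))
generate_rates <- function(design, params, E0, noise = noise_model()) {
  if (inherits(params, "rate_scheme")) params <- derive_steady_state(params)
  mu <- params$kcat * E0 * design / (params$Km + design)
  v <- apply_noise(mu, noise)
  out <- data.frame(S = design, v = pmax(v, 0), sigma = pmax(mu * noise$cv, noise$floor))
  attr(out, "truth") <- list(kcat = params$kcat, Km = params$Km, E0 = E0)
  class(out) <- c("assay_dataset", "data.frame")
  out
}

#' Synthetic inactivation time-course panel
#'
#' Residual-activity traces at several inhibitor concentrations, following
#' the two-state reduction [activity_fraction()] with
#' `kobs = kinact * I / (Ki + I)`, with multiplicative noise.
#'
#' @param scheme a [rate_scheme()] (kinact, Ki, k5 derived) or a list with
#'   `kinact`, `Ki`, `k5`.
#' @param I_concs inhibitor concentrations (M).
#' @param t_grid time grid (s).
#' @param noise a [noise_model()] (CV applied per point; traces get
#'   independent sub-seeds derived from `noise$seed`).
#' @return list of [assay_trace()] objects.
#' @export
generate_inactivation_panel <- function(scheme, I_concs, t_grid,
                                        noise = noise_model(cv = 0.03)) {
  p <- if (inherits(scheme, "rate_scheme")) {
    ss <- derive_steady_state(scheme)
    list(kinact = ss$kinact, Ki = ss$Ki_app, k5 = scheme$k5)
  } else scheme
  lapply(seq_along(I_concs), function(i) {
    I <- I_concs[i]
    kobs <- p$kinact * I / (p$Ki + I)
    mu <- activity_fraction(kobs, p$k5, t_grid)
    sub <- noise_model(noise$cv, noise$floor,
                       seed = (as.numeric(noise$seed) * 1009 + i) %% 2147483647)
    F <- apply_noise(mu, sub)
    assay_trace(t_grid, F, "activity_fraction",
                meta = list(inhibitor_M = I, kobs_true = kobs, k5_true = p$k5,
                            cv = noise$cv, seed = sub$seed))
  })
}

#' Ideal six-membered-ring geometry for a given pucker
#'
#' Places six atoms on a regular hexagon of radius `radius` in the xy-plane
#' and applies the out-of-plane displacements
#' \deqn{z_j = \sqrt{1/3}\, q_2 \cos\!\big(\phi_2 + 4\pi (j-1)/6\big)
#'           + \sqrt{1/6}\, q_3 (-1)^{j-1}}
#' with \eqn{q_2 = Q \sin\theta}, \eqn{q_3 = Q \cos\theta}, \eqn{\phi_2 =
#' \phi}. By construction \eqn{\sum z_j = 0} and the two first-harmonic sums
#' vanish, so the hexagon's plane is exactly the Cremer-Pople mean plane and
#' [cremer_pople()] recovers `(Q, theta, phi)`.
#'
#' @param conformer canonical conformer name (e.g. `"4C1"`, `"2H3"`, `"1S3"`,
#'   `"B2,5"`, `"3E"`; see [canonical_conformers()]) — mutually exclusive
#'   with `Q`/`theta`/`phi`.
#' @param Q total puckering amplitude (Angstrom, >= 0).
#' @param theta polar puckering angle (degrees, `[0, 180]`).
#' @param phi azimuthal puckering angle (degrees, `[0, 360)`).
#' @param radius hexagon radius (Angstrom); default 1.46 gives C-C bonds of
#'   ~1.5 A. Does not affect the puckering coordinates.
#' @param labels six atom labels; default the pyranose-equivalent ordering
#'   `O5, C1..C5`.
#' @return a [ring_coordinates()] object (6 x 3 coordinates).
#' @export
#' @examples
#' r <- ideal_ring(Q = 0.5, theta = 0, phi = 0) # ideal 4C1 chair
#' cremer_pople(r)
ideal_ring <- function(conformer = NULL, Q = 0.5, theta = 0, phi = 0,
                       radius = 1.46,
                       labels = c("O5", "C1", "C2", "C3", "C4", "C5")) {
  if (!is.null(conformer)) {
    tab <- canonical_conformers()
    hit <- match(conformer, tab$name)
    if (is.na(hit))
      stop("unknown conformer '", conformer, "'; valid names: ",
           paste(tab$name, collapse = ", "))
    theta <- tab$theta[hit]
    phi <- tab$phi[hit]
  }
  if (Q < 0) stop("Q must be >= 0")
  j <- 0:5
  # clockwise when viewed from +z: +z is the IUPAC "above" side and the
  # Cremer-Pople mean-plane normal, so theta = 0 is the 4C1 chair
  ang <- -2 * pi * j / 6
  q2 <- Q * sin(theta * pi / 180)
  q3 <- Q * cos(theta * pi / 180)
  z <- sqrt(1 / 3) * q2 * cos(phi * pi / 180 + 4 * pi * j / 6) +
    sqrt(1 / 6) * q3 * (-1)^j
  xyz <- cbind(x = radius * cos(ang), y = radius * sin(ang), z = z)
  ring_coordinates(xyz, labels = labels)
}

#' Write a six-atom ring as a single-residue PDB fixture
#'
#' HETATM records, one residue (`resname`, residue 1, chain A); elements are
#' taken from the first character of each atom label.
#'
#' @param ring a [ring_coordinates()].
#' @param path output file path.
#' @param resname 3-letter residue name (default `"RNG"`).
#' @return `path`, invisibly.
#' @export
write_ring_pdb <- function(ring, path, resname = "RNG") {
  stopifnot(inherits(ring, "ring_coordinates"))
  xyz <- unclass(ring)
  labels <- attr(ring, "labels")
  lines <- vapply(1:6, function(i) {
    sprintf("HETATM%5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, labels[i], resname, 1L,
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.00, 0.00,
            substr(labels[i], 1, 1))
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
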