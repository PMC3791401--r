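# Equilibrium DNA-binding biophysics: 1:1 Langmuir isotherm fitting of
# binding-response curves, fractional site occupancy, and conversion of
# per-cell protein copy numbers and nuclear-envelope geometry into nuclear
# concentrations.

#' Fractional occupancy under 1:1 equilibrium binding
#'
#' The equilibrium fraction of sites bound at free-ligand concentration
#' `c` is `c / (c + kd)`; exactly half of the available sites are occupied
#' at `c == kd`, and occupancy approaches 1 as `c` grows.
#'
#' @param c free-ligand concentration (molar), >= 0.
#' @param kd dissociation constant (molar), > 0.
#' @return Occupancy in [0, 1).
#' @examples
#' fractionalOccupancy(14e-9, 14e-9)   # 0.5
#' fractionalOccupancy(2.9e-6, 14e-9)  # ~0.995
#' @export
fractionalOccupancy <- function(c, kd) {
  if (any(c < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (any(kd <= 0)) stop("kd must be > 0", call. = FALSE)
  c / (c + kd)
}

#' Ratio of a concentration to a dissociation constant
#'
#' The fold by which a nuclear concentration exceeds a site's Kd; values
#' far above 1 predict near-saturated occupancy of accessible sites.
#'
#' @param c concentration (molar), > 0.
#' @param kd dissociation constant (molar), > 0.
#' @return `c / kd`.
#' @export
concentrationKdRatio <- function(c, kd) {
  if (any(c <= 0) || any(kd <= 0)) {
    stop("concentration and kd must be > 0", call. = FALSE)
  }
  c / kd
}

#' Fit a 1:1 binding isotherm to (concentration, response) data
#'
#' Nonlinear least squares of `R = Rmax c / (Kd + c)` via
#' Levenberg-Marquardt, initialised at `Kd = median(c)`,
#' `Rmax = max(R)`.  Deterministic for fixed input.
#'
#' @param concentrations molar concentrations (>= 3 values spanning at
#'   least one decade).
#' @param responses equilibrium response at each concentration (amplitude
#'   at the end of the association step).
#' @return A [BindingCurve-class] with fitted `kd`, `rmax` and the
#'   residual norm.
#' @examples
#' conc <- 10^seq(log10(3e-9), log10(3.8e-6), length.out = 8)
#' resp <- 1 * conc / (14e-9 + conc)
#' fit <- fitBindingIsotherm(conc, resp)
#' kdValue(fit)
#' @export
fitBindingIsotherm <- function(concentrations, responses) {
  if (length(concentrations) != length(responses)) {
    stop("concentrations and responses must have equal length",
         call. = FALSE)
  }
  if (length(concentrations) < 3L) {
    stop("need >= 3 points to fit an isotherm", call. = FALSE)
  }
  if (any(concentrations <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (max(concentrations) / min(concentrations) < 10) {
    stop("concentrations must span at least one decade", call. = FALSE)
  }
  if (diff(range(responses)) == 0) {
    stop("responses are all equal; isotherm is unidentifiable",
         call. = FALSE)
  }
  df <- data.frame(c = concentrations, R = responses)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      R ~ Rmax * c / (Kd + c), data = df,
      start = list(Kd = median(df$c), Rmax = max(df$R)),
      lower = c(Kd = .Machine$double.xmin, Rmax = .Machine$double.xmin),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("isotherm fit failed to converge: ", conditionMessage(e),
           call. = FALSE)
    })
  est <- coef(fit)
  new("BindingCurve",
      concentrations = as.numeric(concentrations),
      responses = as.numeric(responses),
      kd = unname(est["Kd"]), rmax = unname(est["Rmax"]),
      residualNorm = sqrt(sum(residuals(fit)^2)))
}

#' Protein copy number from mass and molecular weight
#'
#' `copies = mass[g] / MW[g/mol] * N_A` with mass in ng and MW in kDa, as
#' used to convert immunoblot standard-curve masses into molecules per
#' embryo or cell.
#'
#' @param massNg protein mass in nanograms (>= 0).
#' @param molecularWeightKda molecular weight in kilodaltons (> 0).
#' @return Number of molecules.
#' @examples
#' copiesFromMass(1, 50)  # ~1.204e10 molecules
#' @export
copiesFromMass <- function(massNg, molecularWeightKda) {
  if (any(molecularWeightKda <= 0)) stop("MW must be > 0", call. = FALSE)
  if (any(massNg < 0)) stop("mass must be >= 0", call. = FALSE)
  (massNg * 1e-9) / (molecularWeightKda * 1e3) * AVOGADRO
}

#' Copies per cell from a total count and a cell census
#'
#' @param totalCopies total molecules in the assayed material.
#' @param nCells number of expressing cells it derives from.
#' @return Molecules per cell.
#' @export
copiesPerCell <- function(totalCopies, nCells) {
  if (any(nCells <= 0)) stop("nCells must be > 0", call. = FALSE)
  totalCopies / nCells
}

#' Nuclear concentration from copy number and nuclear-envelope geometry
#'
#' Models the nucleus as a sphere whose envelope surface is measured:
#' `radius = sqrt(S / 4 pi)`, `volume = 4/3 pi r^3` (converted from um^3
#' to litres), and `concentration = copies * nuclearFraction /
#' (volume_L * N_A)`.  With the canonical inputs (surface ~300 um^2, 90%
#' nuclear localisation) a midgastrula nucleus has radius ~4.89 um and
#' volume ~489 um^3.
#'
#' @param copiesPerCell protein molecules per cell.
#' @param nuclearFraction fraction of the protein that is nuclear, in
#'   (0, 1].
#' @param envelopeSurface nuclear-envelope surface area in um^2 (> 0).
#' @return A list with `radius_um`, `volume_um3`, `volume_l` and
#'   `concentration_molar`.
#' @examples
#' nuclearConcentration(9.5e5, 0.9, 300)$concentration_molar  # ~2.9e-6 M
#' @export
nuclearConcentration <- function(copiesPerCell, nuclearFraction,
                                 envelopeSurface) {
  if (envelopeSurface <= 0) stop("surface must be > 0", call. = FALSE)
  if (nuclearFraction <= 0 || nuclearFraction > 1) {
    stop("nuclearFraction must be in (0, 1]", call. = FALSE)
  }
  r <- sqrt(envelopeSurface / (4 * pi))
  v_um3 <- (4 / 3) * pi * r^3
  v_l <- v_um3 * 1e-15
  conc <- copiesPerCell * nuclearFraction / (v_l * AVOGADRO)
  list(radius_um = r, volume_um3 = v_um3, volume_l = v_l,
       concentration_molar = conc)
}

#' Copies per cell needed for a target nuclear concentration
#'
#' Algebraic inverse of [nuclearConcentration()]; useful for round-trip
#' checks and for asking how many molecules a measured concentration
#' implies.
#'
#' @param concentrationMolar target nuclear concentration (molar).
#' @inheritParams nuclearConcentration
#' @return Molecules per cell.
#' @export
copiesForConcentration <- function(concentrationMolar, nuclearFraction,
                                   envelopeSurface) {
  if (envelopeSurface <= 0) stop("surface must be > 0", call. = FALSE)
  if (nuclearFraction <= 0 || nuclearFraction > 1) {
    stop("nuclearFraction must be in (0, 1]", call. = FALSE)
  }
  r <- sqrt(envelopeSurface / (4 * pi))
  v_l <- (4 / 3) * pi * r^3 * 1e-15
  concentrationMolar * v_l * AVOGADRO / nuclearFraction
}
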