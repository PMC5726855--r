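#' Cellular and synaptic constants of the population model
#'
#' Returns the shared biophysical constants of the activity-based population
#' model: synaptic conductances and reversal potentials, output-function
#' breakpoints, persistent-sodium (INaP) kinetics of the rhythm-generator
#' centers, and the Ornstein-Uhlenbeck noise time constant. Any constant can
#' be overridden by name, e.g. `cell_constants(gSynE = 12)`.
#'
#' @param ... named overrides of individual constants.
#'
#' @return A named list with elements:
#' \describe{
#'   \item{gSynE, gSynI}{synaptic conductances (nS), both 10.}
#'   \item{ESynE, ESynI}{synaptic reversal potentials (mV), -10 and -75.}
#'   \item{ENa}{sodium reversal potential (mV), 50.}
#'   \item{Vthr, Vmax}{output-function breakpoints (mV), -50 and 0.}
#'   \item{gNaP}{maximal INaP conductance (nS), 4.5.}
#'   \item{V12m, km}{INaP activation half-voltage (mV) and slope (mV), -40 and -6.}
#'   \item{V12h, kh}{INaP inactivation half-voltage and slope (mV), -45 and 4.}
#'   \item{V12tau, ktau}{half-voltage and slope (mV) of the inactivation
#'     time-constant curve, -35 and 15.}
#'   \item{tau0, taumax}{baseline and maximal inactivation time constant (ms),
#'     80 and 160.}
#'   \item{tauNoise}{noise time constant (ms), 10.}
#' }
#' @export
#' @examples
#' cst <- cell_constants()
#' cst$gNaP
cell_constants <- function(...) {
  cst <- list(
    gSynE = 10, gSynI = 10,
    ESynE = -10, ESynI = -75, ENa = 50,
    Vthr = -50, Vmax = 0,
    gNaP = 4.5,
    V12m = -40, km = -6,
    V12h = -45, kh = 4,
    V12tau = -35, ktau = 15,
    tau0 = 80, taumax = 160,
    tauNoise = 10
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cst))
    if (length(bad))
      stop("unknown constant(s): ", paste(bad, collapse = ", "))
    cst[names(over)] <- over
  }
  stopifnot(cst$Vthr < cst$Vmax, cst$tau0 < cst$taumax)
  cst
}
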