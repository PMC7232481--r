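## Substrate-side bookkeeping: trace-element contributions of the feed
## components, VFA unit conversions, Buswell/COD methane stoichiometry and
## the COD balance.

#' Round to significant digits, half to even
#'
#' Significant-figure rounding with banker's (round-half-to-even) behaviour
#' at ties, as used for all printed-table comparisons.
#'
#' @param x numeric.
#' @param digits significant digits (default 2).
#' @return rounded numeric.
#' @export
signifEven <- function(x, digits = 2) {
  out <- x
  nz <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz]))) - digits + 1
  out[nz] <- round(x[nz] / 10^e) * 10^e
  out
}

#' Default substrate trace-element contribution table
#'
#' Calculated concentrations of Co, Ni, Se and W contributed by the
#' components of the chemically defined substrate (glucose, sucrose, casein,
#' tap water, vitamin, trace-element and Se/W solutions), in ng per litre of
#' substrate, each entry rounded to two significant digits. Casein dominates
#' every element (e.g. ~540 ng Co/L, ~26 ug Ni/L).
#'
#' @return a [SubstrateTable-class].
#' @export
substrateTable <- function() {
  m <- rbind(
    `Glucose`                = c(Co = 1,   Ni = 63,     Se = 75,   W = 0),
    `Sucrose`                = c(Co = 6,   Ni = 75,     Se = 1100, W = 0),
    `Casein`                 = c(Co = 540, Ni = 26000,  Se = 3000, W = 230),
    `Tap water`              = c(Co = 8,   Ni = 210,    Se = 14,   W = 0),
    `Vitamin solution`       = c(Co = 2,   Ni = 0,      Se = 2,    W = 0),
    `Trace element solution` = c(Co = 20,  Ni = 13,     Se = 4,    W = 2),
    `Se/W solution`          = c(Co = 0,   Ni = 0,      Se = 7,    W = 12)
  )
  new("SubstrateTable", contributions = m)
}

#' Total substrate contribution of one element
#'
#' Column sum over all substrate components, then rounded to two
#' significant digits (round-half-to-even).
#'
#' @param table a [SubstrateTable-class].
#' @param element element symbol.
#' @param digits significant digits of the reported total.
#' @return total contribution, ng per litre of substrate.
#' @examples
#' totalContribution(substrateTable(), "Co")  # 580
#' @export
totalContribution <- function(table, element, digits = 2) {
  stopifnot(is(table, "SubstrateTable"))
  if (!element %in% colnames(table@contributions))
    stop("unknown element '", element, "'")
  signifEven(sum(table@contributions[, element]), digits)
}

#' Molar masses of the volatile fatty acids
#'
#' @param acid optional acid name; when given, the scalar mass (g/mol).
#' @return named numeric vector (or scalar).
#' @export
acidMolarMass <- function(acid = NULL) {
  masses <- c(acetate = 60.05, propionate = 74.08, butyrate = 88.11,
              `iso-butyrate` = 88.11, valerate = 102.13,
              `iso-valerate` = 102.13)
  if (is.null(acid)) return(masses)
  if (!acid %in% names(masses))
    stop("unknown acid '", acid, "'; registered: ",
         paste(names(masses), collapse = ", "))
  masses[[acid]]
}

#' Convert a VFA concentration from mM to mg/L
#'
#' mg/L = mM x molar mass. The raw product is returned; pass `sigfig = 2`
#' to reproduce printed two-significant-figure equivalences (e.g. 10 mM
#' propionate -> 740 mg/L, 38 mM acetate -> 2300 mg/L).
#'
#' @param conc concentration, mM (non-negative).
#' @param acid acid name (see [acidMolarMass()]).
#' @param sigfig optional significant figures for reporting.
#' @return mg per litre.
#' @export
vfaToMgL <- function(conc, acid, sigfig = NULL) {
  stopifnot(all(conc >= 0))
  out <- conc * acidMolarMass(acid)
  if (!is.null(sigfig)) out <- signifEven(out, sigfig)
  out
}

#' COD-methane stoichiometric constant
#'
#' From CH4 + 2 O2 -> CO2 + 2 H2O, one mole of methane carries 64 g of COD,
#' and occupies 22,414 mL at 0 degrees C and 1 atm, so full COD conversion
#' yields 22,414/64 = 350.2 mL CH4 per gram of COD consumed (350 at 3
#' significant figures).
#'
#' @param sigfig significant figures (default `NULL`, the raw ratio).
#' @return mL CH4 per gCOD at dry normal conditions.
#' @export
codMethaneVolume <- function(sigfig = NULL) {
  v <- 22414 / 64
  if (!is.null(sigfig)) v <- signifEven(v, sigfig)
  v
}

#' Buswell stoichiometry of a substrate CnHaOb
#'
#' Theoretical anaerobic conversion
#' \deqn{C_nH_aO_b + (n - a/4 - b/2) H_2O \to (n/2 + a/8 - b/4) CH_4 +
#'       (n/2 - a/8 + b/4) CO_2}
#' giving the methane mole fraction of the biogas and the methane volume per
#' gram of compound at 0 degrees C, 1 atm.
#'
#' @param nC,nH,nO atom counts of the empirical formula.
#' @return list with `molCh4`, `molCo2` (per mol compound), `ch4Fraction`,
#'   `molarMass` (g/mol) and `mlCh4PerGram`.
#' @examples
#' buswell(6, 12, 6)$ch4Fraction  # glucose: 0.5
#' @export
buswell <- function(nC, nH, nO) {
  stopifnot(nC > 0, nH >= 0, nO >= 0)
  molCh4 <- nC / 2 + nH / 8 - nO / 4
  molCo2 <- nC / 2 - nH / 8 + nO / 4
  if (molCh4 < 0) stop("composition yields negative methane; not a Buswell substrate")
  molarMass <- nC * 12.011 + nH * 1.008 + nO * 15.999
  list(
    molCh4 = molCh4, molCo2 = molCo2,
    ch4Fraction = molCh4 / (molCh4 + molCo2),
    molarMass = molarMass,
    mlCh4PerGram = molCh4 * 22414 / molarMass
  )
}

#' COD balance closure
#'
#' Fraction of ingoing COD unaccounted for after methane and biomass:
#' \eqn{1 - f_{CH4} - f_{biomass}}.
#'
#' @param fracCh4 fraction of ingoing COD leaving as methane, in \eqn{[0,1]}.
#' @param fracBiomass fraction converted to microbial biomass, in \eqn{[0,1]}.
#' @return unaccounted fraction.
#' @examples
#' codBalance(0.56, 0.15)  # 0.29
#' @export
codBalance <- function(fracCh4, fracBiomass) {
  stopifnot(all(fracCh4 >= 0 & fracCh4 <= 1),
            all(fracBiomass >= 0 & fracBiomass <= 1))
  if (any(fracCh4 + fracBiomass > 1 + 1e-12))
    stop("fractions sum to more than 1")
  1 - fracCh4 - fracBiomass
}
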