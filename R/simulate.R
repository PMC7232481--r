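## Seeded generator of coherent synthetic digester experiments: gas
## kinetics, VFA trajectories, trace-element washout, a pH proxy, and
## drifting ASV tables, with logged ground-truth events.

#' @useDynLib cstbr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Simulation configuration
#'
#' All tunable parameters of the synthetic digester. Defaults encode the
#' study conditions: four 4-L mesophilic reactors at HRT 30 d and OLR
#' 1.7 gCOD/L/d, supplementation stopped on day 206, an accidental Se/W
#' pulse on days 109-110, a 350-day horizon, weekly VFA sampling and eight
#' community sampling days.
#'
#' @slot reactors data.frame with columns `id` and `depleted` (NA, "Co",
#'   "Ni" or "SeW").
#' @slot hrt,olr,volume operational constants (d, gCOD/L/d, L).
#' @slot horizonDays,depletionDay,pulseDays timeline (days).
#' @slot te list: `initial` (nM per element), `background` (bioavailable
#'   substrate-borne fraction, nM), `hillK` (half-saturation, nM, per
#'   TE-sensitive route), `hillN` (Hill exponent), `pulseTargets` (printed
#'   day-229 concentrations used to back-solve the pulse magnitudes).
#' @slot kinetics named list of rate constants, yields, product shares and
#'   inhibition constants of the COD-pool core (see the methods vignette).
#' @slot feed named list of feed COD fractions (ferm, acetate, propionate,
#'   slow, inert; must sum to 1).
#' @slot noise list: `flowSd` (mL/min), `ch4FracSd`.
#' @slot meter list: `temperature` (C), `pressure` (hPa), `saturated`.
#' @slot community list of community-generator parameters (sequencing
#'   depth, Dirichlet concentration, drift time constant in mM-days).
#' @slot sampleDays community sampling days.
#' @slot vfaEvery VFA sampling interval, days.
#' @slot teLimitation logical master switch for trace-element limitation.
#' @export
setClass("SimConfig",
  representation(
    reactors = "data.frame", hrt = "numeric", olr = "numeric",
    volume = "numeric", horizonDays = "numeric", depletionDay = "numeric",
    pulseDays = "numeric", te = "list", kinetics = "list", feed = "list",
    noise = "list", meter = "list", community = "list",
    sampleDays = "numeric", vfaEvery = "numeric", teLimitation = "logical"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  f <- object@feed
  tot <- f$ferm + f$acetate + f$propionate + f$slow + f$inert
  if (abs(tot - 1) > 1e-9)
    msgs <- c(msgs, sprintf("feed fractions must sum to 1 (got %g)", tot))
  for (nm in c("hrt", "olr", "volume", "horizonDays"))
    if (slot(object, nm) <= 0) msgs <- c(msgs, paste0("'", nm, "' must be positive"))
  kin <- object@kinetics
  for (nm in c("vS", "vA", "vP", "vH", "vB", "kSlowPerDay", "kiP", "kiH"))
    if (kin[[nm]] <= 0) msgs <- c(msgs, paste0("kinetics$", nm, " must be positive"))
  if (abs(kin$shareA + kin$shareP + kin$shareH - 1) > 1e-9)
    msgs <- c(msgs, "fermentation product shares must sum to 1")
  if (object@community$depth <= 0 || object@community$theta <= 0)
    msgs <- c(msgs, "community depth and theta must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d reactor(s) (%s), %g d horizon, depletion day %g\n",
    nrow(object@reactors), paste(object@reactors$id, collapse = ", "),
    object@horizonDays, object@depletionDay))
  cat(sprintf("  HRT %g d | OLR %g gCOD/L/d | V %g L | TE limitation %s\n",
    object@hrt, object@olr, object@volume,
    if (object@teLimitation) "on" else "off"))
})

#' Default simulation configuration
#'
#' @param reactors which reactors to simulate (subset of
#'   R_ctrl, R_Co, R_Ni, R_SeW).
#' @param horizonDays simulation horizon (default 350).
#' @param ... named overrides for any top-level slot or for entries of the
#'   `te`, `kinetics`, `feed`, `noise`, `meter`, `community` lists (pass a
#'   partial list; it is merged over the defaults).
#' @return a [SimConfig-class].
#' @examples
#' cfg <- simConfig(reactors = c("R_ctrl", "R_Ni"), horizonDays = 260)
#' @export
simConfig <- function(reactors = c("R_ctrl", "R_Co", "R_Ni", "R_SeW"),
                      horizonDays = 350, ...) {
  all <- data.frame(
    id = c("R_ctrl", "R_Co", "R_Ni", "R_SeW"),
    depleted = c(NA, "Co", "Ni", "SeW"),
    stringsAsFactors = FALSE
  )
  defaults <- list(
    reactors = all[all$id %in% reactors, , drop = FALSE],
    hrt = 30, olr = 1.7, volume = 4,
    horizonDays = horizonDays, depletionDay = 206, pulseDays = c(109, 110),
    te = list(
      initial = c(Co = 0.32, Ni = 0.13, Se = 0.07, W = 0.08),
      background = c(Co = 9.2, Ni = 0, Se = 0, W = 0),
      hillK = c(P = 0.35, H = 0.30),
      hillN = 3,
      pulseTargets = c(Se = 0.12, W = 0.13), pulseTargetDay = 229
    ),
    kinetics = list(
      vS = 0.01473, vA = 0.0042, vP = 0.0055, vH = 0.0042, vB = 0.0008,
      kSlowPerDay = 1 / 30,
      shareA = 0.55, shareP = 0.25, shareH = 0.20,
      bShiftMax = 0.30, bShiftK = 25,
      yF = 0.12, yP = 0.05, yB = 0.05, yA = 0.05, yH = 0.05,
      kiP = 8, kiH = 0.5,
      splitPA = 0.57, splitBA = 0.8,
      co2Meth = 0.6, co2Ferm = 0.25
    ),
    feed = list(ferm = 0.52, acetate = 0.04, propionate = 0.02,
                slow = 0.25, inert = 0.17),
    noise = list(flowSd = 0.15, ch4FracSd = 0.01),
    meter = list(temperature = 25, pressure = 1013.25, saturated = TRUE),
    community = list(depth = 20000, archaealDepth = 10000, theta = 200,
                     driftTau = 1500, archaealDrift = 0.15),
    sampleDays = c(104, 118, 201, 222, 257, 285, 320, 348),
    vfaEvery = 7,
    teLimitation = TRUE
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(defaults)) stop("unknown configuration field '", nm, "'")
    if (is.list(defaults[[nm]]) && !is.data.frame(defaults[[nm]]) &&
        is.list(dots[[nm]])) {
      defaults[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      defaults[[nm]] <- dots[[nm]]
    }
  }
  defaults$sampleDays <- defaults$sampleDays[defaults$sampleDays <= defaults$horizonDays]
  do.call(new, c(list("SimConfig"), defaults))
}

#' Trace-element dosing histories implied by a configuration
#'
#' Constant supplementation at the initial concentration, a step to zero at
#' the depletion day for the reactor's depleted element(s), and for Se/W the
#' accidental pulses on the configured pulse days, with magnitudes
#' back-solved from the printed day-229 concentrations
#' (see [backsolvePulse()]; the two pulse days share the magnitude equally).
#'
#' @param config a [SimConfig-class].
#' @param reactorId reactor whose depletion assignment applies.
#' @return named list of [TEDosingHistory-class], one per element.
#' @export
teHistories <- function(config, reactorId) {
  depleted <- config@reactors$depleted[config@reactors$id == reactorId]
  depletedElems <- if (length(depleted) == 0 || is.na(depleted)) character()
    else if (depleted == "SeW") c("Se", "W") else depleted
  out <- list()
  for (el in c("Co", "Ni", "Se", "W")) {
    c0 <- config@te$initial[[el]]
    ev <- data.frame(time = numeric(), kind = character(), value = numeric())
    if (el %in% c("Se", "W") && length(config@pulseDays)) {
      # single equivalent pulse at the mean pulse day, magnitude back-solved
      # from the printed day-229 concentration of the supplemented fraction
      ev <- rbind(ev, data.frame(time = mean(config@pulseDays),
                                 kind = "pulse", value = 0))
    }
    if (el %in% depletedElems)
      ev <- rbind(ev, data.frame(time = config@depletionDay,
                                 kind = "step", value = 0))
    ev <- ev[order(ev$time), , drop = FALSE]
    h <- teDosingHistory(el, c0, events = ev, hrt = config@hrt)
    if (el %in% c("Se", "W") && any(ev$kind == "pulse")) {
      h <- backsolvePulse(h, config@te$pulseTargetDay,
                          config@te$pulseTargets[[el]])
    }
    out[[el]] <- h
  }
  out
}

# Normalised Hill limitation factor of one TE-sensitive route.
.teFactor <- function(conc, c0, k, n) {
  hill <- function(c) c^n / (k^n + c^n)
  hill(conc) / hill(c0)
}

# Per-day limitation factors (route P = propionate oxidation, route H =
# hydrogen disposal) for one reactor.
.reactorFactors <- function(config, reactorId, days) {
  depleted <- config@reactors$depleted[config@reactors$id == reactorId]
  ones <- rep(1, length(days))
  if (!config@teLimitation || length(depleted) == 0 || is.na(depleted))
    return(list(P = ones, H = ones))
  hists <- teHistories(config, reactorId)
  elems <- if (depleted == "SeW") c("Se", "W") else depleted
  bg <- config@te$background
  conc <- sapply(elems, function(el)
    concentrationAt(hists[[el]], days) + bg[[el]])
  # the acclimatised baseline is the concentration when depletion starts,
  # not the day-0 value (an earlier pulse may still be washing out)
  c0 <- vapply(elems, function(el)
    concentrationAt(hists[[el]], config@depletionDay) + bg[[el]], numeric(1))
  # the scarcest element (relative to its baseline) limits the route
  rel <- sweep(as.matrix(conc), 2, c0, "/")
  lim <- apply(rel, 1, which.min)
  cEff <- as.matrix(conc)[cbind(seq_along(days), lim)]
  c0Eff <- c0[lim]
  n <- config@te$hillN
  # no limitation during the supplemented (pre-depletion) phase
  pre <- days < config@depletionDay
  facOf <- function(k) {
    f <- pmin(1, .teFactor(cEff, c0Eff, k, n))
    f[pre] <- 1
    f
  }
  list(P = facOf(config@te$hillK[["P"]]), H = facOf(config@te$hillK[["H"]]))
}

# pH proxy: piecewise-linear map of the total pre-feed VFA concentration,
# calibrated so that pH < 5.7 at failure-state VFA levels, floored at the
# buffering limit of a soured digester.
.phProxy <- function(vfaTotMM) {
  excess <- pmax(0, vfaTotMM - 2)
  pmax(4.9, 7.1 - 0.005 * pmin(excess, 30) - 0.03 * pmax(0, excess - 30))
}

# Onset day: first day the residual exceeds `threshold` and does so again
# within the following week (transient blips do not count).
.onsetDay <- function(residual, threshold) {
  hit <- which(residual >= threshold)
  for (d in hit) {
    if (any(hit > d & hit <= d + 7)) return(d)
  }
  NA_real_
}

.runReactorCore <- function(config, reactorId) {
  nDays <- as.integer(config@horizonDays)
  fac <- .reactorFactors(config, reactorId, seq_len(nDays) - 1)
  kin <- config@kinetics
  f <- config@feed
  feedDaily <- config@olr * config@volume
  # slow and inert pools start at their steady-state inventories
  initD <- f$slow * feedDaily / (kin$kSlowPerDay + 1 / config@hrt)
  initI <- f$inert * feedDaily * config@hrt
  pr <- c(kin, list(
    hrt = config@hrt, volume = config@volume, feedDaily = feedDaily,
    fFerm = f$ferm, fAc = f$acetate, fPr = f$propionate, fSlow = f$slow,
    fInert = f$inert,
    initS = 0, initD = initD, initA = 0, initP = 0, initB = 0, initH = 0,
    initI = initI
  ))
  core <- .simCoreCpp(nDays, pr, fac$P, fac$H)
  core$facP <- fac$P
  core$facH <- fac$H
  core
}

#' Run the synthetic digester
#'
#' Simulates every configured reactor with the COD-pool core, converts the
#' noise-free methane/CO2 streams to gas-meter conditions (saturated, at the
#' configured meter temperature), adds seeded Gaussian sensor noise, samples
#' weekly pre-feed VFA profiles and a daily pH proxy, evaluates the
#' trace-element washout series, draws Dirichlet-multinomial ASV tables
#' whose bacterial composition drifts with cumulative VFA exposure (archaea
#' stay near-constant), and logs ground-truth events.
#'
#' @param config a [SimConfig-class].
#' @param seed integer seed; identical seeds give identical bundles.
#' @return a [SimBundle-class].
#' @export
simulateDigester <- function(config = simConfig(), seed = 1L) {
  validObject(config)
  set.seed(seed)
  nDays <- as.integer(config@horizonDays)
  mins <- seq_len(nDays * 1440) - 1
  met <- config@meter
  measFactor <- 1 / normalizeVolume(1, met$temperature, met$pressure,
                                    met$saturated)

  gas <- list(); te <- list(); ledger <- list(); events <- list()
  vfa <- list(); ph <- list(); transitions <- list(); cores <- list()

  for (r in config@reactors$id) {
    core <- .runReactorCore(config, r)
    cores[[r]] <- core

    biogasN <- core$ch4Vol + core$co2Vol
    frac <- ifelse(biogasN > 1e-12, core$ch4Vol / biogasN, 0)
    flowMeas <- biogasN * measFactor +
      stats::rnorm(length(biogasN), 0, config@noise$flowSd)
    fracMeas <- pmin(1, pmax(0, frac +
      stats::rnorm(length(frac), 0, config@noise$ch4FracSd)))
    gas[[r]] <- gasTimeSeries(mins, pmax(0, flowMeas), fracMeas,
                              temperature = met$temperature,
                              pressure = met$pressure,
                              waterSaturated = met$saturated)

    days0 <- seq_len(nDays) - 1
    hists <- teHistories(config, r)
    te[[r]] <- lapply(hists, simulateWashout, tGrid = days0)

    ledger[[r]] <- data.frame(
      reactor = r, day = days0, fed = core$fed, ch4Cod = core$ch4Cod,
      biomass = core$biomass, effluent = core$effluent,
      invStart = core$invStart, invEnd = core$invEnd
    )

    vfaDays <- seq(0, nDays - 1, by = config@vfaEvery)
    vfa[[r]] <- data.frame(
      reactor = r,
      day = rep(vfaDays, 3),
      acid = rep(c("acetate", "propionate", "butyrate"), each = length(vfaDays)),
      mM = c(core$preA[vfaDays + 1], core$preP[vfaDays + 1],
             core$preB[vfaDays + 1])
    )

    vfaTot <- core$preA + core$preP + core$preB
    ph[[r]] <- data.frame(reactor = r, day = days0, ph = .phProxy(vfaTot))

    transitions[[r]] <- data.frame(reactor = r, day = days0,
                                   minute = core$tResid)

    baseSel <- days0 >= min(150, nDays %/% 2) & days0 <= min(200, nDays - 1)
    baselineCh4 <- mean(core$ch4Cod[baseSel])
    failGas <- which(core$ch4Cod < 0.25 * baselineCh4 &
                       days0 > config@depletionDay)
    failPh <- which(.phProxy(vfaTot) < 5.7)
    failIdx <- suppressWarnings(min(c(failGas, failPh)))
    # .onsetDay returns a 1-based index into the daily arrays (day = idx - 1)
    toDay <- function(idx) if (is.finite(idx)) idx - 1 else NA_real_
    events[[r]] <- data.frame(
      reactor = r,
      event = c("propionateOnset", "acetateOnset", "butyrateOnset", "failure"),
      day = c(toDay(.onsetDay(core$preP, 1.0)),
              toDay(.onsetDay(core$preA, 2.0)),
              toDay(.onsetDay(core$preB, 2.0)),
              toDay(failIdx))
    )
  }

  comm <- .communityTables(config, cores, seed)

  new("SimBundle",
    gas = gas, vfa = do.call(rbind, vfa), te = te,
    ph = do.call(rbind, ph), asv = comm$bacteria,
    asvArchaea = comm$archaea,
    events = do.call(rbind, events), ledger = do.call(rbind, ledger),
    transitions = do.call(rbind, transitions),
    config = config, seed = as.integer(seed))
}

#' Daily COD ledger of a simulation
#'
#' Per reactor and day: COD fed, COD leaving as methane, the biomass sink,
#' the effluent, the inventory change of the pools, and the relative
#' imbalance \eqn{|fed - CH_4 - biomass - effluent - \Delta inv| / fed}.
#' The noise-free core balances to floating-point accuracy.
#'
#' @param bundle a [SimBundle-class].
#' @return data.frame, one row per reactor-day.
#' @export
codLedger <- function(bundle) {
  l <- bundle@ledger
  dInv <- l$invEnd - l$invStart
  l$imbalance <- abs(l$fed - l$ch4Cod - l$biomass - l$effluent - dInv) /
    pmax(l$fed, .Machine$double.eps)
  l$dInventory <- dInv
  l
}

## ---- community generator -------------------------------------------------

# Baseline and disturbed bacterial genus compositions. The baseline mirrors
# the stable-operation community (Lachnospiraceae NK3A20-dominated Firmicutes,
# Thermovirga-dominated Synergistetes); the disturbed target mirrors the
# post-VFA-accumulation community (Thermovirga collapse, rise of
# Aminobacterium, Pyramidobacter, Synergistes and Lachnoclostridium).
.bacterialGenera <- function() {
  tax <- function(ph, cl, or, fa, ge)
    paste("Bacteria", ph, cl, or, fa, ge, sep = ";")
  data.frame(
    genus = c("Lachnospiraceae NK3A20", "Thermovirga",
              "Synergistaceae uncl.", "Sphaerochaeta", "Petrimonas",
              "VadinBC27", "Lachnoclostridium", "Pyramidobacter",
              "Aminobacterium", "Synergistes", "Syntrophobacter",
              "Syntrophomonas", "Clostridium sensu stricto", "Aminomonas"),
    taxonomy = c(
      tax("Firmicutes", "Clostridia", "Lachnospirales", "Lachnospiraceae", "Lachnospiraceae NK3A20"),
      tax("Synergistetes", "Synergistia", "Synergistales", "Synergistaceae", "Thermovirga"),
      tax("Synergistetes", "Synergistia", "Synergistales", "Synergistaceae", "Synergistaceae uncl."),
      tax("Spirochaetae", "Spirochaetia", "Spirochaetales", "Spirochaetaceae", "Sphaerochaeta"),
      tax("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Dysgonomonadaceae", "Petrimonas"),
      tax("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Rikenellaceae", "VadinBC27"),
      tax("Firmicutes", "Clostridia", "Lachnospirales", "Lachnospiraceae", "Lachnoclostridium"),
      tax("Synergistetes", "Synergistia", "Synergistales", "Synergistaceae", "Pyramidobacter"),
      tax("Synergistetes", "Synergistia", "Synergistales", "Synergistaceae", "Aminobacterium"),
      tax("Synergistetes", "Synergistia", "Synergistales", "Synergistaceae", "Synergistes"),
      tax("Proteobacteria", "Deltaproteobacteria", "Syntrophobacterales", "Syntrophobacteraceae", "Syntrophobacter"),
      tax("Firmicutes", "Clostridia", "Eubacteriales", "Syntrophomonadaceae", "Syntrophomonas"),
      tax("Firmicutes", "Clostridia", "Eubacteriales", "Clostridiaceae", "Clostridium sensu stricto"),
      tax("Synergistetes", "Synergistia", "Synergistales", "Synergistaceae", "Aminomonas")
    ),
    baseline = c(0.480, 0.280, 0.100, 0.065, 0.028, 0.012, 0.008, 0.004,
                 0.004, 0.004, 0.003, 0.003, 0.006, 0.003),
    disturbed = c(0.390, 0.047, 0.150, 0.005, 0.005, 0.010, 0.090, 0.110,
                  0.075, 0.045, 0.008, 0.008, 0.045, 0.012),
    stringsAsFactors = FALSE
  )
}

.archaealGenera <- function() {
  tax <- function(ph, cl, or, fa, ge)
    paste("Archaea", ph, cl, or, fa, ge, sep = ";")
  data.frame(
    genus = c("Methanosaeta", "Methanoculleus", "WCHA1-57",
              "Methanomassiliicoccus", "Methanomethylovorans",
              "Thermoplasmatales uncl."),
    taxonomy = c(
      tax("Euryarchaeota", "Methanomicrobia", "Methanosarcinales", "Methanosaetaceae", "Methanosaeta"),
      tax("Euryarchaeota", "Methanomicrobia", "Methanomicrobiales", "Methanomicrobiaceae", "Methanoculleus"),
      tax("Euryarchaeota", "Thermoplasmata", "Methanomassiliicoccales", "WCHA1-57", "WCHA1-57"),
      tax("Euryarchaeota", "Thermoplasmata", "Methanomassiliicoccales", "Methanomassiliicoccaceae", "Methanomassiliicoccus"),
      tax("Euryarchaeota", "Methanomicrobia", "Methanosarcinales", "Methanosarcinaceae", "Methanomethylovorans"),
      tax("Euryarchaeota", "Thermoplasmata", "Thermoplasmatales", "Thermoplasmatales uncl.", "Thermoplasmatales uncl.")
    ),
    baseline = c(0.52, 0.38, 0.04, 0.02, 0.03, 0.01),
    disturbed = c(0.44, 0.33, 0.03, 0.10, 0.03, 0.07),
    stringsAsFactors = FALSE
  )
}

# Split each genus into a fixed number of ASVs with fixed proportions so
# that richness is stable while composition drifts.
.asvSplit <- function(genera, perGenus = 3) {
  wts <- c(0.7, 0.2, 0.1)[seq_len(perGenus)]
  wts <- wts / sum(wts)
  idx <- rep(seq_len(nrow(genera)), each = perGenus)
  data.frame(
    asv = paste0("ASV", sprintf("%03d", seq_along(idx))),
    genusIdx = idx,
    weight = rep(wts, nrow(genera)),
    stringsAsFactors = FALSE
  )
}

.communityTables <- function(config, cores, seed) {
  cdays <- config@sampleDays
  cc <- config@community
  build <- function(genera, depth, driftScale) {
    split <- .asvSplit(genera)
    samples <- list(); meta <- list()
    for (r in config@reactors$id) {
      core <- cores[[r]]
      vfaTot <- core$preA + core$preP + core$preB
      cum <- cumsum(pmax(0, vfaTot - 2))
      for (d in cdays) {
        w <- (1 - exp(-cum[min(d + 1, length(cum))] / cc$driftTau)) * driftScale
        comp <- (1 - w) * genera$baseline + w * genera$disturbed
        alpha <- comp[split$genusIdx] * split$weight * cc$theta
        p <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-6))
        p <- p / sum(p)
        cnt <- stats::rmultinom(1, size = depth, prob = p)[, 1]
        id <- paste0(r, "_d", d)
        samples[[id]] <- cnt
        meta[[id]] <- data.frame(sample = id, reactor = r, day = d)
      }
    }
    counts <- do.call(cbind, samples)
    rownames(counts) <- split$asv
    metadata <- do.call(rbind, meta)
    taxStrings <- paste0(genera$taxonomy[split$genusIdx])
    asvExperiment(counts, taxonomy = taxStrings, metadata = metadata)
  }
  list(
    bacteria = build(.bacterialGenera(), cc$depth, 1),
    archaea = build(.archaealGenera(), cc$archaealDepth, cc$archaealDrift)
  )
}
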