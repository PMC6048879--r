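# Synthetic study generator: spatially correlated lognormal element
# fields, stratified Poisson survey sampling (urban / rural / background
# densities), postcode and census-output-area geography, practices and
# patients. Everything is driven by a master seed through documented
# per-stage derived seeds, so a full study is reproducible bit for bit.

#' Synthetic study configuration
#'
#' Defaults describe the demonstration study: a 20 x 20 km domain with
#' four urban centres, survey densities of 4 per km^2 (urban), 1 per
#' 2 km^2 (rural) and 1 per 25 km^2 (background), ~2,000 postcodes
#' averaging 15 (range 1--100) delivery addresses, census output areas of
#' ~8 postcodes, 40 practices with 95% participation among active ones,
#' and 5,000 patients.
#'
#' @slot domainKm domain width and height, km.
#' @slot urbanCentres data.frame `x`, `y`, `radius` (km).
#' @slot densityUrban,densityRural,densityBackground sites per km^2.
#' @slot ruralSplit fraction of the domain width (from the west) whose
#'   non-urban land is rural-surveyed; the rest is background-surveyed.
#' @slot elements data.frame `element`, `logMean`, `logSd`,
#'   `corrLengthKm`, `urbanEnrichment`, `detectionLimit`.
#' @slot noiseSd log-scale sd of multiplicative measurement noise.
#' @slot postcodeCount,urbanShare postcode count and the fraction placed
#'   inside urban centres.
#' @slot addressNbSize,addressNbMu negative-binomial parameters of the
#'   address count (`1 + NB`, capped at 100; defaults give mean 15).
#' @slot oaTargetSize mean postcodes per output area.
#' @slot regionRows,regionCols regular grid of reporting regions.
#' @slot crosserFraction fraction of postcodes marked border-crossing.
#' @slot householdSize population per delivery address.
#' @slot practiceCount,inactiveFraction,participationProb practice counts
#'   and probabilities.
#' @slot patientCount number of patients.
#' @slot blankPostcodeFraction,unknownPostcodeFraction postcode-failure
#'   injection rates.
#' @slot patientInactiveFraction fraction of patients not actively
#'   registered on the census date.
#' @slot censusDate census reference date.
#' @export
setClass("SimConfig",
  representation(
    domainKm = "numeric", urbanCentres = "data.frame",
    densityUrban = "numeric", densityRural = "numeric",
    densityBackground = "numeric", ruralSplit = "numeric",
    elements = "data.frame", noiseSd = "numeric",
    postcodeCount = "numeric", urbanShare = "numeric",
    addressNbSize = "numeric", addressNbMu = "numeric",
    oaTargetSize = "numeric", regionRows = "numeric",
    regionCols = "numeric", crosserFraction = "numeric",
    householdSize = "numeric", practiceCount = "numeric",
    inactiveFraction = "numeric", participationProb = "numeric",
    patientCount = "numeric", blankPostcodeFraction = "numeric",
    unknownPostcodeFraction = "numeric",
    patientInactiveFraction = "numeric", censusDate = "Date"),
  validity = function(object) {
    if (length(object@domainKm) != 2 || any(object@domainKm <= 0))
      return("domainKm must be two positive lengths")
    for (s in c("densityUrban", "densityRural", "densityBackground"))
      if (slot(object, s) <= 0) return(paste(s, "must be > 0"))
    for (s in c("urbanShare", "crosserFraction", "participationProb",
                "inactiveFraction", "blankPostcodeFraction",
                "unknownPostcodeFraction", "patientInactiveFraction")) {
      v <- slot(object, s)
      if (v < 0 || v > 1) return(paste(s, "must be in [0, 1]"))
    }
    need <- c("element", "logMean", "logSd", "corrLengthKm",
              "urbanEnrichment", "detectionLimit")
    if (!all(need %in% names(object@elements)))
      return("elements table lacks required columns")
    if (any(object@elements$logSd < 0))
      return("logSd must be >= 0")
    TRUE
  })

#' Default element field parameters for the synthetic generator
#'
#' Log-scale medians chosen as plausible soil concentrations (mg/kg),
#' a common log-sd of 0.4, a 5 km spatial correlation length, and mild
#' urban enrichment factors (largest for lead, copper and zinc).
#'
#' @return data.frame with one row per panel element.
#' @export
defaultElementParams <- function() {
  panel <- defaultElementPanel()
  medians <- c(Ca = 15000, Al = 45000, Si = 250000, Fe = 30000, As = 15,
               Cr = 60, Cu = 25, Pb = 50, Mn = 600, Ni = 25, P = 800,
               Se = 0.6, U = 2, V = 80, Zn = 80)
  enrich <- c(Ca = 1.1, Al = 1.0, Si = 1.0, Fe = 1.1, As = 1.2,
              Cr = 1.2, Cu = 1.5, Pb = 1.8, Mn = 1.1, Ni = 1.2, P = 1.2,
              Se = 1.1, U = 1.0, V = 1.1, Zn = 1.5)
  el <- panelElements(panel)
  data.frame(element = el,
             logMean = log(unname(medians[el])),
             logSd = 0.4,
             corrLengthKm = 5,
             urbanEnrichment = unname(enrich[el]),
             detectionLimit = unname(panelDetectionLimits(panel)),
             stringsAsFactors = FALSE)
}

#' Construct a synthetic study configuration
#'
#' All arguments default to the demonstration study; see
#' [SimConfig-class] for their meaning.
#'
#' @param domainKm,urbanCentres,densityUrban,densityRural,densityBackground
#'   domain and sampling design.
#' @param ruralSplit,elements,noiseSd field and survey parameters.
#' @param postcodeCount,urbanShare,addressNbSize,addressNbMu,oaTargetSize
#'   postcode geography.
#' @param regionRows,regionCols,crosserFraction,householdSize census
#'   geography.
#' @param practiceCount,inactiveFraction,participationProb,patientCount
#'   population sizes.
#' @param blankPostcodeFraction,unknownPostcodeFraction,patientInactiveFraction
#'   failure/inactivity rates.
#' @param censusDate census reference date.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(domainKm = c(20, 20),
                      urbanCentres = data.frame(
                        x = c(5, 5, 15, 15), y = c(5, 15, 5, 15),
                        radius = 4.8),
                      densityUrban = 4, densityRural = 0.5,
                      densityBackground = 0.04, ruralSplit = 0.8,
                      elements = defaultElementParams(), noiseSd = 0.1,
                      postcodeCount = 2000, urbanShare = 0.8,
                      addressNbSize = 2, addressNbMu = 14,
                      oaTargetSize = 8, regionRows = 2, regionCols = 2,
                      crosserFraction = 0.02, householdSize = 2.4,
                      practiceCount = 40, inactiveFraction = 0.12,
                      participationProb = 0.95, patientCount = 5000,
                      blankPostcodeFraction = 0.02,
                      unknownPostcodeFraction = 0.03,
                      patientInactiveFraction = 0.45,
                      censusDate = as.Date("2011-03-27")) {
  new("SimConfig", domainKm = domainKm, urbanCentres = urbanCentres,
      densityUrban = densityUrban, densityRural = densityRural,
      densityBackground = densityBackground, ruralSplit = ruralSplit,
      elements = elements, noiseSd = noiseSd,
      postcodeCount = postcodeCount, urbanShare = urbanShare,
      addressNbSize = addressNbSize, addressNbMu = addressNbMu,
      oaTargetSize = oaTargetSize, regionRows = regionRows,
      regionCols = regionCols, crosserFraction = crosserFraction,
      householdSize = householdSize, practiceCount = practiceCount,
      inactiveFraction = inactiveFraction,
      participationProb = participationProb, patientCount = patientCount,
      blankPostcodeFraction = blankPostcodeFraction,
      unknownPostcodeFraction = unknownPostcodeFraction,
      patientInactiveFraction = patientInactiveFraction,
      censusDate = as.Date(censusDate))
}

#' @describeIn simConfig the [ElementPanel-class] implied by the config.
#' @param config a [SimConfig-class].
#' @export
configPanel <- function(config) {
  elementPanel(config@elements$element, config@elements$detectionLimit)
}

# is a point (km) inside any urban disc?
inUrban <- function(config, xKm, yKm) {
  u <- config@urbanCentres
  inside <- rep(FALSE, length(xKm))
  for (k in seq_len(nrow(u))) {
    inside <- inside |
      ((xKm - u$x[k])^2 + (yKm - u$y[k])^2 <= u$radius[k]^2)
  }
  inside
}

#' Generate a spatially correlated truth field for one element
#'
#' The log-scale field is a seeded sum of Gaussian bumps with width set by
#' the element's correlation length, standardized over a fixed probe grid
#' to the configured log-mean and log-sd, exponentiated (hence strictly
#' positive and positively skewed) and multiplied by the urban enrichment
#' factor inside urban centres. With `logSd = 0` the non-urban field is
#' the constant `exp(logMean)`.
#'
#' @param config a [SimConfig-class].
#' @param element element symbol (must appear in `config@elements`).
#' @param seed RNG seed.
#' @return a vectorized function `f(x, y)` of planar metre coordinates
#'   returning mg/kg.
#' @export
generateTruthField <- function(config, element, seed) {
  par <- config@elements[config@elements$element == element, ]
  if (nrow(par) != 1)
    stop("element '", element, "' not in config", call. = FALSE)
  W <- config@domainKm[1]; H <- config@domainKm[2]
  ell <- par$corrLengthKm
  sigB <- ell / 2
  nBumps <- max(30L, as.integer(ceiling(8 * (W + 4 * ell) *
                                          (H + 4 * ell) / ell^2)))
  bumps <- withSeed(seed, {
    data.frame(x = stats::runif(nBumps, -2 * ell, W + 2 * ell),
               y = stats::runif(nBumps, -2 * ell, H + 2 * ell),
               a = stats::rnorm(nBumps))
  })
  rawField <- function(xKm, yKm) {
    acc <- numeric(length(xKm))
    for (k in seq_len(nBumps)) {
      d2 <- (xKm - bumps$x[k])^2 + (yKm - bumps$y[k])^2
      acc <- acc + bumps$a[k] * exp(-d2 / (2 * sigB^2))
    }
    acc
  }
  # standardize over a fixed probe grid so logMean/logSd are honoured
  gx <- rep(seq(W / 50, W, length.out = 25), each = 25)
  gy <- rep(seq(H / 50, H, length.out = 25), times = 25)
  probe <- rawField(gx, gy)
  mu <- mean(probe)
  sdv <- stats::sd(probe)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  force(par)
  function(x, y) {
    xKm <- x / 1000; yKm <- y / 1000
    z <- if (par$logSd == 0) rep(0, length(xKm)) else
      par$logSd * (rawField(xKm, yKm) - mu) / sdv
    out <- exp(par$logMean + z)
    urb <- inUrban(config, xKm, yKm)
    out[urb] <- out[urb] * par$urbanEnrichment
    out
  }
}

#' Generate truth fields for every configured element
#'
#' Seeds are derived per element as `derivedSeed(seed, "truth:<element>")`.
#'
#' @param config a [SimConfig-class].
#' @param seed master seed.
#' @return named list of field functions.
#' @export
generateTruthFields <- function(config, seed) {
  els <- config@elements$element
  stats::setNames(lapply(els, function(el) {
    generateTruthField(config, el, derivedSeed(seed, paste0("truth:", el)))
  }), els)
}

#' Generate a stratified survey
#'
#' Each stratum is a homogeneous Poisson point process at its configured
#' density (urban discs at `densityUrban`, the rural portion of the
#' remainder at `densityRural`, the rest at `densityBackground`),
#' realized by thinning a process on the full rectangle. Measured
#' concentrations are the truth field values times multiplicative
#' lognormal noise; values below the element's detection limit are
#' flagged below-detection and carried as missing measurements.
#'
#' @param config a [SimConfig-class].
#' @param fields named list of truth fields from [generateTruthFields()].
#' @param seed RNG seed.
#' @return a [SoilSurvey-class].
#' @export
generateSurvey <- function(config, fields, seed) {
  W <- config@domainKm[1]; H <- config@domainKm[2]
  area <- W * H
  withSeed(seed, {
    strata <- list(
      urban = config@densityUrban,
      rural = config@densityRural,
      background = config@densityBackground)
    pts <- list()
    for (s in names(strata)) {
      n <- stats::rpois(1, strata[[s]] * area)
      x <- stats::runif(n, 0, W); y <- stats::runif(n, 0, H)
      urb <- inUrban(config, x, y)
      keep <- switch(s,
        urban = urb,
        rural = !urb & x < config@ruralSplit * W,
        background = !urb & x >= config@ruralSplit * W)
      pts[[s]] <- data.frame(x = x[keep], y = y[keep],
                             source = rep(s, sum(keep)),
                             stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, pts)
    n <- nrow(sites)
    sites$site_id <- sprintf("S%06d", seq_len(n))
    els <- config@elements$element
    conc <- matrix(NA_real_, length(els), n,
                   dimnames = list(els, NULL))
    bd <- matrix(FALSE, length(els), n, dimnames = list(els, NULL))
    for (i in seq_along(els)) {
      el <- els[i]
      truth <- fields[[el]](sites$x * 1000, sites$y * 1000)
      meas <- truth * exp(stats::rnorm(n, 0, config@noiseSd))
      lod <- config@elements$detectionLimit[i]
      below <- meas < lod
      bd[el, ] <- below
      meas[below] <- NA
      conc[el, ] <- meas
    }
    siteDf <- data.frame(site_id = sites$site_id,
                         x = sites$x * 1000, y = sites$y * 1000,
                         source = sites$source, stringsAsFactors = FALSE)
    SoilSurvey(siteDf, conc, bd, configPanel(config))
  })
}

#' Generate postcodes, output areas and border-crossers
#'
#' Postcode centroids are placed preferentially inside urban centres
#' (`urbanShare`), address counts are `1 + NB(size, mu)` capped at 100,
#' postcodes are grouped into spatially compact output areas by k-means on
#' their centroids, regions are a regular grid over the domain, a
#' configured fraction of postcodes is marked border-crossing (candidate
#' areas: own plus the nearest other output area), and each output area's
#' population is its summed address count times the household-size factor.
#'
#' @param config a [SimConfig-class].
#' @param seed RNG seed.
#' @return list: `postcodes`, `oas`, `borderCrossers` data.frames.
#' @export
generatePostcodesAndOas <- function(config, seed) {
  W <- config@domainKm[1]; H <- config@domainKm[2]
  n <- as.integer(config@postcodeCount)
  withSeed(seed, {
    u <- config@urbanCentres
    urbanPick <- stats::runif(n) < config@urbanShare & nrow(u) > 0
    x <- numeric(n); y <- numeric(n)
    for (i in seq_len(n)) {
      if (urbanPick[i]) {
        repeat {
          k <- sample.int(nrow(u), 1)
          r <- u$radius[k] * sqrt(stats::runif(1))
          th <- stats::runif(1, 0, 2 * pi)
          px <- u$x[k] + r * cos(th); py <- u$y[k] + r * sin(th)
          if (px >= 0 && px <= W && py >= 0 && py <= H) break
        }
      } else {
        px <- stats::runif(1, 0, W); py <- stats::runif(1, 0, H)
      }
      x[i] <- px; y[i] <- py
    }
    addr <- pmin(1 + stats::rnbinom(n, size = config@addressNbSize,
                                    mu = config@addressNbMu), 100)

    k <- max(1L, as.integer(round(n / config@oaTargetSize)))
    km <- stats::kmeans(cbind(x, y), centers = min(k, n), iter.max = 50,
                        nstart = 1)
    oaIds <- sprintf("OA%04d", km$cluster)
    oaList <- sort(unique(oaIds))

    regionOf <- function(px, py) {
      rr <- pmin(config@regionRows,
                 pmax(1, ceiling(py / H * config@regionRows)))
      cc <- pmin(config@regionCols,
                 pmax(1, ceiling(px / W * config@regionCols)))
      sprintf("R%d%d", rr, cc)
    }
    oaCx <- tapply(x, oaIds, mean)[oaList]
    oaCy <- tapply(y, oaIds, mean)[oaList]
    oaRegion <- regionOf(oaCx, oaCy)
    names(oaRegion) <- oaList

    postcodes <- data.frame(
      code = sprintf("PC%05d", seq_len(n)),
      x = x * 1000, y = y * 1000,
      oa_id = oaIds,
      region_id = unname(oaRegion[oaIds]),
      address_count = as.numeric(addr),
      stringsAsFactors = FALSE)

    pop <- tapply(postcodes$address_count, postcodes$oa_id, sum)[oaList]
    oas <- data.frame(oa_id = oaList,
                      region_id = unname(oaRegion[oaList]),
                      population = round(unname(pop) *
                                           config@householdSize),
                      stringsAsFactors = FALSE)

    nCross <- as.integer(floor(config@crosserFraction * n))
    borderCrossers <- data.frame(code = character(0),
                                 candidate_oas = character(0),
                                 stringsAsFactors = FALSE)
    if (nCross > 0 && length(oaList) > 1) {
      # keep at least one non-crossing postcode in every OA, so random
      # reassignment can never leave a populated OA without postcodes
      oaSize <- table(oaIds)
      cap <- as.integer(oaSize) - 1L
      names(cap) <- names(oaSize)
      pick <- integer(0)
      for (i in sample.int(n)) {
        if (length(pick) >= nCross) break
        oa <- oaIds[i]
        if (cap[[oa]] > 0) {
          cap[[oa]] <- cap[[oa]] - 1L
          pick <- c(pick, i)
        }
      }
      cand <- vapply(pick, function(i) {
        own <- postcodes$oa_id[i]
        others <- setdiff(oaList, own)
        d2 <- (oaCx[others] - x[i])^2 + (oaCy[others] - y[i])^2
        paste(c(own, others[which.min(d2)]), collapse = ";")
      }, character(1))
      borderCrossers <- data.frame(code = postcodes$code[pick],
                                   candidate_oas = cand,
                                   stringsAsFactors = FALSE)
    }
    list(postcodes = postcodes, oas = oas,
         borderCrossers = borderCrossers)
  })
}

#' Generate practices and patients
#'
#' Practices are anchored at randomly chosen postcodes (so their regional
#' distribution follows the postcode geography); activity and
#' participation are Bernoulli draws with `participating` implying
#' `active`. Patients are assigned uniformly to practices and draw a
#' residential postcode from the practice's region (address-count
#' weighted); configured fractions then receive a blank postcode or an
#' unknown postcode string, and registration intervals are drawn so that
#' about `1 - patientInactiveFraction` of patients are alive and actively
#' registered on the census date.
#'
#' @param config a [SimConfig-class].
#' @param postcodes postcode data.frame.
#' @param seed RNG seed.
#' @return list: `practices`, `patients` data.frames.
#' @export
generatePopulation <- function(config, postcodes, seed) {
  nPr <- as.integer(config@practiceCount)
  nPt <- as.integer(config@patientCount)
  if (nPr < 1) stop("config has zero practices", call. = FALSE)
  census <- config@censusDate
  withSeed(seed, {
    anchor <- sample.int(nrow(postcodes), nPr, replace = TRUE)
    active <- stats::runif(nPr) >= config@inactiveFraction
    participating <- active & stats::runif(nPr) < config@participationProb
    practices <- data.frame(
      practice_id = sprintf("PR%03d", seq_len(nPr)),
      region_id = postcodes$region_id[anchor],
      active = active,
      participating = participating,
      stringsAsFactors = FALSE)

    prIdx <- sample.int(nPr, nPt, replace = TRUE)
    region <- practices$region_id[prIdx]
    pcByRegion <- split(seq_len(nrow(postcodes)), postcodes$region_id)
    pcIdx <- integer(nPt)
    for (r in names(pcByRegion)) {
      sel <- which(region == r)
      cand <- pcByRegion[[r]]
      if (length(sel) > 0) {
        pcIdx[sel] <- cand[sample.int(length(cand), length(sel),
                                      replace = TRUE,
                                      prob = postcodes$address_count[cand])]
      }
    }
    postcode <- postcodes$code[pcIdx]
    blank <- stats::runif(nPt) < config@blankPostcodeFraction
    unknown <- !blank & stats::runif(nPt) < config@unknownPostcodeFraction
    postcode[blank] <- ""
    postcode[unknown] <- paste0("XX", postcode[unknown])

    activePt <- stats::runif(nPt) >= config@patientInactiveFraction
    start <- rep(census, nPt); end <- rep(as.Date(NA), nPt)
    death <- rep(as.Date(NA), nPt)
    nAct <- sum(activePt)
    start[activePt] <- census - round(stats::runif(nAct, 0, 16 * 365.25))
    stillOpen <- stats::runif(nAct) < 0.7
    endAct <- census + round(stats::runif(nAct, 30, 2000))
    end[activePt][!stillOpen] <- endAct[!stillOpen]

    idxIn <- which(!activePt)
    left <- stats::runif(length(idxIn)) < 0.5
    # ended before the census
    sL <- census - round(stats::runif(sum(left), 2 * 365, 16 * 365.25))
    eL <- sL + round(stats::runif(sum(left)) *
                       pmax(1, as.numeric(census - 1 - sL)))
    start[idxIn[left]] <- sL
    end[idxIn[left]] <- eL
    died <- stats::runif(sum(left)) < 0.2
    death[idxIn[left]][died] <- eL[died]
    # registered after the census
    sA <- census + round(stats::runif(sum(!left), 1, 1500))
    start[idxIn[!left]] <- sA

    patients <- data.frame(
      patient_id = sprintf("P%06d", seq_len(nPt)),
      practice_id = practices$practice_id[prIdx],
      postcode = postcode,
      registration_start = start,
      registration_end = end,
      death_date = death,
      stringsAsFactors = FALSE)
    list(practices = practices, patients = validatePatients(patients))
  })
}

#' Generate a complete synthetic study
#'
#' Runs every generator with seeds derived from the master seed
#' (`"truth:<element>"`, `"survey"`, `"postcodes"`, `"population"`) and
#' optionally writes all tables in the package's file formats.
#'
#' @param config a [SimConfig-class].
#' @param seed master seed.
#' @param outDir optional directory for the CSV artifacts.
#' @return list: `config`, `fields`, `survey`, `postcodes`, `oas`,
#'   `borderCrossers`, `practices`, `patients`.
#' @export
simulateStudy <- function(config, seed, outDir = NULL) {
  validObject(config)
  fields <- generateTruthFields(config, seed)
  survey <- generateSurvey(config, fields, derivedSeed(seed, "survey"))
  geo <- generatePostcodesAndOas(config, derivedSeed(seed, "postcodes"))
  popn <- generatePopulation(config, geo$postcodes,
                             derivedSeed(seed, "population"))
  out <- list(config = config, fields = fields, survey = survey,
              postcodes = geo$postcodes, oas = geo$oas,
              borderCrossers = geo$borderCrossers,
              practices = popn$practices, patients = popn$patients)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSurvey(survey, file.path(outDir, "survey.csv"))
    writePostcodes(geo$postcodes, file.path(outDir, "postcodes.csv"))
    writeOutputAreas(geo$oas, file.path(outDir, "output_areas.csv"))
    writeBorderCrossers(geo$borderCrossers,
                        file.path(outDir, "border_crossers.csv"))
    writePractices(popn$practices, file.path(outDir, "practices.csv"))
    writePatients(popn$patients, file.path(outDir, "patients.csv"))
  }
  out
}
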