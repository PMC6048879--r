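# Shared fixture builders and independent oracles. Everything is built in
# code; no stored fixtures.

# naive all-pairs IDW, the independent oracle for the indexed kernel
naiveIdw <- function(x, y, v, qx, qy, radius = 5000, power = 2, eps = 1) {
  vapply(seq_along(qx), function(q) {
    d <- sqrt((x - qx[q])^2 + (y - qy[q])^2)
    inR <- d <= radius
    if (!any(inR)) return(NA_real_)
    coinc <- inR & d <= eps
    if (any(coinc)) return(mean(v[coinc]))
    w <- d[inR]^(-power)
    sum(w * v[inR]) / sum(w)
  }, numeric(1))
}

# brute-force nearest-site distances
naiveNn <- function(cx, cy, sx, sy) {
  vapply(seq_along(cx), function(i) {
    min(sqrt((sx - cx[i])^2 + (sy - cy[i])^2))
  }, numeric(1))
}

# a survey with explicit per-element site values (elements x sites matrix)
makeSurvey <- function(x, y, values, panel,
                       source = rep("rural", length(x)),
                       belowDetection = NULL) {
  values <- rbind(values)
  if (is.null(belowDetection))
    belowDetection <- matrix(FALSE, nrow(values), ncol(values))
  conc <- values
  conc[belowDetection] <- NA
  sites <- data.frame(site_id = sprintf("S%03d", seq_along(x)),
                      x = x, y = y, source = source,
                      stringsAsFactors = FALSE)
  SoilSurvey(sites, conc, belowDetection, panel)
}

twoElementPanel <- function() elementPanel(c("Pb", "Zn"), c(1.3, 5))

makePostcodes <- function(code, x, y, oa_id = "OA1", region_id = "R1",
                          address_count = 10) {
  data.frame(code = code, x = x, y = y, oa_id = oa_id,
             region_id = region_id, address_count = address_count,
             stringsAsFactors = FALSE)
}

makePractices <- function(n, region_id = "R1", active = TRUE,
                          participating = TRUE) {
  data.frame(practice_id = sprintf("PR%02d", seq_len(n)),
             region_id = rep_len(region_id, n),
             active = rep_len(active, n),
             participating = rep_len(participating, n),
             stringsAsFactors = FALSE)
}

makePatients <- function(n, practice_id, postcode,
                         registration_start = as.Date("2005-01-01"),
                         registration_end = as.Date(NA),
                         death_date = as.Date(NA)) {
  data.frame(patient_id = sprintf("P%04d", seq_len(n)),
             practice_id = rep_len(practice_id, n),
             postcode = rep_len(postcode, n),
             registration_start = rep_len(registration_start, n),
             registration_end = rep_len(registration_end, n),
             death_date = rep_len(death_date, n),
             stringsAsFactors = FALSE)
}

# small, fast config for generator tests; any simConfig argument can be
# overridden
testSimConfig <- function(...) {
  args <- list(domainKm = c(10, 10),
               urbanCentres = data.frame(x = 5, y = 5, radius = 2),
               elements = defaultElementParams()[1:3, ],
               postcodeCount = 300, patientCount = 800,
               practiceCount = 8, oaTargetSize = 6)
  override <- list(...)
  args[names(override)] <- override
  do.call(simConfig, args)
}
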