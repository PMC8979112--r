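#' One-compartment oral PK parameters
#'
#' Minimal linear model for an orally dosed parent compound:
#' `C(t) = F*D*ka / (V*(ka - ke)) * (exp(-ke*t) - exp(-ka*t))`.
#' All generator parameters in this package are synthetic: they emulate the
#' shape of single-peak oral plasma profiles, not any measured compound.
#'
#' @param dose Dose `D` (amount units), > 0.
#' @param f Bioavailability fraction `F` in (0, 1].
#' @param ka First-order absorption rate (1/h), > 0.
#' @param ke First-order elimination rate (1/h), > 0, `ka != ke`.
#' @param v Volume of distribution `V` (volume units), > 0.
#' @return An object of class `"pk_parameters"`.
#' @export
pk_parameters <- function(dose, f, ka, ke, v) {
  vals <- c(dose = dose, f = f, ka = ka, ke = ke, v = v)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("PK parameters must be finite", call. = FALSE)
  if (dose < 0) stop("'dose' must be >= 0", call. = FALSE)
  if (f <= 0 || f > 1) stop("'f' must be in (0, 1]", call. = FALSE)
  if (ka <= 0 || ke <= 0 || v <= 0)
    stop("'ka', 'ke' and 'v' must be > 0", call. = FALSE)
  if (ka == ke)
    stop("'ka' must differ from 'ke' (flip-flop limit not supported)",
         call. = FALSE)
  structure(as.list(vals), class = "pk_parameters")
}

#' Simulate a parent-compound plasma profile
#'
#' Noise-free one-compartment oral profile on the given times. `C(0) = 0`,
#' all values non-negative and unimodal in time.
#'
#' @param params A [pk_parameters()] object.
#' @param times Sampling times in hours (non-negative, strictly increasing).
#' @param compound_id Identifier for the returned profile.
#' @return A [concentration_profile()] in concentration units.
#' @examples
#' p <- pk_parameters(dose = 100, f = 1, ka = 1, ke = 0.1, v = 10)
#' simulate_parent(p, c(0, 1, 2, 4, 8, 24))
#' @export
simulate_parent <- function(params, times, compound_id = "parent") {
  stopifnot(inherits(params, "pk_parameters"))
  times <- as.numeric(times)
  if (any(times < 0)) stop("'times' must be >= 0", call. = FALSE)
  conc <- with(params, f * dose * ka / (v * (ka - ke)) *
                 (exp(-ke * times) - exp(-ka * times)))
  concentration_profile(times, pmax(conc, 0), compound_id, "conc")
}

#' Phase-II metabolite specification
#'
#' First-order formation of a conjugated metabolite from the parent, with
#' its own elimination rate. `fraction` is the fraction of eliminated parent
#' converted along this pathway; under the linear model the metabolite
#' AUC(0-Inf) equals `fraction * parent AUC(0-Inf) * ke/km` (same volume).
#'
#' @param parent_id,metabolite_id Identifiers.
#' @param pathway One of `"glucuronidation"`, `"sulfation"`, `"oxidation"`,
#'   `"other"`.
#' @param fraction Formation fraction in \[0, 1\].
#' @param km Metabolite elimination rate (1/h), > 0.
#' @return An object of class `"metabolite_spec"`.
#' @export
metabolite_spec <- function(parent_id, metabolite_id, pathway, fraction, km) {
  pathway <- match.arg(pathway,
                       c("glucuronidation", "sulfation", "oxidation", "other"))
  if (is.na(fraction) || fraction < 0 || fraction > 1)
    stop("'fraction' must be in [0, 1]", call. = FALSE)
  if (is.na(km) || km <= 0) stop("'km' must be > 0", call. = FALSE)
  structure(list(parent_id = parent_id, metabolite_id = metabolite_id,
                 pathway = pathway, fraction = fraction, km = km),
            class = "metabolite_spec")
}

# Relative tolerance below which rate constants are treated as degenerate
# (the Bateman denominators vanish) and lsoda integration is used instead.
.rate_tol <- 1e-8

#' Simulate a metabolite plasma profile
#'
#' Catenary first-order system: gut -> parent -> metabolite, metabolite
#' eliminated at `km`. Uses the closed-form three-exponential solution;
#' falls back to numerical integration (`deSolve::lsoda`) when `km` is
#' (nearly) equal to `ka` or `ke`, so degenerate rate equalities never
#' produce NaN. Metabolite concentration uses the parent's volume.
#'
#' @param parent_params A [pk_parameters()] object for the parent.
#' @param spec A [metabolite_spec()].
#' @param times Sampling times in hours.
#' @return A [concentration_profile()] for the metabolite.
#' @export
simulate_metabolite <- function(parent_params, spec, times) {
  stopifnot(inherits(parent_params, "pk_parameters"),
            inherits(spec, "metabolite_spec"))
  times <- as.numeric(times)
  if (any(times < 0)) stop("'times' must be >= 0", call. = FALSE)
  ka <- parent_params$ka; ke <- parent_params$ke; km <- spec$km
  f0 <- parent_params$f * parent_params$dose
  fm <- spec$fraction
  degenerate <- abs(km - ke) <= .rate_tol * max(km, ke) ||
    abs(km - ka) <= .rate_tol * max(km, ka)
  if (!degenerate) {
    amt <- fm * ke * f0 * ka / (ka - ke) *
      ((exp(-ke * times) - exp(-km * times)) / (km - ke) -
         (exp(-ka * times) - exp(-km * times)) / (km - ka))
  } else {
    rhs <- function(t, y, p) {
      list(c(-ka * y[1],
             ka * y[1] - ke * y[2],
             fm * ke * y[2] - km * y[3]))
    }
    grid <- sort(unique(c(0, times)))
    sol <- deSolve::lsoda(c(f0, 0, 0), grid, rhs, NULL,
                          rtol = 1e-10, atol = 1e-12)
    amt <- sol[match(times, grid), 4]
  }
  concentration_profile(times, pmax(amt / parent_params$v, 0),
                        spec$metabolite_id, "conc")
}

#' Analytical assay model
#'
#' Maps true concentrations to measured peak areas: multiplicative
#' log-normal noise with the stated coefficient of variation around
#' `response_factor * concentration` (mean-preserving: the log-scale draw
#' has sigma^2/2 subtracted), then LLOQ censoring of the back-calculated
#' concentration (`area / response_factor < lloq` is flagged and zeroed),
#' then optional division by an internal-standard area.
#'
#' @param response_factor Area counts per unit concentration (> 0). A single
#'   number, or a named vector looked up by compound id.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param lloq Lower limit of quantification in concentration units (>= 0).
#' @param is_area Internal-standard area to normalize by, or `NULL` (the
#'   default: raw areas).
#' @return An object of class `"assay_model"`.
#' @export
assay_model <- function(response_factor = 1000, cv = 0.1, lloq = 0.005,
                        is_area = NULL) {
  if (any(response_factor <= 0)) stop("'response_factor' must be > 0",
                                      call. = FALSE)
  if (cv < 0) stop("'cv' must be >= 0", call. = FALSE)
  if (lloq < 0) stop("'lloq' must be >= 0", call. = FALSE)
  if (!is.null(is_area) && is_area <= 0)
    stop("'is_area' must be > 0 when given", call. = FALSE)
  structure(list(response_factor = response_factor, cv = cv, lloq = lloq,
                 is_area = is_area), class = "assay_model")
}

response_for <- function(assay, compound_id) {
  rf <- assay$response_factor
  if (!is.null(names(rf))) {
    if (!compound_id %in% names(rf))
      stop("no response factor for compound '", compound_id, "'",
           call. = FALSE)
    rf <- rf[[compound_id]]
  }
  rf
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards — no hidden global state leaks out.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647)
}

#' Apply the assay model to a noise-free profile
#'
#' Same seed, same output: the entire draw is reproducible and the caller's
#' RNG stream is left untouched.
#'
#' @param profile A [concentration_profile()] in concentration units.
#' @param assay An [assay_model()].
#' @param seed Integer seed for the noise draw.
#' @return A [concentration_profile()] in area units (or `"area_ratio"`
#'   after internal-standard normalization), with `below_lloq` flags set.
#' @export
apply_assay <- function(profile, assay, seed) {
  stopifnot(inherits(profile, "concentration_profile"),
            inherits(assay, "assay_model"))
  if (missing(seed) || is.null(seed))
    stop("'seed' is required: assay noise must be reproducible",
         call. = FALSE)
  rf <- response_for(assay, profile$compound_id)
  n <- length(profile$values)
  if (assay$cv > 0) {
    sigma <- sqrt(log(1 + assay$cv^2))
    noise <- local_seed(seed, exp(stats::rnorm(n, -sigma^2 / 2, sigma)))
  } else {
    noise <- rep(1, n)
  }
  area <- rf * profile$values * noise
  censored <- profile$below_lloq | (area / rf < assay$lloq)
  area[censored] <- 0
  unit <- "area"
  if (!is.null(assay$is_area)) {
    area <- area / assay$is_area
    unit <- "area_ratio"
  }
  concentration_profile(profile$times, area, profile$compound_id, unit,
                        censored)
}

#' Default synthetic compound panel
#'
#' Two oral parents and eight phase-II metabolites across human, rat and
#' mouse. The first parent dominates exposure (a rhein-like profile); each
#' parent forms one glucuronide, two sulfates and one oxidation product.
#' Pathway totals are species-specific: sulfation is preferred in the human
#' settings, glucuronidation in the rodent ones. All values are synthetic.
#'
#' @return A list with elements `parents` (named list of [pk_parameters()]),
#'   `metabolites` (list of templates: parent, id, pathway, km),
#'   `pathway_fractions` (per-species named totals, split evenly across the
#'   parent's metabolites of that pathway), and `reference_available`
#'   (compound ids obtainable as reference substances).
#' @export
default_panel <- function() {
  list(
    parents = list(
      rhein_like  = pk_parameters(dose = 100, f = 0.8, ka = 1.2, ke = 0.25,
                                  v = 10),
      emodin_like = pk_parameters(dose = 40, f = 0.5, ka = 0.9, ke = 0.35,
                                  v = 15)
    ),
    # Conjugate elimination is formation-rate-limited (km >> parent ke), the
    # typical regime for phase-II metabolites: their plasma profiles then
    # track the parent's shape, as observed for anthraquinone conjugates.
    metabolites = list(
      list(parent = "rhein_like",  id = "rhein_glucuronide",
           pathway = "glucuronidation", km = 1.6),
      list(parent = "rhein_like",  id = "rhein_sulfate",
           pathway = "sulfation",       km = 2.0),
      list(parent = "rhein_like",  id = "rhein_sulfate_iso",
           pathway = "sulfation",       km = 1.8),
      list(parent = "rhein_like",  id = "rhein_oxide",
           pathway = "oxidation",       km = 2.2),
      list(parent = "emodin_like", id = "emodin_glucuronide",
           pathway = "glucuronidation", km = 1.7),
      list(parent = "emodin_like", id = "emodin_sulfate",
           pathway = "sulfation",       km = 2.1),
      list(parent = "emodin_like", id = "emodin_sulfate_iso",
           pathway = "sulfation",       km = 1.9),
      list(parent = "emodin_like", id = "emodin_oxide",
           pathway = "oxidation",       km = 2.4)
    ),
    pathway_fractions = list(
      human = c(glucuronidation = 0.20, sulfation = 0.45, oxidation = 0.10),
      rat   = c(glucuronidation = 0.45, sulfation = 0.20, oxidation = 0.10),
      mouse = c(glucuronidation = 0.50, sulfation = 0.18, oxidation = 0.10)
    ),
    reference_available = "rhein_like"
  )
}

# Noise-free serial profiles (concentration units) for every panel compound
# in one species; pathway totals split evenly across each parent's
# metabolites of that pathway.
panel_profiles <- function(panel, species, times) {
  fr <- panel$pathway_fractions[[species]]
  if (is.null(fr))
    stop("panel has no pathway fractions for species '", species, "'",
         call. = FALSE)
  profiles <- list()
  for (pid in names(panel$parents))
    profiles[[pid]] <- simulate_parent(panel$parents[[pid]], times, pid)
  for (m in panel$metabolites) {
    n_path <- sum(vapply(panel$metabolites, function(x)
      x$parent == m$parent && x$pathway == m$pathway, TRUE))
    spec <- metabolite_spec(m$parent, m$id, m$pathway,
                            fraction = fr[[m$pathway]] / n_path, km = m$km)
    profiles[[m$id]] <- simulate_metabolite(panel$parents[[m$parent]], spec,
                                            times)
  }
  profiles
}

#' Simulate a pooled-measurement cohort
#'
#' For each species, compound and replicate: generate the noise-free serial
#' profile, apply assay noise with a derived seed, pool it in silico with
#' the (exact) design for the schedule, and record the pooled area. This is
#' the statistical structure the screening analysis assumes — triplicate
#' pooled LC-MS measurements per compound per species.
#'
#' @param species Character vector of species names present in the panel's
#'   `pathway_fractions`.
#' @param panel A compound panel, see [default_panel()].
#' @param schedule A [sampling_schedule()].
#' @param assay An [assay_model()].
#' @param replicates Number of pooled replicates (>= 1), default 3.
#' @param seed Integer master seed; every draw derives from it.
#' @param design Optional [pooling_volumes()] design; default the exact
#'   (unrounded) design on `schedule`.
#' @return A `peak_area_matrix`: a data frame with columns `compound_id`,
#'   `species`, `replicate`, `area`, carrying the seed as an attribute.
#' @export
simulate_cohort <- function(species = c("human", "rat", "mouse"),
                            panel = default_panel(), schedule,
                            assay = assay_model(), replicates = 3, seed,
                            design = NULL) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  if (length(panel$parents) + length(panel$metabolites) == 0L)
    stop("compound panel is empty", call. = FALSE)
  sched <- as_schedule(schedule)
  if (is.null(design))
    design <- pooling_volumes(sched, total_volume = 480,
                              rounding_increment = 0)
  rows <- list(); idx <- 0L
  for (sp in species) {
    profiles <- panel_profiles(panel, sp, as.numeric(sched))
    for (cid in names(profiles)) {
      for (rep_i in seq_len(replicates)) {
        idx <- idx + 1L
        noisy <- apply_assay(profiles[[cid]], assay, derive_seed(seed, idx))
        rows[[idx]] <- data.frame(
          compound_id = cid, species = sp, replicate = rep_i,
          area = pool_concentration(noisy, design))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("peak_area_matrix", "data.frame")
  out
}

#' Synthesize centroided spectra with Gaussian chromatographic peaks
#'
#' Each compound elutes as a Gaussian of the stated height and width (sigma)
#' at its retention time; every spectrum carries one centroid per compound
#' at the compound's m/z. The analytic peak area is
#' `height * sigma * sqrt(2*pi)`. Intended for exercising the EIC
#' quantifier; emits a warning when two target m/z values fall within twice
#' the stated ppm window of each other (their EICs would overlap).
#'
#' @param panel A data frame with columns `compound_id`, `mz`, `rt_min`
#'   (apex retention time, minutes), `height`, `sigma_min` (peak sigma,
#'   minutes).
#' @param rt_grid Strictly increasing retention times (minutes) at which
#'   spectra are recorded.
#' @param ppm_warn ppm window used for the overlap warning (default 5).
#' @return A list of `centroid_spectrum` objects (see [centroid_spectrum()]).
#' @export
synth_spectra <- function(panel, rt_grid, ppm_warn = 5) {
  needed <- c("compound_id", "mz", "rt_min", "height", "sigma_min")
  if (nrow(panel) > 0 && !all(needed %in% names(panel)))
    stop("spectra panel needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (nrow(panel) > 0) {
    if (any(panel$mz <= 0)) stop("m/z must be > 0", call. = FALSE)
    if (any(panel$sigma_min <= 0))
      stop("peak width 'sigma_min' must be > 0", call. = FALSE)
    mz <- sort(panel$mz)
    if (length(mz) > 1) {
      gap_ppm <- diff(mz) / mz[-length(mz)] * 1e6
      if (any(gap_ppm < 2 * ppm_warn))
        warning("target m/z values within 2x the ", ppm_warn,
                " ppm window: EICs will overlap", call. = FALSE)
    }
  }
  lapply(rt_grid, function(rt) {
    if (nrow(panel) == 0L)
      return(centroid_spectrum(rt, numeric(), numeric()))
    intensity <- panel$height *
      exp(-(rt - panel$rt_min)^2 / (2 * panel$sigma_min^2))
    centroid_spectrum(rt, panel$mz, intensity)
  })
}
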