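# Synthetic administrative-claims generator with known diffusion parameters.
# The generator emulates the structure the analysis assumes -- regionally
# clustered prescriber-client affiliation with heavy-tailed caseloads, a
# logistic adoption hazard driven by lagged peer exposure, a discontinuation
# hazard, and free-text directions fields carrying PSS-identifying keywords --
# and records the ground truth needed for parameter-recovery experiments.

.BC_REGIONS <- c("Interior", "Fraser", "Vancouver Coastal", "Vancouver Island", "Northern")
.SPECIALTIES <- c("general practice", "nurse practitioner", "psychiatry", "other", "unknown")

# Small synthetic formulary: code -> medication class. The PSS-eligible rows
# mirror the medication subgroups used for safer supply (hydromorphone
# tablets, sustained-release oral morphine, dextroamphetamine,
# methylphenidate, diazepam, clonazepam); the rest is background prescribing.
.FORMULARY <- data.frame(
  drug_code = c("HYD-TAB", "MOR-SR", "DEX", "MPH", "DZP", "CZP",
                "AMOX", "ATORVA", "SERT", "METF", "PANTO", "SALB"),
  med_class = c("opioid", "opioid", "stimulant", "stimulant",
                "benzodiazepine", "benzodiazepine",
                "other", "other", "other", "other", "other", "other"),
  stringsAsFactors = FALSE
)
.OAT_CODES <- c("MET-OAT", "BUP-NAL")
.SUD_DX_CODES <- c("291", "292", "303", "304", "305")

.NEUTRAL_DIRECTIONS <- c(
  "take one tablet daily",
  "take twice daily with food",
  "one capsule at bedtime",
  "as directed by prescriber",
  "apply once daily",
  "take one tablet every morning"
)
.PSS_DIRECTIONS <- c(
  "risk mitigation - dispense daily witnessed",
  "RMG pandemic supply - daily pickup",
  "safer supply per risk mitigation guidance",
  "pandemic prescribing - dispense weekly"
)

#' Configuration for the synthetic study generator
#'
#' Bundles every tunable of the generator with validation. Defaults describe a
#' desk-scale study: 500 prescribers followed for 18 months across 5 regional
#' health authorities, with caseload skew, patient-sharing rates and adoption/
#' discontinuation frequencies shaped to resemble the provincial PSS cohort
#' margins (about 2% seeded innovators, overall uptake under 15%, roughly one
#' additional prescriber seen by the average client).
#'
#' @param n_prescribers number of prescribers.
#' @param n_clients number of clients.
#' @param n_regions number of regional health authorities (5 uses the BC
#'   names; other values use generic labels).
#' @param specialty_mix named probability vector over the five specialty
#'   groups (general practice, nurse practitioner, psychiatry, other,
#'   unknown); must sum to 1.
#' @param region_unknown_prob probability a prescriber's practice region is
#'   missing/unknown.
#' @param caseload_dispersion log-normal sd of the latent prescriber caseload
#'   weight; larger values give heavier-tailed clients-per-prescriber
#'   distributions.
#' @param sharing_rate expected number of prescribers per client (so
#'   \code{sharing_rate - 1} is the expected number of *additional*
#'   prescribers a client sees; the cohort medians put this near 1).
#' @param region_mixing probability that an attachment crosses region lines.
#' @param dispensing_rate per-month probability that an attached
#'   prescriber-client pair generates a (non-PSS) dispensation; every pair is
#'   guaranteed at least one record in the study window.
#' @param n_months study length in months (index 1 = origin month).
#' @param origin origin month \code{"YYYY-MM"}; index 1 maps to it.
#' @param sud_pathway_mix named probability vector over SUD-indication
#'   pathways \code{oat}, \code{visits}, \code{acute}, \code{perinatal} and
#'   \code{none} (clients with \code{none} get two SUD-coded visits, below the
#'   three-visit threshold, and are never flagged).
#' @param adopt_intercept log-odds intercept of the monthly adoption hazard.
#' @param adopt_beta_exposure log-odds increase per unit of lagged peer
#'   exposure (the proportion of connected peers that previously prescribed
#'   PSS).
#' @param adopt_beta_caseload log-odds increase per standard deviation of log
#'   caseload.
#' @param discont_intercept log-odds intercept of the monthly hazard of
#'   ceasing PSS prescribing, among active adopters.
#' @param discont_beta_exposure log-odds change per unit lagged peer exposure
#'   in the cessation hazard (negative: peers still prescribing keep you
#'   prescribing).
#' @param n_innovator_seed number of innovators seeded in the innovation
#'   window (months 1-2), sampled preferentially from high-caseload
#'   prescribers.
#' @param innovation_months integer months making up the innovation window.
#' @param seed master RNG seed; independent streams are derived per stage.
#' @return an object of class \code{"sim_config"} (a validated list).
#' @export
sim_config <- function(n_prescribers = 500L,
                       n_clients = 3000L,
                       n_regions = 5L,
                       specialty_mix = c("general practice" = 0.55,
                                         "nurse practitioner" = 0.05,
                                         "psychiatry" = 0.05,
                                         "other" = 0.25,
                                         "unknown" = 0.10),
                       region_unknown_prob = 0.03,
                       caseload_dispersion = 1.1,
                       sharing_rate = 2.0,
                       region_mixing = 0.10,
                       dispensing_rate = 0.35,
                       n_months = 18L,
                       origin = "2020-03",
                       sud_pathway_mix = c(oat = 0.55, visits = 0.25,
                                           acute = 0.12, perinatal = 0.03,
                                           none = 0.05),
                       adopt_intercept = -6.0,
                       adopt_beta_exposure = log(3.79),
                       adopt_beta_caseload = 0.9,
                       discont_intercept = -1.6,
                       discont_beta_exposure = log(0.29),
                       n_innovator_seed = 10L,
                       innovation_months = 1:2,
                       seed = 1L) {
  cfg <- list(
    n_prescribers = as.integer(n_prescribers), n_clients = as.integer(n_clients),
    n_regions = as.integer(n_regions), specialty_mix = specialty_mix,
    region_unknown_prob = region_unknown_prob,
    caseload_dispersion = caseload_dispersion, sharing_rate = sharing_rate,
    region_mixing = region_mixing, dispensing_rate = dispensing_rate,
    n_months = as.integer(n_months), origin = origin,
    sud_pathway_mix = sud_pathway_mix,
    adopt_intercept = adopt_intercept,
    adopt_beta_exposure = adopt_beta_exposure,
    adopt_beta_caseload = adopt_beta_caseload,
    discont_intercept = discont_intercept,
    discont_beta_exposure = discont_beta_exposure,
    n_innovator_seed = as.integer(n_innovator_seed),
    innovation_months = as.integer(innovation_months),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_prescribers >= 1L, cfg$n_clients >= 1L, cfg$n_regions >= 1L)
  if (cfg$n_months < 4L)
    stop("n_months must be >= 4: confirming discontinuation needs a 3-month gap",
         call. = FALSE)
  for (nm in c("specialty_mix", "sud_pathway_mix")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(sprintf("%s must be a probability vector summing to 1", nm), call. = FALSE)
  }
  if (!setequal(names(cfg$specialty_mix), .SPECIALTIES))
    stop("specialty_mix must be named over: ", paste(.SPECIALTIES, collapse = ", "),
         call. = FALSE)
  if (cfg$sharing_rate < 1)
    stop("sharing_rate is expected prescribers per client and must be >= 1",
         call. = FALSE)
  if (cfg$n_innovator_seed > cfg$n_prescribers)
    stop("n_innovator_seed cannot exceed n_prescribers", call. = FALSE)
  if (max(cfg$innovation_months) >= cfg$n_months)
    stop("innovation window must end before the study window does", call. = FALSE)
  invisible(cfg)
}

# One RNG substream per logical stage, derived from the master seed so each
# stage is reproducible in isolation.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 2654435L + stage * 97L) %% 2147483647L)
}

region_names <- function(n_regions) {
  if (n_regions == 5L) .BC_REGIONS else paste0("region_", seq_len(n_regions))
}

#' Simulate prescriber and client populations
#'
#' Draws prescriber attributes (region, specialty, OAT-prescribing history,
#' first SUD-billing date, and a latent heavy-tailed caseload weight) and
#' client attributes (home region, birth year, chronic-disease score, Charlson
#' comorbidity index, social-assistance months, last overdose date, COVID-19
#' diagnosis date, and the SUD-indication pathway used when emitting history
#' records). OAT history is positively associated with caseload weight, as in
#' the real cohort where innovators were overwhelmingly OAT prescribers.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with data.frames \code{prescribers} and \code{clients}.
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, 1L))
  np <- config$n_prescribers
  nc <- config$n_clients
  regions <- region_names(config$n_regions)
  study_start <- month_start_date(1L, config$origin)

  p_region <- sample(regions, np, replace = TRUE)
  p_region[stats::runif(np) < config$region_unknown_prob] <- "Unknown"
  caseload_weight <- stats::rlnorm(np, meanlog = 0, sdlog = config$caseload_dispersion)
  oat_p <- stats::plogis(-1.2 + 1.3 * scale(log(caseload_weight))[, 1L])
  prescribers <- data.frame(
    prescriber_id = sprintf("p%05d", seq_len(np)),
    region = p_region,
    specialty = sample(names(config$specialty_mix), np, replace = TRUE,
                       prob = config$specialty_mix),
    oat_history = stats::runif(np) < oat_p,
    first_sud_billing_date = study_start -
      as.integer(stats::runif(np, min = 30, max = 365.25 * 24)),
    caseload_weight = caseload_weight,
    stringsAsFactors = FALSE
  )

  c_region <- sample(regions, nc, replace = TRUE)
  overdose_gap <- as.integer(stats::runif(nc, 1, 1200))
  has_od <- stats::runif(nc) < 0.20
  covid_month <- sample.int(config$n_months, nc, replace = TRUE)
  has_covid <- stats::runif(nc) < 0.04
  clients <- data.frame(
    client_id = sprintf("c%06d", seq_len(nc)),
    region = c_region,
    birth_year = sample(1945:2002, nc, replace = TRUE),
    chronic_disease_score = round(stats::rgamma(nc, shape = 1.2, scale = 2), 1),
    cci = stats::rpois(nc, 0.8),
    social_assistance_months = ifelse(stats::runif(nc) < 0.45,
                                      sample.int(12L, nc, replace = TRUE), 0L),
    last_overdose_date = as.Date(ifelse(has_od, study_start - overdose_gap, NA),
                                 origin = "1970-01-01"),
    covid_diagnosis_date = as.Date(ifelse(
      has_covid,
      month_start_date(covid_month, config$origin) + sample.int(27L, nc, TRUE),
      NA), origin = "1970-01-01"),
    sud_pathway = sample(names(config$sud_pathway_mix), nc, replace = TRUE,
                         prob = config$sud_pathway_mix),
    stringsAsFactors = FALSE
  )
  list(prescribers = prescribers, clients = clients)
}

#' Simulate historical records that establish SUD indications
#'
#' Emits, per client and according to its assigned pathway, the pre-study
#' records the case definition keys on: OAT dispensations, three SUD-coded
#' outpatient visits, one SUD-coded acute-care visit, or a perinatal record
#' flagged for substance use. Clients on the \code{none} pathway receive only
#' two SUD-coded visits, deliberately below the three-visit threshold.
#'
#' @param population output of \code{\link{simulate_population}}.
#' @param config a \code{\link{sim_config}}.
#' @return list of data.frames \code{dispensations} (historical OAT),
#'   \code{visits}, \code{acute_visits}, \code{perinatal}.
#' @export
simulate_sud_history <- function(population, config) {
  cl <- population$clients   # force inputs before seeding the stage stream
  pr <- population$prescribers
  set.seed(stage_seed(config$seed, 2L))
  study_start <- month_start_date(1L, config$origin)
  hist_date <- function(n) study_start - as.integer(stats::runif(n, 40, 365 * 4))
  rnd_presc <- function(n) sample(pr$prescriber_id, n, replace = TRUE,
                                  prob = pr$caseload_weight)

  oat_cl <- cl$client_id[cl$sud_pathway == "oat"]
  disp <- data.frame(
    client_id = oat_cl,
    prescriber_id = rnd_presc(length(oat_cl)),
    date = hist_date(length(oat_cl)),
    drug_code = sample(.OAT_CODES, length(oat_cl), replace = TRUE),
    med_class = "other",
    directions = "daily witnessed ingestion",
    stringsAsFactors = FALSE
  )

  vis_cl <- cl$client_id[cl$sud_pathway == "visits"]
  sub_cl <- cl$client_id[cl$sud_pathway == "none"]
  visits <- data.frame(
    client_id = c(rep(vis_cl, each = 3L), rep(sub_cl, each = 2L)),
    stringsAsFactors = FALSE
  )
  nv <- nrow(visits)
  visits$prescriber_id <- rnd_presc(nv)
  visits$date <- hist_date(nv) + rep_len(c(0L, 20L, 45L), nv)
  visits$diag_code <- sample(.SUD_DX_CODES, nv, replace = TRUE)

  ac_cl <- cl$client_id[cl$sud_pathway == "acute"]
  acute <- data.frame(
    client_id = ac_cl,
    date = hist_date(length(ac_cl)),
    diag_code = sample(.SUD_DX_CODES, length(ac_cl), replace = TRUE),
    stringsAsFactors = FALSE
  )

  pn_cl <- cl$client_id[cl$sud_pathway == "perinatal"]
  perinatal <- data.frame(
    client_id = pn_cl,
    date = hist_date(length(pn_cl)),
    sud_flag = TRUE,
    stringsAsFactors = FALSE
  )
  list(dispensations = disp, visits = visits, acute_visits = acute,
       perinatal = perinatal)
}

#' Simulate prescriber-client affiliation and background dispensations
#'
#' Attaches each client to one or more prescribers -- preferentially within
#' its home region, with prescriber choice weighted by the heavy-tailed
#' caseload weight -- and emits monthly background (non-PSS) dispensation
#' records for attached pairs. Each pair is guaranteed at least one record in
#' the study window so the patient-sharing network observed from claims
#' coincides with the latent affiliation structure.
#'
#' @param population output of \code{\link{simulate_population}}.
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{attachments} (distinct prescriber-client pairs) and
#'   \code{dispensations} (the in-window background stream).
#' @export
simulate_affiliation <- function(population, config) {
  pr <- population$prescribers  # force inputs before seeding the stage stream
  cl <- population$clients
  set.seed(stage_seed(config$seed, 3L))
  np <- nrow(pr)
  nc <- nrow(cl)

  k <- 1L + stats::rpois(nc, config$sharing_rate - 1)
  k <- pmin(k, np)
  by_region <- split(seq_len(np), pr$region)
  pres_idx <- vector("list", nc)
  for (i in seq_len(nc)) {
    ki <- k[i]
    pool <- by_region[[cl$region[i]]]
    cross <- stats::runif(ki) < config$region_mixing
    chosen <- integer(0)
    n_local <- sum(!cross)
    if (n_local > 0L && length(pool) > 0L) {
      n_local <- min(n_local, length(pool))
      chosen <- pool[sample.int(length(pool), n_local,
                                prob = pr$caseload_weight[pool])]
    }
    n_any <- ki - length(chosen)
    if (n_any > 0L) {
      rest <- setdiff(seq_len(np), chosen)
      chosen <- c(chosen, rest[sample.int(length(rest), min(n_any, length(rest)),
                                          prob = pr$caseload_weight[rest])])
    }
    pres_idx[[i]] <- chosen
  }
  attachments <- data.frame(
    client_id = rep(cl$client_id, lengths(pres_idx)),
    prescriber_id = pr$prescriber_id[unlist(pres_idx)],
    stringsAsFactors = FALSE
  )

  na <- nrow(attachments)
  nm <- config$n_months
  # month-by-pair emission matrix, with one guaranteed month per pair
  emit <- matrix(stats::runif(na * nm) < config$dispensing_rate, na, nm)
  forced <- sample.int(nm, na, replace = TRUE)
  emit[cbind(seq_len(na), forced)] <- TRUE
  pair_rep <- rep(seq_len(na), times = rowSums(emit))
  months <- rep(seq_len(nm), times = na)[as.vector(t(emit))]
  # first study month opens on the 27th (guidance release date)
  day_lo <- ifelse(months == 1L, 27L, 1L)
  day_hi <- 28L
  n_rec <- length(pair_rep)
  mstarts <- month_start_date(seq_len(nm), config$origin)
  dates <- mstarts[months] +
    (day_lo - 1L) + floor(stats::runif(n_rec) * (day_hi - day_lo + 1L))
  codes_i <- sample.int(nrow(.FORMULARY), n_rec, replace = TRUE,
                        prob = c(2, 2, 1, 1, 1.5, 1.5, 3, 3, 3, 3, 3, 3))
  dispensations <- data.frame(
    client_id = attachments$client_id[pair_rep],
    prescriber_id = attachments$prescriber_id[pair_rep],
    date = dates,
    drug_code = .FORMULARY$drug_code[codes_i],
    med_class = .FORMULARY$med_class[codes_i],
    directions = sample(.NEUTRAL_DIRECTIONS, n_rec, replace = TRUE),
    stringsAsFactors = FALSE
  )
  dispensations <- dispensations[order(dispensations$date), ]
  rownames(dispensations) <- NULL
  list(attachments = attachments, dispensations = dispensations)
}

#' Simulate peer-driven PSS adoption and discontinuation
#'
#' Seeds innovators in the innovation window, then lets each remaining
#' eligible prescriber adopt month by month with a logistic hazard driven by
#' its *lagged* peer exposure -- computed with the very same network and
#' exposure code the analysis uses (\code{\link{build_monthly_network}},
#' \code{\link{peer_exposure}}) so the planted coefficient is the estimand the
#' panel regression targets -- plus a standardized log-caseload effect.
#' Adopters face an analogous monthly cessation hazard; active
#' prescriber-months emit PSS dispensations whose directions text carries a
#' planted keyword.
#'
#' @param affiliation output of \code{\link{simulate_affiliation}}.
#' @param population output of \code{\link{simulate_population}}.
#' @param eligible character vector of prescriber ids at risk of adoption
#'   (the study cohort); exposure is evaluated on the network restricted to
#'   these prescribers.
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{pss_dispensations} (data.frame) and \code{truth}
#'   (class \code{"simulation_truth"}: coefficients, adoption / cessation /
#'   confirmable discontinuation months, caseload z-scores, exposure history).
#' @export
simulate_diffusion <- function(affiliation, population, eligible, config) {
  nm <- config$n_months
  disp <- affiliation$dispensations  # force inputs before seeding
  att <- affiliation$attachments
  force(eligible)
  force(population)
  set.seed(stage_seed(config$seed, 4L))
  att <- att[att$prescriber_id %in% eligible, ]
  ids <- sort(unique(eligible))
  n <- length(ids)

  cz <- caseload_zscore(att)
  z <- cz[match(ids, names(cz))]
  z[is.na(z)] <- 0

  adoption <- stats::setNames(rep(NA_integer_, n), ids)
  cessation <- stats::setNames(rep(NA_integer_, n), ids)

  w <- population$prescribers$caseload_weight[
    match(ids, population$prescribers$prescriber_id)]
  seeds <- ids[sample.int(n, min(config$n_innovator_seed, n), prob = w)]
  iw <- config$innovation_months
  adoption[seeds] <- iw[sample.int(length(iw), length(seeds), replace = TRUE)]

  att_by_p <- split(att$client_id, att$prescriber_id)
  pss_codes <- c("HYD-TAB", "MOR-SR", "DEX", "MPH", "DZP", "CZP")
  pss_code_w <- c(4, 2, 1, 1, 1, 1)
  emit_month <- function(active_ids, m) {
    n_disp <- 1L + stats::rpois(length(active_ids), 0.7)
    p_rep <- rep(active_ids, n_disp)
    cl <- vapply(p_rep, function(p) {
      pool <- att_by_p[[p]]
      pool[sample.int(length(pool), 1L)]
    }, character(1L), USE.NAMES = FALSE)
    day_lo <- if (m == 1L) 27L else 1L
    ci <- sample(pss_codes, length(p_rep), replace = TRUE, prob = pss_code_w)
    data.frame(
      client_id = cl,
      prescriber_id = p_rep,
      date = month_start_date(m, config$origin) + (day_lo - 1L) +
        floor(stats::runif(length(p_rep)) * (28L - day_lo + 1L)),
      drug_code = ci,
      med_class = .FORMULARY$med_class[match(ci, .FORMULARY$drug_code)],
      directions = sample(.PSS_DIRECTIONS, length(p_rep), replace = TRUE),
      stringsAsFactors = FALSE
    )
  }

  # Distinct prescriber-client pairs of the background stream with the month
  # each first appears; PSS emissions can only advance a pair's first month
  # (they go to already-attached clients), tracked in pss_first.
  bg_m <- month_index(disp$date, config$origin)
  bkey <- paste(disp$prescriber_id, disp$client_id, sep = "\r")
  ord <- order(bg_m)
  fst <- !duplicated(bkey[ord])
  pair_tab <- data.frame(prescriber_id = disp$prescriber_id[ord][fst],
                         client_id = disp$client_id[ord][fst],
                         first_month = bg_m[ord][fst],
                         stringsAsFactors = FALSE)
  pair_tab <- pair_tab[pair_tab$prescriber_id %in% ids, ]
  pair_key <- paste(pair_tab$prescriber_id, pair_tab$client_id, sep = "\r")
  pss_first <- rep(NA_integer_, nrow(pair_tab))

  # Month-by-month: the network feeding the hazard at month m is built from
  # every record dated <= end of m-1 -- background AND already-emitted PSS
  # dispensations -- exactly what the analysis sees when it lags exposure.
  exposure_hist <- matrix(0, n, nm, dimnames = list(ids, NULL))
  first_risk <- max(config$innovation_months) + 1L
  pss_out <- vector("list", nm)
  for (m in seq_len(nm)) {
    if (m >= first_risk) {
      eff_first <- pmin(pair_tab$first_month, pss_first, na.rm = TRUE)
      snap <- snapshot_from_pairs(
        pair_tab[eff_first <= m - 1L, ], m - 1L, ids,
        sprintf("months 1..%d (cumulative)", m - 1L))
      adopters <- ids[!is.na(adoption) & adoption <= m - 1L]
      e <- peer_exposure(snap, adopters)
      e <- e[match(ids, names(e))]
      exposure_hist[, m] <- e

      at_risk <- is.na(adoption)
      eta <- config$adopt_intercept + config$adopt_beta_exposure * e[at_risk] +
        config$adopt_beta_caseload * z[at_risk]
      newly <- at_risk
      newly[at_risk] <- stats::runif(sum(at_risk)) < stats::plogis(eta)
      adoption[newly] <- m

      active_prev <- !is.na(adoption) & adoption < m & is.na(cessation)
      if (any(active_prev)) {
        eta_s <- config$discont_intercept +
          config$discont_beta_exposure * e[active_prev]
        stopping <- active_prev
        stopping[active_prev] <- stats::runif(sum(active_prev)) <
          stats::plogis(eta_s)
        cessation[stopping] <- m
      }
    }
    active_now <- ids[!is.na(adoption) & adoption <= m &
                        (is.na(cessation) | cessation > m)]
    if (length(active_now) > 0L) {
      em <- emit_month(active_now, m)
      pss_out[[m]] <- em
      pidx <- match(paste(em$prescriber_id, em$client_id, sep = "\r"),
                    pair_key)
      pss_first[pidx] <- pmin(pss_first[pidx], m, na.rm = TRUE)
    }
  }
  pss_disp <- do.call(rbind, pss_out[!vapply(pss_out, is.null, logical(1L))])
  if (is.null(pss_disp)) pss_disp <- disp[0, ]

  # discontinuation is confirmable only when a full 3-month PSS-free gap fits
  discont <- ifelse(!is.na(cessation) & cessation + 2L <= nm, cessation, NA_integer_)
  truth <- structure(list(
    true_coefficients = c(adopt_intercept = config$adopt_intercept,
                          adopt_beta_exposure = config$adopt_beta_exposure,
                          adopt_beta_caseload = config$adopt_beta_caseload,
                          discont_intercept = config$discont_intercept,
                          discont_beta_exposure = config$discont_beta_exposure),
    adoption_month = adoption,
    cessation_month = cessation,
    discontinuation_month = stats::setNames(as.integer(discont), ids),
    caseload_z = stats::setNames(z, ids),
    exposure = exposure_hist,
    seeds = seeds
  ), class = "simulation_truth")
  list(pss_dispensations = pss_disp, truth = truth)
}

#' Generate a complete synthetic PSS study
#'
#' Runs the population, history, affiliation and diffusion stages and returns
#' the five record-level tables the analysis consumes plus the ground-truth
#' ledger. Regenerating with the same config (including seed) reproduces the
#' tables byte-for-byte.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{data} (dispensations, visits, acute_visits,
#'   perinatal, prescribers, clients), \code{truth}, \code{config}.
#' @export
#' @examples
#' study <- simulate_pss_study(sim_config(n_prescribers = 40, n_clients = 150,
#'                                        n_innovator_seed = 3, seed = 7))
#' nrow(study$data$prescribers)
simulate_pss_study <- function(config = sim_config()) {
  validate_sim_config(config)
  pop <- simulate_population(config)
  hist <- simulate_sud_history(pop, config)
  aff <- simulate_affiliation(pop, config)

  # the cohort at risk: prescribers with >= 1 in-window dispensation to a
  # client flagged before that dispensation (same rule the analysis applies)
  flags <- flag_sud_clients(hist$dispensations, hist$visits, hist$acute_visits,
                            hist$perinatal)
  window <- c(month_start_date(1L, config$origin) + 26L,
              month_end_date(config$n_months, config$origin))
  eligible <- build_prescriber_cohort(aff$dispensations, flags, window)

  diff <- simulate_diffusion(aff, pop, eligible, config)
  dispensations <- rbind(hist$dispensations, aff$dispensations,
                         diff$pss_dispensations)
  dispensations <- dispensations[order(dispensations$date,
                                       method = "radix"), ]
  rownames(dispensations) <- NULL
  dispensations$dispensation_id <- sprintf("d%07d", seq_len(nrow(dispensations)))
  list(
    data = list(dispensations = dispensations,
                visits = hist$visits,
                acute_visits = hist$acute_visits,
                perinatal = hist$perinatal,
                prescribers = pop$prescribers,
                clients = pop$clients),
    truth = diff$truth,
    config = config
  )
}

#' Write / read the synthetic study tables as delimited text
#'
#' Tables are tab-separated with a header row; dates are ISO-8601. The truth
#' ledger is written as a key-value header plus a tab-separated event table.
#'
#' @param study result of \code{\link{simulate_pss_study}}.
#' @param dir output directory (created if needed).
#' @return \code{write_study_data}: invisibly, the vector of files written;
#'   \code{read_study_data}: the list of tables.
#' @export
write_study_data <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(study$data)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(study$data[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    files <- c(files, f)
  }
  tf <- file.path(dir, "simulation_truth.txt")
  write_simulation_truth(study$truth, tf)
  invisible(c(files, tf))
}

#' @rdname write_study_data
#' @export
read_study_data <- function(dir) {
  tabs <- c("dispensations", "visits", "acute_visits", "perinatal",
            "prescribers", "clients")
  out <- lapply(tabs, function(nm) {
    d <- utils::read.table(file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           na.strings = "", quote = "", comment.char = "")
    for (cn in intersect(names(d), c("date", "first_sud_billing_date",
                                     "last_overdose_date",
                                     "covid_diagnosis_date")))
      d[[cn]] <- as.Date(d[[cn]])
    for (cn in intersect(names(d), c("diag_code", "drug_code")))
      d[[cn]] <- as.character(d[[cn]])
    d
  })
  stats::setNames(out, tabs)
}

#' @param truth a \code{simulation_truth} object.
#' @param path file path.
#' @rdname write_study_data
#' @export
write_simulation_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(truth$true_coefficients))
    writeLines(sprintf("# %s=%.10g", nm, truth$true_coefficients[[nm]]), con)
  ev <- data.frame(prescriber_id = names(truth$adoption_month),
                   adoption_month = unname(truth$adoption_month),
                   cessation_month = unname(truth$cessation_month),
                   discontinuation_month = unname(truth$discontinuation_month),
                   caseload_z = unname(truth$caseload_z))
  utils::write.table(ev, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_study_data
#' @export
read_simulation_truth <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "="))
  coefs <- stats::setNames(as.numeric(kv[, 2L]), kv[, 1L])
  ev <- utils::read.table(text = lines[!grepl("^# ", lines)], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          na.strings = "")
  structure(list(
    true_coefficients = coefs,
    adoption_month = stats::setNames(ev$adoption_month, ev$prescriber_id),
    cessation_month = stats::setNames(ev$cessation_month, ev$prescriber_id),
    discontinuation_month = stats::setNames(ev$discontinuation_month,
                                            ev$prescriber_id),
    caseload_z = stats::setNames(ev$caseload_z, ev$prescriber_id)
  ), class = "simulation_truth")
}

#' Standardized log-caseload per prescriber
#'
#' The z-score of log distinct-client count across prescribers, the caseload
#' regressor shared by the generator's adoption hazard and the recovery model.
#'
#' @param attachments data.frame with columns \code{prescriber_id},
#'   \code{client_id} (duplicates allowed).
#' @return named numeric vector of z-scores.
#' @export
caseload_zscore <- function(attachments) {
  n_cl <- tapply(attachments$client_id, attachments$prescriber_id,
                 function(x) length(unique(x)))
  x <- log(as.numeric(n_cl))
  s <- stats::sd(x)
  z <- if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  stats::setNames(z, names(n_cl))
}
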