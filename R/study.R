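# End-to-end study assembly: cohort -> case-finding -> monthly networks ->
# panels, with every analysis choice carried in one config object.

#' Analysis configuration
#'
#' Collects the knobs of the full pipeline. Defaults reproduce the primary
#' analysis: calendar-month binning anchored at 2020-03, an 18-month study
#' window opening March 27, cumulative network accumulation, the sensitive
#' case-finding algorithm, a 2-month innovation window, a discontinuation
#' panel starting July 2020, the 3-month gap rule, unweighted peer exposure,
#' and empirical quartile bins. Sensitivity variants are config switches:
#' \code{scheme = "mid16"} (16th-to-15th measurement months),
#' \code{window = "trailing"} with \code{trailing_k}, \code{algorithm =
#' "specific"}, longer \code{innovation_months}, \code{exposure_variant =
#' "weighted"} or \code{"two_degree"}, \code{min_sud_clients} row-inclusion
#' thresholds, and \code{quartile_mode = "printed"} for the published
#' replication cut points.
#'
#' @param origin origin month \code{"YYYY-MM"}.
#' @param n_months study length.
#' @param scheme month binning (\code{\link{month_index}}).
#' @param window,trailing_k network accumulation window
#'   (\code{\link{build_monthly_network}}).
#' @param algorithm case-finding tier (\code{\link{classify_dispensations}}).
#' @param keywords keyword config; NULL loads the packaged default.
#' @param codes SUD/OAT code sets; NULL uses the packaged default.
#' @param innovation_months innovation window months.
#' @param discont_panel_start first month of the discontinuation panel.
#' @param gap PSS-free months confirming discontinuation.
#' @param quartile_mode \code{"empirical"} or \code{"printed"}.
#' @param exposure_variant peer-exposure variant
#'   (\code{\link{peer_exposure}}).
#' @param min_sud_clients minimum lagged SUD caseload for a panel row
#'   (0 disables the client-load inclusion threshold).
#' @param window_start_day day-of-month the study window opens in month 1.
#' @return object of class \code{"pss_config"}.
#' @export
pss_config <- function(origin = "2020-03", n_months = 18L,
                       scheme = c("calendar", "mid16"),
                       window = c("cumulative", "trailing"), trailing_k = NULL,
                       algorithm = c("sensitive", "specific"),
                       keywords = NULL, codes = NULL,
                       innovation_months = 1:2, discont_panel_start = 5L,
                       gap = 3L, quartile_mode = c("empirical", "printed"),
                       exposure_variant = c("unweighted", "weighted",
                                            "two_degree"),
                       min_sud_clients = 0L, window_start_day = 27L) {
  cfg <- list(origin = origin, n_months = as.integer(n_months),
              scheme = match.arg(scheme), window = match.arg(window),
              trailing_k = trailing_k, algorithm = match.arg(algorithm),
              keywords = keywords, codes = codes,
              innovation_months = as.integer(innovation_months),
              discont_panel_start = as.integer(discont_panel_start),
              gap = as.integer(gap), quartile_mode = match.arg(quartile_mode),
              exposure_variant = match.arg(exposure_variant),
              min_sud_clients = as.integer(min_sud_clients),
              window_start_day = as.integer(window_start_day))
  cfg$study_window <- c(month_start_date(1L, origin) + (cfg$window_start_day - 1L),
                        month_end_date(cfg$n_months, origin))
  class(cfg) <- "pss_config"
  cfg
}

#' Run the full PSS network-diffusion analysis pipeline
#'
#' From the five record tables: flags SUD clients, assembles the prescriber
#' cohort, classifies PSS dispensations, derives adoption status, builds one
#' patient-sharing network snapshot per study month with node metrics and
#' lagged peer exposure, aggregates monthly client case mix, and assembles the
#' adoption and discontinuation panels.
#'
#' @param data list of tables as produced by \code{\link{simulate_pss_study}}
#'   (or \code{\link{read_study_data}}): \code{dispensations}, \code{visits},
#'   \code{acute_visits}, \code{perinatal}, \code{prescribers},
#'   \code{clients}.
#' @param config a \code{\link{pss_config}}.
#' @param keep_snapshots retain the monthly network snapshots on the object
#'   (needed for edge-list reports; modest memory at desk scale).
#' @return object of class \code{"pss_study"}.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_pss_study(sim_config(n_prescribers = 60, n_clients = 250,
#'                                      n_innovator_seed = 4, seed = 11))
#' study <- pss_study(sim$data)
#' head(study$adoption_panel)
#' }
pss_study <- function(data, config = pss_config(), keep_snapshots = TRUE) {
  cfg <- config
  if (is.null(cfg$keywords)) cfg$keywords <- load_keyword_config()
  if (is.null(cfg$codes))
    cfg$codes <- list(sud_diagnostic_codes = .SUD_DX_CODES,
                      oat_drug_codes = .OAT_CODES)

  flags <- flag_sud_clients(data$dispensations, data$visits,
                            data$acute_visits, data$perinatal, cfg$codes)
  cohort <- build_prescriber_cohort(data$dispensations, flags,
                                    cfg$study_window)
  classified <- classify_dispensations(data$dispensations, cfg$keywords,
                                       cfg$algorithm)
  adoption <- derive_adoption(classified, cohort, cfg$innovation_months,
                              cfg$origin, cfg$scheme)

  pss <- classified[classified$is_pss &
                      classified$prescriber_id %in% cohort, ]
  pss$month <- month_index(pss$date, cfg$origin, cfg$scheme)
  pss <- pss[pss$month >= 1L & pss$month <= cfg$n_months, ]
  pss_months <- lapply(split(pss$month, pss$prescriber_id), function(x)
    sort(unique(x)))

  nm <- cfg$n_months
  nodes <- sort(unique(as.character(cohort)))
  cum_pairs <- NULL
  if (cfg$window == "cumulative") {
    # distinct in-window pairs with their first month: each cumulative
    # snapshot is then a cheap filter instead of a full rebuild
    d <- data$dispensations
    dm <- month_index(d$date, cfg$origin, cfg$scheme)
    sel <- dm >= 1L & dm <= nm & d$prescriber_id %in% cohort
    dk <- paste(d$prescriber_id[sel], d$client_id[sel], sep = "\r")
    ordm <- order(dm[sel])
    fst <- !duplicated(dk[ordm])
    cum_pairs <- data.frame(
      prescriber_id = d$prescriber_id[sel][ordm][fst],
      client_id = d$client_id[sel][ordm][fst],
      first_month = dm[sel][ordm][fst], stringsAsFactors = FALSE)
  }
  snapshots <- metrics <- exposure <- case_mix <- vector("list", nm)
  for (m in seq_len(nm)) {
    snap <- if (!is.null(cum_pairs))
      snapshot_from_pairs(cum_pairs[cum_pairs$first_month <= m, ], m, nodes,
                          sprintf("months 1..%d (cumulative)", m))
    else build_monthly_network(data$dispensations, cohort, m,
                               window = cfg$window, k = cfg$trailing_k,
                               origin = cfg$origin, scheme = cfg$scheme)
    metrics[[m]] <- node_metrics(snap)
    adopters <- adoption$prescriber_id[!is.na(adoption$first_pss_month) &
                                         adoption$first_pss_month <= m]
    e <- peer_exposure(snap, adopters, cfg$exposure_variant)
    exposure[[m]] <- data.frame(prescriber_id = names(e), month = m,
                                exposure = as.numeric(e),
                                stringsAsFactors = FALSE)
    case_mix[[m]] <- aggregate_case_mix(data$dispensations, data$clients,
                                        flags, cohort, m, cfg$origin,
                                        cfg$scheme)
    if (keep_snapshots) snapshots[[m]] <- snap
  }

  win_pairs <- data$dispensations[
    as.Date(data$dispensations$date) >= cfg$study_window[1L] &
      as.Date(data$dispensations$date) <= cfg$study_window[2L] &
      data$dispensations$prescriber_id %in% cohort,
    c("prescriber_id", "client_id")]
  cz <- caseload_zscore(win_pairs)

  study <- structure(list(
    data = data, config = cfg, flags = flags, cohort = cohort,
    adoption = adoption, pss_months = pss_months,
    pss_dispensations = pss,
    snapshots = if (keep_snapshots) snapshots else NULL,
    metrics = metrics, exposure = exposure, case_mix = case_mix,
    caseload_z = cz), class = "pss_study")
  study$adoption_panel <- assemble_panel(study, "adoption")
  study$discontinuation_panel <- assemble_panel(study, "discontinuation")
  study
}

#' @export
print.pss_study <- function(x, ...) {
  st <- table(x$adoption$status)
  cat("<pss_study>\n")
  cat(sprintf("  cohort: %d prescribers, %d flagged SUD clients\n",
              length(x$cohort), nrow(x$flags)))
  cat(sprintf("  adoption: %d innovators, %d early adopters, %d non-adopters\n",
              st[["innovator"]], st[["early adopter"]], st[["non-adopter"]]))
  cat(sprintf("  panels: %d adoption rows, %d discontinuation rows over %d months\n",
              nrow(x$adoption_panel), nrow(x$discontinuation_panel),
              x$config$n_months))
  invisible(x)
}
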