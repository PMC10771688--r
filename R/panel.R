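# Monthly outcome indicators, lagged covariates, quartile categorization, and
# assembly of the adoption and discontinuation analysis panels.

#' Adoption outcome indicator
#'
#' 1 iff the month is the prescriber's first PSS month; afterwards the
#' prescriber leaves the risk set (no rows exist).
#'
#' @param first_pss_month integer first PSS month (NA for non-adopters).
#' @param month study month index.
#' @return integer 0/1 vector.
#' @export
adoption_outcome <- function(first_pss_month, month) {
  as.integer(!is.na(first_pss_month) & first_pss_month == month)
}

#' Discontinuation event month under the 3-month-gap rule
#'
#' Discontinuation is the first month \code{m} after PSS initiation such that
#' months \code{m, m+1, ..., m+gap-1} all lack PSS dispensations; the full gap
#' must be observable inside the study window, so a trailing shorter gap is
#' censored (no event). The event month is the first gap month.
#'
#' @param pss_months integer vector of months with >= 1 PSS dispensation.
#' @param n_months last observable study month.
#' @param gap required PSS-free run length (default 3).
#' @return integer event month, or NA if censored.
#' @export
#' @examples
#' discontinuation_month(c(4), n_months = 18)    # event at month 5
#' discontinuation_month(c(4:18), n_months = 18) # never discontinues
discontinuation_month <- function(pss_months, n_months, gap = 3L) {
  pss_months <- sort(unique(as.integer(pss_months)))
  if (length(pss_months) == 0L) stop("prescriber has no PSS months", call. = FALSE)
  first <- pss_months[1L]
  has <- rep(FALSE, n_months)
  has[pss_months[pss_months <= n_months]] <- TRUE
  for (m in seq.int(first + 1L, length.out = max(0L, n_months - first))) {
    if (m + gap - 1L > n_months) break
    if (!any(has[m:(m + gap - 1L)])) return(as.integer(m))
  }
  NA_integer_
}

#' Discontinuation outcome indicator
#'
#' @inheritParams discontinuation_month
#' @param month query month; must not precede the first PSS month.
#' @return integer 0/1.
#' @export
discontinuation_outcome <- function(pss_months, month, n_months, gap = 3L) {
  first <- min(pss_months)
  if (month < first)
    stop("month precedes the first PSS month", call. = FALSE)
  ev <- discontinuation_month(pss_months, n_months, gap)
  as.integer(!is.na(ev) && month == ev)
}

#' Quartile cut points
#'
#' \code{mode = "empirical"} computes type-1 quantile cut points at 25/50/75%
#' from the supplied values (the panel-entry distribution); \code{mode =
#' "printed"} returns the replication defaults matching the published
#' category boundaries for the given panel kind and variable.
#'
#' @param x numeric values (empirical mode).
#' @param mode \code{"empirical"} or \code{"printed"}.
#' @param kind panel kind, \code{"adoption"} or \code{"discontinuation"}.
#' @param variable \code{"caseload"} or \code{"experience"}.
#' @return numeric vector of three increasing cut points.
#' @export
quartile_cuts <- function(x = NULL, mode = c("empirical", "printed"),
                          kind = c("adoption", "discontinuation"),
                          variable = c("caseload", "experience")) {
  mode <- match.arg(mode)
  kind <- match.arg(kind)
  variable <- match.arg(variable)
  if (mode == "printed") {
    printed <- list(
      adoption = list(caseload = c(2, 6, 13), experience = c(4.5, 10.9, 22.4)),
      discontinuation = list(caseload = c(18, 43, 85),
                             experience = c(4, 8.3, 17.4)))
    return(printed[[kind]][[variable]])
  }
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 1, na.rm = TRUE))
  # degenerate distributions collapse; nudge into a strictly increasing set
  if (any(diff(q) <= 0)) q <- q + seq(0, 2e-9, length.out = 3L) * max(1, abs(q))
  q
}

#' Bin values into quartile categories
#'
#' @param x numeric values.
#' @param cuts three increasing cut points.
#' @param right if TRUE bins are right-closed at the cuts (counts: <= c1,
#'   (c1, c2], ...); if FALSE they are left-closed (experience-style: < c1,
#'   [c1, c2), ...).
#' @return factor with levels \code{Q1..Q4} (Q1 is the reference bin).
#' @export
apply_quartiles <- function(x, cuts, right = TRUE) {
  stopifnot(length(cuts) == 3L, !is.unsorted(cuts))
  idx <- if (right) 1L + (x > cuts[1L]) + (x > cuts[2L]) + (x > cuts[3L])
  else 1L + (x >= cuts[1L]) + (x >= cuts[2L]) + (x >= cuts[3L])
  factor(paste0("Q", idx), levels = paste0("Q", 1:4))
}

#' Monthly caseload and client case-mix aggregates per prescriber
#'
#' The month's SUD caseload is the set of flagged clients with at least one
#' dispensation from the prescriber during the calendar month. Aggregates are
#' percentages over that caseload: clients aged 40+ at month end, Charlson
#' comorbidity index above 1, any benzodiazepine dispensation in the 12
#' months ending with the month, social-assistance receipt, overdose in the
#' prior 12 months; plus a flag for having treated any client with a COVID-19
#' diagnosis by month end. Prescribers with an empty caseload that month get
#' zero percentages (a stated convention keeping their panel rows estimable).
#'
#' @param dispensations full dispensation table.
#' @param clients client attribute table.
#' @param sud_flags output of \code{\link{flag_sud_clients}}.
#' @param cohort cohort prescriber ids.
#' @param month study month index.
#' @param origin,scheme month binning, see \code{\link{month_index}}.
#' @return data.frame with one row per cohort prescriber.
#' @export
aggregate_case_mix <- function(dispensations, clients, sud_flags, cohort,
                               month, origin = "2020-03",
                               scheme = "calendar") {
  m_rec <- month_index(dispensations$date, origin, scheme)
  mend <- month_end_date(month, origin)
  in_m <- m_rec == month & dispensations$prescriber_id %in% cohort &
    dispensations$client_id %in% sud_flags$client_id
  load_pairs <- unique(dispensations[in_m, c("prescriber_id", "client_id")])

  # client-level flags evaluated at month end
  benzo_win <- m_rec >= month - 11L & m_rec <= month &
    dispensations$med_class == "benzodiazepine"
  benzo_clients <- unique(dispensations$client_id[benzo_win])
  cl <- clients
  cl$aged40 <- as.integer(format(mend, "%Y")) - cl$birth_year >= 40
  cl$cci_gt1 <- cl$cci > 1
  cl$benzo <- cl$client_id %in% benzo_clients
  cl$social <- cl$social_assistance_months > 0
  cl$od12 <- !is.na(cl$last_overdose_date) &
    cl$last_overdose_date > (mend - 365L) & cl$last_overdose_date <= mend
  cl$covid <- !is.na(cl$covid_diagnosis_date) & cl$covid_diagnosis_date <= mend

  ids <- sort(unique(as.character(cohort)))
  out <- data.frame(prescriber_id = ids, month = as.integer(month),
                    caseload = 0L, pct_age40 = 0, pct_cci_gt1 = 0,
                    pct_benzo = 0, pct_social_assistance = 0,
                    pct_overdose_12m = 0, covid_client = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(load_pairs) == 0L) return(out)
  ci <- match(load_pairs$client_id, cl$client_id)
  agg <- function(v) tapply(v[ci], load_pairs$prescriber_id, mean) * 100
  n_by <- table(load_pairs$prescriber_id)
  rows <- match(names(n_by), out$prescriber_id)
  out$caseload[rows] <- as.integer(n_by)
  out$pct_age40[rows] <- as.numeric(agg(cl$aged40))
  out$pct_cci_gt1[rows] <- as.numeric(agg(cl$cci_gt1))
  out$pct_benzo[rows] <- as.numeric(agg(cl$benzo))
  out$pct_social_assistance[rows] <- as.numeric(agg(cl$social))
  out$pct_overdose_12m[rows] <- as.numeric(agg(cl$od12))
  cov <- tapply(cl$covid[ci], load_pairs$prescriber_id, any)
  out$covid_client[rows] <- as.integer(cov)
  out
}

#' Assemble an analysis panel of prescriber-months
#'
#' Builds the repeated-measures panel for the adoption or discontinuation
#' model from a \code{\link{pss_study}} object. Every time-varying regressor
#' in a month-\code{m} row is the month-\code{m-1} value (network metrics,
#' peer exposure and its category, caseload, case-mix aggregates, years of
#' experience), so no regressor uses information past the end of \code{m-1}.
#'
#' The adoption panel covers months from the first post-innovation month to
#' study end; innovators never enter (their event precedes the panel), other
#' prescribers contribute rows while unadopted plus their initiation month
#' (outcome 1). The discontinuation panel covers PSS initiators from
#' \code{max(first PSS month, discontinuation panel start)} until the
#' confirmed 3-month-gap event (outcome 1 at the event month, the first gap
#' month) or study end.
#'
#' @param study a \code{\link{pss_study}} object.
#' @param kind \code{"adoption"} or \code{"discontinuation"}.
#' @return data.frame panel; quartile categories are bound per the study
#'   config (\code{quartile_mode}).
#' @export
assemble_panel <- function(study, kind = c("adoption", "discontinuation")) {
  kind <- match.arg(kind)
  cfg <- study$config
  nm <- cfg$n_months
  adoption <- study$adoption
  start <- if (kind == "adoption") max(cfg$innovation_months) + 1L
  else cfg$discont_panel_start

  rows <- vector("list", 0L)
  if (kind == "adoption") {
    sub <- adoption[is.na(adoption$first_pss_month) |
                      adoption$first_pss_month >= start, ]
    for (i in seq_len(nrow(sub))) {
      last <- if (is.na(sub$first_pss_month[i])) nm else sub$first_pss_month[i]
      if (last < start) next
      rows[[length(rows) + 1L]] <- data.frame(
        prescriber_id = sub$prescriber_id[i],
        month = seq.int(start, last),
        outcome = adoption_outcome(sub$first_pss_month[i], seq.int(start, last)),
        stringsAsFactors = FALSE)
    }
  } else {
    pm <- study$pss_months
    init <- adoption[!is.na(adoption$first_pss_month), ]
    for (i in seq_len(nrow(init))) {
      id <- init$prescriber_id[i]
      months_i <- pm[[id]]
      ev <- discontinuation_month(months_i, nm, cfg$gap)
      first_row <- max(init$first_pss_month[i], start)
      last <- if (is.na(ev)) nm else ev
      if (last < first_row) next
      mm <- seq.int(first_row, last)
      rows[[length(rows) + 1L]] <- data.frame(
        prescriber_id = id, month = mm,
        outcome = as.integer(!is.na(ev) & mm == ev),
        stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, c(rows, list(data.frame(
    prescriber_id = character(0), month = integer(0), outcome = integer(0),
    stringsAsFactors = FALSE))))
  if (nrow(panel) == 0L) return(panel)

  # lagged month-(m-1) regressors from the cached monthly tables
  lag_m <- panel$month - 1L
  met <- do.call(rbind, study$metrics)
  key_m <- paste(met$prescriber_id, met$month)
  mi <- match(paste(panel$prescriber_id, lag_m), key_m)
  panel$degree <- met$degree[mi]
  panel$clustering <- met$clustering[mi]
  panel$degree_centrality <- met$degree_centrality[mi]
  panel$adjusted_strength <- met$adjusted_strength[mi]

  expo <- do.call(rbind, study$exposure)
  ei <- match(paste(panel$prescriber_id, lag_m),
              paste(expo$prescriber_id, expo$month))
  panel$exposure <- expo$exposure[ei]
  panel$exposure_cat <- categorize_exposure(panel$exposure)

  cmx <- do.call(rbind, study$case_mix)
  xi <- match(paste(panel$prescriber_id, lag_m),
              paste(cmx$prescriber_id, cmx$month))
  for (cn in c("caseload", "pct_age40", "pct_cci_gt1", "pct_benzo",
               "pct_social_assistance", "pct_overdose_12m", "covid_client"))
    panel[[cn]] <- cmx[[cn]][xi]

  pr <- study$data$prescribers
  pi <- match(panel$prescriber_id, pr$prescriber_id)
  panel$region <- stats::relevel(factor(pr$region[pi]), ref = ref_level(
    pr$region[pi], "Interior"))
  panel$specialty <- stats::relevel(factor(pr$specialty[pi]), ref = ref_level(
    pr$specialty[pi], "general practice"))
  panel$oat_history <- as.integer(pr$oat_history[pi])
  panel$experience_years <- as.numeric(
    month_end_date(lag_m, cfg$origin) - pr$first_sud_billing_date[pi]) / 365.25
  panel$caseload_z <- study$caseload_z[panel$prescriber_id]
  panel$study_month <- panel$month

  # quartile bins from the panel-entry distribution (first row/prescriber)
  entry <- !duplicated(panel$prescriber_id)
  cl_cuts <- if (cfg$quartile_mode == "printed")
    quartile_cuts(mode = "printed", kind = kind, variable = "caseload")
  else quartile_cuts(panel$caseload[entry], "empirical")
  ex_cuts <- if (cfg$quartile_mode == "printed")
    quartile_cuts(mode = "printed", kind = kind, variable = "experience")
  else quartile_cuts(panel$experience_years[entry], "empirical")
  panel$caseload_cat <- apply_quartiles(panel$caseload, cl_cuts, right = TRUE)
  panel$experience_cat <- apply_quartiles(panel$experience_years, ex_cuts,
                                          right = FALSE)
  if (cfg$min_sud_clients > 0L)
    panel <- panel[panel$caseload >= cfg$min_sud_clients, ]
  panel <- panel[order(panel$prescriber_id, panel$month), ]
  rownames(panel) <- NULL
  attr(panel, "kind") <- kind
  attr(panel, "cuts") <- list(caseload = cl_cuts, experience = ex_cuts)
  panel
}

ref_level <- function(x, preferred) {
  if (preferred %in% x) preferred else sort(unique(x))[1L]
}
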