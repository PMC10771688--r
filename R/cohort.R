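# SUD client case definition and the eligible prescriber cohort.

#' Load diagnostic-code and OAT-drug sets
#'
#' Reads a YAML file with keys \code{sud_diagnostic_codes} and
#' \code{oat_drug_codes} (each a list of strings). The defaults shipped under
#' \code{inst/extdata/sud_codes.yaml} are illustrative stand-ins for the
#' registry code lists used provincially, which are not reproduced here; any
#' real application should substitute its own lists.
#'
#' @param path YAML file; default is the packaged illustrative set.
#' @return list with character vectors \code{sud_diagnostic_codes},
#'   \code{oat_drug_codes}.
#' @export
load_code_sets <- function(path = system.file("extdata", "sud_codes.yaml",
                                              package = "pssnet")) {
  raw <- yaml::read_yaml(path)
  for (nm in c("sud_diagnostic_codes", "oat_drug_codes")) {
    if (is.null(raw[[nm]]) || length(raw[[nm]]) == 0L)
      stop("code set '", nm, "' missing or empty in ", path, call. = FALSE)
    bad <- !vapply(raw[[nm]], function(x) is.character(x) || is.numeric(x),
                   logical(1L))
    if (any(bad))
      stop("malformed entry in code set '", nm, "': ",
           paste(raw[[nm]][bad], collapse = ", "), call. = FALSE)
  }
  list(sud_diagnostic_codes = as.character(unlist(raw$sud_diagnostic_codes)),
       oat_drug_codes = as.character(unlist(raw$oat_drug_codes)))
}

#' Flag clients with a substance use disorder indication
#'
#' A client is flagged iff any of: (i) at least one OAT dispensation; (ii) at
#' least three outpatient physician or nurse-practitioner visits on distinct
#' dates carrying an SUD diagnostic code; (iii) at least one acute-care visit
#' with an SUD diagnostic code; or (iv) an SUD-indicating perinatal record.
#' All historical records are used (the lookback is a property of the input
#' extract, not of this function). The first indication date is the earliest
#' date at which any pathway is satisfied -- for the visit-count rule that is
#' the date of the third distinct-date visit.
#'
#' @param dispensations data.frame with \code{client_id}, \code{drug_code},
#'   \code{date}.
#' @param visits outpatient visits: \code{client_id}, \code{date},
#'   \code{diag_code}.
#' @param acute_visits acute-care visits: \code{client_id}, \code{date},
#'   \code{diag_code}.
#' @param perinatal perinatal records: \code{client_id}, \code{date},
#'   \code{sud_flag} (logical).
#' @param codes code sets as from \code{\link{load_code_sets}}.
#' @param min_visits outpatient visit threshold (default 3 distinct dates).
#' @return data.frame \code{client_id}, \code{sud_indicated},
#'   \code{first_indication_date}, \code{pathway}; one row per flagged
#'   client. Empty inputs give an empty table.
#' @export
flag_sud_clients <- function(dispensations, visits, acute_visits, perinatal,
                             codes = list(sud_diagnostic_codes = .SUD_DX_CODES,
                                          oat_drug_codes = .OAT_CODES),
                             min_visits = 3L) {
  if (length(codes$sud_diagnostic_codes) == 0L ||
      length(codes$oat_drug_codes) == 0L)
    stop("code sets must be non-empty", call. = FALSE)

  empty <- data.frame(client_id = character(0), date = as.Date(character(0)),
                      pathway = character(0), stringsAsFactors = FALSE)
  cand <- list(empty)

  if (!is.null(dispensations) && nrow(dispensations) > 0L) {
    oat <- dispensations[dispensations$drug_code %in% codes$oat_drug_codes, ]
    if (nrow(oat) > 0L) {
      d <- tapply(as.Date(oat$date), oat$client_id, min)
      cand <- c(cand, list(data.frame(
        client_id = names(d), date = as.Date(d, origin = "1970-01-01"),
        pathway = "OAT receipt", stringsAsFactors = FALSE)))
    }
  }
  if (!is.null(visits) && nrow(visits) > 0L) {
    sv <- visits[visits$diag_code %in% codes$sud_diagnostic_codes,
                 c("client_id", "date")]
    sv <- unique(data.frame(client_id = sv$client_id, date = as.Date(sv$date),
                            stringsAsFactors = FALSE))
    if (nrow(sv) > 0L) {
      sv <- sv[order(sv$client_id, sv$date), ]
      kth <- function(d) if (length(d) >= min_visits) d[min_visits] else NA
      d <- tapply(sv$date, sv$client_id, kth)
      d <- d[!is.na(d)]
      if (length(d) > 0L)
        cand <- c(cand, list(data.frame(
          client_id = names(d), date = as.Date(d, origin = "1970-01-01"),
          pathway = "visit-count rule", stringsAsFactors = FALSE)))
    }
  }
  if (!is.null(acute_visits) && nrow(acute_visits) > 0L) {
    sa <- acute_visits[acute_visits$diag_code %in% codes$sud_diagnostic_codes, ]
    if (nrow(sa) > 0L) {
      d <- tapply(as.Date(sa$date), sa$client_id, min)
      cand <- c(cand, list(data.frame(
        client_id = names(d), date = as.Date(d, origin = "1970-01-01"),
        pathway = "acute-care rule", stringsAsFactors = FALSE)))
    }
  }
  if (!is.null(perinatal) && nrow(perinatal) > 0L) {
    pn <- perinatal[isTRUE_vec(perinatal$sud_flag), ]
    if (nrow(pn) > 0L) {
      d <- tapply(as.Date(pn$date), pn$client_id, min)
      cand <- c(cand, list(data.frame(
        client_id = names(d), date = as.Date(d, origin = "1970-01-01"),
        pathway = "perinatal record", stringsAsFactors = FALSE)))
    }
  }

  all <- do.call(rbind, cand)
  if (nrow(all) == 0L)
    return(data.frame(client_id = character(0), sud_indicated = logical(0),
                      first_indication_date = as.Date(character(0)),
                      pathway = character(0), stringsAsFactors = FALSE))
  # earliest qualifying date wins; ties broken by the pathway order above
  all <- all[order(all$client_id, all$date), ]
  first <- all[!duplicated(all$client_id), ]
  data.frame(client_id = first$client_id, sud_indicated = TRUE,
             first_indication_date = first$date, pathway = first$pathway,
             stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Assemble the eligible prescriber cohort
#'
#' A prescriber enters the cohort iff it has at least one dispensation inside
#' the study window to a client whose first SUD indication date strictly
#' precedes that dispensation ("prior indication"; same-day indications do
#' not qualify). Attachment is any medication dispensation record between the
#' prescriber and the client.
#'
#' @param dispensations data.frame with \code{prescriber_id},
#'   \code{client_id}, \code{date}.
#' @param sud_flags output of \code{\link{flag_sud_clients}}.
#' @param study_window length-2 Date vector (start, end); default the PSS
#'   study window 2020-03-27 to 2021-08-31.
#' @return sorted character vector of cohort prescriber ids, with the
#'   qualifying prescriber-client attachment table in attribute
#'   \code{"attachments"}.
#' @export
build_prescriber_cohort <- function(dispensations, sud_flags,
                                    study_window = as.Date(c("2020-03-27",
                                                             "2021-08-31"))) {
  study_window <- as.Date(study_window)
  if (study_window[2L] < study_window[1L])
    stop("study window end precedes its start", call. = FALSE)
  d <- dispensations
  dd <- as.Date(d$date)
  keep <- dd >= study_window[1L] & dd <= study_window[2L]
  d <- d[keep, ]
  ind <- sud_flags$first_indication_date[match(d$client_id, sud_flags$client_id)]
  qual <- !is.na(ind) & ind < as.Date(d$date)
  q <- unique(d[qual, c("prescriber_id", "client_id")])
  q <- q[order(q$prescriber_id, q$client_id), ]
  rownames(q) <- NULL
  structure(sort(unique(q$prescriber_id)), attachments = q)
}
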