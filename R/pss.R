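# Keyword-based PSS case-finding over the free-text "directions for use"
# field, and adoption timing/status derivation.

#' Load the PSS keyword configuration
#'
#' The case-finding algorithm has no dedicated drug identification numbers to
#' key on, so PSS dispensations are recognized by case-insensitive keyword
#' matches over the prescriber-entered directions-for-use text, restricted to
#' an eligible medication-class set. Two tiers exist: a \emph{sensitive}
#' algorithm (broad keyword list, the primary analysis choice) and a
#' \emph{specific} one whose keyword list and class set must be subsets of the
#' sensitive tier, guaranteeing that every specific-algorithm PSS record is
#' also a sensitive-algorithm PSS record.
#'
#' The packaged default lexicon is an illustrative, editable stand-in (the
#' provincial lists are not public); all downstream results are parameterized
#' by this file.
#'
#' @param path YAML file with \code{sensitive}/\code{specific} blocks, each
#'   holding \code{patterns} and \code{classes}.
#' @return list of two algorithm configs.
#' @export
load_keyword_config <- function(path = system.file("extdata",
                                                   "pss_keywords.yaml",
                                                   package = "pssnet")) {
  raw <- yaml::read_yaml(path)
  for (alg in c("sensitive", "specific")) {
    if (is.null(raw[[alg]]$patterns) || length(raw[[alg]]$patterns) == 0L)
      stop("keyword config lacks patterns for algorithm '", alg, "'",
           call. = FALSE)
    raw[[alg]]$patterns <- tolower(as.character(unlist(raw[[alg]]$patterns)))
    raw[[alg]]$classes <- as.character(unlist(raw[[alg]]$classes))
  }
  if (!all(raw$specific$patterns %in% raw$sensitive$patterns) ||
      !all(raw$specific$classes %in% raw$sensitive$classes))
    stop("specific algorithm must be a subset of the sensitive algorithm",
         call. = FALSE)
  raw[c("sensitive", "specific")]
}

#' Classify dispensations as PSS
#'
#' A record is PSS iff its medication class is in the algorithm's eligible
#' set AND its directions text contains at least one configured keyword
#' (case-insensitive substring match). Records with missing/empty directions
#' are classified not-PSS and counted in the \code{"n_null_directions"}
#' attribute rather than raising an error. The classification is
#' deterministic and independent of row order.
#'
#' @param dispensations data.frame with \code{drug_code}, \code{directions}
#'   and (if \code{drug_class_map} is NULL) \code{med_class}.
#' @param keywords keyword configuration from
#'   \code{\link{load_keyword_config}}.
#' @param algorithm \code{"sensitive"} (default, the primary analysis) or
#'   \code{"specific"}.
#' @param drug_class_map optional data.frame \code{drug_code},
#'   \code{med_class} overriding any class column on the input.
#' @return the input data.frame with columns \code{is_pss} (logical),
#'   \code{med_class} and \code{algorithm} appended; attribute
#'   \code{"n_null_directions"} tallies blank-directions records.
#' @export
classify_dispensations <- function(dispensations,
                                   keywords = load_keyword_config(),
                                   algorithm = c("sensitive", "specific"),
                                   drug_class_map = NULL) {
  algorithm <- match.arg(algorithm)
  cfg <- keywords[[algorithm]]
  d <- dispensations
  if (!is.null(drug_class_map)) {
    d$med_class <- drug_class_map$med_class[match(d$drug_code,
                                                  drug_class_map$drug_code)]
    d$med_class[is.na(d$med_class)] <- "other"
  } else if (is.null(d$med_class)) {
    stop("no med_class column and no drug_class_map supplied", call. = FALSE)
  }
  txt <- d$directions
  blank <- is.na(txt) | !nzchar(trimws(txt))
  txt_l <- tolower(ifelse(blank, "", txt))
  hit <- rep(FALSE, nrow(d))
  for (p in cfg$patterns) hit <- hit | grepl(p, txt_l, fixed = TRUE)
  d$is_pss <- !blank & hit & d$med_class %in% cfg$classes
  d$algorithm <- algorithm
  attr(d, "n_null_directions") <- sum(blank)
  d
}

#' Derive prescriber adoption timing and diffusion status
#'
#' The first PSS month of each prescriber is the study month of its earliest
#' PSS-classified dispensation. Status follows the diffusion-of-innovation
#' partition: \code{innovator} if the first PSS month falls in the innovation
#' window (default months 1-2, i.e. March 27 to April 30, 2020),
#' \code{early adopter} if later, \code{non-adopter} if the prescriber never
#' had a PSS dispensation.
#'
#' @param classified dispensations with an \code{is_pss} column (see
#'   \code{\link{classify_dispensations}}).
#' @param cohort character vector of cohort prescriber ids (the partition is
#'   over these).
#' @param innovation_months integer months forming the innovation window;
#'   lengthen (e.g. \code{1:4} for a July 2020 start of follow-up) for the
#'   longer-innovation-period sensitivity analysis.
#' @param origin,scheme month binning, see \code{\link{month_index}}.
#' @return data.frame \code{prescriber_id}, \code{first_pss_month} (integer
#'   or NA), \code{status} (factor innovator/early adopter/non-adopter).
#' @export
derive_adoption <- function(classified, cohort, innovation_months = 1:2,
                            origin = "2020-03", scheme = "calendar") {
  p <- classified[isTRUE_vec(classified$is_pss) &
                    classified$prescriber_id %in% cohort, ]
  first <- if (nrow(p) > 0L) {
    m <- month_index(p$date, origin, scheme)
    tapply(m, p$prescriber_id, min)
  } else {
    integer(0)
  }
  ids <- sort(unique(as.character(cohort)))
  fm <- as.integer(first[match(ids, names(first))])
  status <- ifelse(is.na(fm), "non-adopter",
                   ifelse(fm <= max(innovation_months), "innovator",
                          "early adopter"))
  data.frame(prescriber_id = ids, first_pss_month = fm,
             status = factor(status, levels = c("innovator", "early adopter",
                                                "non-adopter")),
             stringsAsFactors = FALSE)
}
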