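# Descriptive outputs: stratified characteristics table with small-cell
# suppression, the monthly active-prescriber series, and display-pruned edge
# lists.

#' Round half-up
#'
#' Deterministic half-up rounding (0.05 -> 0.1 at one digit), the convention
#' used for every printed percentage and median in the reports; base R's
#' banker's rounding would make reports depend on the parity of digits.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Format a count with its percentage of a total
#'
#' Percentages are half-up rounded to one decimal place, e.g.
#' \code{"228 (1.6\%)"}.
#'
#' @param count,total numeric.
#' @return character vector.
#' @export
fmt_count_pct <- function(count, total) {
  sprintf("%d (%.1f%%)", as.integer(count),
          round_half_up(100 * count / total, 1L))
}

.SUPPRESS_TOKEN <- "< 10"
.SUPPRESS_MIN <- 10L

#' Stratified prescriber characteristics table
#'
#' Summarizes prescriber characteristics by adoption status (innovator /
#' early adopter / non-adopter), each prescriber measured at its PSS
#' initiation month (adopters) or at the final study month (non-adopters).
#' Categorical variables are reported as count (percent), continuous ones as
#' median with 1st--3rd quartile bounds; no test statistics are produced.
#'
#' Privacy-style suppression: any categorical cell with a count below 10 is
#' rendered as \code{"< 10"}; if exactly one cell of a variable within a
#' stratum is suppressed, the next-smallest cell is suppressed as well so the
#' hidden count cannot be recovered from the stratum total (secondary
#' suppression). Strata with fewer than 10 prescribers have their continuous
#' summaries suppressed too. Suppression is applied after all aggregation and
#' is idempotent.
#'
#' @param study a \code{\link{pss_study}} object.
#' @return data.frame (class \code{"pss_table_one"}) in long form: columns
#'   \code{variable}, \code{level}, \code{stratum}, \code{type},
#'   \code{count}, \code{percent}, \code{median}, \code{q1}, \code{q3},
#'   \code{suppressed}, \code{display}.
#' @export
table_one <- function(study) {
  cfg <- study$config
  adopt <- study$adoption
  meas_month <- ifelse(is.na(adopt$first_pss_month), cfg$n_months,
                       adopt$first_pss_month)
  met <- do.call(rbind, study$metrics)
  expo <- do.call(rbind, study$exposure)
  cmx <- do.call(rbind, study$case_mix)
  key <- paste(adopt$prescriber_id, meas_month)
  mi <- match(key, paste(met$prescriber_id, met$month))
  ei <- match(key, paste(expo$prescriber_id, expo$month))
  xi <- match(key, paste(cmx$prescriber_id, cmx$month))
  pr <- study$data$prescribers
  pi <- match(adopt$prescriber_id, pr$prescriber_id)

  nm_end <- month_end_date(cfg$n_months, cfg$origin)
  disc <- vapply(adopt$prescriber_id, function(id) {
    pm <- study$pss_months[[id]]
    if (is.null(pm)) return(NA)
    !is.na(discontinuation_month(pm, cfg$n_months, cfg$gap))
  }, logical(1L))

  tab <- data.frame(
    stratum = as.character(adopt$status),
    region = pr$region[pi],
    specialty = pr$specialty[pi],
    oat_history = ifelse(pr$oat_history[pi], "yes", "no"),
    discontinued = ifelse(is.na(disc), NA, ifelse(disc, "yes", "no")),
    degree = met$degree[mi],
    strength = met$strength[mi],
    exposure = expo$exposure[ei],
    clustering = met$clustering[mi],
    adjusted_strength = met$adjusted_strength[mi],
    degree_centrality = met$degree_centrality[mi],
    experience_years = as.numeric(
      month_end_date(meas_month, cfg$origin) -
        pr$first_sud_billing_date[pi]) / 365.25,
    caseload = cmx$caseload[xi],
    pct_age40 = cmx$pct_age40[xi],
    pct_cci_gt1 = cmx$pct_cci_gt1[xi],
    pct_benzo = cmx$pct_benzo[xi],
    pct_social_assistance = cmx$pct_social_assistance[xi],
    pct_overdose_12m = cmx$pct_overdose_12m[xi],
    stringsAsFactors = FALSE)

  cat_vars <- c("region", "specialty", "oat_history", "discontinued")
  cont_vars <- setdiff(names(tab), c("stratum", cat_vars))
  strata <- c("innovator", "early adopter", "non-adopter")
  rows <- list()
  for (st in strata) {
    sub <- tab[tab$stratum == st, ]
    n_st <- nrow(sub)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "n", level = "", stratum = st, type = "count",
      count = n_st, percent = NA_real_, median = NA_real_, q1 = NA_real_,
      q3 = NA_real_, stringsAsFactors = FALSE)
    for (v in cat_vars) {
      x <- sub[[v]]
      x <- x[!is.na(x)]
      if (length(x) == 0L) next
      cnt <- table(x)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = names(cnt), stratum = st, type = "categorical",
        count = as.integer(cnt),
        percent = round_half_up(100 * as.integer(cnt) / length(x), 1L),
        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
        stringsAsFactors = FALSE)
    }
    for (v in cont_vars) {
      x <- sub[[v]]
      qs <- if (n_st > 0L) stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
      else rep(NA_real_, 3L)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "", stratum = st, type = "continuous",
        count = n_st, percent = NA_real_,
        median = round_half_up(qs[2L], 1L), q1 = round_half_up(qs[1L], 1L),
        q3 = round_half_up(qs[3L], 1L), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$suppressed <- FALSE
  # primary suppression
  small <- out$type == "categorical" & out$count < .SUPPRESS_MIN
  out$suppressed[small] <- TRUE
  # continuous summaries of tiny strata
  tiny <- out$type == "continuous" & out$count < .SUPPRESS_MIN
  out$suppressed[tiny] <- TRUE
  # secondary suppression within variable x stratum blocks
  for (st in strata) for (v in cat_vars) {
    sel <- which(out$stratum == st & out$variable == v)
    if (length(sel) < 2L) next
    supp <- out$suppressed[sel]
    if (sum(supp) == 1L) {
      rest <- sel[!supp]
      out$suppressed[rest[which.min(out$count[rest])]] <- TRUE
    }
  }
  out$display <- ifelse(
    out$suppressed, .SUPPRESS_TOKEN,
    ifelse(out$type == "categorical",
           sprintf("%d (%.1f%%)", out$count, out$percent),
           ifelse(out$type == "continuous",
                  sprintf("%.1f (%.1f-%.1f)", out$median, out$q1, out$q3),
                  sprintf("%d", out$count))))
  class(out) <- c("pss_table_one", "data.frame")
  out
}

#' Render a stratified table as markdown
#'
#' @param x a \code{\link{table_one}} result.
#' @return character vector of markdown lines.
#' @export
format_table_one <- function(x) {
  strata <- unique(x$stratum)
  keys <- unique(paste(x$variable, x$level, sep = "\r"))
  header <- paste0("| variable | level | ", paste(strata, collapse = " | "),
                   " |")
  sep <- paste0("|", paste(rep("---|", length(strata) + 2L), collapse = ""))
  body <- vapply(keys, function(k) {
    vl <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    lev <- if (length(vl) > 1L) vl[2L] else ""
    cells <- vapply(strata, function(st) {
      r <- x[x$stratum == st & x$variable == vl[1L] &
               (x$level == lev | (lev == "" & x$level == "")), ]
      if (nrow(r) == 0L) "" else r$display[1L]
    }, character(1L))
    paste0("| ", vl[1L], " | ", lev, " | ", paste(cells, collapse = " | "),
           " |")
  }, character(1L))
  c(header, sep, unname(body))
}

#' Monthly active PSS prescriber series
#'
#' For each study month: the number of prescribers with at least one PSS
#' dispensation that month (active), the cumulative number that had initiated
#' by the month's end, and the lapsed count (cumulative minus active).
#'
#' @param classified dispensations with \code{is_pss} (see
#'   \code{\link{classify_dispensations}}).
#' @param cohort cohort prescriber ids.
#' @param n_months study length.
#' @param origin,scheme month binning.
#' @return data.frame \code{month}, \code{active}, \code{cumulative},
#'   \code{lapsed}.
#' @export
monthly_active_series <- function(classified, cohort, n_months = 18L,
                                  origin = "2020-03", scheme = "calendar") {
  p <- classified[isTRUE_vec(classified$is_pss) &
                    classified$prescriber_id %in% cohort, ]
  m <- month_index(p$date, origin, scheme)
  keep <- m >= 1L & m <= n_months
  p <- p[keep, ]; m <- m[keep]
  active <- vapply(seq_len(n_months), function(t)
    length(unique(p$prescriber_id[m == t])), integer(1L))
  first <- tapply(m, p$prescriber_id, min)
  cumulative <- vapply(seq_len(n_months), function(t)
    sum(first <= t), integer(1L))
  data.frame(month = seq_len(n_months), active = active,
             cumulative = cumulative, lapsed = cumulative - active)
}

#' Prune a network to mutually top-quantile edges
#'
#' Retains an edge iff its weight ranks within the top \code{q} of incident
#' edge weights for \emph{both} endpoints, with ties at the quantile boundary
#' retained: an edge survives at a node when fewer than
#' \code{ceiling(q * degree)} incident edges are strictly heavier. Used for
#' display-scale network drawings only.
#'
#' @param snapshot a \code{\link{build_monthly_network}} result.
#' @param q retained weight quantile (default 0.20).
#' @return edge-list data.frame \code{a}, \code{b}, \code{weight},
#'   \code{month}.
#' @export
prune_edges_top_quantile <- function(snapshot, q = 0.20) {
  ed <- snapshot$edges
  if (nrow(ed) == 0L)
    return(data.frame(a = character(0), b = character(0), weight = integer(0),
                      month = integer(0)))
  inc <- rbind(data.frame(node = ed$a, w = ed$weight, e = seq_len(nrow(ed))),
               data.frame(node = ed$b, w = ed$weight, e = seq_len(nrow(ed))))
  keep_at_node <- function(d) {
    lim <- ceiling(q * nrow(d))
    vapply(seq_len(nrow(d)), function(i) sum(d$w > d$w[i]) < lim, logical(1L))
  }
  ok <- unsplit(lapply(split(inc, inc$node), keep_at_node), inc$node)
  both <- tapply(ok, inc$e, all)
  out <- ed[as.logical(both[as.character(seq_len(nrow(ed)))]), ]
  out$month <- snapshot$month
  rownames(out) <- NULL
  out
}
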