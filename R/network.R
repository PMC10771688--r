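# Monthly patient-sharing networks among cohort prescribers, per-node network
# covariates, and the lagged peer-exposure measures.

#' Build the patient-sharing network for one measurement month
#'
#' Restricts dispensation records to the accumulation window ending with the
#' measurement month, keeps prescribers in the cohort, and projects the
#' bipartite prescriber-client record set onto prescribers: an edge joins two
#' prescribers iff at least one client received dispensations from both within
#' the window, weighted by the number of distinct shared clients.
#'
#' The default window is cumulative from the study start through the end of
#' the measurement month, reflecting exposure over a stable professional
#' network that is "updated monthly"; a trailing window of \code{k} months is
#' available as a variant.
#'
#' @param dispensations data.frame with at least \code{client_id},
#'   \code{prescriber_id}, \code{date}.
#' @param cohort character vector of cohort prescriber ids; these are the
#'   network's node set (isolates included).
#' @param month measurement month index (records after its end are ignored).
#' @param window \code{"cumulative"} (from month 1) or \code{"trailing"}.
#' @param k trailing window length in months (used when
#'   \code{window = "trailing"}).
#' @param origin,scheme month binning, see \code{\link{month_index}}.
#' @return object of class \code{"pss_network"}: list with \code{month},
#'   \code{nodes} (sorted ids), \code{edges} (data.frame \code{a}, \code{b},
#'   \code{weight} with \code{a < b}), \code{pairs} (distinct in-window
#'   prescriber-client pairs, used for adjusted strength), and
#'   \code{accumulation_window} (description).
#' @export
#' @examples
#' d <- data.frame(client_id = c("c1", "c1"), prescriber_id = c("p1", "p2"),
#'                 date = as.Date("2020-04-10"))
#' net <- build_monthly_network(d, c("p1", "p2"), month = 2)
#' net$edges
build_monthly_network <- function(dispensations, cohort, month,
                                  window = c("cumulative", "trailing"),
                                  k = NULL, origin = "2020-03",
                                  scheme = "calendar") {
  window <- match.arg(window)
  m_rec <- month_index(dispensations$date, origin, scheme)
  lo <- if (window == "cumulative") 1L else {
    if (is.null(k) || k < 1L) stop("trailing window needs k >= 1", call. = FALSE)
    month - as.integer(k) + 1L
  }
  keep <- m_rec >= lo & m_rec <= month &
    dispensations$prescriber_id %in% cohort
  nodes <- sort(unique(as.character(cohort)))
  sub <- dispensations[keep, c("prescriber_id", "client_id")]
  desc <- if (window == "cumulative")
    sprintf("months 1..%d (cumulative)", month)
  else sprintf("months %d..%d (trailing %d)", lo, month, as.integer(k))
  key <- paste(sub$prescriber_id, sub$client_id, sep = "\r")
  snapshot_from_pairs(sub[!duplicated(key), ], month, nodes, desc)
}

# Project a distinct prescriber-client pair set onto the prescriber graph.
snapshot_from_pairs <- function(pairs, month, nodes, desc) {
  if (nrow(pairs) == 0L) {
    return(structure(list(
      month = as.integer(month), nodes = nodes,
      edges = data.frame(a = character(0), b = character(0),
                         weight = integer(0), stringsAsFactors = FALSE),
      pairs = data.frame(prescriber_id = character(0),
                         client_id = character(0), stringsAsFactors = FALSE),
      accumulation_window = desc), class = "pss_network"))
  }
  pi <- match(pairs$prescriber_id, nodes)
  cl <- unique(pairs$client_id)
  ci <- match(pairs$client_id, cl)
  B <- Matrix::sparseMatrix(i = pi, j = ci, x = 1,
                            dims = c(length(nodes), length(cl)))
  W <- Matrix::tcrossprod(B)
  Wt <- Matrix::triu(W, k = 1)
  idx <- Matrix::summary(Wt)
  keep <- idx$x > 0
  o <- order(idx$i[keep], idx$j[keep])
  edges <- data.frame(a = nodes[idx$i[keep]][o], b = nodes[idx$j[keep]][o],
                      weight = as.integer(idx$x[keep])[o],
                      stringsAsFactors = FALSE)
  pairs <- pairs[, c("prescriber_id", "client_id")]
  rownames(pairs) <- NULL
  structure(list(month = as.integer(month), nodes = nodes, edges = edges,
                 pairs = pairs, accumulation_window = desc),
            class = "pss_network")
}

#' @export
print.pss_network <- function(x, ...) {
  cat(sprintf("<pss_network> month %d: %d nodes, %d edges (%s)\n",
              x$month, length(x$nodes), nrow(x$edges), x$accumulation_window))
  invisible(x)
}

snapshot_graph <- function(snapshot) {
  igraph::graph_from_data_frame(
    snapshot$edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = snapshot$nodes))
}

#' Per-node network covariates for one snapshot
#'
#' Computes, for every cohort node: degree (number of connected prescribers),
#' total edge weight (sum of shared-client counts), the local clustering
#' coefficient (proportion of neighbour pairs that are themselves connected;
#' 0 when degree < 2), degree centrality (degree divided by the number of
#' other nodes), and adjusted strength -- the mean, over the prescriber's
#' in-window clients, of the number of *other* prescribers each client
#' received dispensations from. Adjusted strength is computed from the
#' client-attachment records carried by the snapshot, not from the projected
#' graph, because it is defined client-wise.
#'
#' @param snapshot a \code{\link{build_monthly_network}} result.
#' @return data.frame with one row per node: \code{prescriber_id},
#'   \code{month}, \code{degree}, \code{strength}, \code{clustering},
#'   \code{degree_centrality}, \code{adjusted_strength}.
#' @export
node_metrics <- function(snapshot) {
  nodes <- snapshot$nodes
  g <- snapshot_graph(snapshot)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2L] <- 0
  strength <- stats::setNames(rep(0L, length(nodes)), nodes)
  if (nrow(snapshot$edges) > 0L) {
    s <- tapply(c(snapshot$edges$weight, snapshot$edges$weight),
                c(snapshot$edges$a, snapshot$edges$b), sum)
    strength[names(s)] <- as.integer(s)
  }
  adj <- stats::setNames(rep(0, length(nodes)), nodes)
  if (nrow(snapshot$pairs) > 0L) {
    per_client <- table(snapshot$pairs$client_id)
    extra <- as.numeric(per_client[snapshot$pairs$client_id]) - 1
    m <- tapply(extra, snapshot$pairs$prescriber_id, mean)
    adj[names(m)] <- as.numeric(m)
  }
  nn <- length(nodes)
  data.frame(
    prescriber_id = nodes,
    month = snapshot$month,
    degree = as.integer(deg[nodes]),
    strength = as.integer(strength[nodes]),
    clustering = as.numeric(cc[match(nodes, igraph::V(g)$name)]),
    degree_centrality = if (nn > 1L) as.numeric(deg[nodes]) / (nn - 1L) else 0,
    adjusted_strength = as.numeric(adj[nodes]),
    stringsAsFactors = FALSE
  )
}

#' Lagged peer exposure to PSS prescribing
#'
#' The proportion of a prescriber's network that had previously prescribed
#' PSS. \code{adopters} must contain every prescriber with at least one PSS
#' dispensation in any month up to and including the snapshot month (i.e. the
#' caller passes the adopter set through month m-1 when scoring month m).
#'
#' Variants: \code{"unweighted"} (default) is the share of connected
#' prescribers that are adopters, 0 for isolates; \code{"weighted"} is the
#' share of total edge weight attached to adopter peers; \code{"two_degree"}
#' is the adopter share of the neighbourhood within two steps (peers and
#' peers-of-peers, excluding the node itself).
#'
#' @param snapshot a \code{\link{build_monthly_network}} result.
#' @param adopters character vector of adopter prescriber ids.
#' @param variant exposure variant.
#' @return named numeric vector in \code{[0, 1]} over the snapshot nodes.
#' @export
peer_exposure <- function(snapshot, adopters,
                          variant = c("unweighted", "weighted", "two_degree")) {
  variant <- match.arg(variant)
  nodes <- snapshot$nodes
  nn <- length(nodes)
  ed <- snapshot$edges
  out <- stats::setNames(rep(0, nn), nodes)
  if (nrow(ed) == 0L) return(out)
  ia <- match(ed$a, nodes); ib <- match(ed$b, nodes)
  A <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                            x = rep(as.numeric(ed$weight), 2L),
                            dims = c(nn, nn))
  isad <- as.numeric(nodes %in% adopters)
  if (variant == "unweighted") {
    Ab <- A
    Ab@x <- rep(1, length(Ab@x))
    deg <- Matrix::rowSums(Ab)
    na <- as.numeric(Ab %*% isad)
    out[] <- ifelse(deg > 0, na / deg, 0)
  } else if (variant == "weighted") {
    tot <- Matrix::rowSums(A)
    wa <- as.numeric(A %*% isad)
    out[] <- ifelse(tot > 0, wa / tot, 0)
  } else {
    Ab <- A
    Ab@x <- rep(1, length(Ab@x))
    reach <- (Ab + Ab %*% Ab) > 0
    Matrix::diag(reach) <- FALSE
    nsize <- Matrix::rowSums(reach)
    na <- as.numeric(reach %*% isad)
    out[] <- ifelse(nsize > 0, na / nsize, 0)
  }
  out
}

#' Categorize a peer-exposure proportion
#'
#' Fixed cut points follow the published categories: \code{none} (exactly 0,
#' including isolates), \code{le10} (0 < e <= 0.10, "10% or less"),
#' \code{gt10_20} (0.10 < e <= 0.20), and \code{gt20} (e > 0.20, the 3rd
#' quartile threshold of the empirical exposure distribution). Boundaries are
#' closed on the right, matching the printed labels.
#'
#' @param exposure numeric vector in \code{[0, 1]}.
#' @return factor with levels \code{none}, \code{le10}, \code{gt10_20},
#'   \code{gt20}.
#' @export
#' @examples
#' categorize_exposure(c(0, 0.1, 0.15, 0.21))
categorize_exposure <- function(exposure) {
  if (any(is.na(exposure)) || any(exposure < 0 | exposure > 1))
    stop("exposure must lie in [0, 1]", call. = FALSE)
  lv <- c("none", "le10", "gt10_20", "gt20")
  out <- ifelse(exposure == 0, "none",
                ifelse(exposure <= 0.10, "le10",
                       ifelse(exposure <= 0.20, "gt10_20", "gt20")))
  factor(out, levels = lv)
}
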