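# Brute-force reference implementations, kept deliberately naive and
# independent of the package's sparse-matrix / igraph code paths.

# weighted projection by double loop over prescriber pairs
oracle_projection <- function(pairs, nodes) {
  by_p <- lapply(stats::setNames(nodes, nodes), function(p)
    unique(pairs$client_id[pairs$prescriber_id == p]))
  out <- list()
  for (i in seq_along(nodes)) for (j in seq_len(i - 1L)) {
    w <- length(intersect(by_p[[nodes[i]]], by_p[[nodes[j]]]))
    if (w > 0L)
      out[[length(out) + 1L]] <- data.frame(
        a = min(nodes[i], nodes[j]), b = max(nodes[i], nodes[j]),
        weight = w, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(a = character(0), b = character(0),
                      weight = integer(0)))
  e <- do.call(rbind, out)
  e[order(e$a, e$b), ]
}

oracle_neighbors <- function(edges, node) {
  unique(c(edges$b[edges$a == node], edges$a[edges$b == node]))
}

# local clustering by explicit triangle counting
oracle_clustering <- function(edges, nodes) {
  has_edge <- function(x, y) any((edges$a == x & edges$b == y) |
                                   (edges$a == y & edges$b == x))
  vapply(nodes, function(v) {
    nb <- oracle_neighbors(edges, v)
    d <- length(nb)
    if (d < 2L) return(0)
    tri <- 0L
    for (i in seq_along(nb)) for (j in seq_len(i - 1L))
      if (has_edge(nb[i], nb[j])) tri <- tri + 1L
    tri / (d * (d - 1L) / 2)
  }, numeric(1L))
}

oracle_exposure <- function(edges, nodes, adopters,
                            variant = "unweighted") {
  vapply(nodes, function(v) {
    nb <- oracle_neighbors(edges, v)
    if (variant == "unweighted") {
      if (length(nb) == 0L) return(0)
      mean(nb %in% adopters)
    } else if (variant == "weighted") {
      if (length(nb) == 0L) return(0)
      wts <- vapply(nb, function(u) {
        edges$weight[(edges$a == v & edges$b == u) |
                       (edges$a == u & edges$b == v)][1L]
      }, numeric(1L))
      sum(wts[nb %in% adopters]) / sum(wts)
    } else {
      two <- unique(unlist(lapply(nb, oracle_neighbors, edges = edges)))
      reach <- setdiff(unique(c(nb, two)), v)
      if (length(reach) == 0L) return(0)
      mean(reach %in% adopters)
    }
  }, numeric(1L))
}

# mean over a prescriber's clients of the other prescribers each client saw
oracle_adjusted_strength <- function(pairs, nodes) {
  vapply(nodes, function(p) {
    cls <- unique(pairs$client_id[pairs$prescriber_id == p])
    if (length(cls) == 0L) return(0)
    mean(vapply(cls, function(cl)
      length(unique(pairs$prescriber_id[pairs$client_id == cl])) - 1L,
      numeric(1L)))
  }, numeric(1L))
}

# per-node top-q ranking with boundary ties retained
oracle_prune <- function(edges, q = 0.2) {
  keep_at <- function(v, w) {
    inc <- edges$weight[edges$a == v | edges$b == v]
    sum(inc > w) < ceiling(q * length(inc))
  }
  keep <- vapply(seq_len(nrow(edges)), function(i)
    keep_at(edges$a[i], edges$weight[i]) &&
      keep_at(edges$b[i], edges$weight[i]), logical(1L))
  edges[keep, ]
}

# run-scanning reimplementation of the gap rule
oracle_discontinuation <- function(pss_months, n_months, gap = 3L) {
  first <- min(pss_months)
  for (m in seq.int(first + 1L, n_months)) {
    if (m + gap - 1L > n_months) return(NA_integer_)
    if (!any(pss_months %in% m:(m + gap - 1L))) return(m)
  }
  NA_integer_
}

# random bipartite affiliation rendered as month-1 dispensations
random_affiliation <- function(n_p = 20L, n_c = 40L, p_attach = 0.08,
                               seed = 1L) {
  set.seed(seed)
  nodes <- sprintf("p%03d", seq_len(n_p))
  clients <- sprintf("c%03d", seq_len(n_c))
  idx <- which(matrix(runif(n_p * n_c) < p_attach, n_p, n_c), arr.ind = TRUE)
  data.frame(prescriber_id = nodes[idx[, 1L]], client_id = clients[idx[, 2L]],
             date = as.Date("2020-03-28") + sample(0:3, nrow(idx), TRUE),
             stringsAsFactors = FALSE)
}

# one small simulated study shared across test files (built once per run)
tiny_sim <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- simulate_pss_study(sim_config(
        n_prescribers = 70L, n_clients = 300L, n_innovator_seed = 5L,
        adopt_intercept = -4.5, seed = 424L))
    val
  }
})

tiny_study <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- pss_study(tiny_sim()$data)
    val
  }
})
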