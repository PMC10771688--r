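disp1 <- function(pairs) {
  data.frame(prescriber_id = pairs[[1L]], client_id = pairs[[2L]],
             date = rep(as.Date("2020-03-28"), length(pairs[[1L]])),
             stringsAsFactors = FALSE)
}

test_that("one shared client makes one edge of weight one", {
  net <- build_monthly_network(disp1(list(c("p1", "p2"), c("c1", "c1"))),
                               c("p1", "p2"), 1L)
  expect_equal(net$edges,
               data.frame(a = "p1", b = "p2", weight = 1L,
                          stringsAsFactors = FALSE))
})

test_that("three prescribers sharing one client form a unit triangle", {
  net <- build_monthly_network(
    disp1(list(c("p1", "p2", "p3"), rep("c1", 3L))), paste0("p", 1:3), 1L)
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$weight == 1L))
  nm <- node_metrics(net)
  expect_true(all(nm$clustering == 1))
  expect_true(all(nm$degree_centrality == 1))
})

test_that("a star centre has clustering zero", {
  pairs <- list(c("p0", "p1", "p0", "p2", "p0", "p3", "p0", "p4"),
                c("c1", "c1", "c2", "c2", "c3", "c3", "c4", "c4"))
  net <- build_monthly_network(disp1(pairs), paste0("p", 0:4), 1L)
  nm <- node_metrics(net)
  expect_equal(nm$clustering[nm$prescriber_id == "p0"], 0)
  expect_equal(nm$degree[nm$prescriber_id == "p0"], 4L)
})

test_that("edge weights count distinct shared clients, not records", {
  d <- rbind(disp1(list(c("p1", "p2"), c("c1", "c1"))),
             disp1(list(c("p1", "p2"), c("c1", "c1"))),
             disp1(list(c("p1", "p2"), c("c2", "c2"))))
  net <- build_monthly_network(d, c("p1", "p2"), 1L)
  expect_equal(net$edges$weight, 2L)
})

test_that("records after the measurement month are excluded; trailing windows drop old months", {
  d <- disp1(list(c("p1", "p2"), c("c1", "c1")))
  d2 <- d; d2$date <- as.Date("2020-07-10"); d2$client_id <- "c9"
  both <- rbind(d, d2)
  expect_equal(build_monthly_network(both, c("p1", "p2"), 2L)$edges$weight, 1L)
  expect_equal(build_monthly_network(both, c("p1", "p2"), 5L)$edges$weight, 2L)
  tr <- build_monthly_network(both, c("p1", "p2"), 5L, window = "trailing",
                              k = 2L)
  expect_equal(tr$edges$weight, 1L)
  expect_error(build_monthly_network(both, c("p1", "p2"), 5L,
                                     window = "trailing"), "k >= 1")
})

test_that("an empty record set yields an empty graph, not an error", {
  net <- build_monthly_network(disp1(list(character(0), character(0))),
                               c("p1", "p2"), 1L)
  expect_equal(nrow(net$edges), 0L)
  nm <- node_metrics(net)
  expect_equal(nm$degree, c(0L, 0L))
  expect_equal(peer_exposure(net, "p1"), c(p1 = 0, p2 = 0))
})

test_that("exposure ratios follow the printed conventions", {
  # p0 with 5 neighbours, 2 of them adopters -> 0.40
  pairs <- list(rep(c("p0", paste0("p", 1:5)), times = c(5L, rep(1L, 5L))),
                c(paste0("c", 1:5), paste0("c", 1:5)))
  net <- build_monthly_network(disp1(pairs), paste0("p", 0:6), 1L)
  e <- peer_exposure(net, c("p1", "p2"))
  expect_equal(unname(e["p0"]), 0.40)
  expect_equal(unname(e["p6"]), 0)  # isolate
  expect_equal(as.character(categorize_exposure(e["p6"])), "none")
})

test_that("weighted exposure uses edge weights", {
  # p0-p1 weight 3 (adopter), p0-p2 weight 1 -> 0.75
  d <- disp1(list(c("p0", "p1", "p0", "p1", "p0", "p1", "p0", "p2"),
                  c("c1", "c1", "c2", "c2", "c3", "c3", "c4", "c4")))
  net <- build_monthly_network(d, paste0("p", 0:2), 1L)
  e <- peer_exposure(net, "p1", variant = "weighted")
  expect_equal(unname(e["p0"]), 0.75)
  expect_error(peer_exposure(net, "p1", variant = "nope"))
})

test_that("two-degree exposure scores the two-step neighbourhood", {
  # path p1 - p2 - p3; adopter p3
  d <- disp1(list(c("p1", "p2", "p2", "p3"), c("c1", "c1", "c2", "c2")))
  net <- build_monthly_network(d, paste0("p", 1:3), 1L)
  e2 <- peer_exposure(net, "p3", variant = "two_degree")
  expect_equal(unname(e2["p1"]), 0.5)   # reaches p2, p3
  e1 <- peer_exposure(net, "p3")
  expect_equal(unname(e1["p1"]), 0)
})

test_that("exposure category boundaries are closed on the right", {
  expect_equal(as.character(categorize_exposure(c(0, 0.10, 0.1000001, 0.20,
                                                  0.21, 1))),
               c("none", "le10", "gt10_20", "gt10_20", "gt20", "gt20"))
  expect_error(categorize_exposure(1.2), "0, 1")
  expect_error(categorize_exposure(NA_real_), "0, 1")
})

test_that("exposure never decreases when the adopter set grows", {
  for (s in 1:5) {
    d <- random_affiliation(25L, 50L, 0.08, seed = 100L + s)
    nodes <- sprintf("p%03d", 1:25)
    net <- build_monthly_network(d, nodes, 1L)
    ad1 <- sample(nodes, 3L)
    ad2 <- union(ad1, sample(nodes, 4L))
    for (v in c("unweighted", "weighted", "two_degree"))
      expect_true(all(peer_exposure(net, ad2, v) >=
                        peer_exposure(net, ad1, v) - 1e-12))
  }
})

test_that("cumulative edge sets grow monotonically over months", {
  study <- tiny_study()
  key <- function(s) paste(s$edges$a, s$edges$b)
  for (m in 2:study$config$n_months)
    expect_true(all(key(study$snapshots[[m - 1L]]) %in%
                      key(study$snapshots[[m]])))
})

test_that("projection, metrics and exposure match brute force on random graphs", {
  for (s in 1:12) {
    n_p <- sample(8:30, 1L)
    d <- random_affiliation(n_p, sample(10:60, 1L), 0.10, seed = 7000L + s)
    nodes <- sprintf("p%03d", seq_len(n_p))
    net <- build_monthly_network(d, nodes, 1L)
    pairs <- unique(d[, c("prescriber_id", "client_id")])
    exp_edges <- oracle_projection(pairs, nodes)
    expect_equal(net$edges, exp_edges, ignore_attr = TRUE)
    nm <- node_metrics(net)
    expect_equal(nm$clustering, unname(oracle_clustering(net$edges, nodes)))
    expect_equal(nm$degree_centrality, vapply(nodes, function(v)
      length(oracle_neighbors(net$edges, v)) / (n_p - 1L), numeric(1L)),
      ignore_attr = TRUE)
    expect_equal(nm$adjusted_strength,
                 unname(oracle_adjusted_strength(pairs, nodes)))
    adopters <- sample(nodes, max(1L, n_p %/% 4L))
    for (v in c("unweighted", "weighted", "two_degree"))
      expect_equal(unname(peer_exposure(net, adopters, v)),
                   unname(oracle_exposure(net$edges, nodes, adopters, v)))
  }
})
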