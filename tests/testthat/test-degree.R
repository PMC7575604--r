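# Degree tables, distributions and TF ranking.

test_that("degree table counts distinct partners, including self-loops", {
  net <- regnet_from_edges(c("A", "A", "B"), c("g1", "g2", "g1"))
  dt <- degree_table(net)
  expect_equal(dt$node, c("A", "B", "G1", "G2"))
  expect_equal(dt$in_degree, c(0L, 0L, 2L, 1L))
  expect_equal(dt$out_degree, c(2L, 1L, 0L, 0L))

  auto <- degree_table(regnet_from_edges("A", "A"))
  expect_equal(auto$in_degree, 1L)
  expect_equal(auto$out_degree, 1L)
})

test_that("degree table equals a brute-force recount on generated networks", {
  for (seed in c(3, 17)) {
    net <- generate_trn(synthetic_spec(n_tf = 15, n_tg = 150,
                                       seed = seed))$net
    expect_equal(as.data.frame(degree_table(net)), recount_degrees(net))
  }
})

test_that("handshake: in-degrees, out-degrees and interactions balance", {
  for (seed in 1:6) {
    net <- generate_trn(synthetic_spec(n_tf = 10, n_tg = 80, seed = seed))$net
    dt <- degree_table(net)
    expect_equal(sum(dt$in_degree), n_interactions(net))
    expect_equal(sum(dt$out_degree), n_interactions(net))
  }
})

test_that("in-degree distribution honours the unregulated-node exclusion", {
  net <- regnet_from_edges(c("A", "A", "B"), c("g1", "g2", "g1"))
  dt <- degree_table(net)
  with_ex <- in_degree_distribution(dt, exclude_unregulated = TRUE)
  expect_equal(with_ex$degree, c(1L, 2L))
  expect_equal(with_ex$count, c(1L, 1L))
  expect_equal(attr(with_ex, "excluded"), 2L)
  without <- in_degree_distribution(dt, exclude_unregulated = FALSE)
  expect_equal(without$degree, c(0L, 1L, 2L))
  expect_equal(without$count, c(2L, 1L, 1L))
  expect_equal(attr(without, "excluded"), 0L)
  # the two variants differ only in the degree-0 entry
  expect_equal(without[without$degree > 0, ], as.data.frame(with_ex),
               ignore_attr = TRUE)
  # counts account for every non-excluded node
  expect_equal(sum(with_ex$count), nrow(dt) - attr(with_ex, "excluded"))
})

test_that("distribution counts are invariant under node relabeling", {
  net <- generate_trn(synthetic_spec(n_tf = 8, n_tg = 40, seed = 21))$net
  x <- net$interactions
  perm <- withr::with_seed(1, sample(network_nodes(net)))
  names(perm) <- sort(perm)
  relab <- regnet_from_edges(unname(perm[x$tf]), unname(perm[x$target]))
  d1 <- in_degree_distribution(degree_table(net))
  d2 <- in_degree_distribution(degree_table(relab))
  expect_equal(as.data.frame(d1), as.data.frame(d2))
})

test_that("out-degree binning uses half-open bins of the requested width", {
  dt <- data.frame(node = c("A", "B", "C", "g"),
                   in_degree = c(0L, 0L, 0L, 3L),
                   out_degree = c(3L, 250L, 399L, 0L))
  class(dt) <- c("degree_table", "data.frame")
  od <- out_degree_distribution(dt, bin_width = 200)
  expect_equal(od$bin_lo, c(0L, 200L))
  expect_equal(od$count, c(1L, 2L))
  # width 1 carries the same information as the raw TF degrees
  od1 <- out_degree_distribution(dt, bin_width = 1)
  expect_equal(rep(od1$bin_lo, od1$count), sort(c(3L, 250L, 399L)))
  expect_error(out_degree_distribution(dt, bin_width = 0))
  # truncation drops tail bins and reports the excluded TF count
  odt <- out_degree_distribution(dt, bin_width = 200, truncate_at = 200)
  expect_equal(odt$bin_lo, 0L)
  expect_equal(attr(odt, "excluded"), 2L)
})

test_that("realized in-degree mean matches the generator law", {
  spec <- synthetic_spec(n_tf = 150, n_tg = 2000,
                         in_degree_law = list(law = "geometric", p = 0.35),
                         seed = 77)
  net <- generate_trn(spec)$net
  dt <- degree_table(net)
  realized <- dt$in_degree[grepl("^TG", dt$node)]
  mom <- in_degree_law_moments(spec)
  se <- mom$sd / sqrt(spec$n_tg)
  expect_lt(abs(mean(realized) - mom$mean), 3 * se)
})

test_that("power-law out-degrees give a decreasing binned distribution", {
  spec <- synthetic_spec(n_tf = 150, n_tg = 2000,
                         out_degree_law = list(law = "power_law", alpha = 2.0),
                         seed = 99)
  dt <- degree_table(generate_trn(spec)$net)
  od <- out_degree_distribution(dt, bin_width = 200)
  # heavy-tailed samples leave empty bins before isolated outliers, so the
  # decreasing trend is asserted over the occupied bins
  occupied <- od$count[od$count > 0]
  expect_true(all(diff(occupied) <= 0))
  expect_gt(od$count[1] / sum(od$count), 0.5)  # head-heavy
})

test_that("TF ranking includes threshold ties", {
  dt <- data.frame(node = c("A", "B", "C", "D", "g"),
                   in_degree = c(0L, 0L, 0L, 0L, 4L),
                   out_degree = c(10L, 7L, 7L, 1L, 0L))
  class(dt) <- c("degree_table", "data.frame")
  top <- rank_tfs(dt, k = 2, end = "top")
  expect_equal(top$records$node, c("A", "B", "C"))
  expect_equal(top$threshold, 7L)
  bottom <- rank_tfs(dt, k = 1, end = "bottom")
  expect_equal(bottom$records$node, "D")
  all4 <- rank_tfs(dt, k = 4, end = "top")
  expect_equal(nrow(all4$records), 4)
  expect_error(rank_tfs(dt, k = 0), "positive")
  expect_error(rank_tfs(dt, k = 5), "cannot rank")
})

test_that("TF ranking equals sort-and-cut with tie inclusion on random tables", {
  withr::with_seed(42, {
    outd <- sample(0:30, 200, replace = TRUE)
  })
  dt <- data.frame(node = sprintf("T%03d", 1:200),
                   in_degree = rep(0L, 200), out_degree = as.integer(outd))
  class(dt) <- c("degree_table", "data.frame")
  tfs <- dt[dt$out_degree >= 1, ]
  for (end in c("top", "bottom")) {
    res <- rank_tfs(dt, k = 25, end = end)
    sorted <- sort(tfs$out_degree, decreasing = (end == "top"))
    thr <- sorted[25]
    expected <- if (end == "top") tfs$node[tfs$out_degree >= thr]
                else tfs$node[tfs$out_degree <= thr]
    expect_setequal(res$records$node, expected)
    expect_equal(res$threshold, thr)
  }
})
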