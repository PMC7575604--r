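# Data model, I/O, evidence filtering and summary statistics.

test_that("duplicate (tf, target) rows merge annotations", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "tf\ttarget\tevidence\tsign\tconditions\treferences",
    "A\tg1\tbinding\t\t\tR1",
    "A\tg1\texpression\tpositive\tStress\tR2",
    "B\tg2\texpression\tnegative\t\tR3"), path)
  net <- read_network(path)
  expect_equal(n_interactions(net), 2)
  a <- net$interactions[net$interactions$tf == "A", ]
  expect_true(a$has_binding && a$has_expression)
  expect_equal(a$sign, "positive")
  expect_equal(a$references[[1]], c("R1", "R2"))
  expect_equal(a$conditions[[1]], "Stress")
})

test_that("rows without evidence annotation are dropped with a warning", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("tf\ttarget\tevidence", "A\tg1\t"), path)
  expect_warning(net <- read_network(path), "without evidence")
  expect_equal(n_interactions(net), 0)
})

test_that("unknown evidence tokens and malformed rows are rejected", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("tf\ttarget\tevidence", "A\tg1\tchip"), path)
  expect_error(read_network(path), "binding, expression")
  writeLines(c("tf\ttarget\tevidence", "A\tg1\tbinding\textra\tx\ty\tz"), path)
  expect_error(read_network(path), "line 2")
  writeLines(c("tf\ttarget\tevidence", "\tg1\tbinding"), path)
  expect_error(read_network(path), "line 2")
})

test_that("write/read round-trips losslessly and byte-identically", {
  net <- generate_trn(synthetic_spec(n_tf = 8, n_tg = 40, seed = 5))$net
  p1 <- tempfile(); p2 <- tempfile()
  write_network(net, p1)
  back <- read_network(p1, label = net$label)
  expect_true(regnet_equal(net, back))
  write_network(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # empty network -> header-only file
  empty <- regnet(data.frame(tf = character(0), target = character(0),
                             has_binding = logical(0),
                             has_expression = logical(0),
                             sign = character(0)))
  p3 <- tempfile()
  write_network(empty, p3)
  expect_equal(length(readLines(p3)), 1)
})

test_that("sign aggregation follows the all-positive/all-negative/dual rule", {
  cases <- list(
    list(c("positive", "positive"), "positive"),
    list(c("negative", "negative", "negative"), "negative"),
    list(c("positive", "negative"), "dual"),
    list(c("positive", "dual"), "dual"),
    list(c("unknown"), "unknown"),
    list(c("unknown", "positive"), "positive"),
    list(c("unknown", "negative", "unknown"), "negative"))
  for (cs in cases) expect_equal(aggregate_sign(cs[[1]]), cs[[2]])
  expect_error(aggregate_sign(character(0)), "empty")
  expect_error(aggregate_sign("up"), "unknown sign token")
})

test_that("evidence selectors partition correctly and satisfy inclusion-exclusion", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "tf\ttarget\tevidence\tsign",
    "A\tg1\tbinding\t",
    "A\tg1\texpression\tpositive",
    "B\tg2\texpression\tnegative"), path)
  net <- read_network(path)
  be <- filter_by_evidence(net, "B_and_E")
  expect_equal(n_interactions(be), 1)
  expect_equal(be$interactions$tf, "A")
  expect_error(filter_by_evidence(net, "BE"), "selector")

  # B on an all-expression network is empty
  eonly <- regnet_from_edges(c("A", "B"), c("C", "D"), evidence = "expression")
  expect_equal(n_interactions(filter_by_evidence(eonly, "B")), 0)

  # inclusion-exclusion and no-isolated-nodes on generated networks
  for (seed in 1:5) {
    g <- generate_trn(synthetic_spec(n_tf = 10, n_tg = 50, seed = seed))$net
    nB <- n_interactions(filter_by_evidence(g, "B"))
    nE <- n_interactions(filter_by_evidence(g, "E"))
    nBE <- n_interactions(filter_by_evidence(g, "B_and_E"))
    nU <- n_interactions(filter_by_evidence(g, "B_or_E"))
    expect_equal(nB + nE - nBE, nU)
    sub <- filter_by_evidence(g, "B")
    dt <- degree_table(sub)
    expect_true(all(dt$in_degree + dt$out_degree >= 1))
  }
  # holds exactly on the published counts
  expect_equal(45209 + 161747 - 11486, 195470)
})

test_that("condition filtering selects by tag and recomputes node sets", {
  df <- data.frame(tf = c("A", "A", "B", "C", "C"),
                   target = c("g1", "g2", "g1", "g3", "g4"),
                   stringsAsFactors = FALSE)
  df$has_binding <- TRUE; df$has_expression <- FALSE
  df$sign <- "not_applicable"
  df$conditions <- I(list("Stress", character(0), "Stress",
                          "In vitro", character(0)))
  net <- regnet(df)
  st <- filter_by_condition(net, "Stress")
  expect_equal(n_interactions(st), 2)
  expect_setequal(network_nodes(st), c("A", "B", "G1"))
  expect_warning(empty <- filter_by_condition(net, "Biofilm formation"),
                 "matches no interaction")
  expect_equal(n_interactions(empty), 0)
  # a tag carried by every interaction is the identity
  df$conditions <- I(rep(list("Stress"), 5))
  net2 <- regnet(df)
  expect_true(regnet_equal(
    net2, structure(filter_by_condition(net2, "Stress"),
                    label = net2$label)))
})

test_that("summaries reproduce the published density table", {
  pub <- read.delim(published_path("published_network_stats.tsv"))
  for (i in seq_len(nrow(pub))) {
    s <- network_summary(pub$n_nodes[i], pub$n_interactions[i],
                         pub$n_tfs[i], pub$n_tgs[i])
    expect_equal(s$density_pct, pub$density_pct_published[i],
                 info = pub$network[i])
  }
  s <- network_summary(3937, 11486, 152, 3912)
  expect_equal(s$n_possible, 598424)
  # minimal worked example: 1 TF, 1 target, 1 interaction
  tiny <- summarize_network(regnet_from_edges("A", "B"))
  expect_equal(tiny$density_pct, 50.00)
  expect_error(summarize_network(
    regnet(data.frame(tf = character(0), target = character(0),
                      has_binding = logical(0), has_expression = logical(0),
                      sign = character(0)))), "empty")
})

test_that("venn partition reproduces published percentages and sums to 100", {
  # |B| = 45209, |E| = 161747, |B&E| = 11486
  ep <- evidence_partition(161747 - 11486, 45209 - 11486, 11486)
  expect_equal(ep$pct_expression_only, 76.87)
  expect_equal(ep$pct_binding_only, 17.25)
  expect_equal(ep$pct_both, 5.88)
  expect_equal(ep$n_union, 195470)

  allb <- venn_partition(regnet_from_edges(c("A", "B"), c("C", "D")))
  expect_equal(c(allb$pct_expression_only, allb$pct_binding_only,
                 allb$pct_both), c(0, 100, 0))

  for (seed in 1:8) {
    g <- generate_trn(synthetic_spec(n_tf = 10, n_tg = 60, seed = seed))$net
    vp <- venn_partition(g)
    expect_lt(abs(vp$pct_expression_only + vp$pct_binding_only +
                    vp$pct_both - 100), 0.02)
  }
})

test_that("overlap statistics match published values and are symmetric", {
  pub <- read.delim(published_path("published_overlaps.tsv"))
  o1 <- overlap_stats(pub$n_common[1], pub$n_a[1], pub$n_b[1])
  expect_equal(o1$pct_of_a, 84.76)
  o2 <- overlap_stats(pub$n_common[2], pub$n_a[2], pub$n_b[2])
  expect_equal(o2$pct_of_b, 29.24)

  a <- generate_trn(synthetic_spec(n_tf = 8, n_tg = 40, seed = 1))$net
  b <- generate_trn(synthetic_spec(n_tf = 8, n_tg = 40, seed = 2))$net
  expect_equal(network_overlap(a, b)$n_common, network_overlap(b, a)$n_common)
  self <- network_overlap(a, a)
  expect_equal(self$n_common, n_interactions(a))
  expect_equal(c(self$pct_of_a, self$pct_of_b), c(100, 100))
})

test_that("reference support statistics recompute from raw assignments", {
  df <- data.frame(tf = c("A", "B"), target = c("C", "D"),
                   has_binding = TRUE, has_expression = FALSE,
                   sign = "not_applicable", stringsAsFactors = FALSE)
  df$references <- I(list("R1", "R1"))
  one <- regnet(df)
  rs <- reference_support_stats(one)
  expect_equal(rs$mean_references_per_interaction, 1.0)
  expect_equal(unname(rs$per_reference_exclusive["R1"]), 2L)

  g <- generate_trn(synthetic_spec(n_tf = 12, n_tg = 170, seed = 9,
                                   reference_mu = 0.6))
  rs <- reference_support_stats(g$net)
  refs <- g$ledger$references
  expect_equal(rs$mean_references_per_interaction, mean(lengths(refs)))
  tab <- table(unlist(refs))
  expect_equal(rs$mean_interactions_per_reference, mean(as.integer(tab)))
  expect_true(all(rs$per_reference_exclusive <= rs$per_reference_counts))
  expect_equal(sum(rs$per_reference_counts), sum(lengths(refs)))
})

test_that("plain edge lists load with a default evidence class", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("tf\ttarget", "r1\tg1", "r1\tg2", "r2\tg1"), path)
  net <- read_edge_list(path)
  expect_equal(n_interactions(net), 3)
  expect_true(all(net$interactions$has_binding))
  expect_false(any(net$interactions$has_expression))
  # headerless variant parses every line
  writeLines(c("r1\tg1", "r2\tg2"), path)
  expect_equal(n_interactions(read_edge_list(path)), 2)
})
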