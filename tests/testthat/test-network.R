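test_that("build_network restricts vertices to retained edge endpoints", {
  edges <- make_edges(c("a", "b"), c("b", "c"), c("d", "e"))
  edges$source <- c("small_scale", "high_throughput", "high_throughput")
  net <- build_network(edges)
  expect_setequal(net$vertices, c("a", "b", "c", "d", "e"))
  expect_equal(nrow(net$edges), 3)

  ht <- build_network(edges, source_filter = "high_throughput")
  expect_equal(nrow(ht$edges), 2)
  expect_setequal(ht$vertices, c("b", "c", "d", "e"))

  res <- build_network(edges, restrict_to = c("a", "b", "c"))
  expect_setequal(res$vertices, c("a", "b", "c"))

  # random tables: vertex set == endpoints of retained edges
  set.seed(11)
  for (i in 1:5) {
    net <- random_gnp_network(15, 0.15)
    expect_setequal(net$vertices, unique(c(net$edges$gene_a, net$edges$gene_b)))
  }
  expect_warning(build_network(edges[0, , drop = FALSE]), "no edges")
})

test_that("sticky filter: fixed point, hub removal, cascade survivor", {
  # under-threshold graph unchanged
  net <- make_net(c("a", "b"), c("b", "c"))
  same <- filter_sticky(net, threshold = 50)
  expect_equal(same$edges, net$edges, ignore_attr = TRUE)
  expect_length(attr(same, "removal_log"), 0)

  # hub of degree 4 (> 3) among leaves: removed in one round, leaves
  # lose their only edge and drop out
  star <- make_net(c("hub", "l1"), c("hub", "l2"), c("hub", "l3"),
                   c("hub", "l4"))
  f <- filter_sticky(star, threshold = 3)
  expect_equal(nrow(f$edges), 0)
  expect_equal(attr(f, "removal_log")[[1]], "hub")

  # cascade: A exceeds the threshold by a lot, B only via its edges to
  # A's neighborhood; removing A first drops B to the threshold, so B
  # survives -- matches the hand simulation
  t <- 3
  a_edges <- lapply(sprintf("x%d", 1:5), function(x) c("A", x))
  b_edges <- list(c("B", "A"), c("B", "x1"), c("B", "x2"), c("B", "x3"))
  adv <- build_network(do.call(make_edges, c(a_edges, b_edges)))
  # hand simulation: degrees A=6, B=4, x1..x3=2, x4,x5=1 -> round 1
  # removes A only (max degree); then B has degree 3 <= t -> stop
  f2 <- filter_sticky(adv, threshold = t)
  expect_equal(attr(f2, "removal_log"), list("A"))
  expect_true("B" %in% f2$vertices)
  expect_equal(max(degree_centrality(f2)), t)

  # fixed point of itself
  f3 <- filter_sticky(f2, threshold = t)
  expect_equal(f3$edges, f2$edges, ignore_attr = TRUE)
})

test_that("degree centrality equals adjacency row sums", {
  net <- make_net(c("c", "l1"), c("c", "l2"), c("c", "l3"))
  deg <- degree_centrality(net)
  expect_equal(deg[["c"]], 3)
  expect_equal(deg[["l1"]], 1)

  set.seed(21)
  for (i in 1:5) {
    net <- random_gnp_network(20, 0.2)
    g <- as_igraph(net)
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)[net$vertices, net$vertices]
    expect_equal(degree_centrality(net), rowSums(A),
                 ignore_attr = FALSE, tolerance = 0)
  }
})

test_that("betweenness matches closed forms and the enumeration oracle", {
  star <- make_net(c("c", "l1"), c("c", "l2"), c("c", "l3"))
  bc <- betweenness_centrality(star)
  expect_equal(bc[["c"]], 1.0)
  expect_equal(bc[["l1"]], 0.0)

  path3 <- make_net(c("a", "b"), c("b", "c"))
  bc <- betweenness_centrality(path3)
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))

  # 4-cycle: each vertex lies on half the (single) opposite-pair paths:
  # 0.5 / 3 pairs = 1/6; confirmed by the enumeration oracle
  c4 <- make_net(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a"))
  bc <- betweenness_centrality(c4)
  expect_equal(unname(bc), rep(1 / 6, 4))
  expect_equal(bc, oracle_betweenness(c4))

  # n < 3 -> all zeros
  tiny <- make_net(c("a", "b"))
  expect_equal(unname(betweenness_centrality(tiny)), c(0, 0))

  # vertex relabeling leaves the multiset of values unchanged
  set.seed(5)
  net <- random_gnp_network(15, 0.25)
  perm <- setNames(sprintf("w%03d", sample(length(net$vertices))),
                   net$vertices)
  renamed <- build_network(data.frame(gene_a = perm[net$edges$gene_a],
                                      gene_b = perm[net$edges$gene_b],
                                      stringsAsFactors = FALSE))
  expect_equal(sort(unname(betweenness_centrality(renamed))),
               sort(unname(betweenness_centrality(net))))
})

test_that("length normalization divides elementwise and flags gaps", {
  cat <- make_catalog(c("a", "b"), length_aa = c(200L, 50L))
  v <- c(a = 10, b = 0)
  out <- normalize_by_length(v, cat)
  expect_equal(out, c(a = 0.05, b = 0))
  expect_error(normalize_by_length(c(zz = 1), cat), "zz")

  set.seed(3)
  cat2 <- make_catalog(sprintf("g%02d", 1:30),
                       length_aa = sample(50:500, 30))
  vals <- setNames(runif(30), cat2$gene_id)
  expect_equal(normalize_by_length(vals, cat2),
               vals / setNames(cat2$length_aa, cat2$gene_id))
})

test_that("group summary computes mean and standard error per group", {
  cls <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    age = c("pre_wgd", "pre_wgd", "post_wgd", "post_wgd"),
                    origin = c("novel", "novel", "novel", "novel"),
                    stringsAsFactors = FALSE)
  v <- c(g1 = 1, g2 = 3, g3 = 5, g4 = 5, absent = 99)
  s <- group_summary(v, cls)
  pn <- s[s$group == "pre_wgd/novel", ]
  expect_equal(pn$n, 2)
  expect_equal(pn$mean, 2)
  expect_equal(pn$se, 1)  # sd sqrt(2) over sqrt(2)
  expect_equal(s[s$group == "post_wgd/novel", "se"], 0)
  expect_equal(s[s$group == "wgd/duplicate", "n"], 0)
  expect_true(is.na(s[s$group == "wgd/duplicate", "mean"]))
  # order invariance
  s2 <- group_summary(v[c(5, 4, 3, 2, 1)], cls[4:1, ])
  expect_equal(s2, s)
})

test_that("ego subnetwork induces the neighborhood and reports components", {
  tri <- make_net(c("a", "b"), c("b", "c"), c("a", "c"), c("x", "y"))
  ego <- ego_subnetwork(tri, seeds = "a")
  # induced: the b-c edge is kept even though neither is a seed
  expect_equal(nrow(ego$network$edges), 3)
  expect_setequal(ego$network$vertices, c("a", "b", "c"))
  expect_equal(ego$components$size, 3)
  expect_equal(ego$components$n_seed, 1)

  # seeds without interactions are reported, not silently dropped
  ego2 <- ego_subnetwork(tri, seeds = c("a", "nope"))
  expect_equal(ego2$missing_seeds, "nope")

  expect_warning(none <- ego_subnetwork(tri, seeds = "zz"), "no seed")
  expect_equal(length(none$network$vertices), 0)

  # component sizes match the frontier-expansion oracle
  set.seed(17)
  for (i in 1:5) {
    net <- random_gnp_network(30, 0.05)
    seeds <- sample(net$vertices, 5)
    ego <- suppressWarnings(ego_subnetwork(net, seeds))
    if (length(ego$network$vertices) == 0) next
    oc <- oracle_components(ego$network)
    expect_equal(sort(ego$components$size),
                 sort(unname(as.integer(table(oc)))))
  }
})
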