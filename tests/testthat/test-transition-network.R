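test_that("transition counting follows the ordered-pair rule within segments", {
  net <- build_transition_matrix(c(1, 1, 2))
  expect_equal(net$counts, rbind(c(1, 1), c(0, 0)))
  ## constant series of length n: (a,a) = n-1 only
  net2 <- build_transition_matrix(rep(1, 7))
  expect_equal(net2$counts, matrix(6, 1, 1))
  ## no pairs across segment boundaries
  net3 <- build_transition_matrix(c(1, 2, 2, 1),
                                  segments = rbind(c(1, 2), c(3, 4)))
  expect_equal(net3$counts, rbind(c(0, 1), c(1, 0)))
  expect_error(build_transition_matrix(c(1, 2), segments = rbind(c(1, 1),
                                                                 c(2, 2))),
               "longer than the lag")
})

test_that("total counts equal sum over segments of (length - lag)", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    s <- sample(1:5, n, replace = TRUE)
    cut <- sort(sample(2:(n - 2), 2))
    segs <- rbind(c(1, cut[1]), c(cut[1] + 1, cut[2]), c(cut[2] + 1, n))
    segs <- segs[segs[, 2] - segs[, 1] >= 2, , drop = FALSE]
    if (nrow(segs) < 3) next
    lag <- sample(1:2, 1)
    net <- build_transition_matrix(s, segments = segs, lag = lag)
    expect_equal(sum(net$counts),
                 sum(segs[, 2] - segs[, 1] + 1 - lag))
  }
})

test_that("state relabeling permutes the count matrix consistently", {
  set.seed(32)
  s <- sample(1:4, 300, replace = TRUE)
  net <- build_transition_matrix(s)
  perm <- sample(4)
  net_p <- build_transition_matrix(perm[s])
  expect_equal(net_p$counts[perm, perm], net$counts)
  ## modularity of matched partitions is permutation-invariant
  w <- ctna:::symmetrized_weights(net$counts)
  w_p <- ctna:::symmetrized_weights(net_p$counts)
  memb <- c(1, 1, 2, 2)
  memb_p <- integer(4); memb_p[perm] <- memb
  expect_equal(ctna:::modularity_value(w_p, memb_p),
               ctna:::modularity_value(w, memb))
})

test_that("two cliques joined by one edge split into exactly their communities", {
  counts <- two_cliques_counts(5)
  net <- build_transition_matrix(c(1, 2))   # shell; replace counts
  net$counts <- counts
  net$populations <- diag(counts)
  net <- detect_communities(net)
  expect_equal(length(unique(net$communities)), 2)
  expect_equal(net$communities, rep(1:2, each = 5))
  ## and the achieved modularity equals the exhaustive-search optimum
  w <- ctna:::symmetrized_weights(counts)
  expect_equal(net$modularity, oracle_best_modularity(w), tolerance = 1e-12)
})

test_that("community detection attains the exhaustive optimum on small random graphs", {
  set.seed(33)
  for (rep in 1:8) {
    n <- sample(5:7, 1)
    w <- matrix(0, n, n)
    up <- upper.tri(w)
    w[up] <- sample(0:3, sum(up), replace = TRUE)
    w <- w + t(w)
    if (sum(w) == 0) next
    net <- build_transition_matrix(c(1, 2))
    net$counts <- w; net$populations <- diag(w)
    net <- detect_communities(net)
    expect_equal(net$modularity, oracle_best_modularity(w),
                 tolerance = 1e-10)
  }
})

test_that("degenerate networks are handled: singleton and disconnected components", {
  net <- build_transition_matrix(rep(1, 10))
  net <- detect_communities(net)
  expect_equal(net$communities, 1L)
  ## two disconnected components never share a community
  net2 <- build_transition_matrix(c(1, 2, 1, 2, 3, 4, 3, 4),
                                  segments = rbind(c(1, 4), c(5, 8)))
  net2 <- detect_communities(net2)
  expect_length(intersect(net2$communities[1:2], net2$communities[3:4]), 0)
})

test_that("node sizes scale linearly onto [1, 10] with the degenerate midpoint", {
  expect_equal(scale_node_sizes(c(2, 11)), c(1, 10))
  expect_equal(scale_node_sizes(c(4, 4, 4)), c(5.5, 5.5, 5.5))
  expect_equal(scale_node_sizes(c(0, 5, 10)), c(1, 5.5, 10))
  set.seed(34)
  p <- rpois(20, 40)
  expect_true(all(scale_node_sizes(p) >= 1 & scale_node_sizes(p) <= 10))
})

test_that("community summaries average raw descriptors and fractions sum to 1", {
  spec <- abeta_like_spec(n_frames = 400, seed = 17)
  ens <- realize_trajectory(spec)
  ss <- project_trajectory(ens)
  net <- detect_communities(build_transition_matrix(ss), seed = 1)
  summ <- summarize_communities(net, ss)
  expect_equal(sum(summ$fraction), 1)
  ## spot-check one community against a direct average
  cf <- net$communities[ss$states]
  for (k in summ$community) {
    expect_equal(summ$dNC[summ$community == k], mean(ss$raw$dNC[cf == k]))
    expect_equal(summ$Nbeta[summ$community == k], mean(ss$raw$Nbeta[cf == k]))
  }
})

test_that("network export round-trips through graphml, gexf and csv", {
  spec <- abeta_like_spec(n_frames = 200, seed = 23)
  ss <- project_trajectory(realize_trajectory(spec))
  net <- detect_communities(build_transition_matrix(ss), seed = 1)
  net$summary <- summarize_communities(net, ss)

  fg <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, fg)
  g2 <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::vcount(g2), nrow(net$counts))
  expect_equal(igraph::ecount(g2), sum(net$counts > 0))
  expect_equal(sort(igraph::E(g2)$count), sort(net$counts[net$counts > 0]))
  expect_equal(igraph::V(g2)$population[order(as.integer(igraph::V(g2)$name))],
               unname(net$populations))

  fx <- withr::local_tempfile(fileext = ".gexf")
  export_network(net, fx)
  skip_if_not_installed("xml2")
  doc <- xml2::read_xml(fx)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes <- xml2::xml_find_all(doc, ".//g:node", ns)
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  expect_length(nodes, nrow(net$counts))
  expect_length(edges, sum(net$counts > 0))
  wts <- as.numeric(xml2::xml_attr(edges, "weight"))
  expect_equal(sort(wts), sort(net$counts[net$counts > 0]))

  fc <- withr::local_tempfile(fileext = ".csv")
  export_network(net, fc, format = "csv_edgelist")
  el <- read.csv(fc)
  expect_identical(names(el), c("source", "target", "count"))
  expect_equal(sum(el$count), sum(net$counts))
})

test_that("a one-node zero-edge network still exports a valid file", {
  net <- build_transition_matrix(rep(1, 3))
  net$counts <- matrix(0, 1, 1); net$populations <- 0
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 1)
  expect_equal(igraph::ecount(g), 0)
})
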