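test_that("network construction dedupes, drops self-loops, keeps max prob", {
  empty <- build_network(tibble::tibble(g1 = character(), g2 = character()))
  expect_equal(length(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)

  e <- tibble::tibble(g1 = c("B", "A", "C", "C"),
                      g2 = c("A", "B", "C", "D"),
                      prob = c(0.6, 0.9, 0.5, 0.7))
  expect_warning(net <- build_network(e), "self-pair")
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$edges$prob[net$edges$g1 == "A"], 0.9)

  e3 <- tibble::tibble(g1 = c("A", "B", "C"), g2 = c("B", "C", "D"))
  expect_equal(length(build_network(e3)$nodes), 4L)
})

test_that("disease subnetworks keep exactly the seed-touching edges", {
  e <- tibble::tibble(g1 = c("S1", "S1", "A", "A", "B"),
                      g2 = c("A", "B", "B", "C", "C"))
  net <- build_network(e)
  sub <- extract_disease_subnetwork(net, c("S1"))
  expect_setequal(paste(sub$edges$g1, sub$edges$g2), c("A S1", "B S1"))
  # edge A-B between two seed-adjacent non-seeds is excluded
  expect_false(any(sub$edges$g1 == "A" & sub$edges$g2 == "B"))

  # star around one seed is fully retained
  star <- build_network(tibble::tibble(g1 = rep("S", 4),
                                       g2 = c("A", "B", "C", "D")))
  expect_equal(nrow(extract_disease_subnetwork(star, "S")$edges), 4L)

  # absent seeds: empty subnetwork, all seeds reported missing
  expect_message(sub2 <- extract_disease_subnetwork(net, c("Z1", "Z2")),
                 "absent")
  expect_equal(nrow(sub2$edges), 0L)
  expect_setequal(attr(sub2, "missing_seeds"), c("Z1", "Z2"))
  expect_error(extract_disease_subnetwork(net, character(0)), "empty")

  # idempotence
  sub_a <- extract_disease_subnetwork(net, "S1")
  sub_b <- extract_disease_subnetwork(sub_a, "S1")
  expect_equal(sub_a$edges, sub_b$edges)
})

test_that("centralities reproduce closed-form values on named graphs", {
  fg <- fixture_graphs(n_random = 0)
  star <- build_network(fg$star5$edges)
  deg <- degree_centrality(star)
  expect_equal(deg$score[deg$gene == "n01"], 4)
  expect_equal(sort(unique(deg$score)), c(1, 4))
  btw <- betweenness_centrality(star)
  expect_equal(btw$score[btw$gene == "n01"], choose(4, 2))
  expect_equal(sum(btw$score), 6)
  ev <- eigenvector_centrality(star)
  expect_equal(ev$score[ev$gene == "n01"] / ev$score[ev$gene == "n02"], 2,
               tolerance = 1e-8)

  p3 <- build_network(fg$p3$edges)
  clo <- closeness_centrality(p3)
  expect_equal(clo$score, c(2 / 3, 1, 2 / 3))
  expect_equal(betweenness_centrality(p3)$score, c(0, 1, 0))

  k3 <- build_network(fg$k3$edges)
  expect_equal(eigenvector_centrality(k3)$score, rep(1 / sqrt(3), 3))
  k4 <- build_network(fg$k4$edges)
  expect_equal(closeness_centrality(k4)$score, rep(1, 4))

  # isolated node scores zero degree and closeness
  iso <- build_network(fg$p3$edges, nodes = c(fg$p3$nodes, "n99"))
  expect_equal(degree_centrality(iso)$score[4], 0)
  expect_equal(closeness_centrality(iso)$score[4], 0)
})

test_that("all four centralities match the brute-force oracle on random graphs", {
  fg <- fixture_graphs(n_random = 20, seed = 99)
  for (nm in names(fg)) {
    g <- fg[[nm]]
    net <- build_network(g$edges, nodes = g$nodes)
    orc <- g$centrality[match(net$nodes, g$centrality$gene), ]
    expect_equal(degree_centrality(net)$score, orc$degree, tolerance = 1e-12)
    expect_equal(closeness_centrality(net)$score, orc$closeness,
                 tolerance = 1e-12)
    expect_equal(betweenness_centrality(net)$score, orc$betweenness,
                 tolerance = 1e-9)
    ev <- eigenvector_centrality(net)$score
    if (nrow(g$edges) == 0) {
      expect_equal(ev, orc$eigenvector)
    } else {
      cosine <- sum(ev * orc$eigenvector) /
        sqrt(sum(ev^2) * sum(orc$eigenvector^2))
      expect_gte(cosine, 1 - 1e-8)
    }
  }
})

test_that("relabeling nodes permutes centrality scores identically", {
  fg <- fixture_graphs(n_random = 5, seed = 3)
  g <- fg$random03
  map <- setNames(sprintf("Z%02d", rev(seq_along(g$nodes))), g$nodes)
  net1 <- build_network(g$edges, nodes = g$nodes)
  net2 <- build_network(tibble::tibble(g1 = unname(map[g$edges$g1]),
                                       g2 = unname(map[g$edges$g2])),
                        nodes = unname(map))
  for (meas in c("degree", "closeness", "betweenness", "eigenvector")) {
    s1 <- centrality_scores(net1, meas)
    s2 <- centrality_scores(net2, meas)
    relabeled <- setNames(s2$score, s2$gene)[unname(map[s1$gene])]
    expect_equal(unname(relabeled), s1$score, tolerance = 1e-8, info = meas)
  }
})

test_that("network statistics match hand values and the triangle oracle", {
  tri <- build_network(tibble::tibble(g1 = c("a", "a", "b"),
                                      g2 = c("b", "c", "c")))
  st <- network_stats(tri)
  expect_equal(st$diameter, 1)
  expect_equal(st$clustering, 1)

  p3 <- build_network(tibble::tibble(g1 = c("a", "b"), g2 = c("b", "c")))
  st2 <- network_stats(p3)
  expect_equal(st2$diameter, 2)
  expect_equal(st2$clustering, 0)

  # triangle plus pendant: local ccs are (1/3, 1, 1, 0)
  tp <- build_network(tibble::tibble(g1 = c("a", "a", "b", "a"),
                                     g2 = c("b", "c", "c", "d")))
  st3 <- network_stats(tp)
  expect_equal(st3$clustering, (1 / 3 + 1 + 1 + 0) / 4)
  expect_equal(st3$diameter, 2)
  # diameter is computed on the largest component
  two <- build_network(tibble::tibble(g1 = c("a", "b", "x"),
                                      g2 = c("b", "c", "y")))
  expect_equal(network_stats(two)$diameter, 2)
  expect_equal(glance(two), network_stats(two))
})

test_that("top-n ranking orders by score with lexicographic tie-breaks", {
  sc <- tibble::tibble(gene = c("B", "A", "C", "D"),
                       score = c(3, 3, 5, 1))
  rk <- rank_top_n(sc, 3)
  expect_equal(rk$gene, c("C", "A", "B"))
  expect_equal(rk$rank, 1:3)
  expect_equal(nrow(rank_top_n(sc, 99)), 4L)
})

test_that("edge lists round-trip through TSV", {
  e <- tibble::tibble(g1 = c("A", "B"), g2 = c("B", "C"), prob = c(0.9, 0.7))
  net <- build_network(e)
  tf <- withr::local_tempfile()
  write_edges(net, tf)
  expect_equal(as.data.frame(read_edges(tf)), as.data.frame(net$edges))
})
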