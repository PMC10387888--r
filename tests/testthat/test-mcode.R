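test_that("vertex weights follow neighbourhood k-core density", {
  # in K4 each open neighbourhood is a triangle: core 2, density 1 -> weight 2
  k4 <- clique_graph(c("a", "b", "c", "d"))
  w <- mcode_vertex_weights(k4)
  expect_equal(unname(w), rep(2, 4))

  # a leaf's neighbourhood has no edges
  path <- named_graph(c("a", "b", "b", "c"))
  wp <- mcode_vertex_weights(path)
  expect_equal(wp[["a"]], 0)
  expect_equal(wp[["c"]], 0)

  # K_n symmetry: all nodes equal
  k6 <- clique_graph(sprintf("n%d", 1:6))
  expect_equal(length(unique(mcode_vertex_weights(k6))), 1)

  # isomorphism invariance under relabelling
  spec <- small_fixture_spec(61)
  g <- simulate_ppi(spec)
  w1 <- mcode_vertex_weights(g)
  g2 <- g
  igraph::V(g2)$name <- paste0("R_", igraph::V(g)$name)
  w2 <- mcode_vertex_weights(g2)
  expect_equal(unname(w2[paste0("R_", names(w1))]), unname(w1))
})

test_that("clustering keeps dense blocks together and discards thin debris", {
  # a single clique is one cluster
  k4 <- clique_graph(c("a", "b", "c", "d"))
  cl <- mcode_clusters(k4)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$pathway_ids, c("a", "b", "c", "d"))

  # an edgeless graph yields nothing
  empty <- named_graph(character(0), isolates = c("x", "y", "z"))
  expect_length(mcode_clusters(empty), 0)

  # barbell: every node has equal weight, so seeded expansion spans the bridge
  # and the two cliques coalesce into a single cluster under these rules
  cliqueA <- t(utils::combn(sprintf("a%d", 1:5), 2))
  cliqueB <- t(utils::combn(sprintf("b%d", 1:5), 2))
  barbell <- named_graph(c(as.vector(t(cliqueA)), as.vector(t(cliqueB)),
                           "a1", "b1"))
  clb <- mcode_clusters(barbell)
  expect_length(clb, 1)
  expect_length(clb[[1]]$pathway_ids, 10)

  # dense blocks joined through low-weight connector nodes separate cleanly
  bridge <- named_graph(c(as.vector(t(cliqueA)), as.vector(t(cliqueB)),
                          "a1", "mid1", "mid1", "mid2", "mid2", "b1"))
  clc <- mcode_clusters(bridge)
  expect_gte(length(clc), 2)
  members <- lapply(clc, `[[`, "pathway_ids")
  expect_true(any(vapply(members, function(m) all(sprintf("a%d", 1:5) %in% m),
                         logical(1))))
  expect_true(any(vapply(members, function(m) all(sprintf("b%d", 1:5) %in% m),
                         logical(1))))
  # node-disjoint, connected clusters with consecutive ranks
  all_members <- unlist(members)
  expect_equal(anyDuplicated(all_members), 0)
  for (m in members) {
    expect_equal(igraph::components(igraph::induced_subgraph(bridge, m))$no, 1)
  }
  expect_equal(vapply(clc, `[[`, integer(1), "rank"), seq_along(clc))
})

test_that("a larger score cutoff can only widen a cluster grown from the same seed", {
  cliqueA <- t(utils::combn(sprintf("a%d", 1:5), 2))
  cliqueB <- t(utils::combn(sprintf("b%d", 1:4), 2))
  g <- named_graph(c(as.vector(t(cliqueA)), as.vector(t(cliqueB)),
                     "a1", "mid", "mid", "b1"))
  narrow <- mcode_clusters(g, mcode_params(node_score_cutoff = 0.1))
  wide <- mcode_clusters(g, mcode_params(node_score_cutoff = 0.6))
  expect_true(all(narrow[[1]]$pathway_ids %in% unlist(lapply(wide, `[[`, "pathway_ids"))))
})

test_that("fluff requests are acknowledged but inert", {
  k4 <- clique_graph(c("a", "b", "c", "d"))
  expect_warning(cl <- mcode_clusters(k4, mcode_params(fluff = TRUE)),
                 "not implemented")
  expect_equal(cl[[1]]$pathway_ids, c("a", "b", "c", "d"))
})

test_that("pathway subnetworks subdivide strictly above the size threshold", {
  # 54 pathways: two 26-cliques joined through two sparse connector nodes
  idsA <- sprintf("pa%02d", 1:26)
  idsB <- sprintf("pb%02d", 1:26)
  edges <- rbind(t(utils::combn(idsA, 2)), t(utils::combn(idsB, 2)),
                 c(idsA[1], "mid1"), c("mid1", "mid2"), c("mid2", idsB[1]))
  g <- named_graph(as.vector(t(edges)))
  pnet <- structure(list(graph = g, threshold = 0.15, kappa = NULL),
                    class = "pathway_network")

  # at the threshold: returned unchanged as a single cluster
  cl50 <- subdivide_large(c(idsA[1:25], idsB[1:25]), pnet, size_threshold = 50)
  expect_length(cl50, 1)
  expect_length(cl50[[1]]$pathway_ids, 50)

  # past the threshold: subdivision separates the dense blocks
  cl54 <- subdivide_large(c(idsA, idsB, "mid1", "mid2"), pnet,
                          size_threshold = 50)
  expect_gte(length(cl54), 2)
  members <- lapply(cl54, `[[`, "pathway_ids")
  expect_true(any(vapply(members, function(m) all(idsA %in% m), logical(1))))
  expect_true(any(vapply(members, function(m) all(idsB %in% m), logical(1))))

  # small subnetworks keep their density x size score
  cl3 <- subdivide_large(idsA[1:3], pnet, size_threshold = 50)
  expect_equal(cl3[[1]]$mcode_score, 3)   # triangle: density 1 x size 3
  expect_error(subdivide_large("nope", pnet), "missing from")
})

test_that("significance-driven pathway search finds the planted pathway cluster", {
  spec <- small_fixture_spec(62)
  pm <- plant_module(simulate_ppi(spec), spec)
  sim <- simulate_pathways(spec, pm$truth)
  pnet <- build_pathway_network(sim$collection, threshold = 0.15)
  ids <- names(sim$collection$sets)
  sig <- setNames(rep(0.9, length(ids)), ids)
  sig[sim$truth$planted_pathway_ids] <- 1e-12
  sn <- pathway_subnetworks(pnet, sig, mc_samples = 1000, seed = 4)
  expect_gt(nrow(sn), 0)
  expect_true(all(sn$s_A >= 3))
  planted <- sim$truth$planted_pathway_ids
  top <- sn$members[[1]]
  expect_gte(length(intersect(top, planted)) / length(planted), 0.8)

  # all pathways at p = 1 yield nothing
  sig1 <- setNames(rep(1, length(ids)), ids)
  expect_equal(nrow(pathway_subnetworks(pnet, sig1, mc_samples = 500, seed = 4)), 0)

  # unlisted pathways default to p = 1 with a message
  expect_message(pathway_subnetworks(pnet, sig[1:10], mc_samples = 500, seed = 4),
                 "without a significance")
})
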