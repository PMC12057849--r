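# deterministic community with engineered correlation structure; rows are
# padded to a common total so relative abundances preserve the designed
# ranks and the flat taxon stays constant after normalisation
corrCommunity <- function(n = 8) {
  set.seed(10)
  base <- seq_len(n) + 10
  m <- cbind(
    up1 = base, up2 = base * 2,                # perfect rank correlation
    down = rev(base),                          # perfect anti-correlation
    flat = rep(3, n),                          # zero variance
    noise1 = sample(50:80, n), noise2 = sample(50:80, n))
  m <- cbind(m, pad = 500 - rowSums(m))
  rownames(m) <- sprintf("s%02d", seq_len(n))
  CommunityExperiment(m, group = rep("G1", n))
}

test_that("top-OTU selection keeps the highest group means", {
  sim <- netSim()
  top <- selectTopOtus(sim$community, "G1", n = 30)
  expect_equal(ncol(communityMatrix(top)), 30)
  rel <- communityMatrix(toRelative(subsetGroup(sim$community, "G1")))
  means <- colMeans(rel)
  kept <- colnames(communityMatrix(top))
  expect_gte(min(means[kept]), max(means[setdiff(names(means), kept)][
    means[setdiff(names(means), kept)] > -Inf]) - 1e-15)
  expect_warning(selectTopOtus(sim$community, "G1", n = 1e5),
                 "taking all")
})

test_that("network edges respect the correlation and p thresholds", {
  x <- corrCommunity()
  expect_warning(net <- buildNetwork(x, rhoThresh = 0.8, pThresh = 0.01),
                 "zero-variance")
  expect_true("flat" %in% net$excluded_taxa)
  el <- igraph::as_edgelist(net)
  pairs <- apply(el, 1, function(r) paste(sort(r), collapse = "-"))
  expect_true("up1-up2" %in% pairs)
  w <- igraph::E(net)$weight
  s <- igraph::E(net)$sign
  expect_equal(w[pairs == "up1-up2"], 1)
  expect_equal(s[pairs == "up1-up2"], "+")
  expect_true("down-up1" %in% pairs)
  expect_equal(s[pairs == "down-up1"], "-")

  # threshold audit on random data: every retained edge re-checks
  set.seed(3)
  mm <- matrix(runif(8 * 40), 8, 40,
               dimnames = list(sprintf("s%02d", 1:8), sprintf("t%02d", 1:40)))
  xx <- CommunityExperiment(mm, group = rep("G", 8))
  nn <- buildNetwork(xx, rhoThresh = 0.8, pThresh = 0.01)
  rel <- communityMatrix(toRelative(xx))
  if (igraph::ecount(nn) > 0) {
    ell <- igraph::as_edgelist(nn)
    for (e in seq_len(nrow(ell))) {
      ct <- suppressWarnings(cor.test(rel[, ell[e, 1]], rel[, ell[e, 2]],
                                      method = "spearman"))
      expect_gt(abs(ct$estimate), 0.8)
    }
  }
  expect_lt(igraph::ecount(nn), 40)  # far below the 780 candidate pairs
})

test_that("exact permutation p-values are valid and symmetric", {
  x <- corrCommunity(6)
  expect_warning(net <- buildNetwork(x, rhoThresh = 0.8, pThresh = 0.01,
                                     method = "exact"), "zero-variance")
  # perfect monotone pair: exact two-sided p = 2/6! * (ties at |rho|=1)
  el <- igraph::as_edgelist(net)
  pairs <- apply(el, 1, function(r) paste(sort(r), collapse = "-"))
  expect_true("up1-up2" %in% pairs)
})

test_that("topology report satisfies its arithmetic identities", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  igraph::E(tri)$sign <- "+"
  t3 <- networkTopology(tri)
  expect_equal(t3$clustering_coefficient, 1)
  expect_equal(t3$average_path_length, 1)
  expect_equal(t3$diameter, 1)
  expect_equal(t3$density, 1)

  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- paste0("n", 1:5)
  ts <- networkTopology(star)
  expect_equal(ts$clustering_coefficient, 0)
  expect_equal(ts$diameter, 2)
  expect_equal(ts$average_degree, 2 * 4 / 5)

  sim <- netSim()
  suppressWarnings(net <- buildNetwork(
    selectTopOtus(sim$community, "G1", 80), rhoThresh = 0.7,
    pThresh = 0.05))
  tp <- networkTopology(net)
  expect_equal(tp$n_positive + tp$n_negative, tp$n_edges)
  expect_equal(tp$average_degree, 2 * tp$n_edges / tp$n_nodes)
  expect_equal(tp$density,
               2 * tp$n_edges / (tp$n_nodes * (tp$n_nodes - 1)))
})

test_that("Zi-Pi computes participation and roles by the formulas", {
  # two triangles bridged by one edge: bridge nodes split links 2/1
  g <- igraph::make_graph(~ a - b, b - c, a - c, d - e, e - f, d - f, c - d)
  modules <- c(a = 1L, b = 1L, c = 1L, d = 2L, e = 2L, f = 2L)
  zp <- ziPi(g, modules)
  expect_equal(zp$pi[zp$node == "a"], 0)            # all links internal
  pc <- zp$pi[zp$node == "c"]                        # k=3: 2 in, 1 out
  expect_equal(pc, 1 - (2 / 3)^2 - (1 / 3)^2)
  # node with links split evenly across 2 modules
  g2 <- igraph::make_graph(~ x - m1, x - m2)
  zp2 <- ziPi(g2, c(x = 1L, m1 = 1L, m2 = 2L))
  expect_equal(zp2$pi[zp2$node == "x"], 0.5)
  # role boundaries
  role_of <- function(zi, pi) {
    df <- data.frame(zi = zi, pi = pi)
    ifelse(df$zi > 2.5, ifelse(df$pi > 0.62, "network_hub", "module_hub"),
           ifelse(df$pi > 0.62, "connector", "peripheral"))
  }
  expect_equal(role_of(3.0, 0.7), "network_hub")
  expect_equal(role_of(3.0, 0.5), "module_hub")
  expect_equal(role_of(1.0, 0.7), "connector")
  expect_equal(role_of(2.5, 0.62), "peripheral")
  expect_setequal(unique(zp$role), intersect(
    unique(zp$role),
    c("peripheral", "module_hub", "connector", "network_hub")))
})

test_that("natural connectivity matches spectra and orders density", {
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- letters[1:3]
  expect_equal(naturalConnectivity(k3),
               log((exp(2) + 2 * exp(-1)) / 3), tolerance = 1e-12)
  one <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(one)$name <- "a"
  expect_equal(naturalConnectivity(one), 0)
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- letters[1:6]
  c6 <- igraph::make_ring(6)
  igraph::V(c6)$name <- letters[1:6]
  expect_gt(naturalConnectivity(k6), naturalConnectivity(c6))
  # non-increasing under edge removal on the same node set
  g <- k6
  prev <- naturalConnectivity(g)
  for (i in 1:5) {
    g <- igraph::delete_edges(g, 1)
    cur <- naturalConnectivity(g)
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("robustness curves behave under both removal modes", {
  sim <- netSim()
  suppressWarnings(net <- buildNetwork(
    selectTopOtus(sim$community, "G1", 80), rhoThresh = 0.7,
    pThresh = 0.05))
  tgt <- robustnessCurve(net, "targeted", fMax = 0.8, step = 0.1)
  expect_true(all(diff(tgt$natural_connectivity) <= 1e-9))
  rnd1 <- robustnessCurve(net, "random", fMax = 0.4, step = 0.2,
                          nReps = 100, seed = 1)
  rnd2 <- robustnessCurve(net, "random", fMax = 0.4, step = 0.2,
                          nReps = 100, seed = 1)
  expect_equal(rnd1$natural_connectivity, rnd2$natural_connectivity)
  expect_equal(tgt$natural_connectivity[1], naturalConnectivity(net))
})

test_that("GEXF and GraphML exports round-trip node and edge data", {
  skip_if_not_installed("xml2")
  g <- igraph::make_graph(~ a - b, b - c)
  igraph::E(g)$weight <- c(0.9, -0.85)
  igraph::E(g)$sign <- c("+", "-")
  net <- annotateRoles(g, modules = c(a = 1L, b = 1L, c = 2L))
  d <- withr::local_tempdir()
  f <- file.path(d, "net.gexf")
  writeGEXF(net, f)
  doc <- xml2::read_xml(f)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//node"), "id")
  expect_setequal(nodes, c("a", "b", "c"))
  edges <- xml2::xml_find_all(doc, ".//edge")
  expect_length(edges, 2)
  src <- xml2::xml_attr(edges, "source")
  tgt <- xml2::xml_attr(edges, "target")
  expect_setequal(paste(src, tgt), c("a b", "b c"))
  signs <- xml2::xml_find_all(doc, ".//edge//attvalue")
  expect_true(any(xml2::xml_attr(signs, "value") == "-"))
  roles <- xml2::xml_find_all(doc, ".//node//attvalue")
  expect_true(all(xml2::xml_attr(roles, "value") %in%
                    c("1", "2", "peripheral", "module_hub", "connector",
                      "network_hub") |
                    !is.na(suppressWarnings(as.numeric(
                      xml2::xml_attr(roles, "value"))))))

  fg <- file.path(d, "net.graphml")
  writeGraphML(net, fg)
  back <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::ecount(back), 2)
  expect_setequal(igraph::E(back)$sign, c("+", "-"))

  empty <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(empty)$name <- c("x", "y")
  expect_warning(writeGEXF(empty, file.path(d, "empty.gexf")),
                 "zero edges")
})
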