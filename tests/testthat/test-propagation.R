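path_net <- function() {
  functional_network(tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C"),
                                    weight = 1))
}

test_that("RWR on the 3-node path matches the closed form (7/12, 1/3, 1/12)", {
  net <- path_net()
  prof <- rwr(net, "A", r = 0.5, tol = 1e-14)
  expect_equal(prof$affinity[match(c("A", "B", "C"), prof$gene)],
               c(7 / 12, 1 / 3, 1 / 12), tolerance = 1e-8)
  exact <- rwr(net, "A", r = 0.5, method = "exact")
  expect_equal(exact$affinity, prof$affinity, tolerance = 1e-10)
})

test_that("iterative RWR agrees with the dense linear-solve oracle on random graphs", {
  for (s in 1:8) {
    el <- random_edge_list(50, seed = s)
    net <- functional_network(el)
    nodes <- network_nodes(net)
    adj <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(el))) {
      adj[el$gene_a[i], el$gene_b[i]] <- el$weight[i]
      adj[el$gene_b[i], el$gene_a[i]] <- el$weight[i]
    }
    seed_gene <- nodes[1 + (s %% length(nodes))]
    tol <- 1e-10
    p_iter <- rwr(net, seed_gene, r = 0.7, tol = tol)
    p_ref <- rwr_dense_oracle(adj, match(seed_gene, nodes), r = 0.7)
    expect_lt(max(abs(p_iter$affinity - p_ref)), 10 * tol)
  }
})

test_that("affinities are a probability distribution", {
  for (r in c(0.3, 0.7)) {
    net <- functional_network(random_edge_list(40, seed = 3))
    prof <- rwr(net, network_nodes(net)[5], r = r)
    expect_equal(sum(prof$affinity), 1, tolerance = 1e-8)
    expect_true(all(prof$affinity >= 0))
  }
})

test_that("affinity decays monotonically with hop distance on a path", {
  el <- tibble::tibble(gene_a = sprintf("N%d", 1:5),
                       gene_b = sprintf("N%d", 2:6), weight = 1)
  net <- functional_network(el)
  for (r in c(0.1, 0.5, 0.9)) {
    prof <- rwr(net, "N1", r = r, tol = 1e-13)
    aff <- prof$affinity[match(sprintf("N%d", 1:6), prof$gene)]
    # among non-seed nodes affinity strictly decreases with distance at any r;
    # the seed itself dominates once the restart outweighs the degree bias of
    # its interior neighbour (small r drives the walk toward the
    # degree-proportional stationary law)
    expect_true(all(diff(aff[-1]) < 0))
    if (r >= 0.3) expect_true(all(aff[1] > aff[-1]))
  }
})

test_that("restart limits: r -> 1 concentrates on the seed; r -> 0 approaches the degree stationary law", {
  # triangle plus pendant: connected and non-bipartite
  el <- tibble::tibble(gene_a = c("A", "A", "B", "C"),
                       gene_b = c("B", "C", "C", "D"),
                       weight = c(1, 0.5, 1, 0.8))
  net <- functional_network(el)
  hi <- rwr(net, "B", r = 0.999, tol = 1e-13)
  expect_gt(hi$affinity[hi$gene == "B"], 0.99)
  lo <- rwr(net, "B", r = 1e-4, tol = 1e-13)
  wdeg <- c(A = 1.5, B = 2, C = 2.3, D = 0.8)
  stat <- wdeg / sum(wdeg)
  expect_equal(lo$affinity[match(names(stat), lo$gene)], unname(stat),
               tolerance = 1e-3)
})

test_that("edge-list loading collapses duplicates, filters weights, drops small components", {
  net <- functional_network(tibble::tibble(gene_a = c("A", "B"),
                                           gene_b = c("B", "A"),
                                           weight = c(0.5, 0.9)))
  ed <- network_edges(net)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$weight, 0.9)

  net2 <- functional_network(tibble::tibble(gene_a = c("A", "C"),
                                            gene_b = c("B", "D"),
                                            weight = c(0.1, 0.3)),
                             min_weight = 0.2)
  expect_equal(nrow(network_edges(net2)), 1)

  # two disconnected triads: one kept, three nodes reported dropped
  tri2 <- tibble::tibble(gene_a = c("A", "A", "B", "X", "X", "Y"),
                         gene_b = c("B", "C", "C", "Y", "Z", "Z"),
                         weight = 0.9)
  expect_message(net3 <- functional_network(tri2), "3 of 6 nodes dropped")
  expect_length(network_nodes(net3), 3)
  expect_equal(net3$n_dropped, 3)
})

test_that("TSV round trip and parse errors carry line information", {
  el <- random_edge_list(10, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(el, f, sep = "\t", quote = FALSE, row.names = FALSE)
  net <- read_network(f)
  expect_setequal(network_nodes(net), unique(c(el$gene_a, el$gene_b)))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.5", "B\tC\tnot_a_number"), bad)
  expect_error(read_network(bad), class = "evnetprop_parse_error")
})

test_that("pseudo-activation returns strictly-above-threshold genes", {
  net <- functional_network(random_edge_list(5, p_edge = 1, seed = 6))
  prof <- rwr(net, network_nodes(net)[1])
  # connected graph, threshold 0: every non-seed node is pseudo-activated
  expect_setequal(pseudo_activated(prof, 0), network_nodes(net)[-1])
  expect_length(pseudo_activated(prof, 1.0), 0)
  med <- stats::median(prof$affinity)
  expect_setequal(pseudo_activated(prof, med, exclude_seed = FALSE),
                  prof$gene[prof$affinity > med])
})

test_that("top-k vicinity ranks by affinity with lexicographic tie-breaks", {
  # star: all leaves tie, so the tie rule decides
  el <- tibble::tibble(gene_a = "HUB", gene_b = c("L4", "L2", "L1", "L3"),
                       weight = 1)
  net <- functional_network(el)
  prof <- rwr(net, "HUB", tol = 1e-13)
  vic <- top_k_vicinity(prof, k = 3)
  expect_identical(vic$gene, c("L1", "L2", "L3"))

  # k >= n-1 returns all non-seed nodes, flagged truncated only if short
  vic_all <- top_k_vicinity(prof, k = 10)
  expect_setequal(vic_all$gene, c("L1", "L2", "L3", "L4"))
  expect_true(attr(vic_all, "truncated"))

  # on the path graph, the seed's neighbour outranks the far node
  p <- rwr(path_net(), "A", r = 0.5, tol = 1e-13)
  expect_identical(top_k_vicinity(p, k = 1)$gene, "B")
})

test_that("seed handling: missing seeds error (strict) or are skipped with a warning", {
  net <- path_net()
  expect_error(rwr(net, "Q"), class = "evnetprop_seed_error")
  expect_error(rwr(net, "A", r = 1.5), "restart probability")
  expect_error(propagate_all(net, c("A", "Q"), strict = TRUE),
               class = "evnetprop_seed_error")
  expect_warning(res <- propagate_all(net, c("A", "Q"), k = 2), "skipped")
  expect_named(res, "A")
})

test_that("propagation results do not depend on seed iteration order", {
  net <- functional_network(random_edge_list(30, seed = 9))
  seeds <- network_nodes(net)[c(3, 11, 20)]
  a <- propagate_all(net, seeds, k = 5)
  b <- propagate_all(net, rev(seeds), k = 5)
  expect_identical(a, b)
})

test_that("module-planted seeds concentrate affinity within their module", {
  ok <- vapply(1:10, function(s) {
    cfg <- synth_config(n_genes = 200, n_modules = 4, seed = 400 + s)
    nw <- generate_network(cfg)
    mod <- nw$truth$module_of_gene
    seed_gene <- names(mod)[mod == nw$truth$target_module][1]
    prof <- rwr(nw$network, seed_gene)
    same <- mod[prof$gene] == mod[seed_gene]
    mean(prof$affinity[same & prof$gene != seed_gene]) >
      mean(prof$affinity[!same])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
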