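#' Build a weighted functional gene network
#'
#' Constructs an undirected simple weighted graph from an edge list,
#' collapsing duplicate edges by maximum weight, dropping edges below
#' `min_weight` and self-loops, and restricting to the largest connected
#' component (a message names how many nodes were removed — a random walk
#' needs a connected, stochastic support). The column-stochastic transition
#' operator over edge weights is precomputed.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `weight`
#'   (weights in (0, 1]).
#' @param min_weight Drop edges with weight strictly below this value.
#' @param nodes Optional full node set (to represent isolated nodes when the
#'   edge list alone cannot).
#' @return A `functional_network` object.
#' @export
functional_network <- function(edges, min_weight = 0, nodes = NULL) {
  edges <- as_tibble(edges)
  assert_that(all(c("gene_a", "gene_b", "weight") %in% names(edges)),
              "edge list needs columns gene_a, gene_b, weight")
  assert_that(all(is.finite(edges$weight)), "edge weights must be numeric")
  assert_that(all(edges$weight > 0 & edges$weight <= 1),
              "edge weights must lie in (0, 1]")
  edges <- edges |>
    filter(.data$weight >= min_weight, .data$gene_a != .data$gene_b) |>
    mutate(a = pmin(.data$gene_a, .data$gene_b),
           b = pmax(.data$gene_a, .data$gene_b))
  edges <- if (nrow(edges) > 0) {
    edges |> group_by(.data$a, .data$b) |>
      summarise(weight = max(.data$weight), .groups = "drop")
  } else {
    tibble(a = character(0), b = character(0), weight = numeric(0))
  }
  all_nodes <- sort(unique(c(nodes, edges$a, edges$b)))
  if (length(all_nodes) == 0) abort("empty network", class = "evnetprop_network_error")

  g <- igraph::graph_from_data_frame(
    edges |> select("a", "b", "weight"),
    directed = FALSE,
    vertices = data.frame(name = all_nodes))
  comp <- igraph::components(g)
  keep_comp <- which.max(comp$csize)
  dropped <- sum(comp$membership != keep_comp)
  if (dropped > 0) {
    inform(sprintf(
      "network restricted to largest connected component: %d of %d nodes dropped",
      dropped, length(all_nodes)))
    g <- igraph::induced_subgraph(g, which(comp$membership == keep_comp))
  }
  node_names <- sort(igraph::V(g)$name)
  n <- length(node_names)
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el) > 0) {
    i <- match(el$from, node_names)
    j <- match(el$to, node_names)
    A <- sparseMatrix(i = c(i, j), j = c(j, i), x = rep(el$weight, 2),
                      dims = c(n, n), dimnames = list(node_names, node_names))
  } else {
    # single isolated node: a degree-zero column breaks stochasticity, so the
    # walker stays put (implicit self-loop)
    A <- sparseMatrix(i = 1, j = 1, x = 1, dims = c(n, n),
                      dimnames = list(node_names, node_names))
  }
  deg <- Matrix::colSums(A)
  W <- A %*% Diagonal(x = 1 / deg)
  dimnames(W) <- list(node_names, node_names)
  structure(list(nodes = node_names, adjacency = A, transition = W,
                 n_dropped = dropped), class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("<functional_network> %d nodes, %d edges (%d nodes dropped with small components)\n",
              length(x$nodes), length(x$adjacency@x) / 2, x$n_dropped))
  invisible(x)
}

#' @rdname functional_network
#' @param net A `functional_network`.
#' @export
network_nodes <- function(net) net$nodes

#' @rdname functional_network
#' @export
network_edges <- function(net) {
  A <- as(Matrix::triu(x = net$adjacency), "TsparseMatrix")
  tibble(gene_a = net$nodes[A@i + 1], gene_b = net$nodes[A@j + 1],
         weight = A@x) |>
    filter(.data$gene_a != .data$gene_b | length(net$nodes) == 1) |>
    arrange(.data$gene_a, .data$gene_b)
}

#' Read a 3-column edge-list TSV into a functional network
#'
#' Expects `gene_a`, `gene_b`, `weight` columns (header optional; three
#' unnamed columns are accepted in that order, the format tissue-network
#' downloads use).
#'
#' @param path Path to the TSV.
#' @inheritParams functional_network
#' @return A `functional_network`.
#' @export
read_network <- function(path, min_weight = 0) {
  first <- readLines(path, n = 1)
  has_header <- grepl("gene_a", first, fixed = TRUE)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = has_header,
                      stringsAsFactors = FALSE),
    error = function(e) abort(paste0("malformed edge list '", path, "': ",
                                     conditionMessage(e)),
                              class = "evnetprop_parse_error"))
  if (!has_header) names(df) <- c("gene_a", "gene_b", "weight")
  if (!is.numeric(df$weight)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$weight))))[1]
    abort(sprintf("malformed edge list '%s': non-numeric weight at line %d",
                  path, bad + has_header), class = "evnetprop_parse_error")
  }
  functional_network(df, min_weight = min_weight)
}

#' Random walk with restart (RWR)
#'
#' Iterates \eqn{p \leftarrow (1-r) W p + r e} on the column-stochastic
#' transition operator, with the restart vector `e` uniform over the seed
#' genes, until the L1 change falls below `tol`. `method = "exact"` instead
#' solves the fixed point \eqn{p = r (I - (1-r) W)^{-1} e} directly and
#' serves as the independent oracle for the iteration.
#'
#' @param net A [functional_network()].
#' @param seeds Character vector of seed genes (all must be network nodes).
#' @param r Restart probability in (0, 1).
#' @param tol L1 convergence tolerance.
#' @param max_iter Maximum iterations before a non-convergence error.
#' @param method `"iterative"` (default) or `"exact"` (direct linear solve).
#' @return An `affinity_profile` tibble (`gene`, `affinity`, sorted by gene)
#'   with attributes `seeds`, `r`, `iterations`, `residual`.
#' @export
rwr <- function(net, seeds, r = 0.7, tol = 1e-10, max_iter = 10000,
                method = c("iterative", "exact")) {
  method <- match.arg(method)
  assert_that(r > 0 && r < 1, "restart probability r must be in (0, 1)")
  missing <- setdiff(seeds, net$nodes)
  if (length(missing) > 0)
    abort(paste0("seed genes not in network: ", paste(missing, collapse = ", ")),
          class = "evnetprop_seed_error")
  assert_that(length(seeds) >= 1, "at least one seed gene is required")
  n <- length(net$nodes)
  e <- numeric(n)
  e[match(unique(seeds), net$nodes)] <- 1 / length(unique(seeds))
  W <- net$transition
  if (method == "exact") {
    p <- as.numeric(Matrix::solve(Diagonal(n) - (1 - r) * W, r * e))
    iterations <- 0L
    residual <- sum(abs((1 - r) * as.numeric(W %*% p) + r * e - p))
  } else {
    p <- e
    iterations <- 0L
    repeat {
      p_new <- (1 - r) * as.numeric(W %*% p) + r * e
      residual <- sum(abs(p_new - p))
      p <- p_new
      iterations <- iterations + 1L
      if (residual <= tol) break
      if (iterations >= max_iter)
        abort(sprintf("RWR did not converge in %d iterations (residual %.3e)",
                      max_iter, residual), class = "evnetprop_convergence_error")
    }
  }
  out <- tibble(gene = net$nodes, affinity = p)
  class(out) <- c("affinity_profile", class(out))
  attr(out, "seeds") <- unique(seeds)
  attr(out, "r") <- r
  attr(out, "iterations") <- iterations
  attr(out, "residual") <- residual
  out
}

#' Genes pseudo-activated by a random walk
#'
#' Returns the genes whose affinity is strictly above `threshold`. Note that
#' on a connected network with `threshold = 0` this is every non-seed node —
#' which is exactly why the threshold (and the top-k vicinity of
#' [top_k_vicinity()]) are surfaced as explicit choices.
#'
#' @param profile An `affinity_profile` from [rwr()].
#' @param threshold Strict lower bound on affinity.
#' @param exclude_seed Drop the seed genes from the result?
#' @return Character vector of gene identifiers (sorted).
#' @export
pseudo_activated <- function(profile, threshold = 0, exclude_seed = TRUE) {
  genes <- profile$gene[profile$affinity > threshold]
  if (exclude_seed) genes <- setdiff(genes, attr(profile, "seeds"))
  sort(genes)
}

#' Top-k vicinity of a seed
#'
#' The `k` non-seed genes with the highest affinity; ties are broken by
#' lexicographic gene identifier so the vicinity is reproducible
#' bit-for-bit. Returns fewer than `k` genes (with attribute
#' `truncated = TRUE`) when the network is too small.
#'
#' @param profile An `affinity_profile` from [rwr()].
#' @param k Number of vicinity genes.
#' @return A `vicinity` tibble (`gene`, `affinity`, `rank`), attributes
#'   `seeds`, `k`, `truncated`.
#' @export
top_k_vicinity <- function(profile, k = 20) {
  assert_that(k >= 1, "k must be at least 1")
  nonseed <- profile |> filter(!.data$gene %in% attr(profile, "seeds"))
  ord <- nonseed |> arrange(desc(.data$affinity), .data$gene)
  out <- ord |> slice_head(n = k) |> mutate(rank = row_number())
  class(out) <- c("vicinity", class(out))
  attr(out, "seeds") <- attr(profile, "seeds")
  attr(out, "k") <- k
  attr(out, "truncated") <- nrow(out) < k
  out
}

#' Propagate every seed gene independently
#'
#' Runs one RWR per seed gene (seeds are propagated one at a time, each
#' producing its own affinity profile and top-k vicinity).
#'
#' @param net A [functional_network()].
#' @param seed_genes Character vector of seed genes, or a `seed_set` tibble
#'   from [build_seed_set()].
#' @param k Vicinity size.
#' @param strict If `TRUE`, a seed absent from the network is an error;
#'   otherwise it is skipped with a warning.
#' @inheritParams rwr
#' @return A named list (one element per propagated seed), each with
#'   `profile` and `vicinity`.
#' @export
propagate_all <- function(net, seed_genes, r = 0.7, tol = 1e-10, k = 20,
                          max_iter = 10000, strict = FALSE) {
  if (inherits(seed_genes, "seed_set") || is.data.frame(seed_genes))
    seed_genes <- seed_genes$gene_id
  seed_genes <- sort(unique(seed_genes))
  missing <- setdiff(seed_genes, net$nodes)
  if (length(missing) > 0) {
    msg <- paste0("seed genes not in network: ", paste(missing, collapse = ", "))
    if (strict) abort(msg, class = "evnetprop_seed_error")
    warn(paste0(msg, " (skipped)"))
    seed_genes <- setdiff(seed_genes, missing)
  }
  assert_that(length(seed_genes) > 0, "no seed genes present in the network")
  res <- lapply(seed_genes, function(s) {
    prof <- rwr(net, s, r = r, tol = tol, max_iter = max_iter)
    list(profile = prof, vicinity = top_k_vicinity(prof, k = k))
  })
  stats::setNames(res, seed_genes)
}
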