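## Epsilon-relaxed minimum spanning networks and median-joining haplotype
## networks over biallelic allele strings. These are the clustering machinery
## behind locus-scale haplotype genealogy figures: observed haplotypes as
## sized circles, inferred median haplotypes as unlabelled internal nodes,
## edges weighted by Hamming distance.

#' Hamming distance between allele strings
#'
#' @param a,b Character strings of equal length.
#' @return Number of differing positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("length mismatch: ", nchar(a), " vs ", nchar(b))
  }
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## Pairwise Hamming distance matrix of a character vector of strings.
hamming_matrix <- function(strings) {
  mat <- do.call(rbind, strsplit(strings, ""))
  n <- length(strings)
  d <- matrix(0L, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
      }
    }
  }
  d
}

## Prim MST total cost of a distance matrix.
mst_cost <- function(d) {
  n <- nrow(d)
  if (n <= 1) return(0L)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  cost <- 0L
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    cost <- cost + best[v]
    in_tree[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  cost
}

## sigma[i, j]: smallest distance level w such that i and j are connected
## using all edges of weight <= w (the epsilon-MSN connection level).
connection_levels <- function(d) {
  n <- nrow(d)
  sigma <- matrix(0L, n, n)
  if (n <= 1) return(sigma)
  comp <- seq_len(n)
  for (w in sort(unique(d[upper.tri(d)]))) {
    idx <- which(d == w & upper.tri(d), arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      ci <- comp[idx[r, 1]]; cj <- comp[idx[r, 2]]
      if (ci != cj) comp[comp == cj] <- ci
    }
    unresolved <- which(sigma == 0L & upper.tri(sigma), arr.ind = TRUE)
    for (r in seq_len(nrow(unresolved))) {
      i <- unresolved[r, 1]; j <- unresolved[r, 2]
      if (comp[i] == comp[j]) sigma[i, j] <- sigma[j, i] <- w
    }
    if (all(comp == comp[1])) break
  }
  sigma
}

new_haplo_network <- function(nodes, edges, epsilon, cost) {
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon,
                 cost = cost), class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("haplo_network: ", nrow(x$nodes), " nodes (",
      sum(x$nodes$type == "median"), " inferred medians), ",
      nrow(x$edges), " edges, epsilon=", x$epsilon,
      ", spanning cost=", x$cost, "\n", sep = "")
  invisible(x)
}

## Build the epsilon-relaxed MSN over a set of strings (internal core).
msn_core <- function(strings, names, types, n_members, epsilon) {
  d <- hamming_matrix(strings)
  n <- length(strings)
  edges <- data.frame(from = character(0), to = character(0),
                      weight = integer(0), stringsAsFactors = FALSE)
  if (n > 1) {
    sigma <- connection_levels(d)
    keep <- which(upper.tri(d) & d <= sigma + epsilon, arr.ind = TRUE)
    edges <- data.frame(from = names[keep[, 1]], to = names[keep[, 2]],
                        weight = d[keep], stringsAsFactors = FALSE)
    edges <- edges[order(edges$weight, edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- data.frame(name = names, alleles = strings, type = types,
                      n_members = n_members, stringsAsFactors = FALSE)
  new_haplo_network(nodes, edges, epsilon, mst_cost(d))
}

#' Build an epsilon-relaxed minimum spanning network
#'
#' Contains every edge belonging to at least one minimum spanning tree, plus
#' (for `epsilon > 0`) all edges whose weight is within `epsilon` of the
#' distance level at which their two endpoints first become connected.
#'
#' @param haplotypes A [haplotype_set()] or character vector of allele strings.
#' @param epsilon Non-negative integer relaxation parameter (default 0).
#'
#' @return A `haplo_network`: node table (`name`, `alleles`, `type`,
#'   `n_members`), edge table (`from`, `to`, `weight`), `epsilon`, and `cost`
#'   (the minimum spanning cost over the node set).
#' @export
build_msn <- function(haplotypes, epsilon = 0L) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (inherits(haplotypes, "haplotype_set")) {
    strings <- haplotypes$alleles
    names <- haplotypes$name
    n_members <- vapply(haplotypes$members, length, integer(1))
  } else {
    strings <- as.character(haplotypes)
    names <- if (!is.null(names(haplotypes))) names(haplotypes)
             else paste0("H", seq_along(strings))
    n_members <- rep(1L, length(strings))
  }
  if (length(strings) < 1) stop("need at least one haplotype")
  if (length(unique(nchar(strings))) != 1) {
    stop("allele strings must all have the same length")
  }
  msn_core(strings, names, rep("observed", length(strings)), n_members,
           as.integer(epsilon))
}

## Position-wise majority string of three equal-length strings (the
## quasi-median; for biallelic data three distinct states cannot occur, so
## the quasi-median is exactly the majority string).
majority_string <- function(a, b, c) {
  m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]], strsplit(c, "")[[1]])
  paste(apply(m, 2L, function(col) names(which.max(table(col)))),
        collapse = "")
}

#' Build a median-joining haplotype network
#'
#' Iterates the median-joining scheme for biallelic data: starting from the
#' observed haplotypes, repeatedly consider the quasi-medians (position-wise
#' majority strings) of node triples and add the median that most reduces the
#' minimum spanning cost of the node set; stop when no median reduces the
#' cost. Inferred medians whose removal leaves the spanning cost unchanged
#' are then pruned (observed haplotypes are never pruned), and the final
#' epsilon-relaxed minimum spanning network is built over the remaining
#' nodes. Every addition strictly reduces an integer cost bounded below, so
#' the iteration terminates.
#'
#' @param haplotypes A [haplotype_set()] or character vector of equal-length
#'   allele strings.
#' @param epsilon Non-negative integer relaxation parameter (default 0, the
#'   usual default of median-joining software).
#'
#' @return A `haplo_network`; inferred medians are named `mv1`, `mv2`, ...
#'   with `type = "median"` and `n_members = 0`.
#' @export
build_mj_network <- function(haplotypes, epsilon = 0L) {
  if (inherits(haplotypes, "haplotype_set")) {
    obs <- haplotypes$alleles
    obs_names <- haplotypes$name
    n_members <- vapply(haplotypes$members, length, integer(1))
  } else {
    obs <- as.character(haplotypes)
    obs_names <- if (!is.null(names(haplotypes))) names(haplotypes)
                 else paste0("H", seq_along(obs))
    n_members <- rep(1L, length(obs))
  }
  if (length(obs) < 1) stop("need at least one haplotype")
  if (length(unique(nchar(obs))) != 1) {
    stop("allele strings must all have the same length")
  }
  medians <- character(0)
  repeat {
    cur <- c(obs, medians)
    cost0 <- mst_cost(hamming_matrix(cur))
    if (length(cur) < 3) break
    cands <- character(0)
    trips <- combn(length(cur), 3)
    for (t in seq_len(ncol(trips))) {
      m <- majority_string(cur[trips[1, t]], cur[trips[2, t]],
                           cur[trips[3, t]])
      if (!m %in% cur) cands <- c(cands, m)
    }
    cands <- unique(cands)
    if (length(cands) == 0) break
    costs <- vapply(cands, function(m) {
      mst_cost(hamming_matrix(c(cur, m)))
    }, numeric(1))
    if (min(costs) >= cost0) break
    ## deterministic tie-break: lexicographically smallest best median
    best <- sort(cands[costs == min(costs)])[1]
    medians <- c(medians, best)
  }
  ## prune medians that no longer pay for themselves
  repeat {
    cur_cost <- mst_cost(hamming_matrix(c(obs, medians)))
    removable <- NULL
    for (i in seq_along(medians)) {
      without <- mst_cost(hamming_matrix(c(obs, medians[-i])))
      if (without <= cur_cost) { removable <- i; break }
    }
    if (is.null(removable)) break
    medians <- medians[-removable]
  }
  all_strings <- c(obs, medians)
  all_names <- c(obs_names,
                 if (length(medians) > 0) paste0("mv", seq_along(medians)))
  types <- c(rep("observed", length(obs)), rep("median", length(medians)))
  msn_core(all_strings, all_names, types,
           c(n_members, rep(0L, length(medians))), as.integer(epsilon))
}

#' Export a haplotype network
#'
#' Writes the edge list as TSV (`node_a`, `node_b`, `weight`, plus node
#' types) and optionally GraphML for network viewers, with the node table
#' (member counts for circle-size rendering) as a second TSV.
#'
#' @param network A `haplo_network`.
#' @param edge_path Path for the edge-list TSV.
#' @param node_path Optional path for the node-table TSV.
#' @param graphml_path Optional path for a GraphML export.
#' @param comments Optional provenance comment lines for the TSVs.
#'
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, edge_path, node_path = NULL,
                          graphml_path = NULL, comments = NULL) {
  stopifnot(inherits(network, "haplo_network"))
  type_of <- setNames(network$nodes$type, network$nodes$name)
  edges <- network$edges
  out <- data.frame(node_a = edges$from, node_b = edges$to,
                    weight = edges$weight,
                    type_a = unname(type_of[edges$from]),
                    type_b = unname(type_of[edges$to]),
                    stringsAsFactors = FALSE)
  write_table(out, edge_path, comments = comments)
  paths <- edge_path
  if (!is.null(node_path)) {
    write_table(network$nodes, node_path, comments = comments)
    paths <- c(paths, node_path)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      network$edges, directed = FALSE,
      vertices = network$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
    paths <- c(paths, graphml_path)
  }
  invisible(paths)
}
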