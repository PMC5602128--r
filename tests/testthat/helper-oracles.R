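## Independent oracles used against the package implementation. These are
## deliberately separate, simple implementations: Prim MST on a distance
## matrix, brute-force Steiner search over all candidate internal strings,
## the textbook closed-form 2x2 chi-square, and a gene-dropping Monte-Carlo
## estimate of identity by descent.

oracle_hamming_matrix <- function(strings) {
  m <- do.call(rbind, strsplit(strings, ""))
  n <- length(strings)
  d <- matrix(0L, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

oracle_mst_cost <- function(d) {
  n <- nrow(d)
  if (n <= 1) return(0L)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  cost <- 0L
  for (s in 1:(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    cost <- cost + best[v]
    in_tree[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  cost
}

all_binary_strings <- function(L) {
  apply(expand.grid(rep(list(c("R", "A")), L)), 1, paste, collapse = "")
}

## Minimum spanning cost achievable by adding up to n-2 internal strings,
## searched exhaustively over every candidate string of length L.
oracle_steiner_cost <- function(obs, L) {
  cand <- setdiff(all_binary_strings(L), obs)
  best <- oracle_mst_cost(oracle_hamming_matrix(obs))
  maxk <- min(max(0L, length(obs) - 2L), length(cand))
  for (k in seq_len(maxk)) {
    for (idx in as.data.frame(combn(length(cand), k))) {
      cost <- oracle_mst_cost(oracle_hamming_matrix(c(obs, cand[idx])))
      if (cost < best) best <- cost
    }
  }
  best
}

oracle_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  (a * d - b * c)^2 * n / ((a + b) * (c + d) * (a + c) * (b + d))
}

## Gene dropping: inbred lines carry a single allele; each offspring locus
## copies a uniformly chosen parent's allele; an unknown parent side
## contributes a fresh unique allele. COP is estimated as the match
## probability across drops.
gene_drop_cop <- function(x, y, ped, n_drops = 1e5, seed = 1) {
  set.seed(seed)
  n <- length(ped$name)
  idx <- setNames(seq_len(n), ped$name)
  ids <- matrix(NA_real_, n, n_drops)
  fresh <- n
  for (i in order(ped$depth)) {
    p1 <- ped$parent1[i]; p2 <- ped$parent2[i]
    if (p1 == "" && p2 == "") {
      ids[i, ] <- i
      next
    }
    pick1 <- runif(n_drops) < 0.5
    row <- numeric(n_drops)
    for (side in 1:2) {
      sel <- if (side == 1) pick1 else !pick1
      parent <- if (side == 1) p1 else p2
      if (parent == "") {
        k <- sum(sel)
        row[sel] <- fresh + seq_len(k)
        fresh <- fresh + k
      } else {
        row[sel] <- ids[idx[[parent]], sel]
      }
    }
    ids[i, ] <- row
  }
  mean(ids[idx[[x]], ] == ids[idx[[y]], ])
}

## Naive (un-memoized) COP recursion, independent of the package internals.
naive_cop <- function(x, y, ped) {
  idx <- setNames(seq_along(ped$name), ped$name)
  rec <- function(a, b) {
    if (a == b) return(1)
    if (ped$depth[idx[[a]]] < ped$depth[idx[[b]]]) { t <- a; a <- b; b <- t }
    i <- idx[[a]]
    v1 <- if (ped$parent1[i] == "") 0 else rec(ped$parent1[i], b)
    v2 <- if (ped$parent2[i] == "") 0 else rec(ped$parent2[i], b)
    0.5 * (v1 + v2)
  }
  rec(x, y)
}
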