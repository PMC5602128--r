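## Coefficient of parentage (COP) over breeding pedigrees of inbred lines.
## Convention: fully inbred lines, so the self-COP is 1 and distinct founders
## have COP 0; an unknown parent contributes no relatedness.

#' Construct a pedigree
#'
#' A directed acyclic parent graph over named lines. Founders have unknown
#' (empty) parents; every other line has up to two named parents that must
#' themselves be in the table.
#'
#' @param df `data.frame` with character columns `name`, `parent1`,
#'   `parent2`; empty string or `NA` denotes an unknown parent.
#'
#' @return An object of class `pedigree` with elements `name`, `parent1`,
#'   `parent2` and `depth` (generation order; founders have depth 0).
#' @export
pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("name", "parent1", "parent2")
  if (!all(required %in% names(df))) {
    stop("pedigree needs columns: ", paste(required, collapse = ", "))
  }
  name <- as.character(df$name)
  p1 <- as.character(df$parent1); p1[is.na(p1)] <- ""
  p2 <- as.character(df$parent2); p2[is.na(p2)] <- ""
  if (anyDuplicated(name)) stop("duplicated line names in pedigree")
  known <- c(p1, p2); known <- known[known != ""]
  absent <- setdiff(known, name)
  if (length(absent) > 0) {
    stop("parents not present as lines: ", paste(absent, collapse = ", "))
  }
  if (any(p1 == name | p2 == name)) stop("a line cannot be its own parent")
  ## generation depth by iterative resolution; failure to resolve = cycle
  n <- length(name)
  depth <- ifelse(p1 == "" & p2 == "", 0L, NA_integer_)
  idx <- setNames(seq_len(n), name)
  for (pass in seq_len(n + 1L)) {
    unresolved <- which(is.na(depth))
    if (length(unresolved) == 0) break
    progressed <- FALSE
    for (i in unresolved) {
      d1 <- if (p1[i] == "") -1L else depth[idx[[p1[i]]]]
      d2 <- if (p2[i] == "") -1L else depth[idx[[p2[i]]]]
      if (!is.na(d1) && !is.na(d2)) {
        depth[i] <- max(d1, d2) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) stop("cycle detected in pedigree")
  }
  structure(list(name = name, parent1 = p1, parent2 = p2, depth = depth),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree: ", length(x$name), " lines, ",
      sum(x$parent1 == "" & x$parent2 == ""), " founders, max depth ",
      max(x$depth), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.pedigree <- function(x, ...) {
  data.frame(name = x$name, parent1 = x$parent1, parent2 = x$parent2,
             stringsAsFactors = FALSE)
}

#' Read / write pedigree tables
#'
#' TSV with columns `name`, `parent1`, `parent2`; empty = unknown parent.
#'
#' @param path File path.
#' @param ped A [pedigree()] (writer only).
#' @param comments Optional provenance comment lines (writer only).
#' @return A [pedigree()] for the reader; `path` invisibly for the writer.
#' @export
read_pedigree <- function(path) {
  df <- read_table(path)
  for (col in c("parent1", "parent2")) {
    df[[col]][is.na(df[[col]])] <- ""
  }
  pedigree(df)
}

#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path, comments = NULL) {
  write_table(as.data.frame(ped), path, comments = comments)
}

#' Coefficient of parentage between two lines
#'
#' Inbred-line recursion: `cop(x, x) = 1`; otherwise the line with the larger
#' generation depth (the descendant side) is expanded as the mean of the COPs
#' of the other line with its two parents, an unknown parent contributing 0.
#' Distinct founders therefore have COP 0. Values are memoized across a
#' `cop_matrix()` computation.
#'
#' @param x,y Line names.
#' @param ped A [pedigree()].
#' @param cache Optional environment used for memoization (internal).
#'
#' @return COP value in `[0, 1]`.
#' @export
cop <- function(x, y, ped, cache = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  idx <- setNames(seq_along(ped$name), ped$name)
  for (line in c(x, y)) {
    if (!line %in% ped$name) stop("unknown line name: ", line)
  }
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  cop_rec(x, y, ped, idx, cache)
}

cop_rec <- function(a, b, ped, idx, cache) {
  if (a == b) return(1)
  key <- if (a < b) paste0(a, "\r", b) else paste0(b, "\r", a)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  ## expand the deeper line; ancestors always have strictly smaller depth,
  ## so the expanded line is never an ancestor of the other
  if (ped$depth[idx[[a]]] < ped$depth[idx[[b]]]) { tmp <- a; a <- b; b <- tmp }
  i <- idx[[a]]
  p1 <- ped$parent1[i]; p2 <- ped$parent2[i]
  v1 <- if (p1 == "") 0 else cop_rec(p1, b, ped, idx, cache)
  v2 <- if (p2 == "") 0 else cop_rec(p2, b, ped, idx, cache)
  val <- 0.5 * (v1 + v2)
  cache[[key]] <- val
  val
}

#' COP matrix over a set of lines
#'
#' @param lines Character vector of line names (all in the pedigree).
#' @param ped A [pedigree()].
#'
#' @return A symmetric numeric matrix with unit diagonal, dimnames = lines.
#' @export
cop_matrix <- function(lines, ped) {
  stopifnot(inherits(ped, "pedigree"))
  lines <- as.character(lines)
  idx <- setNames(seq_along(ped$name), ped$name)
  missing <- setdiff(lines, ped$name)
  if (length(missing) > 0) {
    stop("unknown line name: ", paste(missing, collapse = ", "))
  }
  cache <- new.env(parent = emptyenv())
  n <- length(lines)
  m <- diag(1, n)
  dimnames(m) <- list(lines, lines)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        m[i, j] <- m[j, i] <- cop_rec(lines[i], lines[j], ped, idx, cache)
      }
    }
  }
  m
}

#' Mean within-group coefficient of parentage
#'
#' Mean COP over all unordered distinct pairs of the usable lines. Lines
#' absent from the pedigree table (unrecorded pedigree) are excluded first;
#' recorded founders participate.
#'
#' @param lines Character vector of line names.
#' @param ped A [pedigree()].
#'
#' @return A list with `mean`, `n_pairs` (`n*(n-1)/2`), `n_lines` and
#'   `excluded` (names dropped for missing pedigree records).
#' @export
mean_cop <- function(lines, ped) {
  stopifnot(inherits(ped, "pedigree"))
  lines <- unique(as.character(lines))
  excluded <- setdiff(lines, ped$name)
  usable <- setdiff(lines, excluded)
  if (length(excluded) > 0) {
    message("excluding ", length(excluded), " line(s) with unrecorded pedigree")
  }
  n <- length(usable)
  if (n < 2) stop("fewer than 2 usable lines")
  m <- cop_matrix(usable, ped)
  vals <- m[upper.tri(m)]
  list(mean = mean(vals), n_pairs = as.integer(n * (n - 1) / 2),
       n_lines = n, excluded = excluded)
}

#' Mean between-group coefficient of parentage
#'
#' Mean COP over the `|a| * |b|` cross pairs of two disjoint groups.
#'
#' @param group_a,group_b Disjoint character vectors of line names.
#' @param ped A [pedigree()].
#'
#' @return A list with `mean` and `n_pairs` (`|a| * |b|`).
#' @export
mean_cop_between <- function(group_a, group_b, ped) {
  stopifnot(inherits(ped, "pedigree"))
  group_a <- unique(as.character(group_a))
  group_b <- unique(as.character(group_b))
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("groups must be nonempty")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  }
  idx <- setNames(seq_along(ped$name), ped$name)
  missing <- setdiff(c(group_a, group_b), ped$name)
  if (length(missing) > 0) {
    stop("unknown line name: ", paste(missing, collapse = ", "))
  }
  cache <- new.env(parent = emptyenv())
  vals <- outer(group_a, group_b,
                Vectorize(function(x, y) cop_rec(x, y, ped, idx, cache)))
  list(mean = mean(vals),
       n_pairs = as.integer(length(group_a) * length(group_b)))
}

#' Table-style mean-COP summary for haplotype groups
#'
#' Produces the usual germplasm-survey summary: one row per group with the
#' mean COP (2 decimals) and the pair count.
#'
#' @param groups Named list of character vectors (line names per group).
#' @param ped A [pedigree()].
#' @param allele_of Optional named character vector mapping group name to an
#'   allele-class label.
#'
#' @return A `data.frame` with columns `group`, `allele`, `mean_cop`,
#'   `n_pairs`.
#' @export
cop_summary <- function(groups, ped, allele_of = NULL) {
  rows <- lapply(names(groups), function(g) {
    res <- mean_cop(groups[[g]], ped)
    data.frame(group = g,
               allele = if (!is.null(allele_of) && g %in% names(allele_of))
                 allele_of[[g]] else NA_character_,
               mean_cop = round(res$mean, 2),
               n_pairs = res$n_pairs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
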