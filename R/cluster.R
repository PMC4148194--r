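#' Pairwise Jaccard distance matrix of cavity fields
#'
#' Symmetric matrix of [jaccard_distance()]s between solids on a common
#' lattice.  A pair of empty solids gets distance 0 (identical emptiness)
#' with a warning, since the Jaccard ratio is 0/0 there.
#'
#' @param fields list of solid regions (>= 2) on congruent lattices.
#' @param labels character labels, one per field.
#' @return object of class `"ep_distmatrix"`: list with `labels` and the
#'   matrix `d`.
#' @export
pairwise_jaccard <- function(fields, labels = NULL) {
  n <- length(fields)
  if (n < 2) stop("need at least two fields to build a distance matrix")
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  stopifnot(length(labels) == n)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is_empty_solid(fields[[i]]) && is_empty_solid(fields[[j]])) {
      warning(sprintf("both '%s' and '%s' are empty; distance set to 0",
                      labels[i], labels[j]), call. = FALSE)
      dij <- 0
    } else {
      dij <- jaccard_distance(fields[[i]], fields[[j]])
    }
    d[i, j] <- d[j, i] <- dij
  }
  distance_matrix(d, labels)
}

#' Labeled symmetric distance matrix
#'
#' @param d symmetric numeric matrix, zero diagonal, no NA.
#' @param labels optional labels (default from dimnames).
#' @export
distance_matrix <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (is.null(labels)) labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(d)))
  stopifnot(nrow(d) == ncol(d), length(labels) == nrow(d))
  if (anyNA(d)) stop("distance matrix contains NA")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (any(d < 0)) stop("distances must be nonnegative")
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, d = d), class = "ep_distmatrix")
}

#' UPGMA hierarchical clustering
#'
#' Unweighted pair group method with arithmetic mean: iteratively merge the
#' closest pair of clusters at height `d/2` (the cophenetic convention used
#' by Phylip's neighbor in UPGMA mode) and update distances to other clusters
#' by the size-weighted arithmetic mean.  Ties are broken deterministically
#' by the smallest pair of original label positions.
#'
#' @param dm an [distance_matrix()] (or bare symmetric matrix).
#' @return object of class `"ep_dendrogram"`: `labels`, an `(n-1) x 2`
#'   hclust-style `merge` matrix (negative entries are leaves) and the vector
#'   of merge `heights` (non-decreasing).
#' @export
upgma <- function(dm) {
  if (!inherits(dm, "ep_distmatrix")) dm <- distance_matrix(dm)
  labels <- dm$labels
  n <- length(labels)
  if (n < 2) stop("need at least two items to cluster")
  d <- dm$d
  active <- seq_len(n)           # column indices still in play
  size <- rep(1, n)
  node <- -seq_len(n)            # hclust coding: -leaf, +merge index
  minlab <- seq_len(n)           # smallest original index in each cluster
  merge <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (m in seq_len(n - 1)) {
    best <- NULL
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      key <- sort(c(minlab[i], minlab[j]))
      if (is.null(best) || d[i, j] < best$d - 1e-15 ||
          (abs(d[i, j] - best$d) <= 1e-15 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = d[i, j], key = key)
      }
    }
    i <- best$i; j <- best$j
    heights[m] <- best$d / 2
    merge[m, ] <- as.integer(c(node[i], node[j]))
    # size-weighted arithmetic mean update, cluster kept in slot i
    for (kk in active) {
      if (kk == i || kk == j) next
      d[i, kk] <- d[kk, i] <- (size[i] * d[i, kk] + size[j] * d[j, kk]) /
        (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    minlab[i] <- min(minlab[i], minlab[j])
    node[i] <- m
    active <- setdiff(active, j)
  }
  structure(list(labels = labels, merge = merge, heights = heights),
            class = "ep_dendrogram")
}

#' @export
print.ep_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram over %d leaves, root height %.6g\n",
              length(x$labels), max(x$heights)))
  cat(to_newick(x), "\n")
  invisible(x)
}

#' Cophenetic distances implied by a dendrogram
#'
#' `coph(i, j)` is twice the height of the lowest merge joining leaves `i`
#' and `j`; on ultrametric input UPGMA reproduces the input matrix exactly.
#'
#' @param t an [upgma()] dendrogram.
#' @export
cophenetic_distances <- function(t) {
  n <- length(t$labels)
  members <- vector("list", n - 1)
  coph <- matrix(0, n, n, dimnames = list(t$labels, t$labels))
  get_members <- function(code) {
    if (code < 0) -code else members[[code]]
  }
  for (m in seq_len(n - 1)) {
    a <- get_members(t$merge[m, 1])
    b <- get_members(t$merge[m, 2])
    for (x in a) for (y in b) coph[x, y] <- coph[y, x] <- 2 * t$heights[m]
    members[[m]] <- c(a, b)
  }
  coph
}

sanitize_label <- function(x) {
  x <- gsub("\\s+", "_", x)
  gsub("[(),:;]", "", x)
}

#' Serialize a dendrogram to Newick
#'
#' Branch lengths are height differences between a node and its parent;
#' labels are sanitized (whitespace to underscores, parentheses, commas,
#' colons and semicolons stripped).
#'
#' @param t an [upgma()] dendrogram.
#' @return a Newick string terminated with `";"`.
#' @export
to_newick <- function(t) {
  stopifnot(inherits(t, "ep_dendrogram"))
  fmt <- function(x) sprintf("%.10g", x)
  render <- function(code, parent_height) {
    if (code < 0) {
      return(paste0(sanitize_label(t$labels[-code]), ":",
                    fmt(parent_height)))
    }
    h <- t$heights[code]
    paste0("(", render(t$merge[code, 1], h), ",",
           render(t$merge[code, 2], h), "):", fmt(parent_height - h))
  }
  root <- length(t$heights)
  h <- t$heights[root]
  paste0("(", render(t$merge[root, 1], h), ",",
         render(t$merge[root, 2], h), ");")
}

#' Write a distance matrix as a delimited file
#' @param dm an [distance_matrix()].
#' @param path file path.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "ep_distmatrix"))
  utils::write.table(data.frame(label = dm$labels, dm$d,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
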