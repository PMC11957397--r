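#' Patristic distance matrix from a phylogenetic tree
#'
#' @param tree an `ape::phylo` object, a newick string, or a path to a
#'   newick file. Branch lengths are required; leaf labels must be unique.
#' @return Symmetric numeric matrix of patristic distances (sums of branch
#'   lengths along tip-to-tip paths) with zero diagonal.
#' @export
distances_from_tree <- function(tree) {
  if (is.character(tree)) {
    tree <- if (length(tree) == 1 && file.exists(tree)) {
      ape::read.tree(tree)
    } else {
      ape::read.tree(text = tree)
    }
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("tree has missing branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  D <- ape::cophenetic.phylo(tree)
  D[order(rownames(D)), order(colnames(D)), drop = FALSE]
}

validate_distance_matrix <- function(D) {
  stopifnot(is.matrix(D), is.numeric(D), nrow(D) == ncol(D))
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("taxon", seq_len(nrow(D)))
  }
  if (max(abs(D - t(D))) > 1e-10) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-10)) stop("distance matrix diagonal is not zero")
  if (any(D < 0)) stop("distance matrix has negative entries")
  D
}

#' Default dendrogram cut heights from distance quantiles
#'
#' Picks the three cut heights as quantiles of the off-diagonal pairwise
#' distance distribution, nudging ties apart so the heights are strictly
#' increasing.
#'
#' @param D symmetric distance matrix.
#' @param quantiles three increasing probabilities in (0, 1), default
#'   `c(0.25, 0.5, 0.75)`.
#' @return Numeric vector of three strictly increasing heights.
#' @export
default_cut_heights <- function(D, quantiles = c(0.25, 0.5, 0.75)) {
  D <- validate_distance_matrix(D)
  stopifnot(length(quantiles) == 3, all(diff(quantiles) > 0),
            quantiles[1] > 0, quantiles[3] < 1)
  d <- D[upper.tri(D)]
  if (length(d) == 0) stop("need at least two taxa")
  if (max(d) - min(d) < 1e-12)
    stop("all pairwise distances identical; supply explicit cut heights")
  h <- stats::quantile(d, quantiles, names = FALSE)
  eps <- 1e-8 * max(d)
  for (i in 2:3) if (h[i] <= h[i - 1]) h[i] <- h[i - 1] + eps
  h
}

#' Three-level phylogenetic hierarchy by complete-linkage clustering
#'
#' Builds one complete-linkage dendrogram from the taxon distance matrix and
#' cuts it at three increasing heights, yielding nested partitions labelled
#' `"S"` (finest), `"G"`, and `"F"` (coarsest). Nestedness is automatic
#' because all three partitions come from the same dendrogram. Cluster ids
#' are deterministic: clusters are numbered by their smallest member taxon
#' index.
#'
#' @param D symmetric taxon distance matrix with taxon ids as dimnames.
#' @param cut_heights three strictly increasing positive heights; default
#'   [default_cut_heights()] of `D`.
#' @return An object of class `"phylo_hierarchy"`: `assignment` (per level,
#'   named integer vector taxon -> cluster), `parent` (maps `S` cluster ->
#'   `G` cluster and `G` -> `F`), `children` (inverse maps, plus `S` ->
#'   member taxa), `cut_heights`, `taxon_ids`.
#' @export
build_hierarchy <- function(D, cut_heights = NULL) {
  D <- validate_distance_matrix(D)
  if (is.null(cut_heights)) cut_heights <- default_cut_heights(D)
  stopifnot(length(cut_heights) == 3, all(cut_heights > 0))
  if (any(diff(cut_heights) <= 0))
    stop("cut_heights must be strictly increasing (S < G < F)")
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  assignment <- lapply(cut_heights, function(h) {
    cl <- stats::cutree(hc, h = h)
    # renumber so cluster ids follow the smallest member taxon index
    stats::setNames(match(cl, unique(cl)), rownames(D))
  })
  names(assignment) <- c("S", "G", "F")
  parent <- list(
    S = vapply(split(assignment$G, assignment$S), function(g) {
      u <- unique(g)
      if (length(u) != 1) stop("partitions are not nested")  # unreachable
      u
    }, integer(1)),
    G = vapply(split(assignment$F, assignment$G), function(f) {
      u <- unique(f)
      if (length(u) != 1) stop("partitions are not nested")
      u
    }, integer(1)))
  children <- list(
    F = split(seq_along(parent$G), unname(parent$G)),     # F -> G clusters
    G = split(seq_along(parent$S), unname(parent$S)),     # G -> S clusters
    S = split(seq_along(assignment$S), unname(assignment$S)))  # S -> taxa
  structure(list(assignment = assignment, parent = parent,
                 children = children, cut_heights = cut_heights,
                 taxon_ids = rownames(D), hclust = hc),
            class = "phylo_hierarchy")
}

#' @export
print.phylo_hierarchy <- function(x, ...) {
  n_cl <- vapply(x$assignment, function(a) length(unique(a)), integer(1))
  cat(sprintf(
    "phylo_hierarchy over %d taxa (complete linkage)\n  clusters: S = %d, G = %d, F = %d\n  cut heights: %s\n",
    length(x$taxon_ids), n_cl["S"], n_cl["G"], n_cl["F"],
    paste(signif(x$cut_heights, 4), collapse = ", ")))
  invisible(x)
}

#' Hierarchy assignment table
#'
#' @param x a `"phylo_hierarchy"`.
#' @param ... unused.
#' @return data.frame with columns `taxon_id`, `S`, `G`, `F`.
#' @export
as.data.frame.phylo_hierarchy <- function(x, ...) {
  data.frame(taxon_id = x$taxon_ids,
             S = unname(x$assignment$S),
             G = unname(x$assignment$G),
             F = unname(x$assignment$F),
             stringsAsFactors = FALSE)
}

#' Aggregate a normalized count matrix to a hierarchy level
#'
#' Cluster abundance is the sum of member taxa normalized counts over
#' non-missing members, log10-transformed with the usual offset. An
#' aggregated entry is missing only when every member entry in that sample
#' is missing.
#'
#' @param normalized normalized count matrix (samples x taxa).
#' @param hierarchy a `"phylo_hierarchy"`.
#' @param level one of `"S"`, `"G"`, `"F"`.
#' @param mask optional logical matrix marking taxon-level entries as
#'   missing (excluded from the sums).
#' @param offset pseudo-count, default 1.01.
#' @return A [log_matrix()] with one column per cluster.
#' @export
aggregate_matrix <- function(normalized, hierarchy, level = c("S", "G", "F"),
                             mask = NULL, offset = 1.01) {
  level <- match.arg(level)
  stopifnot(inherits(hierarchy, "phylo_hierarchy"))
  normalized <- unclass(normalized)[, hierarchy$taxon_ids, drop = FALSE]
  if (is.null(mask)) mask <- matrix(FALSE, nrow(normalized), ncol(normalized))
  cl <- hierarchy$assignment[[level]]
  n_cl <- length(unique(cl))
  obs <- normalized * !mask
  vals <- t(rowsum(t(obs), cl))             # sample x cluster sums
  miss <- t(rowsum(t(1 - mask), cl)) == 0   # all members missing
  colnames(vals) <- paste0(level, seq_len(n_cl))
  out <- log_matrix(log10(vals + offset), miss, offset)
  rownames(out$values) <- rownames(normalized)
  dimnames(out$missing_mask) <- dimnames(out$values)
  out
}
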