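#' Principal component analysis of a genotype matrix
#'
#' Mean-imputes missing dosages per marker, centers columns (optionally
#' scales them) and eigendecomposes the accession covariance via SVD.
#'
#' @param g a [genotype_matrix()] with at least 2 accessions and 1 marker.
#' @param n_components number of components to return scores for. Default 10.
#' @param scale. scale markers to unit variance? Default `FALSE`
#'   (centering only).
#' @return A list of class `pca_result`: `scores` (accession x component),
#'   `eigenvalues` (all computed, non-increasing) and `contribution_ratios`
#'   (fraction of total variance per component; sums to 1 over all
#'   `min(n - 1, m)` components).
#' @export
geno_pca <- function(g, n_components = 10, scale. = FALSE) {
  stopifnot(n_accessions(g) >= 2, n_markers(g) >= 1)
  x <- impute_dosage(g$dosage)
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) stop("cannot scale monomorphic (zero-variance) markers")
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ev <- pr$sdev^2
  k <- min(n_components, ncol(pr$x))
  structure(list(
    scores = pr$x[, seq_len(k), drop = FALSE],
    eigenvalues = ev,
    contribution_ratios = ev / sum(ev)
  ), class = "pca_result")
}

#' Euclidean distance matrix over a marker subsample
#'
#' Subsamples markers uniformly without replacement (deterministically for a
#' given seed), mean-imputes missing dosages — the same convention PCA uses,
#' so distances and PCA see the same matrix — and returns the pairwise
#' Euclidean distance between accession dosage vectors.
#'
#' @param g a [genotype_matrix()].
#' @param n_markers_subset number of markers to subsample; `NULL` (default)
#'   uses all markers.
#' @param seed random seed for the subsample.
#' @return A symmetric numeric matrix with zero diagonal and accession
#'   dimnames; the chosen marker indices are attached as
#'   `attr(, "marker_subset")`.
#' @export
euclidean_distance_matrix <- function(g, n_markers_subset = NULL, seed = 1L) {
  idx <- seq_len(n_markers(g))
  if (!is.null(n_markers_subset)) {
    stopifnot(n_markers_subset <= n_markers(g))
    set.seed(seed)
    idx <- sort(sample(idx, n_markers_subset))
  }
  x <- impute_dosage(g$dosage[, idx, drop = FALSE])
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(g$accessions, g$accessions)
  attr(d, "marker_subset") <- idx
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei neighbor joining (via [ape::nj()]): iterative Q-matrix
#' minimization, pair joining and distance reduction, yielding an unrooted
#' binary tree with branch lengths. For a tree-additive input matrix the
#' generating topology and branch lengths are recovered exactly.
#'
#' @param d symmetric distance matrix (or `dist`) over >= 3 taxa.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  ape::nj(stats::as.dist(d))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples marker columns with replacement (the standard phylogenetic
#' bootstrap), recomputes the distance matrix and NJ tree for each
#' replicate, and tallies how many replicates contain each bipartition
#' (internal edge) of the original tree.
#'
#' @param g the [genotype_matrix()] the tree was built from.
#' @param tree the NJ tree ([ape::phylo]) whose edges are scored.
#' @param n_reps number of bootstrap replicates.
#' @param n_markers_subset marker subsample size used for the original
#'   tree; replicates resample this many columns (with replacement) from
#'   the same subsample. `NULL` uses all markers.
#' @param seed seed; the subsample is re-derived with it exactly as in
#'   [euclidean_distance_matrix()], so pass the same value.
#' @return `tree` with `node.label` set to the support counts (in
#'   `[0, n_reps]`) of the corresponding internal edges.
#' @export
bootstrap_support <- function(g, tree, n_reps, n_markers_subset = NULL,
                              seed = 1L) {
  idx <- seq_len(n_markers(g))
  if (!is.null(n_markers_subset)) {
    set.seed(seed)
    idx <- sort(sample(idx, n_markers_subset))
  }
  x <- impute_dosage(g$dosage[, idx, drop = FALSE])
  rownames(x) <- g$accessions
  if (n_reps == 0) {
    tree$node.label <- rep(0L, tree$Nnode)
    return(tree)
  }
  set.seed(seed + 1L)
  supp <- ape::boot.phylo(
    tree, x,
    FUN = function(mat) ape::nj(stats::dist(mat)),
    B = n_reps, rooted = FALSE, quiet = TRUE
  )
  supp[is.na(supp)] <- 0L  # basal node: no bipartition to assess
  tree$node.label <- supp
  tree
}

#' Cut a tree into varietal groups
#'
#' Removes the `k - 1` internal edges with the largest branch lengths (ties
#' broken by edge order in the tree) and labels the resulting connected
#' leaf components VG1..VGk in order of decreasing size. This is a
#' deterministic, parameter-light convention for delimiting varietal groups
#' on an NJ tree.
#'
#' @param tree an [ape::phylo] tree.
#' @param k number of groups, `1 <= k <=` number of internal edges + 1.
#' @return Named character vector mapping each leaf label to its group.
#' @export
cut_tree_groups <- function(tree, k) {
  n_tip <- length(tree$tip.label)
  edges <- tree$edge
  internal <- edges[, 2] > n_tip  # edge to an internal node = internal edge
  if (k < 1 || k > sum(internal) + 1) {
    stop("k must be between 1 and ", sum(internal) + 1)
  }
  drop <- integer(0)
  if (k > 1) {
    cand <- which(internal)
    cand <- cand[order(-tree$edge.length[cand], cand)]
    drop <- cand[seq_len(k - 1)]
  }
  keep <- setdiff(seq_len(nrow(edges)), drop)
  # union-find over nodes with the remaining edges
  n_nodes <- max(edges)
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (e in keep) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n_tip), find, 0)
  sizes <- table(comp)
  ordered <- names(sizes)[order(-as.integer(sizes), as.numeric(names(sizes)))]
  labels <- paste0("VG", match(as.character(comp), ordered))
  stats::setNames(labels, tree$tip.label)
}

#' Geographic enrichment of varietal groups
#'
#' Cross-tabulates group membership against geographic region, computes
#' expected counts from the contingency margins
#' (`group_total * region_total / grand_total`) and assigns to each group
#' the region with the largest observed/expected ratio (ties broken by
#' larger observed count, then lexicographically).
#'
#' @param groups named vector mapping accession id to group label (as from
#'   [cut_tree_groups()]).
#' @param origins origin table with columns `accession_id` and `region`.
#' @return A list of class `region_enrichment`: `table` (one row per
#'   (group, region) with `observed`, `expected`, `oe_ratio`) and
#'   `assignment` (one row per group with its `assigned_region`).
#' @export
region_enrichment <- function(groups, origins) {
  acc <- intersect(names(groups), origins$accession_id)
  n_drop <- length(groups) - length(acc)
  if (n_drop > 0) message(n_drop, " grouped accession(s) without origin records dropped")
  if (length(acc) == 0) stop("no accessions shared between groups and origins")
  grp <- groups[acc]
  reg <- origins$region[match(acc, origins$accession_id)]
  tab <- table(group = grp, region = reg)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  oe <- tab / expected
  long <- data.frame(
    group = rep(rownames(tab), ncol(tab)),
    region = rep(colnames(tab), each = nrow(tab)),
    observed = as.vector(tab),
    expected = as.vector(expected),
    oe_ratio = as.vector(oe),
    stringsAsFactors = FALSE
  )
  assign_one <- function(gname) {
    rows <- long[long$group == gname, ]
    rows <- rows[order(-rows$oe_ratio, -rows$observed, rows$region), ]
    rows$region[1]
  }
  groups_u <- rownames(tab)
  assignment <- data.frame(
    group = groups_u,
    assigned_region = vapply(groups_u, assign_one, ""),
    stringsAsFactors = FALSE
  )
  structure(list(table = long, assignment = assignment),
            class = "region_enrichment")
}
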