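#' Parameters for unsupervised hierarchical clustering
#'
#' The discovery-phase analysis style: Ward's minimum-variance criterion on
#' Euclidean distances. Both are fixed; the constructor exists so pipeline
#' configurations carry an explicit record of the choice.
#'
#' @param linkage Only `"ward"` is supported (implemented as the Ward.D2
#'   convention: Lance-Williams updates on squared Euclidean distances, so
#'   merge heights are exact within-cluster sum-of-squares increases on
#'   the sqrt(2 * delta-SS) scale).
#' @param distance Only `"euclidean"` is supported.
#' @param leaf_level `"pooled_group"` or `"sample"` (a label recorded in
#'   pipeline manifests; the clustering itself is agnostic).
#' @return A list of class `clustering_params`.
#' @export
clustering_params <- function(linkage = "ward", distance = "euclidean",
                              leaf_level = c("pooled_group", "sample")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  leaf_level <- match.arg(leaf_level)
  structure(list(linkage = linkage, distance = distance,
                 leaf_level = leaf_level),
            class = "clustering_params")
}

#' Euclidean distance matrix between expression profiles
#'
#' @param expr Numeric matrix of complete profiles (rows = objects to
#'   cluster, e.g. pooled groups; columns = miRs). Missing values are an
#'   error: filter or impute before clustering.
#' @return A `dist` object.
#' @export
distance_matrix <- function(expr) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  if (nrow(expr) < 2) stop("need at least 2 profiles")
  if (anyNA(expr)) {
    stop("profiles contain missing values; filter or impute first")
  }
  stats::dist(expr, method = "euclidean")
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering that at each step merges the pair of clusters
#' whose fusion minimally increases the total within-cluster sum of
#' squares (Ward's criterion, computed from Euclidean input distances via
#' the Ward.D2 Lance-Williams recurrence). With Euclidean input the merge
#' heights are guaranteed monotone non-decreasing.
#'
#' @param dist A `dist` object from [distance_matrix()].
#' @param params A [clustering_params()].
#' @return An `hclust` object (fields `merge`, `height`, `labels`).
#' @export
ward_cluster <- function(dist, params = clustering_params()) {
  if (!inherits(dist, "dist")) stop("'dist' must be a dist object")
  if (attr(dist, "Size") < 2) stop("need at least 2 profiles")
  stats::hclust(dist, method = "ward.D2")
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths derive from merge heights with each node placed at half
#' its merge height, so two leaves merged at height `h` serialize as
#' `(A:h/2,B:h/2);`. Parsing the string back yields the same topology.
#'
#' @param tree An `hclust` object from [ward_cluster()].
#' @return A single Newick string (terminated by `;`).
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree))
}
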