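#' A set of same-kind components pooled across subjects
#'
#' Collects temporal (length-`T`) or spatial (length-`S`) component vectors
#' from several subjects for cross-subject clustering.
#'
#' @param vectors numeric matrix with one component per column.
#' @param subject_id vector (length = number of components) naming the
#'   subject each component came from.
#' @param kind `"temporal"` or `"spatial"`.
#' @return an object of class `component_set`.
#' @seealso [cluster_components()] for the full clustering pipeline.
#' @export
component_set <- function(vectors, subject_id, kind = c("temporal", "spatial")) {
  kind <- match.arg(kind)
  vectors <- as.matrix(vectors)
  if (ncol(vectors) < 2L) stop("need at least 2 components")
  if (length(subject_id) != ncol(vectors))
    stop("one subject_id per component required")
  structure(list(vectors = vectors, subject_id = as.character(subject_id),
                 kind = kind),
            class = "component_set")
}

#' Pairwise correlation similarity between components
#'
#' Pearson correlation between all pairs of component vectors; the clustering
#' distance is `1 - r`.
#'
#' @param set a [component_set()].
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwise_similarity <- function(set) {
  stopifnot(inherits(set, "component_set"))
  sds <- apply(set$vectors, 2L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("component %d (subject %s) is constant; correlation undefined",
                 which(sds == 0)[1L], set$subject_id[which(sds == 0)[1L]]))
  stats::cor(set$vectors)
}

#' Average-linkage tree over component dissimilarities
#'
#' Agglomerative hierarchical clustering with average linkage (UPGMA): the
#' distance between two clusters is the mean distance over all cross-cluster
#' pairs. Distances are `1 - r` with `r` the Pearson correlation.
#'
#' @param set a [component_set()], or a `dist` object of precomputed
#'   dissimilarities.
#' @return an [stats::hclust] dendrogram.
#' @export
average_linkage_tree <- function(set) {
  d <- if (inherits(set, "dist")) set
       else stats::as.dist(1 - pairwise_similarity(set))
  stats::hclust(d, method = "average")
}

#' Cut a component tree at the smallest subject-unique partition
#'
#' Scans partitions of the dendrogram at k = 1, 2, ... clusters and returns
#' the first (smallest k) in which no cluster contains two components from
#' the same subject; this groups maximally similar components while keeping
#' at most one component per subject in each cluster. Cluster representatives
#' are the arithmetic means of their members.
#'
#' @param tree an [stats::hclust] tree over the components.
#' @param set the [component_set()] the tree was built from.
#' @return an object of class `cluster_assignment`: list with `cluster_id`
#'   (per component), `n_clusters`, `cluster_means` (matrix, one column per
#'   cluster), `subject_id` and `kind`.
#' @export
cut_by_subject_uniqueness <- function(tree, set) {
  stopifnot(inherits(tree, "hclust"), inherits(set, "component_set"))
  m <- ncol(set$vectors)
  for (k in seq_len(m)) {
    part <- stats::cutree(tree, k = k)
    if (subject_unique(part, set$subject_id)) {
      means <- sapply(sort(unique(part)), function(g)
        rowMeans(set$vectors[, part == g, drop = FALSE]))
      means <- as.matrix(means)
      colnames(means) <- paste0("cluster", sort(unique(part)))
      return(structure(
        list(cluster_id = part, n_clusters = k, cluster_means = means,
             subject_id = set$subject_id, kind = set$kind),
        class = "cluster_assignment"))
    }
  }
  stop("no subject-unique partition found (duplicate components per subject?)")
}

subject_unique <- function(part, subject_id) {
  all(table(part, subject_id) <= 1L)
}

#' Cluster components of one kind across subjects
#'
#' Convenience wrapper: pools the temporal (or spatial) components of several
#' fits, builds the correlation-distance average-linkage tree and cuts it at
#' the smallest subject-unique partition.
#'
#' @param fits named list of `scnm3f` fits (names = subject ids; unnamed
#'   lists get `subject1`, `subject2`, ...).
#' @param kind `"temporal"` or `"spatial"`.
#' @return a `cluster_assignment` (see [cut_by_subject_uniqueness()]).
#' @export
cluster_components <- function(fits, kind = c("temporal", "spatial")) {
  kind <- match.arg(kind)
  if (is.null(names(fits))) names(fits) <- paste0("subject", seq_along(fits))
  vecs <- lapply(fits, function(f)
    if (kind == "temporal") f$w_tem else t(f$w_spa))
  subject <- rep(names(fits), vapply(vecs, ncol, integer(1)))
  set <- component_set(do.call(cbind, vecs), subject, kind)
  cut_by_subject_uniqueness(average_linkage_tree(set), set)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("%s component clustering: %d clusters over %d components from %d subjects\n",
              x$kind, x$n_clusters, length(x$cluster_id),
              length(unique(x$subject_id))))
  print(table(cluster = x$cluster_id, subject = x$subject_id))
  invisible(x)
}
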