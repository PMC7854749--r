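#' Rank features by Mean Decrease Impurity
#'
#' Fits the standard 100-tree forest (the same configuration as the
#' classifiers) and returns Gini importances summing to 1, plus the ranking
#' (descending importance, ties by column order).
#'
#' @param X Feature matrix (columns named).
#' @param y Class labels (>= 2 classes).
#' @param cfg An [rf_config()]; its seed fixes the ranking.
#' @return List with `mdi` (named, sums to 1 unless all splits were
#'   impossible) and `ranking` (feature names, most important first).
#' @export
rank_mdi <- function(X, y, cfg = rf_config()) {
  fit <- rf_fit(X, y, cfg)
  mdi <- fit$importance
  ord <- order(-mdi) # ties keep column order
  list(mdi = mdi, ranking = names(mdi)[ord])
}

#' Cluster correlated features and keep one representative per cluster
#'
#' Spearman rank correlations among the candidate features are computed; each
#' feature's correlation profile (its row of the correlation matrix) is the
#' vector fed to agglomerative (Ward) clustering, and flat clusters are cut at
#' the height threshold (default 1, the "maximum depth" of the procedure).
#' Within each cluster the feature with the highest MDI is kept (ties by rank
#' order). Constant features, whose Spearman correlation is undefined, each
#' form their own cluster and are logged.
#'
#' @param X Feature matrix restricted to the candidate features.
#' @param mdi Named importances covering `colnames(X)`.
#' @param cut_height Dendrogram cut height (default 1).
#' @param linkage hclust linkage (default `"ward.D2"`).
#' @return List with `clusters` (named integer vector) and `selected`
#'   (feature names, in MDI rank order).
#' @export
cluster_select <- function(X, mdi, cut_height = 1, linkage = "ward.D2") {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 features to cluster")
  feats <- colnames(X)
  mdi <- mdi[feats]
  const <- apply(X, 2, function(v) stats::sd(v) == 0 || !all(is.finite(v)))
  clusters <- integer(length(feats))
  names(clusters) <- feats
  nxt <- 0L
  if (any(!const)) {
    Xv <- X[, !const, drop = FALSE]
    if (ncol(Xv) == 1L) {
      clusters[!const] <- 1L
      nxt <- 1L
    } else {
      R <- stats::cor(Xv, method = "spearman")
      hc <- stats::hclust(stats::dist(R), method = linkage)
      cl <- stats::cutree(hc, h = cut_height)
      clusters[!const] <- cl
      nxt <- max(cl)
    }
  }
  if (any(const)) {
    message("cluster_select: ", sum(const),
            " constant feature(s) kept as singleton clusters")
    clusters[const] <- nxt + seq_len(sum(const))
  }
  reps <- vapply(split(feats, clusters[feats]), function(members) {
    members[order(-mdi[members])][1]
  }, character(1))
  selected <- reps[order(-mdi[reps])]
  list(clusters = clusters, selected = unname(selected))
}

#' Two-step optimal-feature selection
#'
#' Step 1: rank all candidates by MDI from a 100-tree forest and keep the top
#' `top_k` (default 50). Step 2: hierarchically cluster the retained features
#' on their Spearman correlation structure, cut at `cut_height` (default 1),
#' and keep the highest-MDI feature of each cluster.
#'
#' @param X Full candidate feature matrix.
#' @param y Class labels.
#' @param top_k Number of top-ranked features retained (default 50).
#' @param cut_height Cluster cut height (default 1).
#' @param cfg An [rf_config()] for the ranking forest.
#' @param linkage hclust linkage.
#' @return A `crop_selection`: list with `table` (data.frame: feature, mdi,
#'   rank, cluster, selected), `selected` (names), `top_k`, `cut_height`,
#'   `seed`.
#' @export
select_features <- function(X, y, top_k = 50L, cut_height = 1,
                            cfg = rf_config(), linkage = "ward.D2") {
  X <- as.matrix(X)
  rk <- rank_mdi(X, y, cfg)
  top <- utils::head(rk$ranking, min(top_k, ncol(X)))
  if (length(top) == 1L) {
    cl <- stats::setNames(1L, top)
    sel <- top
  } else {
    cs <- cluster_select(X[, top, drop = FALSE], rk$mdi, cut_height, linkage)
    cl <- cs$clusters
    sel <- cs$selected
  }
  tab <- data.frame(
    feature = rk$ranking,
    mdi = unname(rk$mdi[rk$ranking]),
    rank = seq_along(rk$ranking),
    cluster = unname(cl[rk$ranking]),
    selected = rk$ranking %in% sel)
  structure(list(table = tab, selected = sel, top = top, top_k = top_k,
                 cut_height = cut_height, seed = cfg$seed),
            class = "crop_selection")
}

#' @export
print.crop_selection <- function(x, ...) {
  cat("Feature selection: ", length(x$selected), " of ",
      nrow(x$table), " candidates (top ", length(x$top),
      " by MDI, cut height ", x$cut_height, ")\n", sep = "")
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
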