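#' Complete-linkage clustering of entities by disturbance similarity
#'
#' Entities are clustered on the distance \code{1 - similarity}
#' (range [0, 2]) by complete-linkage agglomeration and the dendrogram
#' is cut into \code{k} clusters. Cluster labels \code{C1..Ck} are
#' ordered by decreasing cluster size, ties broken by the
#' alphabetically first member.
#'
#' @param sim_matrix Symmetric similarity matrix in [-1, 1] with unit
#'   diagonal and entity names as dimnames. Undefined (\code{NA})
#'   off-diagonal entries are rejected with a message naming the
#'   pairs.
#' @param k Number of clusters, between 2 and the number of entities.
#' @return A \code{cluster_assignment}: list with \code{labels}
#'   (named character vector entity -> \code{"C1"}..), \code{k}, and
#'   the \code{hclust} object (merge heights are the dendrogram's
#'   branch depths).
#' @export
cluster_entities <- function(sim_matrix, k) {
  stopifnot(is.matrix(sim_matrix),
            nrow(sim_matrix) == ncol(sim_matrix))
  n <- nrow(sim_matrix)
  if (k < 2 || k > n) stop("k must be in [2, number of entities]")
  if (max(abs(sim_matrix - t(sim_matrix)), na.rm = TRUE) > 1e-8)
    stop("similarity matrix is not symmetric")
  bad <- which(is.na(sim_matrix) & upper.tri(sim_matrix), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    nm <- rownames(sim_matrix)
    stop("undefined similarity for pair(s): ",
         paste(nm[bad[, 1]], nm[bad[, 2]], sep = " / ", collapse = "; "))
  }
  d <- stats::as.dist(1 - sim_matrix)
  hc <- stats::hclust(d, method = "complete")
  raw <- stats::cutree(hc, k = k)
  # relabel by decreasing size, ties by first entity name
  sizes <- table(raw)
  first <- tapply(names(sort(raw)), sort(raw), function(x) sort(x)[1])
  ord <- order(-as.integer(sizes), first[names(sizes)])
  relabel <- stats::setNames(paste0("C", seq_along(ord)),
                             names(sizes)[ord])
  labels <- stats::setNames(unname(relabel[as.character(raw)]),
                            names(raw))
  structure(list(labels = labels, k = k, hclust = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("complete-linkage clustering into", x$k, "clusters:\n")
  print(table(x$labels))
  invisible(x)
}

#' Compare two similarity matrices
#'
#' Pearson correlation of the paired off-diagonal similarity values of
#' two matrices over their shared entities (e.g., microbiota-based
#' versus etiology-based disease similarity), with a two-tailed
#' p-value. An optional entity categorization yields per-category
#' correlations over within-category pairs.
#'
#' @param A,B Symmetric similarity matrices with entity dimnames;
#'   only entities present in both are compared, and only pairs
#'   defined (non-\code{NA}) in both.
#' @param categories Optional named vector entity -> category label.
#' @return List with \code{r}, \code{p}, \code{n_pairs}, and (when
#'   \code{categories} given) a data frame \code{by_category}.
#' @export
compare_similarity_matrices <- function(A, B, categories = NULL) {
  common <- intersect(rownames(A), rownames(B))
  if (length(common) < 3) stop("fewer than 3 shared entities")
  A <- A[common, common]; B <- B[common, common]
  ut <- upper.tri(A)
  ok <- ut & !is.na(A) & !is.na(B)
  if (sum(ok) < 3) stop("fewer than 3 common defined pairs")
  ct <- stats::cor.test(A[ok], B[ok], method = "pearson",
                        alternative = "two.sided")
  out <- list(r = unname(ct$estimate), p = ct$p.value, n_pairs = sum(ok))
  if (!is.null(categories)) {
    rows <- list()
    for (g in sort(unique(categories[common]))) {
      ents <- common[categories[common] == g]
      if (length(ents) < 3) next
      Ag <- A[ents, ents]; Bg <- B[ents, ents]
      sel <- upper.tri(Ag) & !is.na(Ag) & !is.na(Bg)
      if (sum(sel) < 3) next
      cg <- stats::cor.test(Ag[sel], Bg[sel], method = "pearson")
      rows[[g]] <- data.frame(category = g, r = unname(cg$estimate),
                              p = cg$p.value, n_pairs = sum(sel),
                              stringsAsFactors = FALSE)
    }
    out$by_category <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(out$by_category)) rownames(out$by_category) <- NULL
  }
  out
}
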