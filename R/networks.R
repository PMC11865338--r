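#' Build a signed similarity network
#'
#' Nodes are entities; each defined, nonzero, non-self pair becomes an
#' edge carrying the weighted similarity, its FDR, and the similarity
#' sign. With an FDR threshold only pairs with \code{fdr < threshold}
#' (strict) are retained; with \code{fdr_threshold = NULL} every
#' defined pair is kept (the full network used for the loop census).
#'
#' @param sim A \code{bhwa_similarity} table from one run.
#' @param fdr_threshold Strict upper bound on FDR, or \code{NULL} for
#'   no filtering.
#' @return A \code{signed_network}: list with \code{nodes} and an
#'   edge data frame (\code{node_i}, \code{node_j}, \code{similarity},
#'   \code{fdr}, \code{sign}).
#' @export
build_network <- function(sim, fdr_threshold = NULL) {
  e <- as.data.frame(sim)
  e <- e[e$entity_i != e$entity_j & !is.na(e$sim_weighted) &
           e$sim_weighted != 0, , drop = FALSE]
  if (!is.null(fdr_threshold))
    e <- e[!is.na(e$fdr) & e$fdr < fdr_threshold, , drop = FALSE]
  if (nrow(e) == 0) stop("empty network after filtering")
  edges <- data.frame(node_i = e$entity_i, node_j = e$entity_j,
                      similarity = e$sim_weighted, fdr = e$fdr,
                      sign = ifelse(e$sim_weighted > 0, 1L, -1L),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  nodes <- sort(unique(c(sim$entity_i, sim$entity_j)))
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat("signed network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (", sum(x$edges$sign > 0), "positive /",
      sum(x$edges$sign < 0), "negative )\n")
  invisible(x)
}

#' Theoretical maximum number of three-node loops
#'
#' The number of node triples in a complete graph on \code{n} nodes,
#' \code{n (n-1) (n-2) / 6}.
#'
#' @param n_nodes Number of nodes, at least 3.
#' @return Integer-valued count.
#' @export
#' @examples
#' theoretical_max_loops(32)   # 4960
#' theoretical_max_loops(161)  # 682640
theoretical_max_loops <- function(n_nodes) {
  if (any(n_nodes < 3)) stop("n_nodes must be >= 3")
  n_nodes * (n_nodes - 1) * (n_nodes - 2) / 6
}

# signed adjacency matrix of a network (0 where no edge)
.signed_adjacency <- function(network) {
  n <- length(network$nodes)
  S <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  e <- network$edges
  i <- match(e$node_i, network$nodes)
  j <- match(e$node_j, network$nodes)
  S[cbind(i, j)] <- e$sign
  S[cbind(j, i)] <- e$sign
  S
}

#' Census of three-node loops and their coherency
#'
#' Enumerates all node triples whose three edges exist. A loop is
#' coherent when the product of its three edge signs is positive
#' (structural balance), incoherent otherwise; the all-positive
#' triangle is coherent and the all-negative one incoherent. Counts
#' are obtained from trace identities on the signed adjacency matrix
#' \code{S}: with \code{A = |S|}, the total is \code{tr(A^3)/6} and
#' \code{coherent - incoherent = tr(S^3)/6}.
#'
#' @param network A \code{signed_network}.
#' @return A \code{loop_census}: list with \code{total_loops},
#'   \code{coherent}, \code{incoherent}, \code{ratio}
#'   (coherent / incoherent; \code{NA} sentinel when
#'   \code{incoherent = 0}) and \code{theoretical_max}.
#' @export
loop_census <- function(network) {
  S <- .signed_adjacency(network)
  A <- abs(S)
  total <- round(sum(diag(A %*% A %*% A)) / 6)
  signed <- round(sum(diag(S %*% S %*% S)) / 6)
  coherent <- (total + signed) / 2
  incoherent <- (total - signed) / 2
  n <- length(network$nodes)
  structure(list(
    total_loops = total, coherent = coherent, incoherent = incoherent,
    ratio = if (incoherent > 0) coherent / incoherent else NA_real_,
    theoretical_max = if (n >= 3) theoretical_max_loops(n) else 0
  ), class = "loop_census")
}

#' @export
print.loop_census <- function(x, ...) {
  cat(sprintf(
    "three-node loops: %d of %d possible; %d coherent / %d incoherent (ratio %s)\n",
    x$total_loops, x$theoretical_max, x$coherent, x$incoherent,
    if (is.na(x$ratio)) "undefined" else sprintf("%.3f", x$ratio)))
  invisible(x)
}

# one permuted copy of the per-rank matrices: within-entity shuffles
# each row across the taxon axis (preserving its multiset of values);
# global shuffles all cells of each rank matrix
.permute_rank_matrices <- function(Dl, null = c("within-entity", "global")) {
  null <- match.arg(null)
  lapply(Dl, function(D) {
    if (ncol(D) < 2) return(D)
    if (null == "within-entity") {
      for (i in seq_len(nrow(D))) D[i, ] <- D[i, sample.int(ncol(D))]
    } else {
      D[] <- D[sample.int(length(D))]
    }
    D
  })
}

# weighted-similarity matrix straight from per-rank matrices (no
# p-values): the fast path shared by the randomization test
.sim_weighted_matrix <- function(Dl) {
  sumW <- NULL; sumWS <- NULL
  for (st in lapply(Dl, .rank_pair_stats)) {
    w <- ifelse(st$contributing, st$W, 0)
    ws <- ifelse(st$contributing, st$W * st$sim, 0)
    if (is.null(sumW)) { sumW <- w; sumWS <- ws }
    else { sumW <- sumW + w; sumWS <- sumWS + ws }
  }
  out <- sumWS / sumW
  out[sumW == 0] <- NA_real_
  out
}

# loop-census ratio of the unfiltered signed network implied by a
# weighted-similarity matrix
.ratio_from_sim_matrix <- function(M) {
  S <- sign(M)
  S[is.na(S)] <- 0
  diag(S) <- 0
  A <- abs(S)
  total <- round(sum(diag(A %*% A %*% A)) / 6)
  signed <- round(sum(diag(S %*% S %*% S)) / 6)
  coherent <- (total + signed) / 2
  incoherent <- (total - signed) / 2
  if (incoherent > 0) coherent / incoherent else NA_real_
}

#' Randomization test for network coherency
#'
#' Compares the observed coherent-to-incoherent loop ratio of the
#' unfiltered similarity network against a permutation null: each
#' iteration independently permutes, within each rank, every entity's
#' vector of disturbance strengths across the taxon axis (preserving
#' the entity's multiset of values), recomputes all pairwise weighted
#' similarities and the loop-census ratio. The alternative
#' \code{"global"} null shuffles all cells of each rank matrix.
#' Iterations whose network has no incoherent loop yield an undefined
#' ratio (\code{NA}), excluded from the null median with a logged
#' count.
#'
#' @param counts A \code{multi_rank_evidence} object.
#' @param iterations Number of null iterations (default 10000).
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @param null Null model: \code{"within-entity"} (default) or
#'   \code{"global"}.
#' @return A \code{randomization_result}: list with \code{iterations},
#'   \code{seed}, \code{null_ratios} (length \code{iterations},
#'   \code{NA} where undefined), \code{observed_ratio},
#'   \code{null_median}, \code{fold_vs_median},
#'   \code{empirical_p} (fraction of defined null ratios >= observed)
#'   and \code{n_undefined}.
#' @export
randomization_test <- function(counts, iterations = 10000L, seed = 1L,
                               null = c("within-entity", "global")) {
  stopifnot(iterations >= 1)
  null <- match.arg(null)
  Dl <- .rank_matrices(counts)
  if (length(Dl) == 0) stop("no rank with >= 2 entities")
  observed <- .ratio_from_sim_matrix(.sim_weighted_matrix(Dl))
  null_ratios <- numeric(iterations)
  set.seed(seed)
  for (b in seq_len(iterations)) {
    Dp <- .permute_rank_matrices(Dl, null)
    null_ratios[b] <- .ratio_from_sim_matrix(.sim_weighted_matrix(Dp))
  }
  defined <- null_ratios[!is.na(null_ratios)]
  if (length(defined) == 0)
    stop("all null iterations yielded undefined ratios")
  med <- stats::median(defined)
  structure(list(
    iterations = iterations, seed = seed, null_ratios = null_ratios,
    observed_ratio = observed, null_median = med,
    fold_vs_median = observed / med,
    empirical_p = mean(defined >= observed),
    n_undefined = sum(is.na(null_ratios))
  ), class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "coherency randomization: observed ratio %.3f, null median %.3f (%d iterations, %d undefined), fold %.2f, empirical p %.4f\n",
    x$observed_ratio, x$null_median, x$iterations, x$n_undefined,
    x$fold_vs_median, x$empirical_p))
  invisible(x)
}
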