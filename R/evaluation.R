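`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prelic-style match score between two bicluster sets
#'
#' `S(E1, E2) = (1/|E1|) * sum over b1 in E1 of max over b2 in E2 of
#' Jaccard(b1, b2)`. In the default `genes_only` mode the Jaccard index is
#' taken on the gene (row) sets; `genes_and_conditions` intersects the
#' (row, column) cell sets instead, for comparability with the original
#' two-dimensional formulation.
#'
#' @param E1,E2 [bicluster_set()] objects; `E1` is the reference side the
#'   average runs over.
#' @param mode `"genes_only"` (default) or `"genes_and_conditions"`.
#' @return a `MatchResult`: list with `score` in \[0, 1\],
#'   `per_bicluster_best` (data.frame of the best-matching index in `E2` and
#'   its Jaccard, one row per member of `E1`), `mode`, and `empty_match`
#'   (`TRUE` when `E2` is empty and the score is 0 by convention).
#' @export
#' @examples
#' s <- bicluster_set(list(bicluster(1:10, 1:4)))
#' match_score(s, s)$score # 1
match_score <- function(E1, E2, mode = c("genes_only",
                                         "genes_and_conditions")) {
  stopifnot(inherits(E1, "BiclusterSet"), inherits(E2, "BiclusterSet"))
  mode <- match.arg(mode)
  if (length(E1) == 0L) {
    stop("match score is undefined for an empty reference set E1",
         call. = FALSE)
  }
  keyset <- function(b) {
    if (mode == "genes_only") b$rows
    else as.vector(outer(b$rows, b$cols, function(r, c) paste0(r, "_", c)))
  }
  if (length(E2) == 0L) {
    per <- data.frame(best_index = rep(NA_integer_, length(E1)),
                      jaccard = rep(0, length(E1)))
    return(structure(list(score = 0, per_bicluster_best = per, mode = mode,
                          empty_match = TRUE), class = "MatchResult"))
  }
  sets2 <- lapply(E2$biclusters, keyset)
  per <- do.call(rbind, lapply(E1$biclusters, function(b1) {
    s1 <- keyset(b1)
    j <- vapply(sets2, function(s2) {
      length(intersect(s1, s2)) / length(union(s1, s2))
    }, numeric(1))
    data.frame(best_index = which.max(j), jaccard = max(j))
  }))
  structure(list(score = mean(per$jaccard), per_bicluster_best = per,
                 mode = mode, empty_match = FALSE), class = "MatchResult")
}

#' @export
print.MatchResult <- function(x, ...) {
  cat(sprintf("match score (%s): %.4f over %d bicluster(s)\n",
              x$mode, x$score, nrow(x$per_bicluster_best)))
  invisible(x)
}

#' Recovery and Relevance
#'
#' Directional match scores against a ground truth: Recovery is
#' `S(implanted, found)` (how much of the truth was recovered) and Relevance
#' is `S(found, implanted)` (how much of the output is real).
#'
#' @param implanted ground-truth [bicluster_set()].
#' @param found [bicluster_set()] produced by a biclustering run.
#' @param mode as in [match_score()].
#' @return a single numeric score in \[0, 1\].
#' @export
recovery <- function(implanted, found, mode = "genes_only") {
  match_score(implanted, found, mode)$score
}

#' @rdname recovery
#' @export
relevance <- function(implanted, found, mode = "genes_only") {
  match_score(found, implanted, mode)$score
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability of observing at least `overlap` category genes in
#' a draw of `draw` genes from `total` genes of which `category` belong to
#' the category:
#' `p = sum_{k = overlap}^{min(category, draw)}
#'   C(category, k) C(total - category, draw - k) / C(total, draw)`.
#' Computed exactly in log space (log-gamma), elementwise over vector
#' inputs.
#'
#' @param total total genes in the reference (T).
#' @param category genes in the category (O), `category <= total`.
#' @param draw genes drawn, e.g. the bicluster size (t), `draw <= total`.
#' @param overlap observed overlap (o), `0 <= overlap <= min(category, draw)`.
#' @return p-value(s) in \[0, 1\].
#' @export
#' @examples
#' hypergeom_pvalue(10, 5, 5, 5) # 1 / choose(10, 5) = 1/252
hypergeom_pvalue <- function(total, category, draw, overlap) {
  n <- max(length(total), length(category), length(draw), length(overlap))
  total <- rep_len(as.numeric(total), n)
  category <- rep_len(as.numeric(category), n)
  draw <- rep_len(as.numeric(draw), n)
  overlap <- rep_len(as.numeric(overlap), n)
  if (any(category > total)) {
    stop("invariant violated: category (O) must not exceed total (T)",
         call. = FALSE)
  }
  if (any(draw > total)) {
    stop("invariant violated: draw (t) must not exceed total (T)",
         call. = FALSE)
  }
  hi <- pmin(category, draw)
  if (any(overlap < 0) || any(overlap > hi)) {
    stop("invariant violated: overlap (o) must lie in [0, min(O, t)]",
         call. = FALSE)
  }
  denom <- lchoose(total, draw)
  p <- numeric(n)
  span <- hi - overlap
  for (d in 0:max(span)) {
    act <- span >= d
    if (!any(act)) break
    k <- overlap[act] + d
    term <- exp(lchoose(category[act], k) +
                  lchoose(total[act] - category[act], draw[act] - k) -
                  denom[act])
    p[act] <- p[act] + term
  }
  pmin(p, 1)
}

#' Proportion of enriched GO items
#'
#' The fraction of tested GO items found significant (p < 0.05) in an
#' enrichment analysis: `R_G / T_G`. Reported to four decimals in text
#' output.
#'
#' @param R_G number of items with p-value below the significance cut.
#' @param T_G total number of items tested; must be positive.
#' @return the proportion, a numeric in \[0, 1\].
#' @export
#' @examples
#' round(enrichment_proportion(621, 814), 4) # 0.7629
enrichment_proportion <- function(R_G, T_G) {
  if (any(T_G <= 0)) stop("T_G must be positive", call. = FALSE)
  if (any(R_G < 0) || any(R_G > T_G)) {
    stop("R_G must lie in [0, T_G]", call. = FALSE)
  }
  R_G / T_G
}
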