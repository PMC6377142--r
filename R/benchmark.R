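#' Edge scores for link-recovery benchmarking
#'
#' Builds the scored edge list compared against a ground-truth adjacency:
#' every directed non-self pair among \code{genes} gets a confidence score
#' (model fitness, aggregated over conditions) and a truth flag.  Pairs
#' with no fitted model score \code{-Inf} (ranked last).
#'
#' @param links link data.frame, or a list of them (one per condition).
#' @param truth data.frame with columns \code{source}, \code{target}.
#' @param genes gene universe; defaults to genes seen in \code{links}.
#' @param agg aggregation over conditions: \code{"max"} (default) or
#'   \code{"mean"}.
#' @return data.frame: source, target, score, truth.
#' @export
edge_scores <- function(links, truth, genes = NULL, agg = c("max", "mean")) {
  agg <- match.arg(agg)
  if (is.data.frame(links)) links <- list(links)
  all_links <- do.call(rbind, links)
  if (is.null(genes))
    genes <- sort(unique(c(all_links$source, all_links$target)))
  pairs <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  key <- link_key(pairs)
  score <- rep(-Inf, nrow(pairs))
  per_cond <- lapply(links, function(l) {
    s <- rep(NA_real_, nrow(pairs))
    s[match(link_key(l), key)] <- l$fitness_pct
    s
  })
  smat <- do.call(cbind, per_cond)
  fn <- if (agg == "max") function(v) max(v, na.rm = TRUE)
        else function(v) mean(v, na.rm = TRUE)
  has <- rowSums(!is.na(smat)) > 0
  score[has] <- apply(smat[has, , drop = FALSE], 1, fn)
  pairs$score <- score
  pairs$truth <- key %in% link_key(truth)
  rownames(pairs) <- NULL
  pairs
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC; tied scores contribute 1/2.
#'
#' @param scores data.frame with \code{score} and logical \code{truth}
#'   columns (see \code{\link{edge_scores}}), or a numeric score vector.
#' @param truth logical vector when \code{scores} is numeric.
#' @return AUROC in \code{[0, 1]}.
#' @export
auroc <- function(scores, truth = NULL) {
  if (is.data.frame(scores)) { truth <- scores$truth; scores <- scores$score }
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("auroc needs both classes in truth")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over recall increments at every distinct score
#' threshold (descending), with tied scores grouped; no interpolation.
#'
#' @inheritParams auroc
#' @return AUPR in \code{(0, 1]}.
#' @export
aupr <- function(scores, truth = NULL) {
  if (is.data.frame(scores)) { truth <- scores$truth; scores <- scores$score }
  truth <- as.logical(truth)
  P <- sum(truth)
  if (P == 0) stop("aupr needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  grp <- cumsum(!duplicated(s))          # tie groups in descending order
  tp <- tapply(y, grp, sum)
  np <- tapply(y, grp, length)
  ctp <- cumsum(tp); cn <- cumsum(np)
  precision <- ctp / cn
  recall <- ctp / P
  sum(diff(c(0, recall)) * precision)
}
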