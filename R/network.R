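# deterministic per-pair seed derived from identifiers + base seed
pair_seed <- function(source, target, condition, base_seed) {
  h <- 0
  for (ch in utf8ToInt(paste(source, target, condition, sep = "|"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(base_seed)) %% 2147483647)
}

link_row <- function(source, target, condition, model) {
  data.frame(source = source, target = target, condition = condition,
             a = model$a, b = model$b, c = model$c, x0 = model$x0,
             fitness_pct = model$fitness_pct, stable = model$stable,
             sign = if (model$a > 0) "activates" else "inhibits",
             stringsAsFactors = FALSE)
}

row_model <- function(row) {
  first_order_model(row$a, row$b, row$c, row$x0, row$fitness_pct)
}

#' Fit first-order models for every directed gene pair
#'
#' Fits the \eqn{n^2 - n} directed models (self-regulation excluded) on
#' replicate-averaged series.  Each pair uses a seed derived from
#' (source, target, condition, rng_seed), so results are deterministic and
#' independent of fitting order.  Per-pair failures are recorded and the
#' pair skipped.
#'
#' @param ds an \code{\link{expression_dataset}}.
#' @param genes gene subset to model; defaults to all genes.
#' @param cfg a \code{\link{dyde_config}}.
#' @param verbose emit a progress message every 50 pairs.
#' @return data.frame of unvalidated links: source, target, condition,
#'   a, b, c, x0, fitness_pct, stable, sign; attribute \code{failures}
#'   lists skipped pairs.
#' @export
fit_all_pairs <- function(ds, genes = ds$gene_ids, cfg = dyde_config(),
                          verbose = FALSE) {
  if (length(genes) < 2) stop("need at least 2 genes")
  series <- lapply(genes, function(g) average_replicates(ds, g))
  names(series) <- genes
  rows <- vector("list", length(genes) * (length(genes) - 1))
  fails <- character(0)
  k <- 0; done <- 0
  for (src in genes) {
    for (tgt in genes) {
      if (src == tgt) next
      done <- done + 1
      if (verbose && done %% 50 == 0)
        message("fit_all_pairs: ", done, " / ", length(rows), " pairs")
      res <- tryCatch({
        m <- fit_first_order(series[[src]], series[[tgt]], ds$times, cfg,
                             seed = pair_seed(src, tgt, ds$condition,
                                              cfg$rng_seed))
        link_row(src, tgt, ds$condition, m)
      }, error = function(e) {
        fails <<- c(fails, sprintf("%s->%s: %s", src, tgt, conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) { k <- k + 1; rows[[k]] <- res }
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  attr(out, "failures") <- fails
  out
}

#' Validate links by fitness threshold
#'
#' Keeps links whose fitness is at or above the threshold.  The retained
#' set is monotone non-increasing in the threshold.
#'
#' @param links link data.frame from \code{\link{fit_all_pairs}}.
#' @param threshold_pct fitness threshold in percent.
#' @return object of class \code{gene_network}: \code{genes}, \code{links}
#'   (data.frame), \code{threshold_pct}.
#' @export
validate_links <- function(links, threshold_pct) {
  if (threshold_pct < 0 || threshold_pct > 100 + 1e-9)
    message("note: threshold ", threshold_pct, " lies outside [0, 100]")
  keep <- links[links$fitness_pct >= threshold_pct, , drop = FALSE]
  rownames(keep) <- NULL
  structure(list(genes = sort(unique(c(links$source, links$target))),
                 links = keep, threshold_pct = threshold_pct),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d links at fitness >= %g%%\n",
              length(x$genes), nrow(x$links), x$threshold_pct))
  invisible(x)
}

link_key <- function(df) paste(df$source, df$target, sep = "\r")

# per-gene connectivity (in + out; a reciprocal pair counts twice) and the
# percentage of a gene's condition-A links absent from condition B
connectivity_loss <- function(linksA, linksB, genes) {
  keyB <- link_key(linksB)
  lostA <- !(link_key(linksA) %in% keyB)
  out <- lapply(genes, function(g) {
    touch <- linksA$source == g | linksA$target == g
    nA <- sum(touch)
    nlost <- sum(touch & lostA)
    data.frame(gene = g, connectivity_A = nA,
               connectivity_B = sum(linksB$source == g | linksB$target == g),
               n_lost = nlost,
               loss_pct = if (nA > 0) 100 * nlost / nA else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare two condition networks
#'
#' Partitions condition-A links into those shared with condition B
#' (\code{common}) and those absent from B (\code{lost}, the
#' regulation-loss network); links only in B are \code{gained}.  Every
#' common link gets the local nu-gap between the two conditions' models.
#' Per-gene connectivity (incoming + outgoing links) and connectivity
#' loss percentage are reported.
#'
#' @param netA,netB \code{gene_network} objects over the same gene universe.
#' @param band frequency band for the nu-gap (rad/h) or \code{"global"};
#'   default the configured circadian band.
#' @param cfg a \code{\link{dyde_config}}.
#' @return object of class \code{network_comparison}: \code{common}
#'   (data.frame with per-link \code{nugap}), \code{lost}, \code{gained},
#'   \code{connectivity}.
#' @export
compare_networks <- function(netA, netB, band = NULL, cfg = dyde_config()) {
  la <- netA$links; lb <- netB$links
  keyA <- link_key(la); keyB <- link_key(lb)
  common <- la[keyA %in% keyB, , drop = FALSE]
  lost <- la[!(keyA %in% keyB), , drop = FALSE]
  gained <- lb[!(keyB %in% keyA), , drop = FALSE]
  if (nrow(common)) {
    ib <- match(link_key(common), keyB)
    common$nugap <- vapply(seq_len(nrow(common)), function(i) {
      nu_gap(row_model(common[i, ]), row_model(lb[ib[i], ]), band, cfg)$value
    }, 1)
    common$fitness_pct_B <- lb$fitness_pct[ib]
  } else {
    common$nugap <- numeric(0)
    common$fitness_pct_B <- numeric(0)
  }
  rownames(common) <- rownames(lost) <- rownames(gained) <- NULL
  genes <- sort(unique(c(netA$genes, netB$genes)))
  structure(list(common = common, lost = lost, gained = gained,
                 connectivity = connectivity_loss(la, lb, genes)),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf(
    "network_comparison: %d common, %d lost, %d gained link(s)\n",
    nrow(x$common), nrow(x$lost), nrow(x$gained)))
  invisible(x)
}

#' Top links by nu-gap
#'
#' @param cmp a \code{network_comparison}.
#' @param k number of links to return (all if fewer are common).
#' @return the \code{k} common links with the largest nu-gap, descending;
#'   ties broken lexicographically by (source, target).
#' @export
rank_nu_gaps <- function(cmp, k = 5) {
  if (k < 1) stop("k must be >= 1")
  cm <- cmp$common
  ord <- order(-cm$nugap, cm$source, cm$target)
  out <- cm[ord, , drop = FALSE][seq_len(min(k, nrow(cm))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage / false-positive curve over fitness thresholds
#'
#' Validates the fitted links at each threshold and scores them against a
#' reference adjacency: coverage is the percentage of reference links
#' recovered, false positives are validated links absent from the reference.
#'
#' @param links link data.frame (one condition).
#' @param reference data.frame with columns \code{source}, \code{target}.
#' @param thresholds numeric vector of fitness thresholds (percent).
#' @return data.frame: threshold, coverage_pct, true_positives,
#'   false_positives, n_validated.
#' @export
threshold_sweep <- function(links, reference, thresholds) {
  if (is.null(reference) || !nrow(reference))
    stop("reference adjacency must contain at least one edge")
  refkey <- unique(link_key(reference))
  do.call(rbind, lapply(thresholds, function(t) {
    v <- links[links$fitness_pct >= t, , drop = FALSE]
    tp <- sum(link_key(v) %in% refkey)
    data.frame(threshold = t,
               coverage_pct = 100 * tp / length(refkey),
               true_positives = tp,
               false_positives = nrow(v) - tp,
               n_validated = nrow(v))
  }))
}

#' Sensitivity of connectivity loss to the fitness threshold
#'
#' Recomputes the per-gene connectivity loss at thresholds
#' \code{t - delta, t, t + delta} and reports mean and standard deviation,
#' quantifying how robust the gene ranking is to the threshold choice.
#'
#' @param linksA,linksB link data.frames for the two conditions.
#' @param threshold central fitness threshold (percent).
#' @param delta_pct threshold perturbation (percent, default 5).
#' @return data.frame: gene, loss_mean_pct, loss_sd_pct.
#' @export
connectivity_loss_sensitivity <- function(linksA, linksB, threshold,
                                          delta_pct = 5) {
  if (delta_pct >= threshold) stop("delta_pct must be smaller than threshold")
  genes <- sort(unique(c(linksA$source, linksA$target,
                         linksB$source, linksB$target)))
  losses <- sapply(c(threshold - delta_pct, threshold, threshold + delta_pct),
    function(t) {
      va <- linksA[linksA$fitness_pct >= t, , drop = FALSE]
      vb <- linksB[linksB$fitness_pct >= t, , drop = FALSE]
      connectivity_loss(va, vb, genes)$loss_pct
    })
  data.frame(gene = genes,
             loss_mean_pct = apply(losses, 1, mean),
             loss_sd_pct = apply(losses, 1, sd),
             stringsAsFactors = FALSE)
}

fit_both_conditions <- function(dsA, dsB, genes, cfg, verbose = FALSE) {
  list(A = fit_all_pairs(subset_genes(dsA, genes), genes, cfg, verbose),
       B = fit_all_pairs(subset_genes(dsB, genes), genes, cfg, verbose))
}

#' Genome-wide scan for perturbed high-confidence links
#'
#' Fits all directed pairs among the given (rhythmic) genes in both
#' conditions, keeps pairs whose fitness reaches the strict threshold
#' (default 80\%) in \emph{both} conditions, and flags as candidate
#' perturbation entry points those whose local nu-gap exceeds the
#' configured threshold (default 0.2).
#'
#' @param dsA,dsB the two condition datasets.
#' @param genes rhythmic gene subset present in both datasets.
#' @param cfg a \code{\link{dyde_config}}.
#' @param verbose progress messages.
#' @return list: \code{high_fitness} (links passing the fitness filter,
#'   with \code{nugap}), \code{candidates} (subset with
#'   \code{nugap > cfg$nugap_threshold}).
#' @export
genome_scan_perturbed <- function(dsA, dsB, genes, cfg = dyde_config(),
                                  verbose = FALSE) {
  fits <- fit_both_conditions(dsA, dsB, genes, cfg, verbose)
  thr <- cfg$strict_fit_threshold_pct
  netA <- validate_links(fits$A, thr)
  netB <- validate_links(fits$B, thr)
  cmp <- compare_networks(netA, netB, cfg$local_band, cfg)
  high <- cmp$common
  cand <- high[high$nugap > cfg$nugap_threshold, , drop = FALSE]
  rownames(cand) <- NULL
  list(high_fitness = high, candidates = cand)
}

#' Scan for genes hub-connected to a core gene set
#'
#' Fits models between every non-core gene and every core (clock) gene in
#' both directions and both conditions.  A connection survives if its
#' fitness reaches the hub threshold (default 60\%) in both conditions and
#' its local nu-gap stays at or below the configured threshold (a
#' consistency requirement: the link must mean the same thing in both
#' conditions).  Non-core genes are ranked by their number of surviving
#' core connections.
#'
#' @param dsA,dsB the two condition datasets.
#' @param core_genes the core (clock) gene identifiers.
#' @param candidate_genes genes to test; defaults to all non-core genes
#'   shared by both datasets.
#' @param cfg a \code{\link{dyde_config}}.
#' @param verbose progress messages.
#' @return list: \code{ranking} (data.frame gene, connectivity, descending,
#'   ties by identifier) and \code{links} (surviving connections with
#'   per-condition fitness and nu-gap).
#' @export
genome_scan_hubs <- function(dsA, dsB, core_genes, candidate_genes = NULL,
                             cfg = dyde_config(), verbose = FALSE) {
  if (is.null(candidate_genes))
    candidate_genes <- setdiff(intersect(dsA$gene_ids, dsB$gene_ids),
                               core_genes)
  if (!all(core_genes %in% dsA$gene_ids) || !all(core_genes %in% dsB$gene_ids))
    stop("core_genes must be present in both datasets")
  thr <- cfg$hub_fit_threshold_pct
  sA <- lapply(setNames(nm = c(core_genes, candidate_genes)),
               function(g) average_replicates(dsA, g))
  sB <- lapply(setNames(nm = c(core_genes, candidate_genes)),
               function(g) average_replicates(dsB, g))
  fit1 <- function(series, src, tgt, ds) {
    fit_first_order(series[[src]], series[[tgt]], ds$times, cfg,
                    seed = pair_seed(src, tgt, ds$condition, cfg$rng_seed))
  }
  rows <- list(); k <- 0; done <- 0
  for (g in candidate_genes) {
    for (cg in core_genes) {
      for (dir in c("out", "in")) {
        src <- if (dir == "out") g else cg
        tgt <- if (dir == "out") cg else g
        done <- done + 1
        if (verbose && done %% 100 == 0)
          message("genome_scan_hubs: ", done, " pair-directions")
        mA <- tryCatch(fit1(sA, src, tgt, dsA), error = function(e) NULL)
        if (is.null(mA) || mA$fitness_pct < thr) next
        mB <- tryCatch(fit1(sB, src, tgt, dsB), error = function(e) NULL)
        if (is.null(mB) || mB$fitness_pct < thr) next
        ng <- nu_gap(mA, mB, cfg$local_band, cfg)$value
        if (ng > cfg$nugap_threshold) next
        k <- k + 1
        rows[[k]] <- data.frame(gene = g, source = src, target = tgt,
                                fitness_A = mA$fitness_pct,
                                fitness_B = mB$fitness_pct, nugap = ng,
                                stringsAsFactors = FALSE)
      }
    }
  }
  links <- if (k) do.call(rbind, rows) else
    data.frame(gene = character(0), source = character(0),
               target = character(0), fitness_A = numeric(0),
               fitness_B = numeric(0), nugap = numeric(0))
  counts <- table(factor(links$gene, levels = candidate_genes))
  ranking <- data.frame(gene = names(counts),
                        connectivity = as.integer(counts),
                        stringsAsFactors = FALSE)
  ranking <- ranking[ranking$connectivity > 0, , drop = FALSE]
  ranking <- ranking[order(-ranking$connectivity, ranking$gene), , drop = FALSE]
  rownames(ranking) <- NULL
  list(ranking = ranking, links = links)
}

#' Export a network as SIF
#'
#' One line per link: \code{source <TAB> relation <TAB> target}, relation
#' \code{activates} or \code{inhibits} from the sign of the input gain.
#'
#' @param net a \code{gene_network}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_network_sif <- function(net, path) {
  df <- net$links[, c("source", "sign", "target")]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export / import a network with full model records as JSON
#'
#' @param net a \code{gene_network}.
#' @param path JSON path.
#' @return \code{path} (write) or the restored \code{gene_network} (read).
#' @export
write_network_json <- function(net, path) {
  jsonlite::write_json(list(genes = net$genes,
                            threshold_pct = net$threshold_pct,
                            links = net$links),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  links <- as.data.frame(obj$links, stringsAsFactors = FALSE)
  structure(list(genes = obj$genes, links = links,
                 threshold_pct = obj$threshold_pct),
            class = "gene_network")
}
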