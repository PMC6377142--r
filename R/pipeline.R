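#' Run the full differential-dynamics pipeline
#'
#' Executes the analysis end to end for two condition datasets: optional
#' rhythmicity screen (genes must be called rhythmic in \emph{both}
#' conditions to enter the modeling stage), all-pairs first-order model
#' fitting per condition, link validation at the fitness threshold,
#' condition comparison with per-link local nu-gaps, nu-gap ranking, and
#' per-gene connectivity-loss analysis with threshold sensitivity.
#'
#' @param dsA,dsB \code{\link{expression_dataset}} objects (or file paths
#'   readable by \code{\link{read_expression}}).
#' @param genes genes to model; default all shared genes (after the screen,
#'   when a classifier is supplied).
#' @param cfg a \code{\link{dyde_config}}.
#' @param classifier optional \code{rhythm_classifier}; when given, the
#'   rhythm screen selects the modeled genes.
#' @param top_k links to report in the nu-gap ranking.
#' @param out_dir optional directory; when given, writes
#'   \code{network_<condition>.json/.sif}, \code{comparison.tsv},
#'   \code{connectivity.tsv} and \code{report.json}.
#' @param verbose progress messages.
#' @return report list: \code{config}, \code{genes}, \code{link_counts}
#'   (validated A/B, lost, common), \code{top_nugap}, \code{connectivity},
#'   \code{networks}, \code{comparison}, and \code{screen} (when run).
#' @export
run_pipeline <- function(dsA, dsB, genes = NULL, cfg = dyde_config(),
                         classifier = NULL, top_k = 5, out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(dsA)) dsA <- read_expression(dsA)
  if (is.character(dsB)) dsB <- read_expression(dsB)
  screen <- NULL
  if (is.null(genes)) genes <- intersect(dsA$gene_ids, dsB$gene_ids)
  if (!is.null(classifier)) {
    scrA <- rhythm_screen(subset_genes(dsA, genes), classifier, cfg)
    scrB <- rhythm_screen(subset_genes(dsB, genes), classifier, cfg)
    keep <- scrA$gene[scrA$is_rhythmic & scrA$gene %in%
                        scrB$gene[scrB$is_rhythmic]]
    screen <- list(A = scrA, B = scrB, selected = keep)
    genes <- keep
  }
  if (length(genes) < 2)
    stop("pipeline stage 'gene selection': fewer than 2 genes to model")
  fits <- fit_both_conditions(dsA, dsB, genes, cfg, verbose)
  netA <- validate_links(fits$A, cfg$fit_threshold_pct)
  netB <- validate_links(fits$B, cfg$fit_threshold_pct)
  cmp <- compare_networks(netA, netB, cfg$local_band, cfg)
  top <- rank_nu_gaps(cmp, top_k)
  sens <- connectivity_loss_sensitivity(fits$A, fits$B,
                                        cfg$fit_threshold_pct)
  report <- list(
    config = unclass(cfg),
    genes = genes,
    link_counts = list(validated_A = nrow(netA$links),
                       validated_B = nrow(netB$links),
                       lost = nrow(cmp$lost), common = nrow(cmp$common),
                       gained = nrow(cmp$gained)),
    top_nugap = top,
    connectivity = merge(cmp$connectivity, sens, by = "gene"),
    networks = list(A = netA, B = netB),
    comparison = cmp,
    screen = screen)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in c("A", "B")) {
    net <- report$networks[[cond]]
    label <- net$links$condition[1]
    if (is.na(label) || is.null(label)) label <- cond
    write_network_json(net, file.path(out_dir,
                                      sprintf("network_%s.json", label)))
    write_network_sif(net, file.path(out_dir, sprintf("network_%s.sif", label)))
  }
  tsv <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(report$comparison$common, "comparison.tsv")
  tsv(report$connectivity, "connectivity.tsv")
  jsonlite::write_json(
    list(config = report$config, genes = report$genes,
         link_counts = report$link_counts, top_nugap = report$top_nugap,
         connectivity = report$connectivity),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# --- command-line interface -------------------------------------------------

parse_cli_args <- function(args) {
  flags <- list(); pos <- character(0); i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        flags[[key]] <- args[i + 1]; i <- i + 2
      } else { flags[[key]] <- TRUE; i <- i + 1 }
    } else { pos <- c(pos, a); i <- i + 1 }
  }
  list(flags = flags, pos = pos)
}

cli_config <- function(flags) {
  cfg <- dyde_config()
  if (!is.null(flags$config)) {
    over <- jsonlite::read_json(flags$config, simplifyVector = TRUE)
    cfg[names(over)] <- over
  }
  if (!is.null(flags$threshold))
    cfg$fit_threshold_pct <- as.numeric(flags$threshold)
  if (!is.null(flags$seed)) cfg$rng_seed <- as.integer(flags$seed)
  if (!is.null(flags$band)) {
    b <- as.numeric(strsplit(flags$band, ":")[[1]])
    cfg$rhythm_band <- b
    cfg$local_band <- 2 * pi / rev(b)
  }
  cfg
}

#' Command-line entry point
#'
#' Dispatches the subcommands \code{rhythm}, \code{fit}, \code{compare},
#' \code{nugap}, \code{scan}, \code{bench}, \code{simulate} and \code{run};
#' the installed \code{exec/dyde} script forwards to this function.  Flags
#' override keys of an optional \code{--config} JSON file.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
dyde_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: dyde <rhythm|fit|compare|nugap|scan|bench|simulate|run> [--flags]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  p <- parse_cli_args(args[-1])
  fl <- p$flags
  cfg <- cli_config(fl)
  switch(cmd,
    rhythm = {
      ds <- read_expression(fl$input)
      lab <- make_labeled_series(100, 100, cfg, seed = cfg$rng_seed)
      feats <- labeled_features(lab, cfg)
      model <- if (!is.null(fl$model)) load_classifier(fl$model)
               else train_classifier(feats$features, feats$labels)
      calls <- rhythm_screen(ds, model, cfg)
      write.table(calls, fl$out, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    fit = {
      ds <- read_expression(fl$input,
                            condition = if (is.null(fl$condition)) NULL
                                        else fl$condition)
      genes <- if (!is.null(fl$genes)) readLines(fl$genes) else ds$gene_ids
      links <- fit_all_pairs(ds, genes, cfg, verbose = isTRUE(fl$verbose))
      net <- validate_links(links, cfg$fit_threshold_pct)
      write_network_json(net, fl$out)
    },
    compare = {
      netA <- read_network_json(p$pos[1])
      netB <- read_network_json(p$pos[2])
      cmp <- compare_networks(netA, netB, cfg$local_band, cfg)
      jsonlite::write_json(
        list(common = cmp$common, lost = cmp$lost, gained = cmp$gained,
             connectivity = cmp$connectivity),
        fl$out, auto_unbox = TRUE, digits = NA)
    },
    nugap = {
      m1 <- read_network_json(p$pos[1])$links[1, ]
      m2 <- read_network_json(p$pos[2])$links[1, ]
      res <- nu_gap(row_model(m1), row_model(m2), cfg$local_band, cfg)
      jsonlite::write_json(unclass(res), fl$out %||% stdout(),
                           auto_unbox = TRUE, digits = NA)
    },
    scan = {
      dsA <- read_expression(fl$a); dsB <- read_expression(fl$b)
      genes <- if (!is.null(fl$genes)) readLines(fl$genes)
               else intersect(dsA$gene_ids, dsB$gene_ids)
      res <- if (identical(fl$mode, "hubs")) {
        genome_scan_hubs(dsA, dsB, readLines(fl$core), cfg = cfg)
      } else genome_scan_perturbed(dsA, dsB, genes, cfg)
      jsonlite::write_json(res, fl$out, auto_unbox = TRUE, digits = NA)
    },
    bench = {
      net <- read_network_json(fl$input)
      truth <- read.table(fl$truth, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
      es <- edge_scores(net$links, truth)
      jsonlite::write_json(list(auroc = auroc(es), aupr = aupr(es)),
                           fl$out, auto_unbox = TRUE, digits = NA)
    },
    simulate = {
      spec <- synthetic_spec(seed = cfg$rng_seed)
      sim <- simulate_pair(spec)
      pre <- fl$`out-prefix` %||% "sim_"
      write_expression(sim$baseline, paste0(pre, "baseline.tsv"))
      write_expression(sim$perturbed, paste0(pre, "perturbed.tsv"))
      write.table(sim$truth, paste0(pre, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    },
    run = {
      rep <- run_pipeline(fl$a, fl$b, cfg = cfg, out_dir = fl$out,
                          verbose = isTRUE(fl$verbose))
      message("pipeline done: ", rep$link_counts$common, " common links")
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
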