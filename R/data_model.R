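#' Expression time-course dataset
#'
#' Container for a genes x replicates x time points expression tensor on a
#' uniform hour grid, with a condition label.  This is the single input type
#' of every analysis stage; values are used as-is (the intended input is
#' normalized log-scale expression, e.g. gcRMA), with no rescaling.
#'
#' @param values numeric 3-d array, dimensions gene x replicate x time.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param times numeric vector of sampling times in hours, strictly
#'   increasing with a constant step.
#' @param condition condition label, e.g. \code{"untreated"}.
#'
#' @return object of class \code{expression_dataset} with fields
#'   \code{gene_ids}, \code{times}, \code{values}, \code{condition}.
#' @export
expression_dataset <- function(values, gene_ids, times,
                               condition = "unspecified") {
  values <- as.array(values)
  if (length(dim(values)) != 3)
    stop("values must be a 3-d array: gene x replicate x time")
  gene_ids <- as.character(gene_ids)
  times <- as.numeric(times)
  if (dim(values)[1] != length(gene_ids))
    stop("first dimension of values must match gene_ids")
  if (dim(values)[3] != length(times))
    stop("third dimension of values must match times")
  if (length(times) < 3)
    stop("at least 3 time points are required")
  if (anyDuplicated(gene_ids))
    stop("gene_ids must be unique")
  if (!all(is.finite(values)))
    stop("all expression values must be finite")
  check_uniform_grid(times)
  dimnames(values) <- list(gene_ids, NULL, NULL)
  structure(list(gene_ids = gene_ids, times = times, values = values,
                 condition = as.character(condition)[1]),
            class = "expression_dataset")
}

check_uniform_grid <- function(times) {
  d <- diff(times)
  if (any(d <= 0))
    stop("times must be strictly increasing")
  if (length(d) > 1 && any(abs(d - d[1]) > 1e-9 * max(abs(d[1]), 1)))
    stop("time grid is not uniform: steps ",
         paste(signif(unique(round(d, 9)), 6), collapse = ", "))
  invisible(d[1])
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d genes, %d replicates, %d time points (%g-%g h, dt %g h), condition '%s'\n",
    length(x$gene_ids), dim(x$values)[2], length(x$times),
    x$times[1], x$times[length(x$times)], diff(x$times)[1], x$condition))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Subset a dataset to a gene set
#'
#' @param ds an \code{expression_dataset}.
#' @param genes character vector of gene identifiers to keep (order kept).
#' @return an \code{expression_dataset} restricted to \code{genes}.
#' @export
subset_genes <- function(ds, genes) {
  missing <- setdiff(genes, ds$gene_ids)
  if (length(missing))
    stop("unknown genes: ", paste(missing, collapse = ", "))
  expression_dataset(ds$values[genes, , , drop = FALSE], genes, ds$times,
                     ds$condition)
}

#' Read an expression time-course file
#'
#' Two plain-text dialects are supported.  \emph{Wide}: one row per gene,
#' first column the gene identifier, remaining column names
#' \code{<condition>:<replicate>:<time_h>} (condition part optional, i.e.
#' \code{<replicate>:<time_h>}).  \emph{Long}: columns
#' \code{gene, condition, replicate, time_h, value}.  Genes with any missing
#' value are dropped with a warning; missing values are never imputed.
#'
#' @param path file path (TSV by default).
#' @param sep field separator.
#' @param format \code{"auto"}, \code{"wide"} or \code{"long"}.
#' @param condition condition to extract when the file stores several;
#'   default takes the first encountered.
#' @return an \code{\link{expression_dataset}}.
#' @export
read_expression <- function(path, sep = "\t", format = c("auto", "wide", "long"),
                            condition = NULL) {
  format <- match.arg(format)
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (format == "auto") {
    format <- if (all(c("gene", "replicate", "time_h", "value") %in%
                      names(df))) "long" else "wide"
  }
  if (format == "long") return(long_to_dataset(df, condition))
  wide_to_dataset(df, condition, path)
}

wide_to_dataset <- function(df, condition, path) {
  gene_ids <- as.character(df[[1]])
  hdr <- names(df)[-1]
  parts <- strsplit(hdr, ":", fixed = TRUE)
  n_parts <- lengths(parts)
  if (any(!n_parts %in% 2:3))
    stop("cannot parse column header(s): ",
         paste(hdr[!n_parts %in% 2:3], collapse = ", "),
         " (expected [condition:]replicate:time_h)")
  cond <- vapply(parts, function(p) if (length(p) == 3) p[1] else "unspecified",
                 "")
  rep_idx <- vapply(parts, function(p) as.integer(p[length(p) - 1]), 1L)
  time_h <- vapply(parts, function(p) as.numeric(p[length(p)]), 1)
  if (anyNA(rep_idx) || anyNA(time_h))
    stop("non-numeric replicate/time field in column headers of ", path)
  if (is.null(condition)) condition <- cond[1]
  keep <- cond == condition
  if (!any(keep)) stop("condition '", condition, "' not found in ", path)
  vals <- as.matrix(df[, -1, drop = FALSE][, keep, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop("non-numeric cell at row ", bad[1, 1], ", column ", bad[1, 2] + 1,
         " of ", path)
  }
  rep_idx <- rep_idx[keep]; time_h <- time_h[keep]
  if (anyNA(vals)) {
    drop <- unique(which(is.na(vals), arr.ind = TRUE)[, 1])
    warning("dropping ", length(drop), " gene(s) with missing values: ",
            paste(head(gene_ids[drop], 5), collapse = ", "),
            if (length(drop) > 5) ", ...")
    vals <- vals[-drop, , drop = FALSE]
    gene_ids <- gene_ids[-drop]
  }
  reps <- sort(unique(rep_idx))
  times <- sort(unique(time_h))
  arr <- array(NA_real_, c(length(gene_ids), length(reps), length(times)))
  for (j in seq_along(rep_idx)) {
    arr[, match(rep_idx[j], reps), match(time_h[j], times)] <- vals[, j]
  }
  if (anyNA(arr))
    stop("incomplete replicate x time grid in ", path)
  expression_dataset(arr, gene_ids, times, condition)
}

long_to_dataset <- function(df, condition) {
  if (!"condition" %in% names(df)) df$condition <- "unspecified"
  if (is.null(condition)) condition <- df$condition[1]
  df <- df[df$condition == condition, , drop = FALSE]
  if (!nrow(df)) stop("condition '", condition, "' not found")
  if (!is.numeric(df$value))
    stop("non-numeric 'value' entries in long-format input")
  genes <- unique(df$gene)
  reps <- sort(unique(df$replicate))
  times <- sort(unique(df$time_h))
  arr <- array(NA_real_, c(length(genes), length(reps), length(times)))
  arr[cbind(match(df$gene, genes), match(df$replicate, reps),
            match(df$time_h, times))] <- df$value
  miss <- apply(arr, 1, anyNA)
  if (any(miss)) {
    warning("dropping ", sum(miss), " gene(s) with missing values")
    arr <- arr[!miss, , , drop = FALSE]
    genes <- genes[!miss]
  }
  expression_dataset(arr, genes, times, condition)
}

#' Write an expression dataset
#'
#' Writes the wide dialect understood by \code{\link{read_expression}}; the
#' numeric content round-trips exactly (values are printed with full
#' precision).  A JSON metadata sidecar (\code{<path>.meta.json}) records
#' gene count, times and condition.
#'
#' @param ds an \code{expression_dataset}.
#' @param path output file path.
#' @param sep field separator.
#' @param sidecar logical, write the JSON metadata sidecar.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(ds, path, sep = "\t", sidecar = FALSE) {
  nr <- dim(ds$values)[2]
  cols <- list(gene = ds$gene_ids)
  for (r in seq_len(nr)) {
    for (ti in seq_along(ds$times)) {
      nm <- sprintf("%s:%d:%s", ds$condition, r,
                    format(ds$times[ti], digits = 15))
      cols[[nm]] <- ds$values[, r, ti]
    }
  }
  df <- as.data.frame(cols, check.names = FALSE)
  old <- options(scipen = 0, digits = 15); on.exit(options(old))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(n_genes = length(ds$gene_ids), times = ds$times,
           n_replicates = nr, condition = ds$condition),
      paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Replicate-averaged series for one gene
#'
#' @param ds an \code{expression_dataset}.
#' @param gene gene identifier.
#' @return numeric vector over time (arithmetic mean across replicates).
#' @export
average_replicates <- function(ds, gene) {
  if (!gene %in% ds$gene_ids) stop("unknown gene: ", gene)
  m <- ds$values[gene, , , drop = TRUE]
  if (is.null(dim(m))) return(as.numeric(m))   # single replicate
  colMeans(m)
}

#' Remove the best straight-line fit from a series
#'
#' Ordinary least-squares detrending; the residual has zero mean and zero
#' OLS slope, and the operation is idempotent.
#'
#' @param series numeric values over time.
#' @param times sampling times (hours); defaults to the sample index.
#' @return detrended numeric vector.
#' @export
detrend <- function(series, times = seq_along(series)) {
  if (length(series) < 2) stop("detrend needs at least 2 points")
  if (length(series) != length(times)) stop("series/times length mismatch")
  tc <- times - mean(times)
  slope <- sum(tc * series) / sum(tc * tc)
  series - mean(series) - slope * tc
}
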