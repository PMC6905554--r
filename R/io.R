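# Readers and writers for the plain-text formats the pipeline exchanges:
# an expression CSV/TSV (first column gene id, remaining columns samples)
# with the sample -> condition mapping either in a two-column sidecar file
# or encoded in the sample names, plus the two-file benchmark layout used
# by the AML study's supplementary material (a positives-only expression
# CSV and the complete matrix).

#' Read a gene x sample expression table
#'
#' @param path CSV or TSV file; first column gene ids, remaining columns
#'   one sample each. The delimiter is sniffed from the header line.
#' @param condition Either a character vector of per-sample labels, the
#'   path to a two-column sidecar file (`sample_id, condition`, header
#'   optional), or `NULL` to infer labels from sample names (names
#'   containing `AML`/`disease`/`tumor`, case-insensitively, are disease).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, condition = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  gene_ids <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  sample_ids <- colnames(values)
  cond <- resolve_condition(condition, sample_ids)
  expression_matrix(values, gene_ids = gene_ids, sample_ids = sample_ids,
                    condition = cond)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

resolve_condition <- function(condition, sample_ids) {
  if (is.null(condition)) {
    dis <- grepl("aml|disease|tumor|tumour|cancer", sample_ids,
                 ignore.case = TRUE)
    return(ifelse(dis, "disease", "healthy"))
  }
  if (length(condition) == 1L && file.exists(condition)) {
    map <- utils::read.table(condition, header = FALSE, sep = sniff_sep(condition),
                             stringsAsFactors = FALSE)
    if (tolower(map[1, 2]) %in% c("condition", "label", "group")) {
      map <- map[-1, , drop = FALSE]
    }
    idx <- match(sample_ids, as.character(map[[1]]))
    if (anyNA(idx)) {
      stop("condition map is missing samples: ",
           paste(utils::head(sample_ids[is.na(idx)], 3), collapse = ", "),
           call. = FALSE)
    }
    return(normalize_condition(as.character(map[[2]])[idx]))
  }
  if (length(condition) != length(sample_ids)) {
    stop(sprintf("'condition' has %d labels for %d samples (or names a file that does not exist)",
                 length(condition), length(sample_ids)), call. = FALSE)
  }
  normalize_condition(condition)
}

normalize_condition <- function(x) {
  x <- tolower(as.character(x))
  out <- ifelse(x %in% c("disease", "aml", "tumor", "tumour", "cancer",
                         "case", "patient"), "disease",
                ifelse(x %in% c("healthy", "normal", "control"),
                       "healthy", NA_character_))
  if (anyNA(out)) {
    stop("unrecognized condition labels: ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected disease/healthy synonyms)", call. = FALSE)
  }
  out
}

#' Write an expression matrix (and optional condition sidecar) as CSV
#'
#' @param expr An [expression_matrix()].
#' @param path Output CSV path; first column `gene_id`.
#' @param condition_path Optional path for a two-column
#'   `sample_id,condition` sidecar.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path, condition_path = NULL) {
  df <- data.frame(gene_id = expr$gene_ids, expr$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(condition_path)) {
    utils::write.csv(data.frame(sample_id = expr$sample_ids,
                                condition = expr$condition),
                     condition_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a benchmark in the two-file supplementary layout
#'
#' Emits the layout used by the AML study's supplementary material: a CSV
#' of the positive genes' expression rows and a CSV of the complete
#' matrix, so either file can be dropped in for the originals.
#'
#' @param benchmark A `pu_benchmark`.
#' @param positives_path,full_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_benchmark <- function(benchmark, positives_path, full_path) {
  f <- benchmark$features
  pos <- data.frame(
    gene_id = benchmark$positives,
    f[match(benchmark$positives, rownames(f)), , drop = FALSE],
    check.names = FALSE)
  utils::write.csv(pos, positives_path, row.names = FALSE, quote = FALSE)
  full <- data.frame(gene_id = rownames(f), f, check.names = FALSE)
  utils::write.csv(full, full_path, row.names = FALSE, quote = FALSE)
  invisible(c(positives_path, full_path))
}

#' Read a benchmark from the two-file supplementary layout
#'
#' The positives file fixes the positive gene set; every other gene in the
#' full matrix is unlabeled. Sample conditions are resolved as in
#' [read_expression()].
#'
#' @param positives_path CSV of positive genes' expression rows.
#' @param full_path CSV of the complete expression matrix.
#' @param condition As in [read_expression()].
#' @return List with `benchmark` (a `pu_benchmark`) and `expr` (the full
#'   [expression_matrix()]).
#' @export
read_benchmark <- function(positives_path, full_path, condition = NULL) {
  pos_sep <- sniff_sep(positives_path)
  pos_ids <- as.character(
    utils::read.table(positives_path, header = TRUE, sep = pos_sep,
                      check.names = FALSE, stringsAsFactors = FALSE)[[1]])
  expr <- read_expression(full_path, condition = condition)
  missing <- setdiff(pos_ids, expr$gene_ids)
  if (length(missing) > 0L) {
    stop("positive genes absent from the full matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  bench <- pu_benchmark(pos_ids, setdiff(expr$gene_ids, pos_ids),
                        expr$values)
  list(benchmark = bench, expr = expr)
}

#' Write the generator's ground truth as a sidecar CSV
#'
#' @param truth A `synthetic_truth`.
#' @param path Output CSV path (`gene_id, role, effect` with role one of
#'   `labeled_positive`, `hidden_positive`, `null`).
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  ids <- names(truth$effects)
  role <- rep("null", length(ids))
  role[ids %in% truth$labeled_positives] <- "labeled_positive"
  role[ids %in% truth$hidden_positives] <- "hidden_positive"
  utils::write.csv(data.frame(gene_id = ids, role = role,
                              effect = unname(truth$effects)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth sidecar back into a `synthetic_truth`
#'
#' @param path File written by [write_truth()].
#' @return A `synthetic_truth` object.
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(
    disease_genes = df$gene_id[df$role != "null"],
    labeled_positives = df$gene_id[df$role == "labeled_positive"],
    hidden_positives = df$gene_id[df$role == "hidden_positive"],
    effects = stats::setNames(df$effect, df$gene_id)
  ), class = "synthetic_truth")
}
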