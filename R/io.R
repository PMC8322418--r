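# Readers and writers for the plain-text interchange formats: delimited
# expression matrices, one-id-per-line TF lists, DREAM-style edge lists
# ("TF <tab> target <tab> value", no header) and ranked edge output.

sep_for <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

#' Read a delimited expression matrix
#'
#' Expects one header row and one identifier column; TSV or CSV is chosen
#' by file extension.  With `orientation = "genes_in_columns"` the file is
#' transposed on ingestion (rows are samples, columns genes).
#'
#' @param path file path.
#' @param orientation `"genes_in_rows"` (default) or
#'   `"genes_in_columns"`.
#' @return A genes-by-samples numeric matrix with gene identifiers as row
#'   names.
#' @export
read_expression <- function(path, orientation = c("genes_in_rows", "genes_in_columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop_kpcboost("format_error", "file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep_for(path),
                      check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = "", quote = "\""),
    error = function(e) stop_kpcboost("format_error", "cannot parse ", path, ": ",
                                      conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop_kpcboost("format_error", "expression file needs an id column and at least one data column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop_kpcboost("format_error", "duplicate identifiers in ", path, ": ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (k in seq_along(vals)) {
    if (!is.numeric(vals[[k]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[k]]))))[1L]
      stop_kpcboost("format_error", "non-numeric value in column '", names(vals)[k],
                    "', row '", ids[bad], "'")
    }
  }
  M <- as.matrix(vals)
  rownames(M) <- ids
  if (anyNA(M))
    stop_kpcboost("format_error", "missing values in expression file ", path)
  if (orientation == "genes_in_columns") M <- t(M)
  M
}

#' Write an expression matrix as delimited text
#'
#' @param X genes-by-samples numeric matrix with identifiers.
#' @param path output path; `.csv` extension selects comma separation,
#'   anything else tab.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path) {
  X <- as_expression_matrix(X)
  df <- data.frame(gene_id = rownames(X),
                   matrix(sprintf("%.15g", X), nrow(X), ncol(X)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[-1L] <- colnames(X)
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a transcription-factor list
#'
#' One gene identifier per line; blank lines ignored.
#'
#' @param path file path.
#' @return Character vector of TF identifiers.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path))
    stop_kpcboost("format_error", "file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  if (!length(ids))
    stop_kpcboost("format_error", "TF list ", path, " is empty")
  if (anyDuplicated(ids))
    stop_kpcboost("format_error", "duplicate TF identifiers in ", path)
  ids
}

parse_edge_lines <- function(path) {
  if (!file.exists(path))
    stop_kpcboost("format_error", "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep))
    stop_kpcboost("format_error", "edge list ", path, " is empty")
  parts <- strsplit(lines[keep], "[\t,]")
  list(parts = parts, lineno = which(keep))
}

#' Read a DREAM-style edge list as gold standard or prior
#'
#' Lines are `TF <tab> target [<tab> value]` without a header.  In gold
#' mode the value is a 0/1 label (missing third column means 1) and pairs
#' absent from the file are treated as unlabeled (partial gold).  In prior
#' mode the value is a weight strictly inside (0, 1) written into a
#' genes-by-TFs matrix pre-filled with `default`; listing pairs at 0.6 over
#' a 0.4 default reproduces the usual ChIP-seq-derived prior construction.
#' Identifiers outside the supplied universe raise a counted warning and
#' are skipped.
#'
#' @param path file path.
#' @param mode `"gold"` or `"prior"`.
#' @param gene_ids,tf_ids identifier universe. Required in prior mode;
#'   optional in gold mode (then taken from the file itself).
#' @param default fill value of the prior matrix for unlisted pairs
#'   (default 0.5).
#' @return A [gold_standard()] (gold mode) or a prior matrix (prior mode).
#' @export
read_edge_list <- function(path, mode = c("gold", "prior"),
                           gene_ids = NULL, tf_ids = NULL, default = 0.5) {
  mode <- match.arg(mode)
  pe <- parse_edge_lines(path)
  n <- length(pe$parts)
  tf <- character(n); target <- character(n); val <- numeric(n)
  for (i in seq_len(n)) {
    p <- trimws(pe$parts[[i]])
    ln <- pe$lineno[i]
    if (length(p) < 2L || length(p) > 3L)
      stop_kpcboost("format_error", path, " line ", ln, ": expected 2 or 3 columns")
    tf[i] <- p[1L]; target[i] <- p[2L]
    if (tf[i] == target[i])
      stop_kpcboost("format_error", path, " line ", ln, ": self-loop ", tf[i],
                    " -> ", target[i])
    if (length(p) == 2L) {
      if (mode == "prior")
        stop_kpcboost("format_error", path, " line ", ln,
                      ": prior mode requires an explicit weight column")
      val[i] <- 1
    } else {
      v <- suppressWarnings(as.numeric(p[3L]))
      if (is.na(v))
        stop_kpcboost("format_error", path, " line ", ln, ": non-numeric value '", p[3L], "'")
      if (mode == "gold" && !v %in% c(0, 1))
        stop_kpcboost("format_error", path, " line ", ln, ": gold label must be 0 or 1")
      if (mode == "prior" && (v <= 0 || v >= 1))
        stop_kpcboost("format_error", path, " line ", ln,
                      ": prior weight must lie strictly in (0, 1)")
      val[i] <- v
    }
  }
  if (!is.null(gene_ids) || !is.null(tf_ids)) {
    ok <- rep(TRUE, n)
    if (!is.null(tf_ids)) ok <- ok & tf %in% tf_ids
    if (!is.null(gene_ids)) ok <- ok & target %in% gene_ids
    if (any(!ok)) {
      warning(sum(!ok), " edge(s) with identifiers outside the universe skipped in ",
              path, call. = FALSE)
      tf <- tf[ok]; target <- target[ok]; val <- val[ok]
    }
  }
  if (mode == "gold") {
    return(gold_standard(data.frame(tf = tf, target = target, label = as.integer(val),
                                    stringsAsFactors = FALSE),
                         tf_ids = tf_ids, gene_ids = gene_ids))
  }
  if (is.null(gene_ids) || is.null(tf_ids))
    stop_kpcboost("invalid_parameter_error", "prior mode requires 'gene_ids' and 'tf_ids'")
  if (default <= 0 || default >= 1)
    stop_kpcboost("invalid_parameter_error", "'default' must lie strictly in (0, 1)")
  W <- matrix(default, length(gene_ids), length(tf_ids),
              dimnames = list(gene_ids, tf_ids))
  W[cbind(match(target, gene_ids), match(tf, tf_ids))] <- val
  W
}

#' Write a gold standard as a DREAM-style edge list
#'
#' Three tab-separated columns (TF, target, 0/1 label), no header.
#'
#' @param gold a [gold_standard()].
#' @param path output path.
#' @param positives_only write only label-1 rows.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(gold, path, positives_only = FALSE) {
  ed <- gold$edges
  if (positives_only) ed <- ed[ed$label == 1L, , drop = FALSE]
  utils::write.table(ed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the ranked edge list of a fitted network
#'
#' Tab-separated `TF target score` rows, score descending, ties broken by
#' (TF, target) lexicographically; no header, no self pairs.
#'
#' @param fit a fitted [kboost()] object.
#' @param path output path.
#' @param use_scaled rank by the variance-scaled matrix instead of the raw
#'   posterior.
#' @return `path`, invisibly.
#' @export
write_ranked_edges <- function(fit, path, use_scaled = FALSE) {
  df <- ranked_edges(fit, use_scaled = use_scaled)
  df$score <- sprintf("%.12g", df$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a ranked edge list written by [write_ranked_edges()]
#'
#' @param path file path.
#' @return Data frame with columns `tf`, `target`, `score`.
#' @export
read_ranked_edges <- function(path) {
  pe <- parse_edge_lines(path)
  bad <- which(lengths(pe$parts) != 3L)
  if (length(bad))
    stop_kpcboost("format_error", path, " line ", pe$lineno[bad[1L]],
                  ": expected 3 columns")
  m <- do.call(rbind, pe$parts)
  score <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(score))
    stop_kpcboost("format_error", "non-numeric score in ", path)
  data.frame(tf = m[, 1L], target = m[, 2L], score = score,
             stringsAsFactors = FALSE)
}

# Full posterior matrix with an id column, for the infer sidecar outputs.
write_matrix_tsv <- function(M, path) {
  df <- data.frame(gene_id = rownames(M),
                   matrix(sprintf("%.12g", M), nrow(M), ncol(M)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[-1L] <- colnames(M)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
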