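# Internal helpers shared across the package.

# Classed conditions so callers/tests can distinguish failure modes.
stop_kpcboost <- function(class, ..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "kpcboost_error", "error", "condition")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed` and
#' restores the previous RNG state afterwards, so seeded simulators never
#' disturb the caller's random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}

# Coerce to a validated genes-by-samples numeric matrix with unique ids.
as_expression_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop_kpcboost("invalid_input_error", "expression data must be a numeric matrix (genes x samples)")
  if (anyNA(X) || any(!is.finite(X)))
    stop_kpcboost("invalid_input_error", "expression matrix contains missing or non-finite values")
  if (nrow(X) < 2L)
    stop_kpcboost("invalid_input_error", "need at least 2 genes, got ", nrow(X))
  if (is.null(rownames(X))) rownames(X) <- paste0("gene_", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("sample_", seq_len(ncol(X)))
  if (anyDuplicated(rownames(X)))
    stop_kpcboost("format_error", "duplicate gene identifiers: ",
                  paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "))
  X
}

# Resolve a TF designation (gene ids or row indices) to integer row indices.
resolve_tf_index <- function(X, tf_ids) {
  if (length(tf_ids) < 1L)
    stop_kpcboost("invalid_parameter_error", "at least one transcription factor must be given")
  if (is.character(tf_ids)) {
    idx <- match(tf_ids, rownames(X))
    if (anyNA(idx))
      stop_kpcboost("invalid_parameter_error", "unknown TF identifiers: ",
                    paste(tf_ids[is.na(idx)], collapse = ", "))
  } else if (is.numeric(tf_ids)) {
    idx <- as.integer(tf_ids)
    if (any(idx < 1L | idx > nrow(X)))
      stop_kpcboost("invalid_parameter_error", "TF row indices out of range [1, ", nrow(X), "]")
  } else {
    stop_kpcboost("invalid_parameter_error", "'tf_ids' must be gene identifiers or row indices")
  }
  if (anyDuplicated(idx))
    stop_kpcboost("invalid_parameter_error", "duplicated TF entries")
  idx
}
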