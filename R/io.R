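# Plain-text serialization of the package's tabular formats.

#' Write / read a beta-value matrix as TSV
#'
#' Samples in rows (first column `sample_id`), CpG identifiers as column
#' headers.
#'
#' @param beta Numeric matrix with sample row names and CpG column names.
#' @param path Output file.
#' @export
write_beta_matrix <- function(beta, path) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  df <- data.frame(sample_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  beta <- as.matrix(df[, -1, drop = FALSE])
  rownames(beta) <- df[[1]]
  storage.mode(beta) <- "double"
  beta
}

#' Write / read a sample table as CSV
#'
#' Columns: sample_id, diagnosis (0 = control, 1 = case), age, sex (0/1),
#' tissue (integer code), cohort.
#'
#' @param samples Sample table data frame.
#' @param path Output file.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_table(df)
  df
}

validate_sample_table <- function(samples, beta = NULL) {
  required <- c("sample_id", "diagnosis", "age", "sex", "tissue")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    stop("sample table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id in sample table", call. = FALSE)
  }
  if (!all(samples$diagnosis %in% c(0L, 1L))) {
    stop("diagnosis must be 0 (control) or 1 (case)", call. = FALSE)
  }
  if (!is.null(beta) && !all(samples$sample_id %in% rownames(beta))) {
    stop("sample table contains ids absent from the beta matrix", call. = FALSE)
  }
  invisible(samples)
}

validate_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) stop("beta must be a numeric matrix", call. = FALSE)
  if (is.null(colnames(beta)) || anyDuplicated(colnames(beta))) {
    stop("beta matrix must have unique CpG column names", call. = FALSE)
  }
  if (is.null(rownames(beta)) || anyDuplicated(rownames(beta))) {
    stop("beta matrix must have unique sample row names", call. = FALSE)
  }
  rng <- range(beta, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1) {
    stop("beta values must be finite and in [0,1] (NA allowed for missing)", call. = FALSE)
  }
  invisible(beta)
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the weights, the architecture spec, the CpG id list
#' (to guarantee index alignment at prediction time), and training metadata
#' under a versioned schema.
#'
#' @param model A fitted [methformer()] object.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "methformer"))
  obj <- unclass(model)
  obj$checkpoint_schema <- "methformer-checkpoint-v1"
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$checkpoint_schema, "methformer-checkpoint-v1")) {
    stop("unrecognized checkpoint schema", call. = FALSE)
  }
  obj$checkpoint_schema <- NULL
  structure(obj, class = "methformer")
}
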