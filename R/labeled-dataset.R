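#' Labeled two-class descriptor dataset
#'
#' The universal input container of the package: a numeric descriptor matrix
#' `X` (one row per object), a two-class label vector `y` with levels coded
#' `1` and `2`, and an optional per-object novelty flag. `feature_kind`
#' records whether the descriptors are continuous (e.g. physicochemical
#' properties) or binary (fingerprint-like 0/1 substructure keys); binary
#' descriptors are left unscaled by the pipeline while continuous ones are
#' autoscaled.
#'
#' @param X numeric matrix, n objects x p descriptors.
#' @param y integer vector of class labels in `{1, 2}`, length n.
#' @param feature_kind `"continuous"` or `"binary"`.
#' @param novel_flag optional logical vector of length n marking objects
#'   displaced from the training density.
#' @param name free-text dataset label.
#' @return an object of class `labeled_dataset` (a list with fields `X`,
#'   `y`, `feature_kind`, `novel_flag`, `name`).
#' @export
labeled_dataset <- function(X, y, feature_kind = c("continuous", "binary"),
                            novel_flag = NULL, name = "dataset") {
  feature_kind <- match.arg(feature_kind)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (nrow(X) < 2L) stop("a labeled_dataset needs at least 2 objects")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(1L, 2L))) stop("class labels must be coded 1 and 2")
  if (feature_kind == "binary" && !all(X %in% c(0, 1)))
    stop("binary feature_kind requires every entry of X to be 0 or 1")
  if (!is.null(novel_flag)) {
    novel_flag <- as.logical(novel_flag)
    if (length(novel_flag) != nrow(X))
      stop("novel_flag must have exactly one entry per object")
  }
  structure(list(X = X, y = y, feature_kind = feature_kind,
                 novel_flag = novel_flag, name = name),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset '%s': %d objects x %d %s descriptors\n",
              x$name, nrow(x$X), ncol(x$X), x$feature_kind))
  tab <- table(factor(x$y, levels = c(1L, 2L)))
  cat(sprintf("  class ratio: %d/%d (%.0f%%/%.0f%%)\n", tab[1L], tab[2L],
              100 * tab[1L] / length(x$y), 100 * tab[2L] / length(x$y)))
  if (!is.null(x$novel_flag))
    cat(sprintf("  novel objects: %d\n", sum(x$novel_flag)))
  invisible(x)
}

#' Write a labeled dataset as delimited text
#'
#' One row per object, descriptor columns first, then a `label` column in
#' `{1,2}` and, when present, a `novel` column in `{0,1}`. UTF-8, header row.
#'
#' @param ds a [labeled_dataset()].
#' @param path output CSV path.
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_dataset"))
  df <- as.data.frame(ds$X)
  if (is.null(colnames(ds$X)))
    names(df) <- paste0("d", seq_len(ncol(ds$X)))
  df$label <- ds$y
  if (!is.null(ds$novel_flag)) df$novel <- as.integer(ds$novel_flag)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a labeled dataset from delimited text
#'
#' Inverse of [write_dataset_csv()]. `feature_kind` is inferred: binary if
#' every descriptor entry is 0/1, continuous otherwise (override via the
#' argument).
#'
#' @param path CSV path with a `label` column and optional `novel` column.
#' @param feature_kind optional override, `"continuous"` or `"binary"`.
#' @param name dataset label; defaults to the file name.
#' @return a [labeled_dataset()].
#' @export
read_dataset_csv <- function(path, feature_kind = NULL, name = NULL) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!"label" %in% names(df)) stop("CSV must contain a 'label' column")
  y <- df$label
  novel <- if ("novel" %in% names(df)) df$novel == 1L else NULL
  X <- as.matrix(df[setdiff(names(df), c("label", "novel"))])
  if (is.null(feature_kind))
    feature_kind <- if (all(X %in% c(0, 1))) "binary" else "continuous"
  labeled_dataset(X, y, feature_kind, novel_flag = novel,
                  name = name %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a fixed RNG seed and restore the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
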