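#' Construct a landmark dataset
#'
#' A `landmark_dataset` bundles the landmark configurations of n specimens
#' (a k x d x n array, d = 2 or 3, coordinates in the digitizer's units,
#' typically mm) with a specimen-level metadata table. Every specimen has the
#' same k landmarks in the same order; landmark homology across specimens is
#' the caller's responsibility.
#'
#' @param coords Numeric k x d x n array. The first dimnames component gives
#'   the landmark names (required, unique); the third the specimen ids
#'   (required, unique).
#' @param metadata Optional `data.frame` with a `specimen_id` column matching
#'   the third dimension of `coords` one-to-one. When `NULL`, a minimal table
#'   holding only `specimen_id` is created.
#' @return An object of class `landmark_dataset` with elements `coords` and
#'   `metadata` (rows ordered as the specimens).
#' @seealso [read_tps()], [read_landmark_csv()], [attach_metadata()]
#' @export
#' @examples
#' tri <- array(c(0, 1, 0, 0, 0, 1), dim = c(3, 2, 1),
#'              dimnames = list(c("a", "b", "c"), NULL, "sp1"))
#' landmark_dataset(tri)
landmark_dataset <- function(coords, metadata = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L)
    stop("'coords' must be a k x d x n array", call. = FALSE)
  d <- dim(coords)[2L]
  k <- dim(coords)[1L]
  n <- dim(coords)[3L]
  if (!d %in% c(2L, 3L)) stop("coordinate dimension must be 2 or 3", call. = FALSE)
  if (k < 3L) stop("at least 3 landmarks are required", call. = FALSE)
  if (!all(is.finite(coords))) stop("all coordinates must be finite", call. = FALSE)
  lm_names <- dimnames(coords)[[1L]]
  ids <- dimnames(coords)[[3L]]
  if (is.null(lm_names)) lm_names <- paste0("lm", seq_len(k))
  if (is.null(ids)) ids <- paste0("specimen_", seq_len(n))
  if (anyDuplicated(lm_names)) stop("duplicate landmark names", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate specimen ids", call. = FALSE)
  dimnames(coords) <- list(lm_names, c("x", "y", "z")[seq_len(d)], ids)
  if (is.null(metadata)) {
    metadata <- data.frame(specimen_id = ids, stringsAsFactors = FALSE)
  } else {
    if (!"specimen_id" %in% names(metadata))
      stop("'metadata' must have a 'specimen_id' column", call. = FALSE)
    mi <- match(ids, metadata$specimen_id)
    if (anyNA(mi))
      stop("metadata missing specimen id(s): ",
           paste(ids[is.na(mi)], collapse = ", "), call. = FALSE)
    metadata <- metadata[mi, , drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(list(coords = coords, metadata = metadata),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  dm <- dim(x$coords)
  cat(sprintf("Landmark dataset: %d specimens, %d landmarks, %dD\n",
              dm[3L], dm[1L], dm[2L]))
  extra <- setdiff(names(x$metadata), "specimen_id")
  if (length(extra))
    cat("metadata columns:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname landmark_dataset
#' @param x A `landmark_dataset`.
#' @export
n_specimens <- function(x) dim(x$coords)[3L]

#' @rdname landmark_dataset
#' @export
n_landmarks <- function(x) dim(x$coords)[1L]

#' @rdname landmark_dataset
#' @export
landmark_names <- function(x) dimnames(x$coords)[[1L]]

#' @rdname landmark_dataset
#' @export
specimen_ids <- function(x) dimnames(x$coords)[[3L]]

#' Extract one specimen's configuration
#'
#' @param dataset A `landmark_dataset`.
#' @param specimen Specimen id (character) or index.
#' @return A k x d coordinate matrix with landmark names as row names.
#' @export
get_configuration <- function(dataset, specimen) {
  if (is.character(specimen)) {
    i <- match(specimen, specimen_ids(dataset))
    if (is.na(i)) stop("unknown specimen id: ", specimen, call. = FALSE)
  } else i <- specimen
  dataset$coords[, , i]
}

#' Attach specimen metadata to a landmark dataset
#'
#' Joins a metadata table onto a dataset by `specimen_id`. The join is strict:
#' every configuration must match exactly one table row. Rows of the table
#' that match no configuration are dropped with a warning. Columns other than
#' `specimen_id`, `sex` and `group` are treated as numeric predictors and must
#' be numeric.
#'
#' @param dataset A `landmark_dataset`.
#' @param table A `data.frame` keyed by `specimen_id`.
#' @return The dataset with `metadata` replaced by the joined table.
#' @export
attach_metadata <- function(dataset, table) {
  stopifnot(inherits(dataset, "landmark_dataset"), is.data.frame(table))
  if (!"specimen_id" %in% names(table))
    stop("metadata table must have a 'specimen_id' column", call. = FALSE)
  dup <- unique(table$specimen_id[duplicated(table$specimen_id)])
  if (length(dup))
    stop("duplicate specimen id(s) in metadata: ",
         paste(dup, collapse = ", "), call. = FALSE)
  ids <- specimen_ids(dataset)
  mi <- match(ids, table$specimen_id)
  if (anyNA(mi))
    stop("no metadata row for specimen id(s): ",
         paste(ids[is.na(mi)], collapse = ", "), call. = FALSE)
  unused <- setdiff(table$specimen_id, ids)
  if (length(unused))
    warning("dropping metadata rows with no matching configuration: ",
            paste(unused, collapse = ", "), call. = FALSE)
  joined <- table[mi, , drop = FALSE]
  rownames(joined) <- NULL
  pred_cols <- setdiff(names(joined), c("specimen_id", "sex", "group"))
  for (cn in pred_cols) {
    if (!is.numeric(joined[[cn]]))
      stop("predictor column '", cn, "' is not numeric", call. = FALSE)
    if (anyNA(joined[[cn]]))
      stop("predictor column '", cn, "' has missing values", call. = FALSE)
  }
  dataset$metadata <- joined
  dataset
}
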