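#' Read landmark configurations from a TPS file
#'
#' Parses the widely used TPS landmark dialect: each record starts with an
#' `LM=k` (2D) or `LM3=k` (3D) line, followed by exactly k whitespace-separated
#' coordinate lines, an optional `SCALE=` line (applied multiplicatively to the
#' record's coordinates) and a mandatory `ID=` line. `IMAGE=` and `CURVES=`
#' lines are ignored. All records in one file must share the same dimensionality
#' and landmark count. Landmarks are unnamed in TPS; names default to
#' `lm1 ... lmk`.
#'
#' @param path Path to a TPS file.
#' @return A [landmark_dataset()] whose metadata holds only `specimen_id`.
#' @seealso [write_tps()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  recs <- list()
  i <- 1L
  rec_no <- 0L
  while (i <= length(lines)) {
    header <- lines[i]
    m <- regmatches(header, regexec("^(LM3?)=\\s*([0-9]+)$", header))[[1L]]
    if (length(m) == 0L)
      stop("TPS parse error: expected LM=/LM3= header at line '", header, "'",
           call. = FALSE)
    rec_no <- rec_no + 1L
    d <- if (m[2L] == "LM3") 3L else 2L
    k <- as.integer(m[3L])
    i <- i + 1L
    coord <- matrix(NA_real_, k, d)
    for (j in seq_len(k)) {
      if (i > length(lines) || grepl("^[A-Z]+3?=", lines[i]))
        stop("TPS parse error in record ", rec_no, ": declared ", k,
             " landmarks but found ", j - 1L, " coordinate lines",
             call. = FALSE)
      vals <- suppressWarnings(as.numeric(strsplit(lines[i], "[ \t]+")[[1L]]))
      if (length(vals) != d || anyNA(vals))
        stop("TPS parse error in record ", rec_no, ": bad coordinate line '",
             lines[i], "'", call. = FALSE)
      coord[j, ] <- vals
      i <- i + 1L
    }
    id <- NULL
    scale <- 1
    while (i <= length(lines) && grepl("^[A-Z]+=", lines[i])) {
      kv <- sub("^([A-Z]+)=.*$", "\\1", lines[i])
      val <- sub("^[A-Z]+=", "", lines[i])
      if (kv == "ID") { id <- trimws(val); i <- i + 1L }
      else if (kv == "SCALE") { scale <- as.numeric(val); i <- i + 1L }
      else if (kv %in% c("IMAGE", "CURVES", "POINTS", "COMMENT")) i <- i + 1L
      else break
    }
    if (is.null(id))
      stop("TPS parse error in record ", rec_no, ": missing ID= line",
           call. = FALSE)
    recs[[length(recs) + 1L]] <- list(coord = coord * scale, d = d, id = id)
  }
  if (!length(recs)) stop("TPS file contains no records", call. = FALSE)
  ds <- vapply(recs, function(r) r$d, integer(1))
  ks <- vapply(recs, function(r) nrow(r$coord), integer(1))
  if (length(unique(ds)) != 1L)
    stop("TPS format error: mixed 2D and 3D records in one file", call. = FALSE)
  if (length(unique(ks)) != 1L)
    stop("TPS format error: records have differing landmark counts",
         call. = FALSE)
  coords <- array(unlist(lapply(recs, function(r) r$coord)),
                  dim = c(ks[1L], ds[1L], length(recs)),
                  dimnames = list(paste0("lm", seq_len(ks[1L])), NULL,
                                  vapply(recs, function(r) r$id, character(1))))
  # unlist concatenates column-major per record, matching array filling order
  landmark_dataset(coords)
}

#' Write a landmark dataset to a TPS file
#'
#' Coordinates are written with 6 decimal places, one `LM=`/`LM3=` record per
#' specimen followed by an `ID=` line. Landmark names are not representable in
#' TPS and are dropped; use the CSV writers to preserve them.
#'
#' @param dataset A `landmark_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(dataset, path) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  d <- dim(dataset$coords)[2L]
  k <- n_landmarks(dataset)
  tag <- if (d == 3L) "LM3" else "LM"
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_specimens(dataset))) {
    writeLines(sprintf("%s=%d", tag, k), con)
    m <- dataset$coords[, , i]
    writeLines(apply(m, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")),
               con)
    writeLines(paste0("ID=", specimen_ids(dataset)[i]), con)
  }
  invisible(path)
}

#' Read landmark coordinates from CSV
#'
#' Two layouts are supported. `wide`: one row per specimen with a
#' `specimen_id` column and coordinate columns named `<landmark>_x`,
#' `<landmark>_y` (and `_z` for 3D). `long`: columns `specimen_id`,
#' `landmark`, `x`, `y` (and `z`). Landmark ordering is taken from the first
#' specimen (wide: column order). Every specimen must provide every landmark.
#'
#' @param path Path to a CSV file.
#' @param layout `"wide"` or `"long"`.
#' @return A [landmark_dataset()].
#' @seealso [write_landmark_csv()]
#' @export
read_landmark_csv <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (layout == "wide") {
    if (!"specimen_id" %in% names(df))
      stop("wide layout requires a 'specimen_id' column", call. = FALSE)
    cc <- setdiff(names(df), "specimen_id")
    ax <- sub("^.*_([xyz])$", "\\1", cc)
    lm <- sub("_[xyz]$", "", cc)
    if (!all(ax %in% c("x", "y", "z")))
      stop("wide coordinate columns must end in _x, _y or _z", call. = FALSE)
    lm_names <- unique(lm)
    d <- length(unique(ax))
    axes <- c("x", "y", "z")[seq_len(d)]
    coords <- array(NA_real_, c(length(lm_names), d, nrow(df)),
                    dimnames = list(lm_names, axes, df$specimen_id))
    for (li in seq_along(lm_names)) for (ai in seq_len(d)) {
      col <- paste0(lm_names[li], "_", axes[ai])
      if (!col %in% cc)
        stop("missing coordinate column '", col, "'", call. = FALSE)
      coords[li, ai, ] <- df[[col]]
    }
  } else {
    need <- c("specimen_id", "landmark", "x", "y")
    if (!all(need %in% names(df)))
      stop("long layout requires columns specimen_id, landmark, x, y[, z]",
           call. = FALSE)
    d <- if ("z" %in% names(df)) 3L else 2L
    axes <- c("x", "y", "z")[seq_len(d)]
    ids <- unique(df$specimen_id)
    lm_names <- df$landmark[df$specimen_id == ids[1L]]
    coords <- array(NA_real_, c(length(lm_names), d, length(ids)),
                    dimnames = list(lm_names, axes, ids))
    for (id in ids) {
      sub <- df[df$specimen_id == id, , drop = FALSE]
      mi <- match(lm_names, sub$landmark)
      if (anyNA(mi) || nrow(sub) != length(lm_names))
        stop("specimen '", id, "' is missing landmark(s): ",
             paste(setdiff(lm_names, sub$landmark), collapse = ", "),
             call. = FALSE)
      for (ai in seq_len(d)) coords[, ai, id] <- sub[[axes[ai]]][mi]
    }
  }
  if (anyNA(coords)) {
    bad <- which(is.na(coords), arr.ind = TRUE)
    stop("missing coordinate for specimen '",
         dimnames(coords)[[3L]][bad[1L, 3L]], "', landmark '",
         dimnames(coords)[[1L]][bad[1L, 1L]], "'", call. = FALSE)
  }
  landmark_dataset(coords)
}

#' Write landmark coordinates to CSV
#'
#' @inheritParams read_landmark_csv
#' @param dataset A `landmark_dataset`.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(dataset, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(dataset, "landmark_dataset"))
  d <- dim(dataset$coords)[2L]
  axes <- c("x", "y", "z")[seq_len(d)]
  lm <- landmark_names(dataset)
  ids <- specimen_ids(dataset)
  if (layout == "wide") {
    out <- data.frame(specimen_id = ids, stringsAsFactors = FALSE)
    for (li in seq_along(lm)) for (ai in seq_len(d))
      out[[paste0(lm[li], "_", axes[ai])]] <- dataset$coords[li, ai, ]
  } else {
    out <- do.call(rbind, lapply(seq_along(ids), function(i) {
      m <- dataset$coords[, , i, drop = FALSE][, , 1L]
      cbind(data.frame(specimen_id = ids[i], landmark = lm,
                       stringsAsFactors = FALSE),
            as.data.frame(m))
    }))
    names(out) <- c("specimen_id", "landmark", axes)
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
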