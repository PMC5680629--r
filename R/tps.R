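# TPS landmark file I/O (the tpsDig dialect: LM=, coordinate lines, ID=,
# optional SCALE=).  Raw TPS coordinates are conventionally in image
# orientation with y increasing downward; by default y is negated on read
# and on write so that in-memory coordinates are in mathematical orientation
# and write -> read round-trips exactly.

#' Read landmark configurations from a TPS file
#'
#' Parses records of the form `LM=k`, followed by `k` lines of `x y`
#' coordinates, an `ID=` line and an optional `SCALE=` line.  A record whose
#' coordinate-line count disagrees with its `LM=` header is an error naming
#' the record; a record without `ID=` gets a sequential id with a warning.
#'
#' @param path TPS file path.
#' @param flip_y negate y on read (image convention is y-down); default TRUE.
#' @return A named list of `k x 2` coordinate matrices, one per specimen;
#'   each element carries its `SCALE=` value (or `NA`) as attribute `scale`.
#' @export
read_tps <- function(path, flip_y = TRUE) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines)
  if (length(starts) == 0L) stop("no LM= records found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  ids <- character(length(starts))
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    k <- as.integer(sub("^LM\\s*=\\s*", "", rec[1L]))
    coord_lines <- rec[-1L][!grepl("^[A-Za-z]", rec[-1L])]
    if (length(coord_lines) != k)
      stop(sprintf("TPS record %d: LM=%d but %d coordinate lines found",
                   r, k, length(coord_lines)))
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "\\s+"), as.numeric))
    if (any(is.na(xy)) || ncol(xy) != 2L)
      stop(sprintf("TPS record %d: malformed coordinate line", r))
    if (flip_y) xy[, 2L] <- -xy[, 2L]
    id_line <- grep("^ID\\s*=", rec, value = TRUE)
    if (length(id_line) == 0L) {
      ids[r] <- sprintf("specimen_%d", r)
      warning(sprintf("TPS record %d has no ID=; using '%s'", r, ids[r]))
    } else {
      ids[r] <- sub("^ID\\s*=\\s*", "", id_line[1L])
    }
    scale_line <- grep("^SCALE\\s*=", rec, value = TRUE)
    attr(xy, "scale") <- if (length(scale_line))
      as.numeric(sub("^SCALE\\s*=\\s*", "", scale_line[1L])) else NA_real_
    colnames(xy) <- c("x", "y")
    out[[r]] <- xy
  }
  names(out) <- ids
  out
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: `write_tps` then `read_tps` reproduces the
#' coordinates to the printed precision (6 decimals by default).
#'
#' @param configs a `k x 2 x n` array or a (named) list of `k x 2` matrices.
#' @param path output file path.
#' @param ids specimen ids; defaults to array/list names.
#' @param flip_y negate y on write (to image convention); default TRUE.
#' @param digits coordinate decimals written.
#' @return Invisibly, `path`.
#' @export
write_tps <- function(configs, path, ids = NULL, flip_y = TRUE, digits = 6) {
  configs <- landmark_list(configs)
  if (is.null(ids)) ids <- names(configs)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- sprintf("specimen_%d", seq_along(configs))
  con <- file(path, open = "wb")  # binary mode: LF line endings everywhere
  on.exit(close(con))
  fmt <- paste0("%.", digits, "f %.", digits, "f")
  for (i in seq_along(configs)) {
    xy <- configs[[i]]
    y <- if (flip_y) -xy[, 2L] else xy[, 2L]
    writeLines(c(sprintf("LM=%d", nrow(xy)),
                 sprintf(fmt, xy[, 1L], y),
                 sprintf("ID=%s", ids[i])),
               con, sep = "\n")
  }
  invisible(path)
}

#' Stack a list of landmark configurations into an array
#'
#' @param configs list of `k x 2` matrices with identical landmark counts,
#'   or an array (returned as is).
#' @return A `k x 2 x n` array with specimen ids as third dimnames.
#' @export
landmark_array <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3L) return(configs)
  ks <- vapply(configs, nrow, integer(1))
  if (length(unique(ks)) != 1L)
    stop("configurations have differing landmark counts: ",
         paste(unique(ks), collapse = ", "))
  arr <- array(unlist(lapply(configs, function(m) m[, 1:2])),
               c(ks[[1L]], 2L, length(configs)),
               dimnames = list(NULL, c("x", "y"), names(configs)))
  arr
}

landmark_list <- function(configs) {
  if (is.list(configs)) return(configs)
  stopifnot(is.array(configs), length(dim(configs)) == 3L)
  n <- dim(configs)[3L]
  out <- lapply(seq_len(n), function(i) configs[, , i])
  names(out) <- dimnames(configs)[[3L]]
  out
}
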