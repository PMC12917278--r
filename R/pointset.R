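# PointSet: the package's basic container. An n x d coordinate matrix with
# optional labels and domain/split tags, validated on construction.

#' Construct a point set
#'
#' @param coords Numeric matrix (n x d) of coordinates/features. A vector is
#'   treated as a single-column matrix.
#' @param labels Optional numeric or binary vector of length n.
#' @param domain_tag One of `"source"`, `"target"`; may be `NA` for generic data.
#' @param split_tag One of `"train"`, `"test"`, `"all"`.
#' @return An object of class `point_set` with elements `coords`, `labels`,
#'   `domain_tag`, `split_tag`, and dimensions `n`, `d`.
#' @export
point_set <- function(coords, labels = NULL, domain_tag = NA_character_,
                      split_tag = "all") {
  if (is.vector(coords)) coords <- matrix(coords, ncol = 1L)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) < 1L) stop("point_set: need at least one point", call. = FALSE)
  if (!all(is.finite(coords))) stop("point_set: non-finite coordinates", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.numeric(labels)
    if (length(labels) != nrow(coords))
      stop("point_set: labels length must equal the number of rows", call. = FALSE)
  }
  if (!is.na(domain_tag) && !domain_tag %in% c("source", "target"))
    stop("point_set: domain_tag must be 'source' or 'target'", call. = FALSE)
  if (!split_tag %in% c("train", "test", "all"))
    stop("point_set: split_tag must be 'train', 'test' or 'all'", call. = FALSE)
  structure(list(coords = coords, labels = labels, domain_tag = domain_tag,
                 split_tag = split_tag, n = nrow(coords), d = ncol(coords)),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("point_set: %d points in %d dimensions%s%s\n", x$n, x$d,
              if (!is.na(x$domain_tag)) paste0(", domain=", x$domain_tag) else "",
              if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

# Row subset preserving labels and tags.
subset_points <- function(ps, idx, split_tag = ps$split_tag) {
  point_set(ps$coords[idx, , drop = FALSE],
            labels = if (is.null(ps$labels)) NULL else ps$labels[idx],
            domain_tag = ps$domain_tag, split_tag = split_tag)
}

#' Write a point set to CSV
#'
#' Columns are `x1..xd`, then optionally `y`, `domain`, `split`. Full float
#' precision, comma separated, header included.
#'
#' @param ps A `point_set`.
#' @param path Output file path.
#' @export
write_point_set <- function(ps, path) {
  df <- as.data.frame(ps$coords)
  names(df) <- paste0("x", seq_len(ps$d))
  if (!is.null(ps$labels)) df$y <- ps$labels
  if (!is.na(ps$domain_tag)) df$domain <- ps$domain_tag
  df$split <- ps$split_tag
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a point set from CSV
#'
#' Expects the schema written by [write_point_set()]: coordinate columns
#' `x1..xd` (or `f1..fD`), optional `y`, `domain`, `split` columns.
#'
#' @param path CSV file path.
#' @return A `point_set`.
#' @export
read_point_set <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cc <- grep("^[xf][0-9]+$", names(df), value = TRUE)
  if (length(cc) == 0L) stop("read_point_set: no coordinate columns x1..xd found",
                             call. = FALSE)
  point_set(as.matrix(df[cc]),
            labels = if ("y" %in% names(df)) df$y else NULL,
            domain_tag = if ("domain" %in% names(df)) df$domain[1L] else NA_character_,
            split_tag = if ("split" %in% names(df)) df$split[1L] else "all")
}

# Normalize bounds input: a length-2 vector recycled to all axes, or a d x 2
# matrix of per-axis (lower, upper).
expand_bounds <- function(bounds, d) {
  if (is.matrix(bounds)) {
    if (nrow(bounds) != d || ncol(bounds) != 2L)
      stop("bounds matrix must be d x 2", call. = FALSE)
    return(bounds)
  }
  if (length(bounds) != 2L || bounds[2L] <= bounds[1L])
    stop("bounds must be an increasing interval", call. = FALSE)
  matrix(rep(as.numeric(bounds), each = d), nrow = d)
}
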