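# Adapters for external tabular point data (species occurrences, cell
# layouts): standardization, deterministic PCA projection, and temporal
# source/target splitting validated by the LCF clustering diagnostic.
# Ingestion starts from a prepared CSV (columns f1..fD or x1..xd, y in {0,1},
# optional year); raster extraction, occurrence cleaning and coordinate
# systems are out of scope.

#' Read a feature table from CSV
#'
#' Schema: numeric feature columns `f1..fD` (or `x1..xd`), a binary label
#' column `y`, optional `year` and `id` columns, comma separated with header.
#' Rows with missing values are dropped with a message reporting the count.
#'
#' @param path CSV path.
#' @return A `feature_table`: data frame with attributes `feature_cols`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  feature_table(df)
}

#' Construct a feature table from a data frame
#'
#' @param df Data frame with feature columns `f1..fD` or `x1..xd`, optional
#'   `y`, `year`, `id`.
#' @return A `feature_table`.
#' @export
feature_table <- function(df) {
  fc <- grep("^[fx][0-9]+$", names(df), value = TRUE)
  if (length(fc) == 0L)
    stop("feature_table: no feature columns f1..fD or x1..xd", call. = FALSE)
  keep <- stats::complete.cases(df)
  if (any(!keep)) {
    message(sprintf("feature_table: dropped %d rows with missing values",
                    sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("feature_table: no complete rows", call. = FALSE)
  structure(df, feature_cols = fc, class = c("feature_table", "data.frame"))
}

ft_coords <- function(table) as.matrix(table[attr(table, "feature_cols")])

#' Standardize feature columns to zero mean and unit variance
#'
#' Statistics are computed on the rows passed in `stats_rows` (by default all
#' rows -- callers supply the pooled source+target training rows, whose
#' unlabeled covariates are legitimately available under covariate shift) and
#' applied to every row. Zero-variance features are dropped with a warning.
#' The transform (centers and scales) is retained as an attribute for reuse;
#' applying it to already-standardized data re-centers rather than acting as
#' the identity.
#'
#' @param table A `feature_table`.
#' @param stats_rows Logical or integer row index for the statistics
#'   (default: all rows).
#' @return The standardized `feature_table` with attribute `transform`.
#' @export
standardize <- function(table, stats_rows = NULL) {
  stopifnot(inherits(table, "feature_table"))
  fc <- attr(table, "feature_cols")
  x <- ft_coords(table)
  ref <- if (is.null(stats_rows)) x else x[stats_rows, , drop = FALSE]
  ctr <- colMeans(ref)
  scl <- apply(ref, 2L, stats::sd)
  zero <- scl <= 0 | !is.finite(scl)
  if (any(zero)) {
    warning(sprintf("standardize: dropping %d zero-variance feature(s): %s",
                    sum(zero), paste(fc[zero], collapse = ", ")), call. = FALSE)
    table[fc[zero]] <- NULL
    fc <- fc[!zero]; x <- x[, !zero, drop = FALSE]
    ctr <- ctr[!zero]; scl <- scl[!zero]
    attr(table, "feature_cols") <- fc
  }
  if (length(fc) == 0L)
    stop("standardize: all features have zero variance", call. = FALSE)
  table[fc] <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  attr(table, "transform") <- list(center = ctr, scale = scl)
  table
}

#' Project features onto principal components
#'
#' Deterministic PCA with a sign convention (the largest-magnitude loading of
#' each component is made positive), so repeated runs are bit-identical.
#' `n_components = "all"` is the identity (no projection).
#'
#' @param table A `feature_table`.
#' @param n_components Integer in `1..d_raw` (typically 2, 3 or 4) or
#'   `"all"`.
#' @return A `feature_table` whose features are the component scores
#'   (`f1..fK`); rotation and centers as attribute `pca`.
#' @export
project_pca <- function(table, n_components) {
  stopifnot(inherits(table, "feature_table"))
  if (identical(n_components, "all")) return(table)
  x <- ft_coords(table)
  if (n_components < 1L || n_components > ncol(x))
    stop("project_pca: n_components out of range", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2L, flip, "*")
  scores <- sweep(x, 2L, pc$center) %*% rot
  out <- table
  out[attr(table, "feature_cols")] <- NULL
  new_fc <- paste0("f", seq_len(n_components))
  for (j in seq_len(n_components)) out[[new_fc[j]]] <- scores[, j]
  attr(out, "feature_cols") <- new_fc
  attr(out, "pca") <- list(rotation = rot, center = pc$center)
  out
}

#' Convert a feature table to a point set
#'
#' @param table A `feature_table`.
#' @param domain_tag Optional domain tag.
#' @return A `point_set` with the feature columns as coordinates and `y` (if
#'   present) as labels.
#' @export
as_point_set <- function(table, domain_tag = NA_character_) {
  point_set(ft_coords(table),
            labels = if ("y" %in% names(table)) table$y else NULL,
            domain_tag = domain_tag)
}

#' Split a feature table into source and target by year
#'
#' Rows with `year <= cut_year` form the early side, the rest the late side.
#' The assignment is then validated by the LCF clustering diagnostic: the
#' more-clustered side becomes the source (swapping if the late side is more
#' clustered), matching the convention that models are trained on clustered
#' observations and deployed on dispersed ones.
#'
#' @param table A `feature_table` with a `year` column.
#' @param cut_year Integer cut.
#' @param r_max Maximum LCF radius for the validation.
#' @param seed Seed for the CSR reference.
#' @return List with `source`, `target` (feature tables) and `swapped`
#'   (logical).
#' @export
temporal_split <- function(table, cut_year, r_max = 25, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (!"year" %in% names(table))
    stop("temporal_split: no 'year' column", call. = FALSE)
  early <- table$year <= cut_year
  if (all(early) || !any(early))
    stop("temporal_split: cut leaves one side empty (degenerate split)",
         call. = FALSE)
  a <- table[early, , drop = FALSE]; b <- table[!early, , drop = FALSE]
  for (s in list(a, b)) attr(s, "feature_cols") <- attr(table, "feature_cols")
  attr(a, "feature_cols") <- attr(table, "feature_cols")
  attr(b, "feature_cols") <- attr(table, "feature_cols")
  class(a) <- class(b) <- class(table)
  ord <- rank_by_clustering(list(as_point_set(a), as_point_set(b)),
                            r_max = r_max, seed = seed)
  swapped <- ord[1L] == 2L
  list(source = if (swapped) b else a, target = if (swapped) a else b,
       swapped = swapped)
}
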