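#' Boolean marker-combination percentages
#'
#' From per-cell boolean positivity matrices, computes for each sample the
#' percentage of gated cells positive for every marker in each combination
#' (AND-gates). The default combination set is all non-empty subsets of the
#' marker panel, the Boolean-gating construction used for inhibitory
#' receptor co-expression profiling.
#'
#' @param samples named list; each element is a logical matrix
#'   (cells x markers) for one sample (mouse), all with identical marker
#'   columns. An all-TRUE lineage gate is assumed to have been applied
#'   upstream; an empty matrix is an error.
#' @param combos optional list of character vectors (marker subsets). `NULL`
#'   uses all non-empty AND-subsets.
#' @param max_markers guard against combinatorial explosion when
#'   `combos = NULL`.
#' @return a `feature_table`: data.frame samples x features of percentages
#'   in `[0, 100]`, feature names like `"TIM3+PD1+"`, with attribute
#'   `feature_kind` (`"percentage"` per column).
#' @export
combo_percentages <- function(samples, combos = NULL, max_markers = 10) {
  stopifnot(is.list(samples), length(samples) >= 1)
  markers <- colnames(samples[[1]])
  stopifnot(!is.null(markers))
  for (s in samples) {
    if (!identical(colnames(s), markers))
      stop("marker set differs across samples")
    if (nrow(s) == 0) stop("empty lineage gate in a sample")
  }
  if (is.null(combos)) {
    if (length(markers) > max_markers)
      stop("refusing to enumerate 2^", length(markers), " subsets; pass combos")
    combos <- unlist(lapply(seq_along(markers), function(k)
      utils::combn(markers, k, simplify = FALSE)), recursive = FALSE)
  }
  feat_names <- vapply(combos, function(cm) paste0(paste(cm, collapse = "+"), "+"), "")
  vals <- t(vapply(samples, function(s) {
    vapply(combos, function(cm) {
      100 * mean(rowSums(!s[, cm, drop = FALSE]) == 0)
    }, numeric(1))
  }, numeric(length(combos))))
  df <- as.data.frame(vals)
  names(df) <- feat_names
  rownames(df) <- names(samples)
  attr(df, "feature_kind") <- setNames(rep("percentage", ncol(df)), names(df))
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Attach a transformed-volume feature to a feature table
#'
#' @param table a `feature_table`.
#' @param volume_mm3 per-sample tumor volumes (mm^3), `> 0`, in row order.
#' @param name feature name.
#' @return the table with one added `volume` column.
#' @export
add_volume_feature <- function(table, volume_mm3, name = "tumor_volume") {
  stopifnot(length(volume_mm3) == nrow(table), all(volume_mm3 > 0))
  kind <- attr(table, "feature_kind")
  table[[name]] <- volume_mm3
  attr(table, "feature_kind") <- c(kind, setNames("volume", name))
  table
}

#' Variance-stabilising feature transforms
#'
#' Percentage features are arcsine-square-root transformed as fractions,
#' `asin(sqrt(p / 100))`; volume features are `log10` transformed.
#'
#' @param table a `feature_table` from [combo_percentages()] (optionally
#'   with [add_volume_feature()]).
#' @return the transformed `feature_table`; `feature_kind` is updated to
#'   `"transformed"` per column.
#' @export
transform_features <- function(table) {
  kind <- attr(table, "feature_kind")
  stopifnot(!is.null(kind))
  for (col in names(kind)) {
    v <- table[[col]]
    if (kind[[col]] == "percentage") {
      if (any(v < 0 | v > 100)) stop("percentage outside [0, 100] in ", col)
      table[[col]] <- asin(sqrt(v / 100))
    } else if (kind[[col]] == "volume") {
      if (any(v <= 0)) stop("non-positive volume in ", col)
      table[[col]] <- log10(v)
    }
  }
  attr(table, "feature_kind") <- setNames(rep("transformed", length(kind)),
                                          names(kind))
  table
}

#' Column standardisation to zero mean / unit SD
#'
#' Per-column z-scores with sample SD (n - 1 denominator). Constant columns
#' carry no information on the correlation scale and are dropped with a
#' warning.
#'
#' @param table a `feature_table` or plain data.frame of numeric features.
#' @return the standardized table (class preserved).
#' @export
standardize <- function(table) {
  sds <- vapply(table, sd, numeric(1))
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(names(table)[const], collapse = ", "))
    kind <- attr(table, "feature_kind")
    cls <- class(table)
    table <- table[, !const, drop = FALSE]
    if (!is.null(kind)) attr(table, "feature_kind") <- kind[!const]
    class(table) <- cls
  }
  for (col in names(table))
    table[[col]] <- (table[[col]] - mean(table[[col]])) / sd(table[[col]])
  table
}

#' Correlation-scale PCA with eigenvalue retention, cos2 and contributions
#'
#' Eigendecomposition of the sample covariance of the standardized data
#' (the correlation matrix of the raw features). Components with eigenvalue
#' above 1 are retained. Variable coordinates are `loading * sqrt(lambda)`;
#' cos2 is the squared coordinate; the contribution of a variable to a
#' component is `100 * cos2 / sum(cos2)` over variables, summing to 100 per
#' component.
#'
#' @param table a standardized feature table (see [standardize()]); rows =
#'   samples (`>= 2`), columns = variables (`>= 2`). With
#'   `scale = "covariance"` the data are centred but not rescaled.
#' @param scale `"correlation"` (default; expects standardized input) or
#'   `"covariance"`.
#' @return object of class `pca_model`: list with `eigenvalues`, `loadings`
#'   (orthonormal columns), `scores`, `retained` (indices with eigenvalue
#'   > 1), `coordinates`, `cos2`, `contribution` and `n_variables`.
#' @export
fit_pca <- function(table, scale = c("correlation", "covariance")) {
  scale <- match.arg(scale)
  x <- as.matrix(as.data.frame(table))
  stopifnot(is.numeric(x))
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (ncol(x) < 2) stop("need at least 2 variables")
  if (scale == "correlation") {
    # tolerate already-standardized input; re-standardize defensively
    x <- scale(x, center = TRUE, scale = apply(x, 2, sd))
  } else {
    x <- scale(x, center = TRUE, scale = FALSE)
  }
  n <- nrow(x); p <- ncol(x)
  sv <- svd(x)
  k <- length(sv$d)
  lambda <- numeric(min(n - 1, p))
  dd <- sv$d[seq_len(min(k, length(lambda)))]
  lambda[seq_along(dd)] <- dd^2 / (n - 1)
  loadings <- sv$v[, seq_along(lambda), drop = FALSE]
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- paste0("PC", seq_along(lambda))
  scores <- x %*% loadings
  coords <- sweep(loadings, 2, sqrt(lambda), `*`)
  cos2 <- coords^2
  contr <- sweep(cos2, 2, colSums(cos2), `/`) * 100
  structure(list(
    eigenvalues = lambda,
    loadings = loadings,
    scores = scores,
    retained = which(lambda > 1),
    coordinates = coords,
    cos2 = cos2,
    contribution = contr,
    n_variables = p,
    scale = scale
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf("<pca_model> %d variables, %d components, %d retained (eigenvalue > 1)\n",
              x$n_variables, length(ev), length(x$retained)))
  cat("  eigenvalues:", paste(format(round(ev[seq_len(min(5, length(ev)))], 3)),
                              collapse = ", "),
      if (length(ev) > 5) "..." else "", "\n")
  invisible(x)
}

#' 95% confidence ellipse of 2D component scores
#'
#' Population-covariance chi-square construction (the convention of common
#' factor-map plots): semi-axes are `sqrt(qchisq(level, 2) * eigenvalue)`
#' along the score-covariance eigenvectors.
#'
#' @param scores_2d numeric matrix (n x 2) of component scores for one
#'   group.
#' @param level coverage level (default 0.95).
#' @return list with `center`, `semi_axes` (major, minor), `angle_rad`
#'   (major-axis angle) and `cov`.
#' @export
group_ellipse <- function(scores_2d, level = 0.95) {
  scores_2d <- as.matrix(scores_2d)
  stopifnot(ncol(scores_2d) == 2, nrow(scores_2d) >= 3)
  ctr <- colMeans(scores_2d)
  cv <- cov(scores_2d)
  e <- eigen(cv, symmetric = TRUE)
  r2 <- qchisq(level, df = 2)
  list(center = ctr,
       semi_axes = sqrt(r2 * pmax(e$values, 0)),
       angle_rad = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       cov = cv)
}

#' Point-in-ellipse test for a fitted group ellipse
#'
#' @param ellipse result of [group_ellipse()].
#' @param points n x 2 matrix.
#' @param level coverage level the ellipse was built with.
#' @return logical vector: Mahalanobis distance within the chi-square
#'   radius.
#' @export
in_ellipse <- function(ellipse, points, level = 0.95) {
  d <- sweep(as.matrix(points), 2, ellipse$center)
  md2 <- rowSums((d %*% solve(ellipse$cov)) * d)
  md2 <= qchisq(level, df = 2)
}
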