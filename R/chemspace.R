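# The constant chemical reference space: zero-mean/unit-variance scaling of
# the seven descriptors, Euclidean distances, and PCA projection.

#' Fit the chemical reference space scaler
#'
#' Computes per-descriptor means and sample standard deviations (ddof = 1)
#' over a set of molecules. The fitted scaler defines the constant reference
#' space in which all distances of a scoring run are measured; by default it
#' is fitted once on the union of all assayed analogs and all virtual
#' candidates of the run.
#'
#' @param data Data frame containing the descriptor columns.
#' @param columns Descriptor columns to use (default: the seven reference
#'   descriptors).
#' @return An object of class `progsat_chemspace` with elements `means`,
#'   `sds`, `n_fit` and `constant` (names of zero-variance columns, which
#'   scale to 0 with a warning).
#' @export
fit_chemspace <- function(data, columns = descriptor_names) {
  stopifnot(all(columns %in% names(data)))
  if (nrow(data) < 2) {
    stop("At least 2 rows are required to fit the reference space.",
         call. = FALSE)
  }
  m <- as.matrix(data[, columns])
  storage.mode(m) <- "double"
  means <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  constant <- columns[sds == 0]
  if (length(constant)) {
    warning("Constant descriptor column(s) scale to 0: ",
            paste(constant, collapse = ", "), call. = FALSE)
  }
  structure(list(means = means, sds = sds, n_fit = nrow(m),
                 columns = columns, constant = constant),
            class = "progsat_chemspace")
}

#' @export
print.progsat_chemspace <- function(x, ...) {
  cat("Chemical reference space scaler (", x$n_fit, " molecules)\n", sep = "")
  print(round(rbind(mean = x$means, sd = x$sds), 4))
  invisible(x)
}

#' Scale descriptors into the reference space
#'
#' @param data Data frame with the descriptor columns of `space`.
#' @param space A fitted [fit_chemspace()] scaler.
#' @return `data` with the descriptor columns replaced by their z-scaled
#'   values (constant columns map to 0).
#' @export
scale_descriptors <- function(data, space) {
  stopifnot(inherits(space, "progsat_chemspace"),
            all(space$columns %in% names(data)))
  for (j in space$columns) {
    s <- space$sds[[j]]
    data[[j]] <- if (s > 0) (as.numeric(data[[j]]) - space$means[[j]]) / s
                 else rep(0, nrow(data))
  }
  data
}

#' Invert reference-space scaling
#'
#' @inheritParams scale_descriptors
#' @return `data` with descriptor columns mapped back to their original
#'   units (constant columns are restored to their fitted mean).
#' @export
unscale_descriptors <- function(data, space) {
  stopifnot(inherits(space, "progsat_chemspace"),
            all(space$columns %in% names(data)))
  for (j in space$columns) {
    data[[j]] <- as.numeric(data[[j]]) * space$sds[[j]] + space$means[[j]]
  }
  data
}

as_descriptor_matrix <- function(data, columns = descriptor_names) {
  if (is.matrix(data)) return(data)
  stopifnot(all(columns %in% names(data)))
  m <- as.matrix(data[, columns])
  storage.mode(m) <- "double"
  rownames(m) <- if ("id" %in% names(data)) data$id else NULL
  m
}

#' Euclidean distance between two scaled descriptor vectors
#'
#' @param a,b Numeric vectors of equal length (scaled descriptors).
#' @return Non-negative Euclidean distance.
#' @export
chem_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("Descriptor vectors differ in dimension (", length(a), " vs ",
         length(b), ").", call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}

# All pairwise Euclidean distances between rows of A and rows of B.
cross_distances <- function(A, B) {
  A <- as_descriptor_matrix(A); B <- as_descriptor_matrix(B)
  if (ncol(A) != ncol(B)) {
    stop("Descriptor matrices differ in dimension.", call. = FALSE)
  }
  # row-wise rowSums accumulation agrees bit-for-bit with the direct
  # sqrt(sum((a - b)^2)) evaluation (closed-ball membership is exact)
  d2 <- matrix(0, nrow(A), nrow(B))
  nb <- nrow(B)
  for (i in seq_len(nrow(A))) {
    d2[i, ] <- rowSums((B - matrix(A[i, ], nb, ncol(B), byrow = TRUE))^2)
  }
  sqrt(d2)
}

#' Project scaled descriptors onto principal components
#'
#' Principal component analysis of the (scaled) descriptor matrix, reporting
#' per-component explained-variance percentages. Used for the
#' chemical-reference-space projections that visualize a series, its actives
#' and its virtual-candidate cloud in two dimensions.
#'
#' @param data Data frame with descriptor columns (typically already scaled)
#'   or a numeric matrix.
#' @param n_components Number of components to retain (default 2).
#' @param columns Descriptor columns (ignored for matrix input).
#' @return A list of class `progsat_projection`: `coords` (tibble `id`,
#'   `PC1`, `PC2`, ...) and `explained` (percent variance per retained
#'   component, non-increasing).
#' @export
pca_project <- function(data, n_components = 2, columns = descriptor_names) {
  m <- as_descriptor_matrix(data, columns)
  if (nrow(m) < n_components) {
    stop("PCA needs at least as many rows (", nrow(m),
         ") as components (", n_components, ").", call. = FALSE)
  }
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  expl <- 100 * p$sdev^2 / sum(p$sdev^2)
  coords <- tibble::as_tibble(p$x[, seq_len(k), drop = FALSE])
  coords <- tibble::add_column(
    coords,
    id = if (!is.null(rownames(m))) rownames(m) else as.character(seq_len(nrow(m))),
    .before = 1)
  structure(list(coords = coords, explained = expl[seq_len(k)]),
            class = "progsat_projection")
}

#' @export
print.progsat_projection <- function(x, ...) {
  cat("PCA projection:", nrow(x$coords), "molecules;",
      paste0("PC", seq_along(x$explained), " = ",
             sprintf("%.1f%%", x$explained), collapse = ", "), "\n")
  invisible(x)
}
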