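# Progression-saturation scoring: neighborhood radii, raw global/local
# scores, ensemble z-scores, and the four-stage classification.

#' Global neighborhood radius
#'
#' The radius placed around every assayed analog when computing the global
#' score. For each virtual compound the distances to its top-1%-nearest
#' virtual neighbors (k = max(1, floor(fraction * (|V| - 1))), self
#' excluded) are collected, and the radius is the median of the pooled
#' distances, so neighborhoods admit only closely related candidates.
#'
#' @param virtual Scaled descriptor rows of the virtual set (data frame or
#'   matrix).
#' @param fraction Nearest-neighbor fraction (default 0.01).
#' @return The pooled-median radius. All-coincident virtual compounds give
#'   radius 0 with a degenerate-geometry warning.
#' @export
global_radius <- function(virtual, fraction = 0.01) {
  V <- as_descriptor_matrix(virtual)
  n <- nrow(V)
  if (n < 2) stop("Need at least 2 virtual compounds.", call. = FALSE)
  k <- max(1L, floor(fraction * (n - 1)))
  pooled <- numeric(n * k)
  step <- max(1L, floor(2e6 / n))
  for (s in seq(1L, n, by = step)) {
    rows <- s:min(s + step - 1L, n)
    d <- cross_distances(V[rows, , drop = FALSE], V)
    for (i in seq_along(rows)) {
      di <- d[i, -rows[i]]
      pooled[(rows[i] - 1L) * k + seq_len(k)] <-
        sort.int(di, partial = k)[seq_len(k)]
    }
  }
  r <- stats::median(pooled)
  if (r == 0) {
    warning("Degenerate geometry: pooled nearest-neighbor distances are ",
            "all zero (coincident virtual compounds).", call. = FALSE)
  }
  r
}

#' Local neighborhood radius
#'
#' The radius placed around every active analog when computing the local
#' score: the median of all pairwise distances between active analogs, so
#' neighborhoods reflect activity-relevant distances.
#'
#' @param actives Scaled descriptor rows of the active analogs.
#' @return The median pairwise distance.
#' @export
local_radius <- function(actives) {
  A <- as_descriptor_matrix(actives)
  if (nrow(A) < 2) stop("Need at least 2 active analogs.", call. = FALSE)
  D <- cross_distances(A, A)
  stats::median(D[upper.tri(D)])
}

# Minimum distance from each row of X to any row of Y, chunked.
min_dist_to_set <- function(X, Y) {
  X <- as_descriptor_matrix(X); Y <- as_descriptor_matrix(Y)
  out <- numeric(nrow(X))
  step <- max(1L, floor(2e6 / max(1L, nrow(Y))))
  for (s in seq(1L, nrow(X), by = step)) {
    rows <- s:min(s + step - 1L, nrow(X))
    d <- cross_distances(X[rows, , drop = FALSE], Y)
    out[rows] <- apply(d, 1, min)
  }
  out
}

#' Assign virtual compounds to neighborhoods
#'
#' Determines, with closed-ball membership (distance <= radius) and set
#' semantics, which virtual compounds fall inside at least one assayed
#' neighborhood (radius `r_global`) and at least one active neighborhood
#' (radius `r_local`).
#'
#' @param members Scaled descriptor rows of all assayed analogs S.
#' @param actives Scaled descriptor rows of the active subset A.
#' @param virtual Scaled descriptor rows of the virtual set V.
#' @param r_global,r_local Neighborhood radii.
#' @return A tibble with one row per virtual compound: `id` (row name or
#'   index), `in_assayed`, `in_active`.
#' @export
assign_neighborhoods <- function(members, actives, virtual,
                                 r_global, r_local) {
  V <- as_descriptor_matrix(virtual)
  ids <- if (!is.null(rownames(V))) rownames(V) else as.character(seq_len(nrow(V)))
  tibble::tibble(
    id = ids,
    in_assayed = min_dist_to_set(V, members) <= r_global,
    in_active = min_dist_to_set(V, actives) <= r_local)
}

#' Raw global saturation score
#'
#' The fraction of virtual candidates lying inside the neighborhood of at
#' least one assayed (active or inactive) analog: |nu_assayed| / |V|. Each
#' virtual compound counts once however many neighborhoods contain it. High
#' values mean the candidate cloud is already well covered by assayed
#' chemistry.
#'
#' @param members Scaled descriptor rows of the assayed analogs.
#' @param virtual Scaled descriptor rows of the virtual set.
#' @param r_global Neighborhood radius (see [global_radius()]).
#' @return A fraction in \[0, 1\].
#' @export
raw_global_score <- function(members, virtual, r_global) {
  V <- as_descriptor_matrix(virtual)
  if (nrow(V) == 0) stop("Empty virtual set.", call. = FALSE)
  if (r_global < 0) stop("Radius must be non-negative.", call. = FALSE)
  mean(min_dist_to_set(V, members) <= r_global)
}

#' Raw local saturation score
#'
#' The number of active analogs divided by the number of virtual candidates
#' inside active neighborhoods: |A| / |nu_active|. High values mean active
#' neighborhoods are sparsely populated with candidates, i.e. few likely
#' active analogs remain to be made. When no candidate falls inside any
#' active neighborhood the ratio is undefined; a 0.5 pseudo-count
#' denominator is used (ranking the series as maximally saturated) and the
#' result carries a `saturation_extreme` attribute.
#'
#' @param actives Scaled descriptor rows of the active analogs.
#' @param virtual Scaled descriptor rows of the virtual set.
#' @param r_local Neighborhood radius (see [local_radius()]).
#' @return A positive real; attribute `n_active_neighbors` holds
#'   |nu_active| and `saturation_extreme` is `TRUE` when it was zero.
#' @export
raw_local_score <- function(actives, virtual, r_local) {
  A <- as_descriptor_matrix(actives); V <- as_descriptor_matrix(virtual)
  if (nrow(A) == 0) stop("Empty active set.", call. = FALSE)
  if (nrow(V) == 0) stop("Empty virtual set.", call. = FALSE)
  n_in <- sum(min_dist_to_set(V, A) <= r_local)
  extreme <- n_in == 0L
  val <- nrow(A) / if (extreme) 0.5 else n_in
  structure(val, n_active_neighbors = as.integer(n_in),
            saturation_extreme = extreme)
}

#' Convert raw scores to ensemble z-scores
#'
#' Raw global scores are centered and scaled by the mean and sample standard
#' deviation over all series of the ensemble. Raw local scores are
#' log-transformed (natural log) first. Rank order within each score type is
#' preserved. A stored reference ensemble (means/sds from a prior run) can
#' be supplied to score fewer than two series.
#'
#' @param raw_global,raw_local Numeric vectors of per-series raw scores
#'   (`raw_local` must be positive).
#' @param reference Optional list with `mean_global`, `sd_global`,
#'   `mean_log_local`, `sd_log_local` from a previous ensemble.
#' @return A tibble with `z_global` and `z_local`; the normalization
#'   parameters are attached as attribute `reference`.
#' @export
to_z_scores <- function(raw_global, raw_local, reference = NULL) {
  stopifnot(length(raw_global) == length(raw_local))
  if (any(raw_local <= 0)) {
    stop("Raw local scores must be positive.", call. = FALSE)
  }
  if (is.null(reference)) {
    if (length(raw_global) < 2) {
      stop("z-scores are ensemble-relative: need at least 2 series, or ",
           "supply a stored reference ensemble via `reference`.",
           call. = FALSE)
    }
    reference <- list(mean_global = mean(raw_global),
                      sd_global = stats::sd(raw_global),
                      mean_log_local = mean(log(raw_local)),
                      sd_log_local = stats::sd(log(raw_local)))
  }
  if (reference$sd_global == 0 || reference$sd_log_local == 0) {
    stop("Ensemble standard deviation is zero; z-scores are undefined.",
         call. = FALSE)
  }
  structure(
    tibble::tibble(
      z_global = (raw_global - reference$mean_global) / reference$sd_global,
      z_local = (log(raw_local) - reference$mean_log_local) /
        reference$sd_log_local),
    reference = reference)
}

CATEGORY_STAGE <- c("low/high" = "early", "low/low" = "intermediate",
                    "high/low" = "late", "high/high" = "saturated")

#' Classify a series by its score combination
#'
#' A score is "high" when its z-score is at or above the threshold
#' (default 1). The four combinations map to optimization stages:
#' low/high = early, low/low = intermediate, high/low = late,
#' high/high = saturated (the saturation alert).
#'
#' @param z_global,z_local Numeric z-scores (finite).
#' @param threshold High/low threshold on both axes (default 1.0; z equal
#'   to the threshold counts as high).
#' @return Character vector of categories `"<global>/<local>"` with levels
#'   low/low, low/high, high/low, high/high.
#' @export
#' @examples
#' classify_stage(1.52, 2.39)  # "high/high"
classify_stage <- function(z_global, z_local, threshold = 1.0) {
  if (any(!is.finite(z_global)) || any(!is.finite(z_local))) {
    stop("z-scores must be finite.", call. = FALSE)
  }
  g <- ifelse(z_global >= threshold, "high", "low")
  l <- ifelse(z_local >= threshold, "high", "low")
  paste(g, l, sep = "/")
}

#' Optimization stage implied by a score category
#'
#' @param category Character vector of categories from [classify_stage()].
#' @return Character vector: early, intermediate, late or saturated.
#' @export
category_stage <- function(category) {
  unname(CATEGORY_STAGE[category])
}

#' Active neighbors of the lead compound
#'
#' Counts the active analogs (other than the lead itself) lying within the
#' local neighborhood radius of the lead.
#'
#' @param actives Data frame of scaled descriptors of the active analogs
#'   with an `id` column (or a matrix with row names).
#' @param lead_id Id of the lead; must be among the actives.
#' @param r_local Local neighborhood radius.
#' @return Non-negative integer count.
#' @export
count_active_neighbors <- function(actives, lead_id, r_local) {
  A <- as_descriptor_matrix(actives)
  ids <- rownames(A)
  if (is.null(ids) || !lead_id %in% ids) {
    stop("Lead '", lead_id, "' is not among the active analogs.",
         call. = FALSE)
  }
  i <- match(lead_id, ids)
  if (nrow(A) == 1) return(0L)
  d <- cross_distances(A[i, , drop = FALSE], A[-i, , drop = FALSE])
  sum(d <= r_local)
}
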