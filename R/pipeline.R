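# End-to-end driver: series extraction -> fragment library -> virtual
# enumeration -> reference space -> dual saturation scores -> stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score progression saturation of analog series
#'
#' Runs the full chain: extracts qualified single-site analog series from a
#' compound-activity table, builds the substituent fragment library from a
#' donor set (excluding substituents already observed in the analyzed
#' series), enumerates virtual candidate analogs per series core, fits the
#' constant seven-descriptor reference space, and computes the global and
#' local saturation scores, their ensemble z-scores and the four-stage
#' classification.
#'
#' @param compounds Data frame with `id`, `smiles`, `assay_id`, `active`,
#'   and optionally `potency` (molar). Ignored if `series` is supplied.
#' @param donors Donor structures for the fragment library (character vector
#'   or data frame with `id`, `smiles`). Ignored if `library` is supplied.
#' @param series Optional pre-extracted series tibble from
#'   [extract_series()].
#' @param library Optional pre-built [build_fragment_library()] object
#'   (exclusion is then assumed to be handled by the caller).
#' @param min_members,min_actives,max_sub_heavy,exclusive,activity_from_potency
#'   Passed to [extract_series()].
#' @param fraction Top-nearest-neighbor fraction for the global radius
#'   (default 0.01).
#' @param threshold z-score threshold separating high from low (default 1).
#' @param scaler_population Fit the reference-space scaler on the union of
#'   assayed and virtual compounds (default) or on assayed compounds only.
#' @param exclusion_scope Exclude substituents observed in any analyzed
#'   series (`"global"`, default) or only those of the series being scored
#'   (`"series"`).
#' @param reference Optional stored normalization parameters (see
#'   [to_z_scores()]) to score a small ensemble against a prior run.
#' @return An object of class `progsat_saturation`; see [tidy.progsat_saturation()].
#' @export
score_saturation <- function(compounds = NULL, donors = NULL,
                             series = NULL, library = NULL,
                             min_members = 30, min_actives = 3,
                             max_sub_heavy = 13, exclusive = FALSE,
                             activity_from_potency = NULL,
                             fraction = 0.01, threshold = 1.0,
                             scaler_population = c("union", "assayed"),
                             exclusion_scope = c("global", "series"),
                             reference = NULL) {
  scaler_population <- match.arg(scaler_population)
  exclusion_scope <- match.arg(exclusion_scope)

  if (is.null(series)) {
    if (is.null(compounds)) stop("Supply `compounds` or `series`.", call. = FALSE)
    series <- extract_series(compounds, min_members = min_members,
                             min_actives = min_actives,
                             max_sub_heavy = max_sub_heavy,
                             exclusive = exclusive,
                             activity_from_potency = activity_from_potency)
  }
  if (nrow(series) == 0) {
    stop("No qualifying analog series (>= ", min_members, " members, >= ",
         min_actives, " actives). Consider lowering the filters.",
         call. = FALSE)
  }

  all_subs <- unique(unlist(lapply(series$members, `[[`, "substituent")))
  if (is.null(library)) {
    if (is.null(donors)) stop("Supply `donors` or `library`.", call. = FALSE)
    excl <- if (exclusion_scope == "global") all_subs else character()
    library <- build_fragment_library(donors, exclusion = excl,
                                      max_sub_heavy = max_sub_heavy)
  }

  virtual <- lapply(seq_len(nrow(series)), function(i) {
    lib <- library
    if (exclusion_scope == "series") {
      own <- series$members[[i]]$substituent
      keep <- !lib$fragments$fragment %in% own
      lib$fragments <- lib$fragments[keep, , drop = FALSE]
      lib$excluded_count <- lib$excluded_count + sum(!keep)
    }
    enumerate_virtual(series$core[i], lib,
                      existing = series$members[[i]]$smiles)
  })
  names(virtual) <- series$series_id

  # one descriptor computation over every unique structure of the run
  all_smiles <- unique(c(unlist(lapply(series$members, `[[`, "smiles")),
                         unlist(lapply(virtual, function(v) v$compounds$smiles))))
  desc <- compute_descriptors(tibble::tibble(id = all_smiles,
                                             smiles = all_smiles))
  assayed_smiles <- unique(unlist(lapply(series$members, `[[`, "smiles")))
  fit_rows <- if (scaler_population == "union") desc else
    desc[desc$id %in% assayed_smiles, , drop = FALSE]
  space <- fit_chemspace(fit_rows)
  scaled <- scale_descriptors(desc, space)
  desc_of <- function(smiles, ids = smiles) {
    m <- as_descriptor_matrix(scaled[match(smiles, scaled$id), , drop = FALSE])
    rownames(m) <- ids
    m
  }

  per <- purrr::map_dfr(seq_len(nrow(series)), function(i) {
    mem <- series$members[[i]]
    vir <- virtual[[i]]$compounds
    flags <- character()
    S <- desc_of(mem$smiles, mem$id)
    A <- S[mem$active, , drop = FALSE]
    if (nrow(vir) < 2) {
      return(tibble::tibble(
        series_id = series$series_id[i], n_virtual = nrow(vir),
        r_global = NA_real_, r_local = NA_real_,
        raw_global = NA_real_, raw_local = NA_real_,
        nu_assayed = NA_integer_, nu_active = NA_integer_,
        lead_active_neighbors = NA_integer_,
        flags = "too_few_virtual_candidates"))
    }
    V <- desc_of(vir$smiles, vir$id)
    r_g <- withCallingHandlers(
      global_radius(V, fraction = fraction),
      warning = function(w) {
        flags <<- c(flags, "degenerate_virtual_geometry")
        invokeRestart("muffleWarning")
      })
    r_l <- local_radius(A)
    rg <- raw_global_score(S, V, r_g)
    rl <- raw_local_score(A, V, r_l)
    if (isTRUE(attr(rl, "saturation_extreme"))) {
      flags <- c(flags, "saturation_extreme")
    }
    lead <- series$lead_id[i]
    lead_nb <- if (!is.na(lead) && lead %in% rownames(A)) {
      count_active_neighbors(A, lead, r_l)
    } else NA_integer_
    nu_a <- sum(min_dist_to_set(V, S) <= r_g)
    tibble::tibble(
      series_id = series$series_id[i], n_virtual = nrow(vir),
      r_global = r_g, r_local = r_l,
      raw_global = rg, raw_local = as.numeric(rl),
      nu_assayed = as.integer(nu_a),
      nu_active = attr(rl, "n_active_neighbors"),
      lead_active_neighbors = lead_nb,
      flags = paste(flags, collapse = ";"))
  })

  scorable <- !is.na(per$raw_global)
  z <- tibble::tibble(z_global = rep(NA_real_, nrow(per)),
                      z_local = rep(NA_real_, nrow(per)))
  ref_out <- reference
  if (sum(scorable) >= 2 || !is.null(reference)) {
    zz <- to_z_scores(per$raw_global[scorable], per$raw_local[scorable],
                      reference = reference)
    z$z_global[scorable] <- zz$z_global
    z$z_local[scorable] <- zz$z_local
    ref_out <- attr(zz, "reference")
  }
  per$z_global <- z$z_global
  per$z_local <- z$z_local
  per$category <- ifelse(is.na(per$z_global), NA_character_,
                         classify_stage(ifelse(is.na(per$z_global), 0,
                                               per$z_global),
                                        ifelse(is.na(per$z_local), 0,
                                               per$z_local),
                                        threshold = threshold))
  per$stage <- category_stage(per$category)

  scores <- dplyr::left_join(
    series[, c("series_id", "assay_id", "core", "n_members", "n_actives",
               "lead_id")],
    per, by = "series_id")

  structure(
    list(scores = tibble::as_tibble(scores), series = series,
         virtual = virtual, library = library, space = space,
         descriptors = scaled, reference = ref_out,
         params = list(min_members = min_members, min_actives = min_actives,
                       max_sub_heavy = max_sub_heavy, fraction = fraction,
                       threshold = threshold,
                       scaler_population = scaler_population,
                       exclusion_scope = exclusion_scope)),
    class = "progsat_saturation")
}

#' @export
print.progsat_saturation <- function(x, ...) {
  cat("Progression saturation of", nrow(x$scores), "analog series\n")
  tab <- table(factor(x$scores$stage,
                      levels = c("early", "intermediate", "late", "saturated")))
  cat(paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  print(x$scores[, c("series_id", "n_members", "n_actives", "n_virtual",
                     "raw_global", "raw_local", "z_global", "z_local",
                     "category")])
  invisible(x)
}

#' Per-series saturation scores as a tibble
#'
#' @param x A `progsat_saturation` object.
#' @param ... Unused.
#' @return One row per series with composition, radii, raw and z scores,
#'   category, stage, lead and flags.
#' @export
tidy.progsat_saturation <- function(x, ...) {
  x$scores
}

#' One-row ensemble summary
#'
#' @inheritParams tidy.progsat_saturation
#' @return A tibble with ensemble size, compound/candidate totals and stage
#'   counts.
#' @export
glance.progsat_saturation <- function(x, ...) {
  s <- x$scores
  tibble::tibble(
    n_series = nrow(s),
    n_compounds = sum(s$n_members),
    n_actives = sum(s$n_actives),
    n_virtual = sum(s$n_virtual),
    n_fragments = nrow(x$library$fragments),
    n_early = sum(s$stage == "early", na.rm = TRUE),
    n_intermediate = sum(s$stage == "intermediate", na.rm = TRUE),
    n_late = sum(s$stage == "late", na.rm = TRUE),
    n_saturated = sum(s$stage == "saturated", na.rm = TRUE))
}

#' Generic tidy/glance (broom-style)
#' @param x Object to tidy.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Score-combination scatter plot
#'
#' Plots z(local) against z(global) for every series, with the high/low
#' threshold lines; the four quadrants correspond to the optimization
#' stages.
#'
#' @param object A `progsat_saturation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.progsat_saturation <- function(object, ...) {
  s <- object$scores[!is.na(object$scores$z_global), , drop = FALSE]
  thr <- object$params$threshold
  ggplot2::ggplot(s, ggplot2::aes(x = .data$z_global, y = .data$z_local,
                                  colour = .data$stage)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "z(global score)", y = "z(local score)",
                  colour = "stage") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Chemical-reference-space projection of one series
#'
#' PCA projection (on the run's scaled descriptors) of a series' assayed
#' analogs and virtual candidates, drawn as three classes: active analog,
#' inactive analog, virtual candidate.
#'
#' @param result A `progsat_saturation` object.
#' @param series_id Id of the series to plot.
#' @return A ggplot object; axis labels report explained variance.
#' @export
plot_series_space <- function(result, series_id) {
  stopifnot(inherits(result, "progsat_saturation"))
  i <- match(series_id, result$scores$series_id)
  if (is.na(i)) stop("Unknown series id: ", series_id, call. = FALSE)
  mem <- result$series$members[[i]]
  vir <- result$virtual[[series_id]]$compounds
  sc <- result$descriptors
  rows <- sc[match(c(mem$smiles, vir$smiles), sc$id), , drop = FALSE]
  rows$id <- c(mem$id, vir$id)
  proj <- pca_project(rows)
  cls <- c(ifelse(mem$active, "active analog", "inactive analog"),
           rep("virtual candidate", nrow(vir)))
  df <- proj$coords
  df$class <- factor(cls, levels = c("virtual candidate", "inactive analog",
                                     "active analog"))
  df <- df[order(df$class), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      "virtual candidate" = "grey70", "inactive analog" = "#d7301f",
      "active analog" = "#2b8cbe")) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", proj$explained[1]),
                  y = sprintf("PC2 (%.1f%%)", proj$explained[2]),
                  colour = NULL, title = series_id) +
    ggplot2::theme_minimal()
}
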