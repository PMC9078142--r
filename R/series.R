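# Analog-series extraction: group compounds by shared RECAP-MMP core within
# one assay, apply the qualification filters, and pick the ligand-efficiency
# lead.

# 32-bit FNV-1a over a string; deterministic ids without external deps.
fnv1a <- function(s) {
  vapply(s, function(x) {
    h <- 2166136261
    for (b in utf8ToInt(enc2utf8(x))) {
      low <- h %% 256
      h <- h - low + bitwXor(as.integer(low), as.integer(b))
      lo <- h %% 65536; hi <- h %/% 65536
      h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
    }
    sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
  }, "", USE.NAMES = FALSE)
}

#' Ligand efficiency
#'
#' LE = 1.37 * pIC50 / N, the free energy of binding implied by an IC50 (or
#' Ki) in molar units, normalized by the number N of non-hydrogen atoms
#' (kcal/mol per heavy atom). Used to rank active analogs when selecting a
#' series lead.
#'
#' @param potency Potency in molar units (IC50 or Ki); must be positive.
#' @param n_heavy Heavy-atom count; must be at least 1.
#' @return Numeric vector of ligand efficiencies.
#' @export
#' @examples
#' ligand_efficiency(1e-5, 20)  # 1.37 * 5 / 20 = 0.3425
ligand_efficiency <- function(potency, n_heavy) {
  if (any(!is.finite(potency)) || any(potency <= 0)) {
    stop("Potency must be positive (molar units).", call. = FALSE)
  }
  if (any(n_heavy < 1)) {
    stop("Heavy-atom count must be at least 1.", call. = FALSE)
  }
  1.37 * (-log10(potency)) / n_heavy
}

#' Select the lead compound of a series
#'
#' The lead is the active member with the highest ligand efficiency. Exact
#' ties are broken by higher potency, then smaller heavy-atom count, then
#' lexicographic id, so selection is deterministic.
#'
#' @param members Data frame with columns `id`, `active`, `potency`
#'   (molar) and `n_heavy`.
#' @return The id of the lead compound.
#' @export
select_lead <- function(members) {
  stopifnot(all(c("id", "active", "potency", "n_heavy") %in% names(members)))
  cand <- members[members$active & !is.na(members$potency), , drop = FALSE]
  if (nrow(cand) == 0) {
    stop("No active member with a potency value; cannot select a lead.",
         call. = FALSE)
  }
  le <- ligand_efficiency(cand$potency, cand$n_heavy)
  ord <- order(-le, cand$potency, cand$n_heavy, cand$id)
  cand$id[ord[1]]
}

#' Extract qualified single-site analog series
#'
#' Fragments every compound by RECAP single cuts, groups compounds sharing
#' the same canonical core within the same assay, and keeps groups with at
#' least `min_members` analogs and `min_actives` active compounds. For each
#' qualifying series the ligand-efficiency lead among the actives is
#' selected.
#'
#' @param compounds Data frame with columns `id`, `smiles`, `assay_id`,
#'   `active` (logical), and optionally `potency` (molar; `NA` allowed).
#' @param min_members Minimum series size (default 30 analogs tested in the
#'   same assay).
#' @param min_actives Minimum number of active compounds (default 3).
#' @param max_sub_heavy Substituent size cap in heavy atoms (default 13);
#'   cuts whose substituent exceeds it are not used for series formation.
#' @param exclusive If `TRUE`, each compound is assigned only to its largest
#'   qualifying series (ties broken by core string); by default a compound
#'   may appear in several series.
#' @param activity_from_potency Optional molar cutoff: when given, `active`
#'   is derived as `potency <= cutoff` instead of being read from the table.
#' @return A tibble with one row per series: `series_id`, `assay_id`,
#'   `core`, `n_members`, `n_actives`, `lead_id`, and a `members`
#'   list-column (tibbles with `id`, `smiles`, `substituent`, `cut_rule`,
#'   `active`, `potency`, `n_heavy`). Sorted by assay then core.
#' @export
extract_series <- function(compounds, min_members = 30, min_actives = 3,
                           max_sub_heavy = 13, exclusive = FALSE,
                           activity_from_potency = NULL) {
  stopifnot(all(c("id", "smiles", "assay_id") %in% names(compounds)))
  if (anyDuplicated(compounds$id)) {
    stop("Duplicate compound ids: ",
         paste(unique(compounds$id[duplicated(compounds$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(activity_from_potency)) {
    compounds$active <- !is.na(compounds$potency) &
      compounds$potency <= activity_from_potency
  }
  stopifnot("active" %in% names(compounds))
  if (!"potency" %in% names(compounds)) compounds$potency <- NA_real_

  can <- canonical_smiles(compounds$smiles)
  if (anyNA(can)) {
    stop("Unparseable structure(s): ",
         paste(compounds$id[is.na(can)], collapse = ", "), call. = FALSE)
  }
  graphs <- mol_graphs(can)
  compounds$smiles <- can
  compounds$n_heavy <- vapply(graphs, `[[`, 0L, "n_heavy")

  cuts <- recap_single_cut(compounds[, c("id", "smiles")])
  cuts <- cuts[cuts$sub_n_heavy <= max_sub_heavy, , drop = FALSE]
  uncut <- setdiff(compounds$id, cuts$id)
  if (length(uncut)) {
    warning(length(uncut), " compound(s) without a usable RECAP cut were ",
            "skipped: ", paste(utils::head(uncut, 5), collapse = ", "),
            if (length(uncut) > 5) ", ...", call. = FALSE)
  }

  info <- compounds[, c("id", "assay_id", "smiles", "active", "potency",
                        "n_heavy")]
  cand <- dplyr::inner_join(cuts, info, by = "id")
  # one substituent per (core, member): keep the smallest, deterministically
  cand <- dplyr::slice_head(
    dplyr::arrange(
      dplyr::group_by(cand, .data$assay_id, .data$core, .data$id),
      .data$sub_n_heavy, .data$substituent),
    n = 1)
  cand <- dplyr::ungroup(cand)

  groups <- tidyr::nest(
    dplyr::group_by(cand, .data$assay_id, .data$core),
    members = -c("assay_id", "core"))
  groups$n_members <- vapply(groups$members, nrow, 0L)
  groups$n_actives <- vapply(groups$members, function(m) sum(m$active), 0L)
  groups <- groups[groups$n_members >= min_members &
                     groups$n_actives >= min_actives, , drop = FALSE]
  groups <- dplyr::arrange(groups, .data$assay_id, .data$core)

  if (exclusive && nrow(groups) > 1) {
    ord <- order(-groups$n_members, groups$core)
    claimed <- character()
    keep_rows <- logical(nrow(groups))
    for (k in ord) {
      m <- groups$members[[k]]
      m <- m[!m$id %in% claimed, , drop = FALSE]
      if (nrow(m) >= min_members && sum(m$active) >= min_actives) {
        groups$members[[k]] <- m
        groups$n_members[k] <- nrow(m)
        groups$n_actives[k] <- sum(m$active)
        claimed <- c(claimed, m$id)
        keep_rows[k] <- TRUE
      }
    }
    groups <- groups[keep_rows, , drop = FALSE]
  }

  if (nrow(groups) == 0) {
    return(tibble::tibble(series_id = character(), assay_id = character(),
                          core = character(), n_members = integer(),
                          n_actives = integer(), lead_id = character(),
                          members = list()))
  }

  groups$series_id <- paste0("s_", fnv1a(paste(groups$assay_id, groups$core)))
  groups$lead_id <- vapply(groups$members, function(m) {
    tryCatch(select_lead(m), error = function(e) NA_character_)
  }, "")
  if (anyNA(groups$lead_id)) {
    warning("Series without an active potency value have no lead: ",
            paste(groups$series_id[is.na(groups$lead_id)], collapse = ", "),
            call. = FALSE)
  }
  groups$members <- lapply(groups$members, function(m) {
    tibble::as_tibble(m[order(m$id),
                        c("id", "smiles", "substituent", "cut_rule",
                          "active", "potency", "n_heavy")])
  })
  tibble::as_tibble(groups[, c("series_id", "assay_id", "core", "n_members",
                               "n_actives", "lead_id", "members")])
}
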