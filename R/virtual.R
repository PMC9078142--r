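# Virtual candidate enumeration: substituent fragment library from a donor
# compound set, recombined with each series core.

#' Build a substituent fragment library
#'
#' Applies RECAP single-cut fragmentation to every donor compound, collects
#' the substituent side of every cut, canonicalizes and deduplicates, and
#' removes fragments present in the exclusion set (typically the union of
#' substituents observed across the analyzed analog series, so candidates
#' are novel by construction).
#'
#' @param donors Character vector of donor SMILES, or a data frame with
#'   `id` and `smiles` columns.
#' @param exclusion Character vector of substituent fragment SMILES (with
#'   `*`) to exclude.
#' @param max_sub_heavy Substituent size cap in heavy atoms (default 13).
#' @return An object of class `progsat_fraglib`: a list with `fragments`
#'   (tibble with `fragment` canonical SMILES and `bond_order`),
#'   `source_count` and `excluded_count`.
#' @export
build_fragment_library <- function(donors, exclusion = character(),
                                   max_sub_heavy = 13) {
  if (is.character(donors)) {
    donors <- tibble::tibble(id = paste0("d", seq_along(donors)),
                             smiles = donors)
  }
  stopifnot(all(c("id", "smiles") %in% names(donors)))
  if (nrow(donors) == 0) {
    warning("Empty donor set; fragment library is empty.", call. = FALSE)
    return(structure(list(fragments = tibble::tibble(fragment = character(),
                                                     bond_order = integer()),
                          source_count = 0L, excluded_count = 0L),
                     class = "progsat_fraglib"))
  }
  can <- canonical_smiles(donors$smiles)
  if (anyNA(can)) {
    warning("Skipping unparseable donor structure(s): ",
            paste(donors$id[is.na(can)], collapse = ", "), call. = FALSE)
    donors <- donors[!is.na(can), , drop = FALSE]
    can <- can[!is.na(can)]
  }
  donors$smiles <- can
  cuts <- recap_single_cut(donors)
  cuts <- cuts[cuts$sub_n_heavy <= max_sub_heavy, , drop = FALSE]
  frag <- dplyr::distinct(cuts[, c("substituent", "bond_order")])
  frag <- dplyr::slice_head(
    dplyr::arrange(dplyr::group_by(frag, .data$substituent), .data$bond_order),
    n = 1)
  frag <- dplyr::ungroup(frag)
  excl <- unique(stats::na.omit(canonical_smiles(exclusion)))
  drop <- frag$substituent %in% excl
  kept <- frag[!drop, , drop = FALSE]
  kept <- kept[order(kept$substituent), , drop = FALSE]
  structure(
    list(fragments = tibble::tibble(fragment = kept$substituent,
                                    bond_order = kept$bond_order),
         source_count = nrow(donors),
         excluded_count = sum(drop)),
    class = "progsat_fraglib")
}

#' @export
print.progsat_fraglib <- function(x, ...) {
  cat("Substituent fragment library: ", nrow(x$fragments),
      " unique fragments from ", x$source_count, " donors (",
      x$excluded_count, " excluded)\n", sep = "")
  invisible(x)
}

#' Enumerate virtual candidate analogs for a series core
#'
#' Attaches every library fragment at the core's attachment point. Products
#' that fail chemical sanitization, duplicate an earlier product, or are
#' identical to an assayed member of the series are removed; all four
#' bookkeeping counts are reported and sum to the library size.
#'
#' @param core Core SMILES with exactly one `*` attachment point.
#' @param library A [build_fragment_library()] object, or a character vector
#'   of fragment SMILES.
#' @param existing Character vector of assayed member SMILES for the series
#'   (virtual candidates must be novel).
#' @return An object of class `progsat_virtual`: `compounds` (tibble `id`,
#'   `smiles`, `fragment`), and counts `n_fragments`, `n_invalid`,
#'   `n_duplicate`, `n_existing`.
#' @export
enumerate_virtual <- function(core, library, existing = character()) {
  frags <- if (inherits(library, "progsat_fraglib")) {
    library$fragments$fragment
  } else {
    as.character(library)
  }
  core_g <- mol_graphs(core)[[1]]
  if (is.null(core_g)) stop("Core SMILES does not parse.", call. = FALSE)
  if (sum(core_g$elem == "*") != 1L) {
    stop("Core must carry exactly one '*' attachment point, found ",
         sum(core_g$elem == "*"), ".", call. = FALSE)
  }
  n_frag <- length(frags)
  if (n_frag == 0) {
    return(structure(list(compounds = tibble::tibble(id = character(),
                                                     smiles = character(),
                                                     fragment = character()),
                          n_fragments = 0L, n_invalid = 0L,
                          n_duplicate = 0L, n_existing = 0L),
                     class = "progsat_virtual"))
  }
  products <- reattach_fragments(core, frags)
  invalid <- is.na(products)
  dup <- !invalid & duplicated(products)
  excl_set <- unique(stats::na.omit(canonical_smiles(existing)))
  exist <- !invalid & !dup & products %in% excl_set
  keep <- !invalid & !dup & !exist
  smiles <- products[keep]
  ids <- paste0("v_", fnv1a(smiles))
  # guard the (rare) hash collision deterministically
  if (anyDuplicated(ids)) {
    d <- duplicated(ids)
    ids[d] <- paste0(ids[d], "_", seq_len(sum(d)))
  }
  structure(
    list(compounds = tibble::tibble(id = ids, smiles = smiles,
                                    fragment = frags[keep]),
         n_fragments = as.integer(n_frag),
         n_invalid = as.integer(sum(invalid)),
         n_duplicate = as.integer(sum(dup)),
         n_existing = as.integer(sum(exist))),
    class = "progsat_virtual")
}

#' @export
print.progsat_virtual <- function(x, ...) {
  cat("Virtual library: ", nrow(x$compounds), " candidates from ",
      x$n_fragments, " fragments (", x$n_invalid, " invalid, ",
      x$n_duplicate, " duplicate, ", x$n_existing,
      " collided with assayed analogs)\n", sep = "")
  invisible(x)
}
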