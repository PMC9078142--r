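# RECAP single-cut fragmentation: matched-molecular-pair decomposition at
# retrosynthetically sensible exocyclic bonds.

# The implemented retrosynthetic bond types. Every cut severs one acyclic
# bond; olefin is the one double-bond rule and its order is recorded so that
# reattachment restores the parent exactly.
RECAP_RULES <- c("quaternary_N", "urea", "amide", "ester", "sulfonamide",
                 "lactam_N_aliphatic_C", "aromatic_N_aliphatic_C", "amine",
                 "ether", "olefin", "aromatic_C_aromatic_C")

# Per-atom perception helpers --------------------------------------------

atom_flags <- function(g) {
  n <- length(g$elem)
  nb <- graph_neighbors(g)
  bridges <- bridge_bonds(g)
  in_ring_bond <- rep(TRUE, nrow(g$bonds))
  in_ring_bond[bridges] <- FALSE
  ring_atom <- rep(FALSE, n)
  if (any(in_ring_bond)) {
    ring_atom[unique(c(g$bonds$a1[in_ring_bond], g$bonds$a2[in_ring_bond]))] <- TRUE
  }
  dbl_o <- rep(0L, n)   # number of double-bonded O neighbours
  for (r in seq_len(nrow(g$bonds))) {
    if (g$bonds$order[r] == 2L) {
      a <- g$bonds$a1[r]; b <- g$bonds$a2[r]
      if (g$elem[b] == "O") dbl_o[a] <- dbl_o[a] + 1L
      if (g$elem[a] == "O") dbl_o[b] <- dbl_o[b] + 1L
    }
  }
  carbonyl <- g$elem == "C" & dbl_o >= 1L
  sulfonyl <- g$elem == "S" & dbl_o >= 2L
  heavy_deg <- vapply(nb, function(v) sum(g$elem[v] != "H"), 0L)
  list(nb = nb, bridges = bridges, ring_atom = ring_atom,
       carbonyl = carbonyl, sulfonyl = sulfonyl, heavy_deg = heavy_deg)
}

# Classify one bond row; NA_character_ if no rule matches.
classify_recap_bond <- function(g, fl, r) {
  a <- g$bonds$a1[r]; b <- g$bonds$a2[r]
  ord <- g$bonds$order[r]
  ea <- g$elem[a]; eb <- g$elem[b]
  if (ea == "*" || eb == "*" || ea == "H" || eb == "H") return(NA_character_)
  if (ord == 2L) {
    if (ea == "C" && eb == "C" && !g$arom[a] && !g$arom[b]) return("olefin")
    return(NA_character_)
  }
  if (ord != 1L) return(NA_character_)

  # orient pairs both ways for asymmetric patterns
  for (swap in c(FALSE, TRUE)) {
    x <- if (swap) b else a
    y <- if (swap) a else b
    ex <- g$elem[x]; ey <- g$elem[y]
    if (ex == "N" && g$chg[x] == 1L && fl$heavy_deg[x] == 4L && ey == "C") {
      return("quaternary_N")
    }
    if (ex == "C" && fl$carbonyl[x] && ey == "N") {
      n_amide_n <- sum(g$elem[fl$nb[[x]]] == "N")
      return(if (n_amide_n >= 2L) "urea" else "amide")
    }
    if (ex == "C" && fl$carbonyl[x] && ey == "O" && fl$heavy_deg[y] == 2L) {
      return("ester")
    }
    if (ex == "S" && fl$sulfonyl[x] && ey == "N") return("sulfonamide")
    if (ex == "N" && fl$ring_atom[x] && ey == "C" && !fl$ring_atom[y] &&
        !fl$carbonyl[y]) {
      ring_carbonyl <- any(fl$carbonyl[fl$nb[[x]]] & fl$ring_atom[fl$nb[[x]]])
      if (ring_carbonyl) return("lactam_N_aliphatic_C")
      if (g$arom[x] && !g$arom[y]) return("aromatic_N_aliphatic_C")
    }
    if (ex == "N" && !g$arom[x] && g$chg[x] == 0L &&
        !any(fl$carbonyl[fl$nb[[x]]]) && !any(fl$sulfonyl[fl$nb[[x]]]) &&
        ey == "C" && !fl$carbonyl[y]) {
      return("amine")
    }
    if (ex == "O" && fl$heavy_deg[x] == 2L &&
        all(g$elem[fl$nb[[x]]] %in% c("C", "H")) &&
        !any(fl$carbonyl[fl$nb[[x]]]) && ey == "C") {
      return("ether")
    }
  }
  if (ea == "C" && eb == "C" && g$arom[a] && g$arom[b]) {
    return("aromatic_C_aromatic_C")
  }
  NA_character_
}

# Extract the fragment on the side of `keep_atom` after deleting bond r,
# adding a dummy atom bonded to the cut atom with the severed bond's order.
cut_fragment <- function(g, r, keep_atom) {
  a1 <- g$bonds$a1; a2 <- g$bonds$a2
  ig <- igraph::graph_from_edgelist(cbind(a1[-r], a2[-r]), directed = FALSE)
  nv <- length(g$elem)
  if (igraph::vcount(ig) < nv) ig <- igraph::add_vertices(ig, nv - igraph::vcount(ig))
  comp <- igraph::components(ig)$membership
  keep <- which(comp == comp[keep_atom])
  remap <- match(seq_len(nv), keep)
  brows <- which(a1 %in% keep & a2 %in% keep)
  brows <- setdiff(brows, r)
  bonds <- g$bonds[brows, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  dummy <- length(keep) + 1L
  bonds <- rbind(bonds, data.frame(a1 = remap[keep_atom], a2 = dummy,
                                   order = g$bonds$order[r],
                                   arom = FALSE, am = FALSE))
  list(elem = c(g$elem[keep], "*"),
       arom = c(g$arom[keep], FALSE),
       chg = c(g$chg[keep], 0L),
       bonds = bonds,
       n_heavy = sum(g$elem[keep] != "H"))
}

#' RECAP single-cut fragmentation
#'
#' Enumerates every acyclic bond of each molecule that matches one of the
#' implemented retrosynthetic bond types (amide, ester, amine, urea, ether,
#' olefin, quaternary nitrogen, aromatic N--aliphatic C, lactam N--aliphatic
#' C, aromatic C--aromatic C, sulfonamide) and cuts it, yielding one
#' core/substituent pair per cut. The larger fragment (by heavy-atom count)
#' is the core; exact ties are broken by canonical SMILES order. Both
#' fragments carry a `*` attachment point, and reattaching them reproduces
#' the parent structure.
#'
#' @param data A data frame with at least an `id` and a `smiles` column, or a
#'   bare character vector of SMILES (ids are then taken from names or made
#'   up as `mol1`, `mol2`, ...).
#' @return A tibble with one row per cut: `id`, `core`, `substituent`
#'   (canonical SMILES with `*`), `cut_rule`, `bond_order`, `core_n_heavy`,
#'   `sub_n_heavy`, sorted deterministically. Molecules with no matching
#'   bond contribute no rows.
#' @export
#' @examples
#' \dontrun{
#' recap_single_cut(c(benzene = "c1ccccc1", anilide = "CC(=O)Nc1ccccc1"))
#' }
recap_single_cut <- function(data) {
  if (is.character(data)) {
    ids <- names(data)
    if (is.null(ids)) ids <- paste0("mol", seq_along(data))
    data <- tibble::tibble(id = ids, smiles = unname(data))
  }
  stopifnot(all(c("id", "smiles") %in% names(data)))
  graphs <- mol_graphs(data$smiles)
  bad <- which(vapply(graphs, is.null, TRUE))
  if (length(bad)) {
    stop("Unparseable structure(s): ",
         paste(data$id[bad], collapse = ", "), call. = FALSE)
  }
  rows <- list(); frag_graphs <- list()
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (nrow(g$bonds) == 0) next
    fl <- atom_flags(g)
    for (r in fl$bridges) {
      rule <- classify_recap_bond(g, fl, r)
      if (is.na(rule)) next
      fa <- cut_fragment(g, r, g$bonds$a1[r])
      fb <- cut_fragment(g, r, g$bonds$a2[r])
      k <- length(rows) + 1L
      rows[[k]] <- list(id = data$id[i], rule = rule,
                        order = g$bonds$order[r],
                        na = fa$n_heavy, nb = fb$n_heavy)
      frag_graphs[[2L * k - 1L]] <- fa
      frag_graphs[[2L * k]] <- fb
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(id = character(), core = character(),
                          substituent = character(), cut_rule = character(),
                          bond_order = integer(), core_n_heavy = integer(),
                          sub_n_heavy = integer()))
  }
  smi <- graphs_to_smiles(frag_graphs)
  res <- purrr::map_dfr(seq_along(rows), function(k) {
    ri <- rows[[k]]
    sa <- smi[2L * k - 1L]; sb <- smi[2L * k]
    if (is.na(sa) || is.na(sb)) return(NULL)
    core_is_a <- ri$na > ri$nb || (ri$na == ri$nb && sa <= sb)
    tibble::tibble(
      id = ri$id,
      core = if (core_is_a) sa else sb,
      substituent = if (core_is_a) sb else sa,
      cut_rule = ri$rule,
      bond_order = ri$order,
      core_n_heavy = if (core_is_a) ri$na else ri$nb,
      sub_n_heavy = if (core_is_a) ri$nb else ri$na)
  })
  dplyr::distinct(
    dplyr::arrange(res, .data$id, .data$core, .data$substituent))
}

# Locate the dummy atom of a fragment graph (exactly one expected).
dummy_atom <- function(g) {
  d <- which(g$elem == "*")
  if (length(d) != 1L) {
    stop("Fragment must carry exactly one attachment point, found ",
         length(d), call. = FALSE)
  }
  d
}

# Merge two fragment graphs at their dummies; bond order is the larger of
# the two attachment orders (they agree for fragments from the same cut).
join_graphs <- function(gc, gs) {
  dc <- dummy_atom(gc); ds <- dummy_atom(gs)
  nbc <- graph_neighbors(gc); nbs <- graph_neighbors(gs)
  anchor_c <- nbc[[dc]][1]; anchor_s <- nbs[[ds]][1]
  ord <- max(gc$bonds$order[gc$bonds$a1 == dc | gc$bonds$a2 == dc],
             gs$bonds$order[gs$bonds$a1 == ds | gs$bonds$a2 == ds])
  keep_c <- setdiff(seq_along(gc$elem), dc)
  keep_s <- setdiff(seq_along(gs$elem), ds)
  remap_c <- match(seq_along(gc$elem), keep_c)
  remap_s <- match(seq_along(gs$elem), keep_s) + length(keep_c)
  bc <- gc$bonds[gc$bonds$a1 != dc & gc$bonds$a2 != dc, , drop = FALSE]
  bc$a1 <- remap_c[bc$a1]; bc$a2 <- remap_c[bc$a2]
  bs <- gs$bonds[gs$bonds$a1 != ds & gs$bonds$a2 != ds, , drop = FALSE]
  bs$a1 <- remap_s[bs$a1]; bs$a2 <- remap_s[bs$a2]
  bonds <- rbind(bc, bs,
                 data.frame(a1 = remap_c[anchor_c], a2 = remap_s[anchor_s],
                            order = ord, arom = FALSE, am = FALSE))
  list(elem = c(gc$elem[keep_c], gs$elem[keep_s]),
       arom = c(gc$arom[keep_c], gs$arom[keep_s]),
       chg = c(gc$chg[keep_c], gs$chg[keep_s]),
       bonds = bonds,
       n_heavy = sum(c(gc$elem[keep_c], gs$elem[keep_s]) != "H"))
}

#' Reattach core and substituent fragments
#'
#' Joins fragment pairs at their `*` attachment points, restoring the bond
#' order recorded in the fragments. Vectorized: cores and substituents are
#' matched elementwise (with recycling of a length-1 core).
#'
#' @param core,substituent Character vectors of fragment SMILES, each
#'   containing exactly one `*`.
#' @return Character vector of canonical SMILES of the joined molecules;
#'   `NA` where the join does not produce a valid molecule.
#' @export
reattach_fragments <- function(core, substituent) {
  n <- max(length(core), length(substituent))
  core <- rep_len(core, n); substituent <- rep_len(substituent, n)
  gc_all <- mol_graphs(core)
  gs_all <- mol_graphs(substituent)
  joined <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.null(gc_all[[i]]) || is.null(gs_all[[i]])) next
    joined[[i]] <- tryCatch(join_graphs(gc_all[[i]], gs_all[[i]]),
                            error = function(e) NULL)
  }
  graphs_to_smiles(joined)
}
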