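# The constant seven-descriptor chemical reference space: molecular size,
# hydrogen-bonding capacity, flexibility, hydrophobicity, solubility, and
# polar surface area.

#' Names of the seven reference-space descriptors, in canonical order
#' @export
descriptor_names <- c("mw", "hbd", "hba", "rotb", "logp", "logs", "tpsa")

# Strict rotatable-bond count on a molecular graph: acyclic single bonds
# between two non-terminal heavy atoms, excluding amide C-N bonds and bonds
# to triple-bonded atoms.
rotatable_bonds <- function(g) {
  if (nrow(g$bonds) == 0) return(0L)
  fl <- atom_flags(g)
  triple_atom <- rep(FALSE, length(g$elem))
  tr <- g$bonds$order == 3L
  if (any(tr)) triple_atom[unique(c(g$bonds$a1[tr], g$bonds$a2[tr]))] <- TRUE
  n <- 0L
  for (r in fl$bridges) {
    a <- g$bonds$a1[r]; b <- g$bonds$a2[r]
    if (g$bonds$order[r] != 1L) next
    if (g$elem[a] %in% c("H", "*") || g$elem[b] %in% c("H", "*")) next
    if (fl$heavy_deg[a] < 2L || fl$heavy_deg[b] < 2L) next
    if (triple_atom[a] || triple_atom[b]) next
    amide <- g$bonds$am[r] ||
      (g$elem[a] == "C" && fl$carbonyl[a] && g$elem[b] == "N") ||
      (g$elem[b] == "C" && fl$carbonyl[b] && g$elem[a] == "N")
    if (amide) next
    n <- n + 1L
  }
  n
}

largest_component_smiles <- function(smiles) {
  vapply(strsplit(smiles, ".", fixed = TRUE), function(parts) {
    if (length(parts) == 1L) return(parts)
    # heavy-atom count per component, counted from the SMILES tokens
    nh <- vapply(parts, function(p) {
      toks <- gregexpr("Cl|Br|[BCNOSPFI]|\\[[^]]+\\]", p, ignore.case = TRUE)[[1]]
      sum(attr(toks, "match.length") > 0)
    }, 0)
    parts[which.max(nh)]
  }, "")
}

#' Compute the seven reference-space descriptors
#'
#' Computes, for each molecule, molecular weight (Da), Lipinski hydrogen-bond
#' donor and acceptor counts, the strict rotatable-bond count, Crippen-type
#' logP and Ertl topological polar surface area (via OpenBabel), and an
#' ESOL-style aqueous solubility estimate (log10 mol/L) derived from logP,
#' molecular weight, rotatable bonds and aromatic proportion.
#'
#' @param data Data frame with `id` and `smiles` columns, or a character
#'   vector of SMILES (named or not).
#' @param strip_salts If `TRUE` (default), multi-fragment inputs (salts,
#'   mixtures) are reduced to their largest component before computation;
#'   if `FALSE` they are rejected.
#' @return A tibble with columns `id`, `smiles` (canonical), the seven
#'   descriptors `mw, hbd, hba, rotb, logp, logs, tpsa`, and `n_heavy`.
#' @export
#' @examples
#' \dontrun{compute_descriptors(c(benzene = "c1ccccc1"))}
compute_descriptors <- function(data, strip_salts = TRUE) {
  if (is.character(data)) {
    ids <- names(data)
    if (is.null(ids)) ids <- paste0("mol", seq_along(data))
    data <- tibble::tibble(id = ids, smiles = unname(data))
  }
  stopifnot(all(c("id", "smiles") %in% names(data)))
  if (anyDuplicated(data$id)) {
    stop("Duplicate compound ids: ",
         paste(unique(data$id[duplicated(data$id)]), collapse = ", "),
         call. = FALSE)
  }
  smi <- data$smiles
  multi <- grepl(".", smi, fixed = TRUE)
  if (any(multi)) {
    if (!strip_salts) {
      stop("Multi-fragment structure(s) rejected (set strip_salts = TRUE ",
           "to keep the largest component): ",
           paste(data$id[multi], collapse = ", "), call. = FALSE)
    }
    smi[multi] <- largest_component_smiles(smi[multi])
  }
  can <- canonical_smiles(smi)
  if (anyNA(can)) {
    stop("Unparseable structure(s): ",
         paste(data$id[is.na(can)], collapse = ", "), call. = FALSE)
  }
  graphs <- mol_graphs(can)
  if (any(vapply(graphs, is.null, TRUE))) {
    stop("Structure(s) failed graph perception: ",
         paste(data$id[vapply(graphs, is.null, TRUE)], collapse = ", "),
         call. = FALSE)
  }
  sdf <- ChemmineR::smiles2sdf(stats::setNames(can, seq_along(can)))
  props <- ChemmineR::propOB(sdf)
  rotb <- vapply(graphs, rotatable_bonds, 0L)
  n_heavy <- vapply(graphs, `[[`, 0L, "n_heavy")
  n_arom <- vapply(graphs, function(g) sum(g$arom & g$elem != "H"), 0L)
  ap <- ifelse(n_heavy > 0, n_arom / n_heavy, 0)
  logp <- as.numeric(props$logP)
  mw <- as.numeric(props$MW)
  logs <- 0.16 - 0.63 * logp - 0.0062 * mw + 0.066 * rotb - 0.74 * ap
  tibble::tibble(
    id = data$id,
    smiles = can,
    mw = mw,
    hbd = as.integer(props$HBD),
    hba = as.integer(props$HBA1),
    rotb = rotb,
    logp = logp,
    logs = logs,
    tpsa = as.numeric(props$TPSA),
    n_heavy = n_heavy)
}

#' Descriptors of substituent fragments
#'
#' Computes the reference-space descriptors of fragments carrying a `*`
#' attachment point by capping the attachment with hydrogen first.
#'
#' @param fragments Character vector of fragment SMILES with one `*` each.
#' @return As [compute_descriptors()], with `id` equal to the fragment.
#' @export
fragment_descriptors <- function(fragments) {
  capped <- gsub("\\[\\*\\]|\\*", "[H]", fragments)
  res <- compute_descriptors(tibble::tibble(id = fragments, smiles = capped))
  res
}
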