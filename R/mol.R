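# Molecule layer: batch conversion through OpenBabel plus a light graph
# representation (elements, Kekule bond orders, aromatic/amide perception)
# used by the fragmentation and descriptor code.

ob_binary <- function() {
  bin <- Sys.which("obabel")
  if (!nzchar(bin)) {
    stop("OpenBabel ('obabel') was not found on the PATH; it is required ",
         "for structure parsing and canonicalization.", call. = FALSE)
  }
  bin
}

# Run obabel on a text input written to a temp file; returns output text.
ob_run <- function(input, in_ext, out_ext, args = character()) {
  fin <- tempfile(fileext = paste0(".", in_ext))
  fout <- tempfile(fileext = paste0(".", out_ext))
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(input, fin)
  suppressWarnings(
    system2(ob_binary(), c(shQuote(fin), paste0("-O", shQuote(fout)), args),
            stdout = FALSE, stderr = FALSE)
  )
  if (!file.exists(fout)) return(character())
  readLines(fout, warn = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form in one batch call. Invalid or
#' unparseable records come back as `NA` so callers can report the offending
#' input by position.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
#' @examples
#' \dontrun{canonical_smiles(c("OCC", "CCO"))  # both "CCO"}
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character())
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  out <- rep(NA_character_, length(smiles))
  if (!any(ok)) return(out)
  idx <- which(ok)
  lines <- paste(trimws(smiles[idx]), paste0("t", seq_along(idx)))
  res <- ob_run(lines, "smi", "can")
  if (length(res) == 0) return(out)
  parts <- strsplit(res, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, "", 1L)
  tag <- as.integer(sub("^t", "", vapply(parts, function(p) p[length(p)], "")))
  keep <- !is.na(tag)
  out[idx[tag[keep]]] <- trimws(smi[keep])
  out
}

mol2_blocks <- function(txt) {
  starts <- grep("^@<TRIPOS>MOLECULE", txt)
  ends <- c(starts[-1] - 1L, length(txt))
  Map(function(s, e) txt[s:e], starts, ends)
}

parse_mol2_block <- function(block) {
  name <- trimws(block[2])
  a0 <- grep("^@<TRIPOS>ATOM", block)[1]
  b0 <- grep("^@<TRIPOS>BOND", block)[1]
  sec_ends <- grep("^@<TRIPOS>", block)
  a1 <- min(c(sec_ends[sec_ends > a0], length(block) + 1L)) - 1L
  b1 <- min(c(sec_ends[sec_ends > b0], length(block) + 1L)) - 1L
  atom_lines <- block[seq.int(a0 + 1L, a1)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  af <- strsplit(trimws(atom_lines), "\\s+")
  atype <- vapply(af, `[`, "", 6L)
  bonds <- NULL
  if (b1 > b0) {
    bond_lines <- block[seq.int(b0 + 1L, b1)]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    if (length(bond_lines)) {
      bf <- strsplit(trimws(bond_lines), "\\s+")
      bonds <- list(
        a1 = as.integer(vapply(bf, `[`, "", 2L)),
        a2 = as.integer(vapply(bf, `[`, "", 3L)),
        type = vapply(bf, `[`, "", 4L)
      )
    }
  }
  list(name = name, atom_type = atype, bonds = bonds)
}

#' Parse molecules into graph form
#'
#' Converts SMILES to an internal molecular-graph representation: heavy atoms
#' with element, aromaticity and formal-charge annotation, and bonds with
#' Kekule orders plus aromatic/amide flags. Aromaticity and amide bonds come
#' from OpenBabel's perception; bond orders from the Kekule molfile form so
#' rings can be written back out losslessly.
#'
#' @param smiles Character vector of SMILES.
#' @return A list of graphs (or `NA` where parsing failed), each a list with
#'   `elem`, `arom`, `chg`, `bonds` (data frame `a1,a2,order,arom,am`) and
#'   `n_heavy`.
#' @keywords internal
mol_graphs <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  out <- vector("list", n)
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  idx <- which(ok)
  lines <- paste(trimws(smiles[idx]), paste0("t", seq_along(idx)))
  sdf_txt <- ob_run(lines, "smi", "sdf")
  mol2_txt <- ob_run(lines, "smi", "mol2")
  if (length(sdf_txt) == 0 || length(mol2_txt) == 0) return(out)
  sdf_mols <- parse_sdf_text(sdf_txt)
  m2 <- lapply(mol2_blocks(mol2_txt), parse_mol2_block)
  m2_by_name <- stats::setNames(m2, vapply(m2, `[[`, "", "name"))
  for (mol in sdf_mols) {
    tag <- mol$name
    info <- m2_by_name[[tag]]
    if (is.null(info) || length(info$atom_type) != length(mol$elem)) next
    i <- idx[as.integer(sub("^t", "", tag))]
    out[[i]] <- build_graph(mol, info)
  }
  out
}

# Minimal V2000 reader for obabel output (counts line + atom/bond blocks).
# ChemmineR's reader is used for user-supplied SD files; this one runs on
# obabel's own output inside tight loops where speed matters.
parse_sdf_text <- function(txt) {
  ends <- grep("^\\$\\$\\$\\$", txt)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  mols <- list()
  for (k in seq_along(ends)) {
    blk <- txt[starts[k]:ends[k]]
    blk <- blk[nzchar(blk) | seq_along(blk) <= 4]
    name <- trimws(blk[1])
    counts <- blk[4]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    if (is.na(na)) next
    atoms <- blk[4 + seq_len(na)]
    elem <- trimws(substr(atoms, 32, 34))
    bl <- if (nb > 0) blk[4 + na + seq_len(nb)] else character()
    a1 <- as.integer(substr(bl, 1, 3))
    a2 <- as.integer(substr(bl, 4, 6))
    ord <- as.integer(substr(bl, 7, 9))
    chg <- rep(0L, na)
    for (ln in grep("^M  CHG", blk, value = TRUE)) {
      f <- strsplit(trimws(sub("^M  CHG\\s+\\d+", "", ln)), "\\s+")[[1]]
      if (length(f) >= 2) {
        ii <- as.integer(f[seq(1, length(f), 2)])
        vv <- as.integer(f[seq(2, length(f), 2)])
        chg[ii] <- vv
      }
    }
    mols[[length(mols) + 1L]] <-
      list(name = name, elem = elem, chg = chg,
           a1 = a1, a2 = a2, order = ord)
  }
  mols
}

build_graph <- function(mol, info) {
  btype <- if (is.null(info$bonds)) character() else info$bonds$type
  # align mol2 bonds with sdf bonds by unordered atom pair
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  type_by_pair <- stats::setNames(btype, key(info$bonds$a1, info$bonds$a2))
  bt <- unname(type_by_pair[key(mol$a1, mol$a2)])
  arom_bond <- !is.na(bt) & bt == "ar"
  am_bond <- !is.na(bt) & bt == "am"
  n <- length(mol$elem)
  arom_atom <- rep(FALSE, n)
  atype <- info$atom_type
  arom_atom[grepl("\\.ar$", atype)] <- TRUE
  if (any(arom_bond)) {
    arom_atom[unique(c(mol$a1[arom_bond], mol$a2[arom_bond]))] <- TRUE
  }
  chg <- mol$chg
  chg[atype == "N.4" & chg == 0L] <- 1L
  list(
    elem = mol$elem,
    arom = arom_atom,
    chg = chg,
    bonds = data.frame(a1 = mol$a1, a2 = mol$a2, order = mol$order,
                       arom = arom_bond, am = am_bond),
    n_heavy = sum(mol$elem != "H")
  )
}

# Write a graph as a V2000 molfile ("*" allowed as attachment dummy).
graph_to_molfile <- function(g, name = "") {
  na <- length(g$elem)
  nb <- nrow(g$bonds)
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, g$elem)
  bond_lines <- if (nb > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", g$bonds$a1, g$bonds$a2, g$bonds$order)
  } else character()
  chg_lines <- character()
  charged <- which(g$chg != 0L)
  if (length(charged)) {
    chg_lines <- paste0("M  CHG", formatC(length(charged), width = 3),
                        paste0(formatC(charged, width = 4),
                               formatC(g$chg[charged], width = 4),
                               collapse = ""))
  }
  c(name, " progsat", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
    atom_lines, bond_lines, chg_lines, "M  END")
}

# Canonical SMILES for a list of graphs, via one batched obabel call.
graphs_to_smiles <- function(graphs) {
  n <- length(graphs)
  if (n == 0) return(character())
  ok <- !vapply(graphs, is.null, TRUE)
  out <- rep(NA_character_, n)
  if (!any(ok)) return(out)
  idx <- which(ok)
  sdf <- unlist(lapply(seq_along(idx), function(k) {
    c(graph_to_molfile(graphs[[idx[k]]], name = paste0("t", k)), "$$$$")
  }))
  res <- ob_run(sdf, "sdf", "can")
  if (length(res) == 0) return(out)
  parts <- strsplit(res, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, "", 1L)
  tag <- suppressWarnings(
    as.integer(sub("^t", "", vapply(parts, function(p) p[length(p)], ""))))
  keep <- !is.na(tag) & nzchar(trimws(smi))
  out[idx[tag[keep]]] <- trimws(smi[keep])
  out
}

# Acyclic (bridge) bonds of a graph, as row indices into g$bonds.
bridge_bonds <- function(g) {
  if (nrow(g$bonds) == 0) return(integer())
  ig <- igraph::graph_from_edgelist(
    cbind(g$bonds$a1, g$bonds$a2), directed = FALSE)
  if (igraph::vcount(ig) < length(g$elem)) {
    ig <- igraph::add_vertices(ig, length(g$elem) - igraph::vcount(ig))
  }
  br <- igraph::bridges(ig)
  as.integer(br)
}

# Neighbor list helper: for atom i, indices of bonded atoms.
graph_neighbors <- function(g) {
  n <- length(g$elem)
  nb <- vector("list", n)
  for (r in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a1[r]; b <- g$bonds$a2[r]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  nb
}
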