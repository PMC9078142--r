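# Synthetic analog-series generator. Series are real, parseable molecules
# built from an amide-linked scaffold/substituent grammar, so they survive
# the actual RECAP extraction stage instead of bypassing it. Two knobs
# control the saturation regime: `coverage` (how much of the substituent
# alphabet's descriptor range the members span) and `active_dispersion`
# (how spread out the actives are relative to the members).

# Acyl R-groups, written as SMILES branches valid inside "O=C(<R>)N...".
# Families are graded in size and polarity so the alphabet spans a smooth
# gradient in the reference space. Capped at 9 heavy atoms so the acyl
# substituent (R plus C=O) always stays below every scaffold size and the
# substituent cap.
alphabet_r_groups <- function() {
  chains <- c("", "C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC")
  terms <- c("C", "CO", "COC", "CN(C)C", "CNC", "CCl", "CBr", "CF",
             "C(C)C", "C(C)(C)C", "C(F)(F)F",
             "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "C1CCOCC1",
             "C1CCNCC1",
             "c1ccccc1", "c1ccc(F)cc1", "c1ccc(Cl)cc1", "c1ccc(Br)cc1",
             "c1ccc(C)cc1", "c1ccc(OC)cc1", "c1ccc(CC)cc1",
             "c1ccc(C(F)(F)F)cc1", "c1cccc(F)c1", "c1cccc(Cl)c1",
             "c1cccc(C)c1", "c1cccc(OC)c1",
             "c1ccncc1", "c1cccnc1", "c1ccco1", "c1cccs1", "c1ccc(F)nc1",
             "c1ccc2ccccc2c1")
  singles <- c("CO", "CCO", "C(C)CC", "CC(C)C", "CC(C)(C)C", "COCC",
               "CCOC", "CCOCC", "COCCOC", "CCCCCCC", "CCCCCCCC",
               "CCN(C)C", "CC(F)(F)F", "CCCl", "CCCCl", "CC1CCCCC1",
               "CC1CCC1", "CC1CCCC1", "C(C)c1ccccc1", "C(C)Cc1ccccc1",
               "COc1ccccc1", "CCOc1ccccc1")
  unique(c(as.vector(outer(chains, terms, paste0)), singles))
}

# Amine scaffolds, written with a leading N so that "O=C(R)N<rest>" is a
# valid parent. All are larger than any alphabet substituent, so the amide
# cut always assigns the scaffold side as the core.
scaffold_smiles <- function() {
  slots <- c("F", "Cl", "Br", "C", "CC", "OC", "C(F)(F)F", "CCC", "C(C)C",
             "CCl")
  bases <- c("Nc1ccc(-c2ccc(%s)cc2)cc1",
             "Nc1ccc(Oc2ccc(%s)cc2)cc1",
             "Nc1ccc(-c2ccc(%s)cc2)cc1C",
             "Nc1ccc(Cc2ccc(%s)cc2)cc1")
  as.vector(t(outer(bases, slots, sprintf)))
}

DONOR_SCAFFOLD <- "c1ccc2c(c1)oc1ccc(C)cc12"  # methyl-dibenzofuran amine rest

.progsat_env <- new.env(parent = emptyenv())

# The substituent alphabet with scaled descriptors of the capped acyl
# fragments. Each fragment carries a stratum flag: roughly one third
# (chosen by content hash, hence spatially uniform in descriptor space) is
# reserved for the fragment library and never used as a member substituent,
# so virtual candidates interleave the member chemistry at any ensemble
# size. Memoized per session.
substituent_alphabet <- function() {
  if (!is.null(.progsat_env$alphabet)) return(.progsat_env$alphabet)
  r <- alphabet_r_groups()
  frag <- paste0("*C(=O)", r)
  desc <- fragment_descriptors(frag)
  keep <- desc$n_heavy <= 11  # capped fragment: acyl <= 11 heavy + H cap
  r <- r[keep]; desc <- desc[keep, , drop = FALSE]
  ord <- order(desc$mw, desc$id)
  r <- r[ord]; desc <- desc[ord, , drop = FALSE]
  space <- fit_chemspace(desc)
  scaled <- scale_descriptors(desc, space)
  reserved <- strtoi(substr(fnv1a(r), 8, 8), 16L) %% 4L == 0L
  out <- tibble::tibble(r_group = r,
                        fragment = paste0("*C(=O)", r),
                        reserved = reserved,
                        n_heavy_capped = desc$n_heavy)
  .progsat_env$alphabet <- out
  .progsat_env$alphabet_matrix <- as_descriptor_matrix(scaled)
  out
}

# Scaled descriptor matrix of the alphabet's capped fragments.
alphabet_matrix <- function() {
  substituent_alphabet()
  .progsat_env$alphabet_matrix
}

# Exactly k distinct, evenly spaced integer picks from 1..n (deterministic).
even_picks <- function(n, k) {
  if (k >= n) return(seq_len(n))
  idx <- unique(round(seq(1, n, length.out = k)))
  pool <- setdiff(seq_len(n), idx)
  while (length(idx) < k && length(pool)) {
    idx <- c(idx, pool[1]); pool <- pool[-1]
  }
  sort(idx)[seq_len(k)]
}

#' Default regime configurations
#'
#' One configuration per saturation regime. `coverage` is the target
#' fraction of the substituent alphabet's descriptor range spanned by the
#' members; `active_dispersion` below 0.5 places the actives in a densely
#' synthesized contiguous patch (few candidate analogs remain nearby),
#' above 0.5 spreads them across the whole member set.
#'
#' @param n_members Series sizes, one per regime in the order early,
#'   intermediate, late, saturated (recycled from length 1). The defaults
#'   grow with progression -- well-covered series are well covered partly
#'   because more analogs have been made -- and all pass the >= 30 filter.
#' @param n_actives Active compounds per series (default 5, passing the
#'   >= 3 filter).
#' @param n_fragments Donor fragments to emit (default: the full alphabet).
#' @param seed Base seed; config `i` uses `seed + i`.
#' @param n_per_regime Number of series per regime (default 1).
#' @return A tibble of regime configurations for
#'   [generate_series_dataset()].
#' @export
regime_configs <- function(n_members = c(32, 35, 40, 45), n_actives = 5,
                           n_fragments = NULL, seed = 1, n_per_regime = 1) {
  base <- tibble::tibble(
    regime = c("early", "intermediate", "late", "saturated"),
    coverage = c(0.25, 0.50, 0.75, 0.90),
    active_dispersion = c(0.35, 0.9, 0.9, 0.1),
    n_members = as.integer(rep_len(n_members, 4)))
  cfg <- base[rep(seq_len(4), each = n_per_regime), , drop = FALSE]
  cfg$n_actives <- n_actives
  cfg$n_fragments <- if (is.null(n_fragments)) NA_integer_ else n_fragments
  cfg$seed <- seed + seq_len(nrow(cfg))
  cfg
}

#' Generate a synthetic analog-series dataset
#'
#' For each configuration row, builds a series of amide parents sharing one
#' scaffold core, with acyl substituents drawn from a graded alphabet.
#' Members are sampled radially from a nearest-neighbor ball (in the
#' alphabet's scaled descriptor space, around a seeded center fragment)
#' whose size realizes the configured coverage. Low `active_dispersion`
#' places the actives in a densely synthesized patch — the nearest eligible
#' fragments around a seeded sub-center all become members and every s-th
#' one is active — while high dispersion spreads them across the member
#' set. A content-hashed quarter of the alphabet is reserved for the
#' fragment library, so the candidate clouds always interleave the member
#' chemistry. Donor compounds carry the alphabet on a distinct, larger
#' scaffold. Fully seeded and deterministic.
#'
#' @param configs A configuration tibble (see [regime_configs()]).
#' @return A list of class `progsat_dataset`: `compounds` (id, smiles,
#'   assay_id, active, potency), `donors` (id, smiles), and `truth` (one
#'   row per series: assay_id, regime, scaffold core side, the knobs used).
#' @export
generate_series_dataset <- function(configs) {
  need <- c("regime", "n_members", "n_actives", "coverage",
            "active_dispersion", "seed")
  stopifnot(all(need %in% names(configs)))
  if (!"n_fragments" %in% names(configs)) configs$n_fragments <- NA_integer_
  alpha <- substituent_alphabet()
  D <- alphabet_matrix()
  n_alpha <- nrow(alpha)
  eligible <- which(!alpha$reserved)
  n_pool <- length(eligible)
  scaffolds <- scaffold_smiles()
  if (nrow(configs) > length(scaffolds)) {
    stop("At most ", length(scaffolds), " series are supported (one ",
         "scaffold each); got ", nrow(configs), ".", call. = FALSE)
  }
  bad <- configs$n_actives > configs$n_members
  if (any(bad)) {
    stop("n_actives exceeds n_members in config row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  bad <- configs$coverage < 0 | configs$coverage > 1
  if (any(bad)) {
    stop("coverage must lie in [0, 1] (config row(s) ",
         paste(which(bad), collapse = ", "), ").", call. = FALSE)
  }
  bad <- configs$n_members + 2 > n_pool
  if (any(bad)) {
    stop("Unconstructible config: n_members = ",
         max(configs$n_members[bad]), " exceeds the ", n_pool,
         " member-eligible substituents of the alphabet (row(s) ",
         paste(which(bad), collapse = ", "), ").", call. = FALSE)
  }

  compounds <- list(); truth <- list()
  for (i in seq_len(nrow(configs))) {
    cf <- configs[i, ]
    rng <- local_seed(cf$seed)
    n_m <- cf$n_members; n_a <- cf$n_actives
    # ball of alphabet fragments around a seeded center, sized to realize
    # the coverage target; members sample the eligible part of the ball
    # radially, so the series spans it evenly
    c0 <- sample(eligible, 1)
    d_c0 <- sqrt(colSums((t(D) - D[c0, ])^2))
    w <- min(n_alpha, max(round(cf$coverage * n_alpha),
                          ceiling(1.6 * n_m) + 3L))
    ball <- order(d_c0)[seq_len(w)]
    elig_ball <- ball[!alpha$reserved[ball]]
    while (length(elig_ball) < n_m && w < n_alpha) {
      w <- min(n_alpha, w + 5L)
      ball <- order(d_c0)[seq_len(w)]
      elig_ball <- ball[!alpha$reserved[ball]]
    }
    eb <- elig_ball[order(d_c0[elig_ball])]
    if (cf$active_dispersion < 0.5) {
      # a densely synthesized patch hosts the actives: the nearest eligible
      # fragments around a seeded patch center all become members, and the
      # actives take every s-th of them by distance rank (lower dispersion
      # packs them tighter)
      s <- if (cf$active_dispersion >= 0.25) 2L else 1L
      patch_size <- min(s * (n_a - 1L) + 3L, n_m)
      if (patch_size < s * (n_a - 1L) + 1L) s <- 1L
      a0 <- eb[sample.int(max(1L, length(eb) %/% 2L), 1)]
      d_a0 <- sqrt(colSums((t(D[eligible, , drop = FALSE]) - D[a0, ])^2))
      patch <- eligible[order(d_a0)][seq_len(patch_size)]
      active_idx <- eligible[order(d_a0)][1L + s * (seq_len(n_a) - 1L)]
      rest <- setdiff(eb, patch)
      fill <- rest[even_picks(length(rest), n_m - length(patch))]
      member_idx <- sort(c(patch, fill))
    } else {
      member_idx <- eb[even_picks(length(eb), n_m)]
      active_idx <- member_idx[even_picks(n_m, n_a)]
    }
    active <- member_idx %in% active_idx
    potency <- rep(NA_real_, n_m)
    potency[active] <- 10^-stats::runif(sum(active), 5, 8)
    scaf <- scaffolds[i]
    assay <- sprintf("A%03d", i)
    smiles <- paste0("O=C(", alpha$r_group[member_idx], ")", scaf)
    compounds[[i]] <- tibble::tibble(
      id = sprintf("%s_c%03d", assay, seq_len(n_m)),
      smiles = smiles, assay_id = assay,
      active = active, potency = potency)
    truth[[i]] <- tibble::tibble(
      assay_id = assay, regime = cf$regime, scaffold = scaf,
      coverage = cf$coverage, active_dispersion = cf$active_dispersion,
      seed = cf$seed)
    restore_seed(rng)
  }

  n_frag <- max(c(configs$n_fragments, 0L), na.rm = TRUE)
  if (anyNA(configs$n_fragments) || n_frag <= 0) n_frag <- n_alpha
  donor_idx <- even_picks(n_alpha, min(n_frag, n_alpha))
  donors <- tibble::tibble(
    id = sprintf("d%04d", seq_along(donor_idx)),
    smiles = paste0("O=C(", alpha$r_group[donor_idx], ")N", DONOR_SCAFFOLD))

  structure(list(compounds = dplyr::bind_rows(compounds),
                 donors = donors,
                 truth = dplyr::bind_rows(truth)),
            class = "progsat_dataset")
}

# Seed scoping: run a block under a fixed seed without disturbing the
# caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}

#' @export
print.progsat_dataset <- function(x, ...) {
  cat("Synthetic analog-series dataset: ",
      length(unique(x$compounds$assay_id)), " series, ",
      nrow(x$compounds), " compounds, ", nrow(x$donors), " donors\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Emits `compounds.smi`, `activity.csv`, `donors.smi`, and the regime
#' ground truth as `truth.json`.
#'
#' @param dataset A [generate_series_dataset()] result.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_dataset_files <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(paste(dataset$compounds$smiles, dataset$compounds$id),
             file.path(dir, "compounds.smi"))
  act <- dataset$compounds[, c("id", "assay_id", "active", "potency")]
  names(act)[4] <- "potency_M"
  act$active <- as.integer(act$active)
  utils::write.csv(act, file.path(dir, "activity.csv"), row.names = FALSE,
                   na = "")
  writeLines(paste(dataset$donors$smiles, dataset$donors$id),
             file.path(dir, "donors.smi"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' The shipped micro example
#'
#' A fixed two-series dataset (6 members and 3 actives each, 10 donor
#' fragments) small enough that every radius and score can be recomputed by
#' hand from the distance matrices. Series EX1 carries its actives on three
#' adjacent alkyl substituents (a tight active cluster); EX2's actives are
#' spread across its substituent range.
#'
#' Scoring it with `score_saturation(..., min_members = 6, min_actives = 3)`
#' gives, per series (values recomputed independently by a plain-loop
#' evaluation of the distance matrices and frozen here):
#'
#' | series | \eqn{|V|} | r_global | r_local | \eqn{\nu_{assayed}} | \eqn{\nu_{active}} | raw_global | raw_local | z_global | z_local | category | lead (active NBs) |
#' |---|---|---|---|---|---|---|---|---|---|---|---|
#' | EX1 | 13 | 0.8523251 | 0.9804959 | 2 | 2 | 2/13 | 3/2 | -1/sqrt(2) | +1/sqrt(2) | low/low | EX1_c1 (1) |
#' | EX2 | 13 | 0.8533028 | 3.2251754 | 4 | 12 | 4/13 | 3/12 | +1/sqrt(2) | -1/sqrt(2) | low/low | EX2_c1 (1) |
#'
#' Both donor-derived fragment libraries contain 13 fragments (10 amide
#' cuts plus 3 from secondary cuts; none excluded). With only two series
#' the ensemble z-scores can only reach \eqn{\pm 1/\sqrt{2}}, so both
#' categories sit at low/low under the default threshold of 1.
#'
#' @return A `progsat_dataset` list (`compounds`, `donors`, `truth`).
#' @export
worked_example <- function() {
  scaf1 <- "Nc1ccc(-c2ccc(F)cc2)cc1"
  scaf2 <- "Nc1ccc(Oc2ccc(Cl)cc2)cc1"
  r1 <- c("CC", "CCC", "CCCC", "CO", "CCO", "COC")  # actives: adjacent alkyls
  a1 <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  p1 <- c(1e-6, 5e-7, 2e-6, NA, NA, NA)
  r2 <- c("C", "CCCC", "CCOCC", "C1CCCCC1", "c1ccccc1", "Cc1ccc(F)cc1")
  a2 <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  p2 <- c(2e-6, NA, 8e-7, NA, 3e-7, NA)
  donors_r <- c("CCCCC", "CC(C)C", "CCCO", "CCOC", "C(C)C",
                "CCCCCC", "C1CCCC1", "Cc1ccccc1", "c1ccc(F)cc1", "CCN(C)C")
  compounds <- tibble::tibble(
    id = c(sprintf("EX1_c%d", 1:6), sprintf("EX2_c%d", 1:6)),
    smiles = c(paste0("O=C(", r1, ")", scaf1),
               paste0("O=C(", r2, ")", scaf2)),
    assay_id = rep(c("EX1", "EX2"), each = 6),
    active = c(a1, a2),
    potency = c(p1, p2))
  donors <- tibble::tibble(
    id = sprintf("exd%02d", seq_along(donors_r)),
    smiles = paste0("O=C(", donors_r, ")N", DONOR_SCAFFOLD))
  truth <- tibble::tibble(assay_id = c("EX1", "EX2"),
                          regime = c("narrow", "spread"),
                          scaffold = c(scaf1, scaf2),
                          coverage = NA_real_,
                          active_dispersion = NA_real_,
                          seed = NA_integer_)
  structure(list(compounds = compounds, donors = donors, truth = truth),
            class = "progsat_dataset")
}
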