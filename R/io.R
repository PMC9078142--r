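# File formats: SMILES (.smi), SDF, activity CSV, descriptor CSV, and the
# JSON/CSV score reports.

#' Read a SMILES file
#'
#' Whitespace-separated format: SMILES in the first field, id in the second
#' (missing ids are filled as `mol<line>`).
#'
#' @param path Path to a `.smi` file.
#' @return A tibble with `id` and `smiles`. Unparseable records raise an
#'   error naming the line number.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  smi <- vapply(parts, `[`, "", 1L)
  ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  ids[is.na(ids)] <- paste0("mol", keep[is.na(ids)])
  can <- canonical_smiles(smi)
  if (anyNA(can)) {
    bad <- which(is.na(can))[1]
    stop("Malformed SMILES at line ", keep[bad], " of ", path, ": '",
         smi[bad], "'", call. = FALSE)
  }
  tibble::tibble(id = ids, smiles = smi)
}

#' Read an SD file
#'
#' @param path Path to an SDF/MOL file.
#' @return A tibble with `id` (molecule title, or `mol<i>`) and canonical
#'   `smiles`.
#' @export
read_sdf <- function(path) {
  res <- ob_run(readLines(path, warn = FALSE), "sdf", "can")
  if (length(res) == 0) {
    stop("No molecule could be read from ", path, call. = FALSE)
  }
  parts <- strsplit(res, "\t", fixed = TRUE)
  smi <- trimws(vapply(parts, `[`, "", 1L))
  ids <- trimws(vapply(parts, function(p) if (length(p) > 1) p[2] else "", ""))
  blank <- !nzchar(ids)
  ids[blank] <- paste0("mol", which(blank))
  tibble::tibble(id = ids, smiles = smi)
}

#' Read structures from SMILES or SDF by extension
#' @param path `.smi`/`.txt` (SMILES) or `.sdf`/`.mol` file.
#' @return A tibble with `id` and `smiles`.
#' @export
read_structures <- function(path) {
  if (grepl("\\.(sdf|mol)$", path, ignore.case = TRUE)) read_sdf(path)
  else read_smiles(path)
}

#' Read an activity table
#'
#' CSV with columns `id`, `assay_id`, `active` (logical or 0/1), and
#' optionally `potency_M` (molar IC50/Ki).
#'
#' @param path CSV path.
#' @return A tibble with `id`, `assay_id`, `active`, `potency`.
#' @export
read_activity <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "assay_id", "active")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("Activity table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  act <- df$active
  if (!is.logical(act)) act <- as.logical(as.integer(act))
  if (anyNA(act)) {
    stop("Activity table ", path, ": 'active' must be logical or 0/1 (bad ",
         "value at data line ", which(is.na(act))[1], ").", call. = FALSE)
  }
  tibble::tibble(
    id = as.character(df$id),
    assay_id = as.character(df$assay_id),
    active = act,
    potency = if ("potency_M" %in% names(df)) as.numeric(df$potency_M)
              else NA_real_)
}

#' Join structures and activity into a compound table
#' @param structures Tibble from [read_structures()].
#' @param activity Tibble from [read_activity()].
#' @return Compound tibble ready for [extract_series()].
#' @export
join_compounds <- function(structures, activity) {
  missing_ids <- setdiff(activity$id, structures$id)
  if (length(missing_ids)) {
    stop("Activity records without a structure: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) ", ...", call. = FALSE)
  }
  dplyr::inner_join(structures, activity, by = "id")
}

#' Write a descriptor matrix as CSV
#'
#' Fixed header: `id` followed by the seven descriptor columns.
#'
#' @param descriptors Tibble from [compute_descriptors()] (scaled or not).
#' @param path Output CSV path.
#' @export
write_descriptor_csv <- function(descriptors, path) {
  utils::write.csv(descriptors[, c("id", descriptor_names)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

report_columns <- c("series_id", "assay_id", "core", "n_members",
                    "n_actives", "n_virtual", "r_global", "r_local",
                    "raw_global", "raw_local", "z_global", "z_local",
                    "category", "stage", "lead_id",
                    "lead_active_neighbors", "flags")

#' Write the per-series score report
#'
#' Writes the report both as JSON (with the run parameters and the
#' normalization reference) and as CSV with numbers at 12 significant
#' digits, so the two forms are interconvertible without loss.
#'
#' @param result A `progsat_saturation` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_saturation_report <- function(result, dir) {
  stopifnot(inherits(result, "progsat_saturation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scores <- result$scores[, report_columns]
  json_path <- file.path(dir, "saturation_report.json")
  csv_path <- file.path(dir, "saturation_report.csv")
  jsonlite::write_json(
    list(params = result$params,
         reference = result$reference,
         scores = scores),
    json_path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  out <- scores
  for (j in names(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 12)
  }
  utils::write.csv(out, csv_path, row.names = FALSE, na = "")
  invisible(c(json = json_path, csv = csv_path))
}

#' Read a score report back (JSON or CSV)
#' @param path Path written by [write_saturation_report()].
#' @return The per-series score tibble.
#' @export
read_saturation_report <- function(path) {
  if (grepl("\\.json$", path)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    tibble::as_tibble(x$scores)[, report_columns]
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(flags = "character",
                                         category = "character",
                                         stage = "character"))
    tibble::as_tibble(df)[, report_columns]
  }
}

#' Write a run manifest
#'
#' Records configuration, package and tool versions, seed and headline
#' counts so every run is reproducible.
#'
#' @param result A `progsat_saturation` object.
#' @param path Output JSON path.
#' @param seed Seed used for any fixture generation (`NULL` for none).
#' @export
write_run_manifest <- function(result, path, seed = NULL) {
  ob_ver <- tryCatch(
    system2(ob_binary(), "-V", stdout = TRUE, stderr = FALSE)[1],
    error = function(e) NA_character_)
  g <- glance(result)
  jsonlite::write_json(
    list(package = as.character(utils::packageVersion("progsat")),
         r_version = R.version.string,
         openbabel = ob_ver,
         seed = seed,
         params = result$params,
         counts = as.list(g)),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Write per-series SMILES files and manifest for extracted series
#'
#' @param series Tibble from [extract_series()].
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_series_files <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(series))) {
    m <- series$members[[i]]
    writeLines(paste(m$smiles, m$id),
               file.path(dir, paste0(series$series_id[i], ".smi")))
  }
  manifest <- lapply(seq_len(nrow(series)), function(i) {
    m <- series$members[[i]]
    list(series_id = series$series_id[i],
         assay_id = series$assay_id[i],
         core = series$core[i],
         lead_id = series$lead_id[i],
         members = m)
  })
  path <- file.path(dir, "series_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, na = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a series manifest written by [write_series_files()]
#' @param path Path to `series_manifest.json`.
#' @return A series tibble equivalent to the [extract_series()] output.
#' @export
read_series_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  members <- lapply(x$members, function(m) {
    m <- tibble::as_tibble(m)
    m$active <- as.logical(m$active)
    m$potency <- as.numeric(m$potency)
    m
  })
  tibble::tibble(
    series_id = x$series_id, assay_id = x$assay_id, core = x$core,
    n_members = vapply(members, nrow, 0L),
    n_actives = vapply(members, function(m) sum(m$active), 0L),
    lead_id = as.character(x$lead_id),
    members = members)
}
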