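# Dataset submission: per-lab format mapping, validation and
# pseudo-anonymization.
#
# Each laboratory keeps its own table layout; a lab format spec (a JSON
# document) maps source columns to canonical fields and source
# vocabularies to the canonical one. Dataset acceptance is
# all-or-nothing: any bad row rejects the dataset, with row-level
# diagnostics.

.FIVE_TIER <- c("B", "LB", "VUS", "LP", "P")

#' Five-tier classification labels
#'
#' @return `c("B", "LB", "VUS", "LP", "P")`.
#' @export
five_tier_labels <- function() .FIVE_TIER

#' Supported variant callers
#'
#' @return character vector of caller names accepted in dataset metadata.
#' @export
supported_callers <- function() {
  c("VarScan2", "Strelka2", "GATK HaplotypeCaller", "GATK UnifiedGenotyper",
    "Torrent Variant Caller", "VarDict", "DNAscope")
}

#' Create a lab format spec
#'
#' @param lab_id laboratory identifier.
#' @param columns named character vector mapping canonical field ->
#'   source column name.
#' @param values named list of value maps, one per canonical field; each
#'   a named character vector mapping source value -> canonical value
#'   (must be injective).
#' @param date_format `strptime` format of dates in this lab's files.
#' @return an object of class `lab_format_spec`.
#' @export
lab_format_spec <- function(lab_id, columns, values = list(),
                            date_format = "%Y-%m-%d") {
  stopifnot(is.character(columns), !is.null(names(columns)))
  for (f in names(values)) {
    vm <- unlist(values[[f]])
    if (anyDuplicated(vm))
      .stopf("value map for field '%s' is not injective", f)
    values[[f]] <- vm
  }
  structure(list(lab_id = lab_id, columns = columns, values = values,
                 date_format = date_format),
            class = "lab_format_spec")
}

#' Read a lab format spec from JSON
#'
#' @param path JSON file with fields `lab_id`, `columns`, `values`,
#'   `date_format`.
#' @return a `lab_format_spec`.
#' @export
read_lab_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lab_format_spec(j$lab_id, unlist(j$columns), as.list(j$values),
                  if (is.null(j$date_format)) "%Y-%m-%d" else j$date_format)
}

#' Write a lab format spec to JSON
#'
#' @param spec a `lab_format_spec`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lab_spec <- function(spec, path) {
  jsonlite::write_json(list(lab_id = spec$lab_id,
                            columns = as.list(spec$columns),
                            values = lapply(spec$values, as.list),
                            date_format = spec$date_format),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# map a raw table to canonical columns; returns dt or a missing-column error
.map_columns <- function(tab, spec, mandatory) {
  missing <- setdiff(unname(spec$columns), names(tab))
  if (length(missing))
    .stopf("lab '%s': mandatory column(s) missing from file: %s",
           spec$lab_id, paste(missing, collapse = ", "))
  out <- data.table::as.data.table(tab)[, unname(spec$columns), with = FALSE]
  data.table::setnames(out, names(spec$columns))
  need <- setdiff(mandatory, names(out))
  if (length(need))
    .stopf("lab '%s': spec does not map mandatory field(s): %s",
           spec$lab_id, paste(need, collapse = ", "))
  out
}

# apply a value map to one field, recording row diagnostics
.map_values <- function(out, spec, field, diags) {
  vm <- spec$values[[field]]
  if (is.null(vm)) return(diags)
  raw <- out[[field]]
  mapped <- unname(vm[raw])
  keep_raw <- raw %in% vm            # already canonical values pass through
  mapped[is.na(mapped) & keep_raw] <- raw[is.na(mapped) & keep_raw]
  bad <- which(is.na(mapped) & !is.na(raw))
  for (i in bad)
    diags <- rbind(diags, data.table::data.table(
      row = i, field = field,
      problem = sprintf("unmappable value '%s'", raw[i])))
  data.table::set(out, j = field, value = mapped)
  diags
}

.empty_diags <- function() {
  data.table::data.table(row = integer(), field = character(),
                         problem = character())
}

#' Parse a classification submission table
#'
#' Reads a TSV/CSV classification table through a lab format spec and
#' normalizes it to canonical fields. A row must define the variant
#' either genomically (`chrom`, `pos`, `ref`, `alt`) or as `cdna` +
#' `transcript`, and must carry a five-tier `classification` and a
#' parseable `date`. Acceptance is all-or-nothing.
#'
#' @param file path to a delimited table (or a data.frame).
#' @param spec a `lab_format_spec`.
#' @return list with `accepted` (logical), `records` (canonical
#'   `data.table`, only when accepted; includes `lab` and `key` for
#'   genomically defined variants) and `diagnostics` (row-level issues).
#' @export
parse_classifications <- function(file, spec) {
  tab <- if (is.data.frame(file)) data.table::as.data.table(file)
         else data.table::fread(file, colClasses = "character")
  genomic <- all(c("chrom", "pos", "ref", "alt") %in% names(spec$columns))
  cdna <- all(c("cdna", "transcript") %in% names(spec$columns))
  if (!genomic && !cdna)
    .stopf("lab '%s': spec maps neither a genomic nor a cDNA variant definition",
           spec$lab_id)
  mandatory <- c(if (genomic) c("chrom", "pos", "ref", "alt")
                 else c("cdna", "transcript"),
                 "classification", "date")
  out <- .map_columns(tab, spec, mandatory)
  diags <- .empty_diags()
  diags <- .map_values(out, spec, "classification", diags)
  bad_cls <- which(!out$classification %in% .FIVE_TIER)
  for (i in setdiff(bad_cls, diags$row))
    diags <- rbind(diags, data.table::data.table(
      row = i, field = "classification",
      problem = sprintf("label '%s' outside five-tier vocabulary",
                        out$classification[i])))
  dates <- as.Date(out$date, format = spec$date_format)
  for (i in which(is.na(dates)))
    diags <- rbind(diags, data.table::data.table(
      row = i, field = "date",
      problem = sprintf("unparseable date '%s'", out$date[i])))
  data.table::set(out, j = "date", value = dates)
  if (genomic) {
    data.table::set(out, j = "pos", value = suppressWarnings(as.integer(out$pos)))
    for (i in which(is.na(out$pos)))
      diags <- rbind(diags, data.table::data.table(
        row = i, field = "pos", problem = "unparseable position"))
  }
  accepted <- nrow(diags) == 0L
  out[, "lab" := spec$lab_id]
  if (genomic && accepted)
    out[, "key" := paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")]
  out[, "row_in_file" := seq_len(nrow(out))]
  list(accepted = accepted,
       records = if (accepted) out[] else NULL,
       diagnostics = diags)
}

#' Parse an individual-metadata submission table
#'
#' Mandatory canonical fields: `individual_id`, `sex` and a
#' `suspicion` term from the configured clinical-suspicion vocabulary.
#' Optional: `family_id`, `cancer_history`, `birth_date`, `deceased`.
#' Acceptance is all-or-nothing.
#'
#' @param file path to a delimited table (or a data.frame).
#' @param spec a `lab_format_spec`.
#' @param suspicion_terms character vector: the controlled vocabulary of
#'   clinical-suspicion terms.
#' @return list with `accepted`, `records`, `diagnostics` as in
#'   [parse_classifications()].
#' @export
parse_individuals <- function(file, spec, suspicion_terms) {
  tab <- if (is.data.frame(file)) data.table::as.data.table(file)
         else data.table::fread(file, colClasses = "character")
  out <- .map_columns(tab, spec, c("individual_id", "sex", "suspicion"))
  diags <- .empty_diags()
  for (f in intersect(names(spec$values), names(out)))
    diags <- .map_values(out, spec, f, diags)
  for (i in which(is.na(out$individual_id) | !nzchar(out$individual_id)))
    diags <- rbind(diags, data.table::data.table(
      row = i, field = "individual_id", problem = "empty individual id"))
  for (i in which(is.na(out$suspicion) | !out$suspicion %in% suspicion_terms))
    diags <- rbind(diags, data.table::data.table(
      row = i, field = "suspicion",
      problem = sprintf("term '%s' not in configured vocabulary",
                        out$suspicion[i])))
  if ("birth_date" %in% names(out)) {
    bd <- as.Date(out$birth_date, format = spec$date_format)
    for (i in which(!is.na(out$birth_date) & nzchar(out$birth_date) & is.na(bd)))
      diags <- rbind(diags, data.table::data.table(
        row = i, field = "birth_date",
        problem = sprintf("unparseable date '%s'", out$birth_date[i])))
    data.table::set(out, j = "birth_date", value = bd)
  }
  accepted <- nrow(diags) == 0L
  out[, "lab" := spec$lab_id]
  list(accepted = accepted,
       records = if (accepted) out[] else NULL,
       diagnostics = diags)
}

.PSEUDO_ALPHABET <- c(LETTERS, as.character(0:9))

#' Create an empty pseudonym map
#'
#' A mutable bidirectional map between source identifiers and randomly
#' generated pseudonyms: 6 characters for individuals, 5 for families,
#' drawn from the 36 uppercase alphanumerics. One global namespace per
#' kind.
#'
#' @return an object of class `pseudonym_map`.
#' @export
pseudonym_map <- function() {
  structure(list(env = new.env(parent = emptyenv())), class = "pseudonym_map")
}

.kind_len <- c(individual = 6L, family = 5L)

#' Pseudonymize an identifier
#'
#' Returns the existing pseudonym when the source id is already mapped;
#' otherwise draws codes uniformly from the alphabet until unique within
#' the kind. Uses R's RNG: seed upstream for reproducibility.
#'
#' @param map a `pseudonym_map`.
#' @param source_id source identifier.
#' @param kind `"individual"` (6 characters) or `"family"` (5).
#' @return the pseudonym (character scalar).
#' @export
pseudonymize <- function(map, source_id, kind = c("individual", "family")) {
  kind <- match.arg(kind)
  e <- map$env
  fwd_key <- paste0("fwd:", kind, ":", source_id)
  if (!is.null(e[[fwd_key]])) return(e[[fwd_key]])
  len <- .kind_len[[kind]]
  if (length(ls(e, pattern = paste0("^rev:", kind, ":"))) >= 36^len)
    .stopf("pseudonym space exhausted for kind '%s'", kind)
  repeat {
    code <- paste(sample(.PSEUDO_ALPHABET, len, replace = TRUE), collapse = "")
    rev_key <- paste0("rev:", kind, ":", code)
    if (is.null(e[[rev_key]])) {
      e[[fwd_key]] <- code
      e[[rev_key]] <- source_id
      return(code)
    }
  }
}

#' Look up the source id behind a pseudonym
#'
#' @inheritParams pseudonymize
#' @param code pseudonym.
#' @return source id, or `NA` if unmapped.
#' @export
unpseudonymize <- function(map, code, kind = c("individual", "family")) {
  kind <- match.arg(kind)
  v <- map$env[[paste0("rev:", kind, ":", code)]]
  if (is.null(v)) NA_character_ else v
}

#' Export a pseudonym map as a table
#'
#' @param map a `pseudonym_map`.
#' @return `data.table` with columns `kind`, `source_id`, `pseudonym`.
#' @export
pseudonym_table <- function(map) {
  e <- map$env
  keys <- ls(e, pattern = "^fwd:")
  if (length(keys) == 0L)
    return(data.table::data.table(kind = character(), source_id = character(),
                                  pseudonym = character()))
  parts <- data.table::tstrsplit(sub("^fwd:", "", keys), ":", fixed = TRUE)
  data.table::data.table(kind = parts[[1]],
                         source_id = parts[[2]],
                         pseudonym = vapply(keys, function(k) e[[k]], ""))
}

#' Validate dataset metadata
#'
#' A dataset of individuals' variants must declare its sequencing
#' platform, read type, panel version and region file, genome build,
#' aligner, a supported variant caller and a depth threshold of at
#' least 10.
#'
#' @param m named list with fields `platform`, `read_type`,
#'   `panel_version`, `panel_file`, `genome_build`, `aligner`, `caller`,
#'   `depth_threshold`, and optionally `dataset_id`.
#' @return the validated metadata (invisibly the same list), or an error.
#' @export
validate_metadata <- function(m) {
  need <- c("platform", "read_type", "panel_version", "panel_file",
            "genome_build", "aligner", "caller", "depth_threshold")
  absent <- setdiff(need, names(m))
  absent <- c(absent, need[vapply(m[intersect(need, names(m))],
                                  function(x) is.null(x) || (is.character(x) && !nzchar(x)),
                                  logical(1))])
  if (length(absent))
    .stopf("dataset metadata missing field(s): %s",
           paste(unique(absent), collapse = ", "))
  if (!m$caller %in% supported_callers())
    .stopf("variant caller '%s' is not supported (supported: %s)",
           m$caller, paste(supported_callers(), collapse = ", "))
  m$depth_threshold <- as.integer(m$depth_threshold)
  if (is.na(m$depth_threshold) || m$depth_threshold < 10L)
    .stopf("depth threshold must be >= 10, got %s", m$depth_threshold)
  if (is.null(m$dataset_id)) m$dataset_id <- NA_character_
  m
}

#' Record an accepted submission in a dataset manifest
#'
#' Every accepted submission results in a new incremental version of the
#' database; versions are tracked in a JSON manifest.
#'
#' @param manifest_path JSON manifest file (created if absent).
#' @param dataset_id persistent dataset identifier.
#' @param kind `"classifications"` or `"individuals"`.
#' @return the new version number (integer).
#' @export
bump_dataset_version <- function(manifest_path, dataset_id, kind) {
  man <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  else list(version = 0L, submissions = data.frame())
  version <- as.integer(man$version) + 1L
  sub <- data.frame(version = version, dataset_id = dataset_id, kind = kind,
                    stringsAsFactors = FALSE)
  subs <- rbind(as.data.frame(man$submissions), sub)
  jsonlite::write_json(list(version = version, submissions = subs),
                       manifest_path, auto_unbox = TRUE)
  version
}
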