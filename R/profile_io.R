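#' Apply the four MGnify taxonomy-summary harmonization edits
#'
#' MGnify taxonomy-summary exports need four textual fixes before their
#' lineage keys line up with Greengenes-style OTU tables: (i) a leading
#' \code{"s"} rank-prefix artifact is removed from each OTU identifier,
#' (ii) all \code{"Root;"} occurrences are removed, (iii) the header cell
#' \code{"SampleID"} is renamed \code{"OTU ID"}, and (iv) \code{";"} is
#' replaced with \code{"|"} everywhere. The edits are applied in that order
#' and the function is idempotent.
#'
#' Edit (i) is ambiguous as usually stated; by default it strips the
#' superkingdom artifact (the \code{"s"} of a leading \code{"sk__"}, so
#' \code{"sk__Bacteria"} becomes \code{"k__Bacteria"}). Pass a different
#' \code{otu_prefix_pattern} (a Perl regex replaced by \code{""} at the
#' start of the first tab-field of each data line) to encode another
#' reading.
#'
#' @param raw_table Character vector of tab-separated lines, header first.
#' @param otu_prefix_pattern Perl regex anchored at the start of each data
#'   line's first field; the match is deleted. Default \code{"^s(?=k__)"}.
#' @return Character vector of fixed lines, same length as the input.
#' @export
apply_mgnify_fixes <- function(raw_table, otu_prefix_pattern = "^s(?=k__)") {
  if (length(raw_table) < 1L) {
    gi_error("MGnify table has no header line", "format_error")
  }
  lines <- raw_table
  body <- seq_along(lines)[-1L]
  # (i) leading "s" artifact on each OTU identifier (first tab-field)
  if (length(body) > 0L) {
    lines[body] <- sub(otu_prefix_pattern, "", lines[body], perl = TRUE)
  }
  # (ii) every "Root;" occurrence
  lines <- gsub("Root;", "", lines, fixed = TRUE)
  # (iii) header "SampleID" -> "OTU ID"
  lines[1L] <- sub("(^|\t)SampleID(\t|$)", "\\1OTU ID\\2", lines[1L])
  # (iv) ";" -> "|" everywhere
  lines <- gsub(";", "|", lines, fixed = TRUE)
  lines
}

new_abundance_profile <- function(sample_id, abundance, taxa) {
  stopifnot(is.numeric(abundance), nrow(taxa) == length(abundance))
  if (any(abundance < 0)) {
    gi_error(sprintf("profile %s has negative abundances", sample_id),
             "validation_error")
  }
  if (!any(abundance > 0)) {
    gi_error(sprintf("profile %s has no positive abundance", sample_id),
             "degenerate_sample")
  }
  structure(
    list(sample_id = sample_id, abundance = abundance, taxa = taxa),
    class = "abundance_profile"
  )
}

#' Construct an abundance profile
#'
#' @param sample_id Sample identifier.
#' @param abundance Named non-negative numeric vector; names are lineage
#'   strings (any supported dialect).
#' @param dialect Lineage dialect of the names.
#' @return An \code{abundance_profile}: sample id, abundance vector, and a
#'   parsed taxa frame (canonical lineage, genus, species).
#' @export
abundance_profile <- function(sample_id, abundance, dialect = "plain") {
  if (is.null(names(abundance)) || any(!nzchar(names(abundance)))) {
    gi_error("abundance vector must be fully named by lineage strings",
             "validation_error")
  }
  taxa <- parse_lineage_frame(names(abundance), dialect)
  ab <- as.numeric(abundance)
  # duplicate lineages (distinct OTUs, same taxon) are summed
  if (anyDuplicated(taxa$lineage)) {
    ab <- as.numeric(rowsum(ab, taxa$lineage, reorder = FALSE))
    taxa <- taxa[!duplicated(taxa$lineage), , drop = FALSE]
    rownames(taxa) <- NULL
  }
  new_abundance_profile(sample_id, ab, taxa)
}

#' Convert a profile to relative abundances
#'
#' Divides every abundance by the sample total so the profile sums to 1.
#' Keystone scoring and cross-cohort comparison operate on this scale;
#' MAPI itself is scale-invariant and accepts either counts or proportions.
#'
#' @param profile An \code{abundance_profile}.
#' @return The profile with abundances summing to 1 (within 1e-9).
#' @export
to_relative <- function(profile) {
  stopifnot(inherits(profile, "abundance_profile"))
  total <- sum(profile$abundance)
  if (total <= 0) {
    gi_error(sprintf("profile %s has zero total abundance", profile$sample_id),
             "degenerate_sample")
  }
  profile$abundance <- profile$abundance / total
  profile
}

new_cohort_table <- function(abundance, taxa, metadata) {
  stopifnot(is.matrix(abundance), nrow(taxa) == nrow(abundance))
  sample_ids <- colnames(abundance)
  if (anyDuplicated(sample_ids)) {
    gi_error(sprintf(
      "duplicate sample ids: %s",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")
    ), "validation_error")
  }
  if (is.null(metadata)) {
    metadata <- data.frame(
      sample_id = sample_ids,
      age = NA_real_,
      gender = NA_character_,
      conditions = NA_character_,
      phenotype = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(abundance = abundance, taxa = taxa, metadata = metadata),
    class = "cohort_table"
  )
}

#' Build a cohort table from profiles
#'
#' Assembles per-sample abundance profiles into a samples-by-taxa cohort with
#' aligned per-sample metadata. Metadata rows and profiles are matched on
#' \code{sample_id}; unmatched entries on either side raise an error naming
#' them rather than being dropped silently.
#'
#' @param profiles List of \code{abundance_profile} objects.
#' @param metadata Optional data frame with columns \code{sample_id},
#'   \code{age}, \code{gender}, \code{conditions} (semicolon-joined),
#'   \code{phenotype}.
#' @return A \code{cohort_table}: abundance matrix (taxa x samples), taxa
#'   frame, metadata frame.
#' @export
cohort_table <- function(profiles, metadata = NULL) {
  if (length(profiles) == 0L) {
    gi_error("cohort has no profiles", "empty_input")
  }
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    gi_error(sprintf("duplicate sample ids: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "validation_error")
  }
  all_taxa <- unique(do.call(rbind, lapply(profiles, `[[`, "taxa")))
  if (anyDuplicated(all_taxa$lineage)) {
    all_taxa <- all_taxa[!duplicated(all_taxa$lineage), , drop = FALSE]
  }
  rownames(all_taxa) <- NULL
  mat <- matrix(0, nrow = nrow(all_taxa), ncol = length(profiles),
                dimnames = list(all_taxa$lineage, ids))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    mat[p$taxa$lineage, j] <- p$abundance
  }
  if (!is.null(metadata)) {
    metadata <- validate_metadata(metadata, ids)
  }
  new_cohort_table(mat, all_taxa, metadata)
}

validate_metadata <- function(metadata, sample_ids) {
  stopifnot(is.data.frame(metadata), "sample_id" %in% names(metadata))
  extra <- setdiff(metadata$sample_id, sample_ids)
  missing <- setdiff(sample_ids, metadata$sample_id)
  if (length(extra) || length(missing)) {
    gi_error(sprintf(
      "metadata/profile mismatch: %d metadata rows without a profile (%s); %d profiles without metadata (%s)",
      length(extra), paste(utils::head(extra, 5), collapse = ", "),
      length(missing), paste(utils::head(missing, 5), collapse = ", ")
    ), "validation_error")
  }
  for (col in c("age", "gender", "conditions", "phenotype")) {
    if (!col %in% names(metadata)) metadata[[col]] <- NA
  }
  metadata <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  metadata
}

#' Number of taxa and samples in a cohort
#' @param x A \code{cohort_table}.
#' @export
dim.cohort_table <- function(x) dim(x$abundance)

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d taxa x %d samples\n",
              nrow(x$abundance), ncol(x$abundance)))
  if (!all(is.na(x$metadata$phenotype))) {
    tab <- table(x$metadata$phenotype, useNA = "ifany")
    cat("phenotypes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# Extract one sample as an abundance_profile.
cohort_profile <- function(cohort, sample_id) {
  j <- match(sample_id, colnames(cohort$abundance))
  if (is.na(j)) {
    gi_error(sprintf("no sample %s in cohort", sample_id), "validation_error")
  }
  new_abundance_profile(sample_id, cohort$abundance[, j], cohort$taxa)
}

#' Read a taxonomic abundance table
#'
#' Reads a TSV abundance table in one of three dialects into a
#' \code{cohort_table}. The \code{plain} dialect has a first column
#' \code{taxon} holding lineage strings and one column per sample;
#' \code{microbiomehd} covers 100\% OTU tables with Latin lineages;
#' \code{mgnify} additionally applies the four taxonomy-summary fixes
#' (see \code{\link{apply_mgnify_fixes}}) before parsing. Duplicate taxon
#' rows (distinct OTUs collapsing to one lineage) are summed.
#'
#' @param path Path to the TSV file.
#' @param dialect One of \code{"plain"}, \code{"mgnify"},
#'   \code{"microbiomehd"}.
#' @param orientation \code{"taxa_rows"} (default), \code{"samples_rows"}
#'   for a transposed table, or \code{"auto"} to pick the axis whose margin
#'   labels are non-numeric.
#' @return A \code{cohort_table} with metadata unset.
#' @export
read_abundance_table <- function(path,
                                 dialect = c("plain", "mgnify", "microbiomehd"),
                                 orientation = c("taxa_rows", "samples_rows",
                                                 "auto")) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    gi_error(sprintf("no such file: %s", path), "format_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    gi_error(sprintf("%s: need a header and at least one data row", path),
             "format_error")
  }
  if (dialect == "mgnify") {
    lines <- apply_mgnify_fixes(lines)
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ <- length(cells[[1L]])
  ragged <- which(vapply(cells, length, integer(1)) != ncol_)
  if (length(ragged)) {
    gi_error(sprintf("%s: ragged rows at lines %s", path,
                     paste(utils::head(ragged, 5), collapse = ", ")),
             "format_error")
  }
  header <- cells[[1L]]
  body <- do.call(rbind, cells[-1L])
  row_keys <- body[, 1L]
  vals_chr <- body[, -1L, drop = FALSE]
  vals <- suppressWarnings(array(as.numeric(vals_chr), dim = dim(vals_chr)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    gi_error(sprintf("%s: non-numeric cell at data row %d, column %d",
                     path, bad[[1]], bad[[2]] + 1L), "format_error")
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1L, ]
    gi_error(sprintf("%s: negative abundance at data row %d, column %d",
                     path, bad[[1]], bad[[2]] + 1L), "validation_error")
  }
  col_keys <- header[-1L]
  if (orientation == "auto") {
    # lineage strings live on whichever margin carries rank prefixes
    looks_lineage <- function(x) mean(grepl("__|[;|]", x)) > 0.5
    orientation <- if (looks_lineage(row_keys)) "taxa_rows"
                   else if (looks_lineage(col_keys)) "samples_rows"
                   else "taxa_rows"
  }
  if (orientation == "samples_rows") {
    vals <- t(vals)
    tmp <- row_keys; row_keys <- col_keys; col_keys <- tmp
  }
  taxa <- parse_lineage_frame(row_keys, dialect)
  if (anyDuplicated(taxa$lineage)) {
    vals <- rowsum(vals, taxa$lineage, reorder = FALSE)
    taxa <- taxa[!duplicated(taxa$lineage), , drop = FALSE]
    rownames(taxa) <- NULL
  }
  dimnames(vals) <- list(taxa$lineage, col_keys)
  new_cohort_table(vals, taxa, NULL)
}

#' Write a cohort's abundance table in the plain dialect
#'
#' @param cohort A \code{cohort_table}.
#' @param path Output TSV path.
#' @param digits Significant digits used for numeric cells (default 15,
#'   enough for exact text-decimal round-trip of doubles in practice).
#' @export
write_abundance_table <- function(cohort, path, digits = 15) {
  stopifnot(inherits(cohort, "cohort_table"))
  header <- paste(c("taxon", colnames(cohort$abundance)), collapse = "\t")
  rows <- apply(cohort$abundance, 1L, function(v) {
    paste(format(v, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = "\t")
  })
  writeLines(c(header, paste(rownames(cohort$abundance), rows, sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read or write per-sample metadata
#'
#' Metadata TSVs have columns \code{sample_id}, \code{age}, \code{gender},
#' \code{conditions} (semicolon-joined list, empty for none) and optionally
#' \code{phenotype}.
#'
#' @param path TSV path.
#' @return A metadata data frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), encoding = "UTF-8")
  if (!"sample_id" %in% names(md)) {
    gi_error(sprintf("%s: metadata needs a sample_id column", path),
             "format_error")
  }
  for (col in c("age", "gender", "conditions", "phenotype")) {
    if (!col %in% names(md)) md[[col]] <- NA
  }
  md$conditions[is.na(md$conditions)] <- ""
  md
}

#' @rdname read_metadata
#' @param metadata Metadata data frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# Split a semicolon-joined conditions cell into a character vector.
split_conditions <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}
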