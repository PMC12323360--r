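AERO_CATEGORIES <- c("aerotolerant", "strict_anaerobe")

#' Construct an aerotolerance classification table
#'
#' The MAPI numerator and denominator are defined by a curated list of
#' prokaryotes classified by their aerotolerant or obligate-anaerobic
#' metabolism. The table maps genera to a category, with species-level
#' overrides consulted first — the bundled list uses the override mechanism
#' for \emph{Bifidobacterium}, whose strict anaerobes are defined at the
#' species level, but overrides are honored for any genus.
#'
#' @param genus_map Named character vector: genus name -> category.
#' @param species_overrides Named character vector: binomial -> category.
#' @param provenance Free-text source note.
#' @return An \code{aerotolerance_table}.
#' @export
aerotolerance_table <- function(genus_map = character(),
                                species_overrides = character(),
                                provenance = "") {
  check_cats <- function(x, what) {
    bad <- setdiff(unique(unname(x)), AERO_CATEGORIES)
    if (length(bad)) {
      gi_error(sprintf("unknown %s category: %s", what,
                       paste(bad, collapse = ", ")), "validation_error")
    }
  }
  names(genus_map) <- normalize_taxon_name(names(genus_map))
  names(species_overrides) <- normalize_taxon_name(names(species_overrides))
  check_cats(genus_map, "genus")
  check_cats(species_overrides, "species")
  if (anyDuplicated(names(genus_map)) || anyDuplicated(names(species_overrides))) {
    gi_error("duplicate taxon in aerotolerance table", "conflict_error")
  }
  structure(
    list(genus_map = genus_map, species_overrides = species_overrides,
         provenance = provenance),
    class = "aerotolerance_table"
  )
}

#' Load an aerotolerance classification TSV
#'
#' Expects columns \code{taxon}, \code{level} (\code{genus} or
#' \code{species}), \code{category} (\code{aerotolerant} or
#' \code{strict_anaerobe}) and an optional \code{citation} column.
#' Duplicate rows that agree are collapsed; conflicting duplicates are an
#' error. The table is a swappable input: scores are reproducible against
#' any curated list without code changes.
#'
#' @param path TSV path. The default is the starter table bundled with the
#'   package, covering common gut genera.
#' @return An \code{aerotolerance_table}.
#' @export
load_classification <- function(path = default_aerotolerance_path()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(df) == 0L) {
    warning("empty aerotolerance table loaded from ", path)
    return(aerotolerance_table(provenance = path))
  }
  need <- c("taxon", "level", "category")
  if (!all(need %in% names(df))) {
    gi_error(sprintf("%s: aerotolerance table needs columns %s", path,
                     paste(need, collapse = ", ")), "validation_error")
  }
  bad_level <- which(!df$level %in% c("genus", "species"))
  if (length(bad_level)) {
    gi_error(sprintf("%s: unknown level %s at line %d", path,
                     dQuote(df$level[bad_level[1]]), bad_level[1] + 1L),
             "validation_error")
  }
  bad_cat <- which(!df$category %in% AERO_CATEGORIES)
  if (length(bad_cat)) {
    gi_error(sprintf("%s: unknown category %s at line %d", path,
                     dQuote(df$category[bad_cat[1]]), bad_cat[1] + 1L),
             "validation_error")
  }
  df$taxon <- normalize_taxon_name(df$taxon)
  key <- paste(df$level, df$taxon)
  conflicts <- tapply(df$category, key, function(x) length(unique(x)) > 1L)
  if (any(conflicts)) {
    gi_error(sprintf("%s: conflicting categories for %s", path,
                     paste(names(conflicts)[conflicts], collapse = ", ")),
             "conflict_error")
  }
  df <- df[!duplicated(key), , drop = FALSE]
  g <- df[df$level == "genus", , drop = FALSE]
  s <- df[df$level == "species", , drop = FALSE]
  aerotolerance_table(
    genus_map = stats::setNames(g$category, g$taxon),
    species_overrides = stats::setNames(s$category, s$taxon),
    provenance = path
  )
}

#' Path to the bundled starter aerotolerance table
#' @export
default_aerotolerance_path <- function() {
  system.file("extdata", "aerotolerance_gut_panel.tsv",
              package = "gutindices", mustWork = TRUE)
}

#' Classify a taxon's aerotolerance
#'
#' Species-level overrides are consulted first when the lineage carries a
#' binomial; otherwise the genus map decides; taxa matching neither are
#' \code{"unclassified"} (a value, not an error). Matching is exact after
#' case normalization and underscore/space unification; no synonym
#' resolution is attempted.
#'
#' @param lineage A \code{taxon_lineage} (see \code{\link{parse_lineage}}).
#' @param table An \code{aerotolerance_table}.
#' @return One of \code{"aerotolerant"}, \code{"strict_anaerobe"},
#'   \code{"unclassified"}.
#' @export
classify <- function(lineage, table) {
  stopifnot(inherits(lineage, "taxon_lineage"),
            inherits(table, "aerotolerance_table"))
  classify_taxa(data.frame(genus = lineage$genus, species = lineage$species,
                           stringsAsFactors = FALSE), table)
}

# Vectorized classification over a taxa frame (genus, species columns).
classify_taxa <- function(taxa, table) {
  lower <- function(x) ifelse(is.na(x), NA_character_, tolower(x))
  sp_cat <- table$species_overrides[match(lower(taxa$species),
                                          tolower(names(table$species_overrides)))]
  g_cat <- table$genus_map[match(lower(taxa$genus),
                                 tolower(names(table$genus_map)))]
  out <- ifelse(!is.na(sp_cat), sp_cat, g_cat)
  out[is.na(out)] <- "unclassified"
  unname(out)
}
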