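#' @keywords internal
RANK_CODES <- c("k", "p", "c", "o", "f", "g", "s")

# prefixes accepted in lineage strings; superkingdom/domain fold into "k"
RANK_PREFIX_MAP <- c(
  sk = "k", k = "k", d = "k",
  p = "p", c = "c", o = "o", f = "f", g = "g", s = "s"
)

gi_error <- function(message, class) {
  stop(structure(
    class = c(class, "gutindices_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

normalize_taxon_name <- function(x) {
  x <- gsub("_", " ", trimws(x))
  x <- gsub("\\s+", " ", x)
  x
}

#' Parse a taxonomic lineage string
#'
#' Splits a Greengenes-style lineage string (e.g.
#' \code{"k__Bacteria|g__Faecalibacterium|s__prausnitzii"}) into an ordered
#' rank ladder and extracts the canonical genus and binomial species names.
#' Both \code{";"} and \code{"|"} are accepted as separators in every
#' dialect, since harmonization pipelines routinely convert between the two.
#' A leading \code{"Root"} element is discarded, superkingdom/domain prefixes
#' (\code{sk__}, \code{d__}) are folded into the kingdom rank, and a species
#' field holding a bare epithet is joined with the genus into a binomial.
#'
#' @param lineage_string A single lineage string.
#' @param dialect One of \code{"mgnify"}, \code{"microbiomehd"},
#'   \code{"plain"}. The dialects share one grammar; the argument is kept so
#'   callers state the provenance of their tables and future dialect-specific
#'   quirks have a home.
#' @return An object of class \code{taxon_lineage}: a list with
#'   \code{ranks} (data frame of \code{rank}, \code{name} from highest to
#'   lowest assigned rank), \code{genus} (character or \code{NA}) and
#'   \code{species} (full binomial or \code{NA}).
#' @examples
#' parse_lineage("Root;k__Bacteria;p__Proteobacteria;g__Escherichia", "mgnify")
#' parse_lineage(
#'   "k__Bacteria|f__Ruminococcaceae|g__Faecalibacterium|s__prausnitzii",
#'   "microbiomehd"
#' )
#' @export
parse_lineage <- function(lineage_string,
                          dialect = c("plain", "mgnify", "microbiomehd")) {
  dialect <- match.arg(dialect)
  if (length(lineage_string) != 1L || is.na(lineage_string)) {
    gi_error("lineage_string must be a single non-NA string",
             "malformed_lineage")
  }
  s <- trimws(lineage_string)
  if (!nzchar(s)) {
    gi_error("malformed lineage: empty string", "malformed_lineage")
  }
  parts <- strsplit(s, "[;|]")[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  # leading Root element (MGnify exports) carries no rank information
  if (length(parts) > 0L && tolower(parts[[1]]) == "root") {
    parts <- parts[-1L]
  }
  m <- regmatches(parts, regexec("^([A-Za-z]+)__(.*)$", parts))
  codes <- vapply(m, function(x) if (length(x) == 3L) x[[2]] else NA_character_,
                  character(1))
  names_ <- vapply(m, function(x) if (length(x) == 3L) x[[3]] else NA_character_,
                   character(1))
  keep <- !is.na(codes) & tolower(codes) %in% names(RANK_PREFIX_MAP)
  if (!any(keep)) {
    gi_error(sprintf("malformed lineage: no parseable rank in %s",
                     dQuote(lineage_string)), "malformed_lineage")
  }
  codes <- unname(RANK_PREFIX_MAP[tolower(codes[keep])])
  names_ <- normalize_taxon_name(names_[keep])
  # drop unassigned ranks ("g__")
  assigned <- nzchar(names_)
  codes <- codes[assigned]
  names_ <- names_[assigned]
  idx <- match(codes, RANK_CODES)
  if (is.unsorted(idx, strictly = TRUE)) {
    gi_error(sprintf("malformed lineage: rank order does not descend in %s",
                     dQuote(lineage_string)), "malformed_lineage")
  }
  genus <- if ("g" %in% codes) names_[match("g", codes)] else NA_character_
  species <- NA_character_
  if ("s" %in% codes) {
    sp <- names_[match("s", codes)]
    if (grepl(" ", sp)) {
      species <- sp
    } else if (!is.na(genus)) {
      species <- paste(genus, sp)
    }
    # bare epithet with no genus cannot form a binomial; species stays NA
  }
  if (!is.na(species) && is.na(genus)) {
    genus <- strsplit(species, " ")[[1]][1]
  }
  structure(
    list(
      ranks = data.frame(rank = codes, name = names_,
                         stringsAsFactors = FALSE),
      genus = genus,
      species = species
    ),
    class = "taxon_lineage"
  )
}

#' @export
print.taxon_lineage <- function(x, ...) {
  cat("<taxon_lineage> ",
      paste0(x$ranks$rank, "__", x$ranks$name, collapse = "|"), "\n", sep = "")
  invisible(x)
}

#' @export
format.taxon_lineage <- function(x, ...) {
  paste0(x$ranks$rank, "__", gsub(" ", "_", x$ranks$name), collapse = "|")
}

# Vectorized lineage parse used by the table readers: returns a data frame
# with the canonical key plus genus/species columns, one row per input.
parse_lineage_frame <- function(strings, dialect) {
  lins <- lapply(strings, parse_lineage, dialect = dialect)
  data.frame(
    lineage = vapply(lins, format, character(1)),
    genus = vapply(lins, `[[`, character(1), "genus"),
    species = vapply(lins, `[[`, character(1), "species"),
    stringsAsFactors = FALSE
  )
}
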