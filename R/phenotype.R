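#' Condition lexicon for phenotype binning
#'
#' Subjects are binned from self-reported condition lists into three
#' phenotypes. Mild conditions are bloating, constipation, gassiness and
#' IBS; diseased conditions are celiac disease, Crohn's disease,
#' gastroesophageal reflux disease, inflammatory bowel disease and
#' ulcerative colitis. A synonym map absorbs common survey spellings
#' (e.g. "GERD", "IBD"). Mild and diseased term sets must be disjoint.
#'
#' @param mild_terms Character vector of mild condition names.
#' @param diseased_terms Character vector of diseased condition names.
#' @param synonyms Named character vector mapping alias -> canonical term.
#' @return A \code{condition_lexicon}.
#' @export
condition_lexicon <- function(mild_terms = NULL, diseased_terms = NULL,
                              synonyms = NULL) {
  if (is.null(mild_terms)) {
    mild_terms <- c("bloating", "constipation", "gassiness", "ibs")
  }
  if (is.null(diseased_terms)) {
    diseased_terms <- c("celiac disease", "crohn's disease",
                        "gastroesophageal reflux disease",
                        "inflammatory bowel disease", "ulcerative colitis")
  }
  if (is.null(synonyms)) {
    synonyms <- c(
      "irritable bowel syndrome" = "ibs",
      "gerd" = "gastroesophageal reflux disease",
      "acid reflux" = "gastroesophageal reflux disease",
      "ibd" = "inflammatory bowel disease",
      "crohns disease" = "crohn's disease",
      "crohn disease" = "crohn's disease",
      "celiac" = "celiac disease",
      "coeliac disease" = "celiac disease",
      "gas" = "gassiness",
      "bloated" = "bloating"
    )
  }
  mild_terms <- tolower(trimws(mild_terms))
  diseased_terms <- tolower(trimws(diseased_terms))
  names(synonyms) <- tolower(trimws(names(synonyms)))
  synonyms <- tolower(trimws(synonyms))
  overlap <- intersect(mild_terms, diseased_terms)
  if (length(overlap)) {
    gi_error(sprintf("terms in both mild and diseased sets: %s",
                     paste(overlap, collapse = ", ")), "validation_error")
  }
  structure(list(mild_terms = mild_terms, diseased_terms = diseased_terms,
                 synonyms = synonyms),
            class = "condition_lexicon")
}

#' Load a condition lexicon TSV
#'
#' Columns: \code{term}, \code{class} (\code{mild}, \code{diseased} or
#' \code{synonym}) and \code{canonical} (the target term, synonym rows
#' only).
#'
#' @param path TSV path.
#' @return A \code{condition_lexicon}.
#' @export
read_condition_lexicon <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("term", "class")
  if (!all(need %in% names(df))) {
    gi_error(sprintf("%s: lexicon needs columns term, class", path),
             "validation_error")
  }
  bad <- which(!df$class %in% c("mild", "diseased", "synonym"))
  if (length(bad)) {
    gi_error(sprintf("%s: unknown class %s at line %d", path,
                     dQuote(df$class[bad[1]]), bad[1] + 1L),
             "validation_error")
  }
  syn <- df[df$class == "synonym", , drop = FALSE]
  condition_lexicon(
    mild_terms = df$term[df$class == "mild"],
    diseased_terms = df$term[df$class == "diseased"],
    synonyms = if (nrow(syn)) stats::setNames(syn$canonical, syn$term)
               else character()
  )
}

normalize_condition <- function(x, lexicon) {
  x <- tolower(trimws(x))
  hit <- match(x, names(lexicon$synonyms))
  x[!is.na(hit)] <- lexicon$synonyms[hit[!is.na(hit)]]
  x
}

#' Assign a phenotype from a condition list
#'
#' Each reported condition is normalized (case-folded, trimmed,
#' synonym-mapped). Any diseased term makes the subject \code{diseased};
#' otherwise any mild term makes it \code{mild}; an empty list is
#' \code{healthy} (no health or gut issues reported); a non-empty list with
#' only unrecognized terms is \code{unknown} and excluded from phenotype
#' comparisons. Diseased-dominates precedence means adding a condition can
#' never lower the phenotype.
#'
#' @param conditions Character vector of reported conditions (may be empty).
#' @param lexicon A \code{condition_lexicon}.
#' @return One of \code{"healthy"}, \code{"mild"}, \code{"diseased"},
#'   \code{"unknown"}.
#' @examples
#' assign_phenotype(character(0))          # healthy
#' assign_phenotype("bloating")            # mild
#' assign_phenotype(c("Crohn's disease", "gassiness")) # diseased
#' @export
assign_phenotype <- function(conditions, lexicon = condition_lexicon()) {
  stopifnot(inherits(lexicon, "condition_lexicon"))
  conditions <- conditions[!is.na(conditions) & nzchar(trimws(conditions))]
  if (length(conditions) == 0L) return("healthy")
  norm <- normalize_condition(conditions, lexicon)
  if (any(norm %in% lexicon$diseased_terms)) return("diseased")
  if (any(norm %in% lexicon$mild_terms)) return("mild")
  "unknown"
}

#' Annotate a cohort with phenotypes
#'
#' Sets the metadata \code{phenotype} field for every sample from its
#' \code{conditions} cell (semicolon-joined). Re-annotation is idempotent.
#' Per-phenotype counts are reported via \code{message}.
#'
#' @param cohort A \code{cohort_table} with metadata.
#' @param lexicon A \code{condition_lexicon}.
#' @param quiet Suppress the count message.
#' @return The cohort with \code{metadata$phenotype} filled.
#' @export
annotate_cohort <- function(cohort, lexicon = condition_lexicon(),
                            quiet = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  conds <- cohort$metadata$conditions
  conds[is.na(conds)] <- ""
  phen <- vapply(conds, function(cell) {
    assign_phenotype(split_conditions(cell), lexicon)
  }, character(1), USE.NAMES = FALSE)
  cohort$metadata$phenotype <- phen
  if (!quiet) {
    tab <- table(factor(phen, levels = c("healthy", "mild", "diseased",
                                         "unknown")))
    message("phenotype counts: ",
            paste(names(tab), tab, sep = "=", collapse = " "))
  }
  cohort
}
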