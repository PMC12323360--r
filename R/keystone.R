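#' The default keystone species panel
#'
#' Six strictly anaerobic gut commensals posited to carry functions
#' essential for microbiome balance: \emph{Akkermansia muciniphila},
#' \emph{Bifidobacterium longum}, \emph{Christensenella minuta},
#' \emph{Faecalibacterium prausnitzii}, \emph{Methanobrevibacter smithii}
#' and \emph{Ruminococcus bromii}.
#'
#' @return Character vector of binomials.
#' @export
default_keystone_panel <- function() {
  c("Akkermansia muciniphila",
    "Bifidobacterium longum",
    "Christensenella minuta",
    "Faecalibacterium prausnitzii",
    "Methanobrevibacter smithii",
    "Ruminococcus bromii")
}

#' Read a keystone panel file (one binomial per line)
#'
#' @param path Text file with one species binomial per line; blank lines
#'   and lines starting with \code{#} are ignored.
#' @return Character vector of binomials.
#' @export
read_keystone_panel <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  validate_keystone_panel(lines)
}

validate_keystone_panel <- function(panel) {
  panel <- normalize_taxon_name(panel)
  if (length(panel) == 0L) {
    gi_error("keystone panel is empty", "validation_error")
  }
  if (anyDuplicated(tolower(panel))) {
    gi_error("keystone panel has duplicate binomials", "validation_error")
  }
  panel
}

#' Extract the keystone relative-proportion matrix
#'
#' Builds a samples-by-species matrix of relative proportions for the panel
#' binomials. Matching is on the parsed binomial after case and
#' underscore/space normalization; a species absent from a sample yields 0.
#' A panel binomial matching more than one distinct lineage in the cohort
#' is an ambiguity error naming the collision (duplicate OTU rows for one
#' lineage are already summed at read time).
#'
#' @param cohort A \code{cohort_table}.
#' @param panel Character vector of binomials
#'   (default \code{\link{default_keystone_panel}()}).
#' @return Numeric matrix, samples x species, entries in [0, 1].
#' @export
extract_keystone_matrix <- function(cohort, panel = default_keystone_panel()) {
  stopifnot(inherits(cohort, "cohort_table"))
  panel <- validate_keystone_panel(panel)
  totals <- colSums(cohort$abundance)
  if (any(totals <= 0)) {
    gi_error(sprintf("samples with zero total abundance: %s",
                     paste(colnames(cohort$abundance)[totals <= 0],
                           collapse = ", ")), "degenerate_sample")
  }
  rel <- sweep(cohort$abundance, 2L, totals, "/")
  sp <- tolower(cohort$taxa$species)
  out <- matrix(0, nrow = ncol(rel), ncol = length(panel),
                dimnames = list(colnames(rel), panel))
  for (j in seq_along(panel)) {
    hits <- which(!is.na(sp) & sp == tolower(panel[j]))
    if (length(hits) > 1L) {
      gi_error(sprintf("panel species %s matches %d distinct lineages: %s",
                       panel[j], length(hits),
                       paste(cohort$taxa$lineage[hits], collapse = "; ")),
               "ambiguity_error")
    }
    if (length(hits) == 1L) out[, j] <- rel[hits, ]
  }
  out
}

#' Cohort-referenced keystone Z-scores
#'
#' For each panel species, relative proportions are log10-transformed after
#' adding a pseudocount (so absences stay finite) and standardized across
#' the cohort: z = (L - mean(L)) / sd(L) with the sample (n-1) standard
#' deviation. Z-scores are referenced to the whole analyzed cohort, all
#' phenotypes pooled, so per-phenotype contrasts share one scale. A species
#' constant across the cohort (sd = 0) gets all-zero z-scores.
#'
#' @param matrix Samples x species relative-proportion matrix from
#'   \code{\link{extract_keystone_matrix}}.
#' @param pseudocount Positive floor added before log10. Default
#'   \code{1e-6} on the relative-abundance scale.
#' @return Samples x species z-score matrix.
#' @export
keystone_zscores <- function(matrix, pseudocount = 1e-6) {
  stopifnot(is.matrix(matrix))
  if (nrow(matrix) < 2L) {
    gi_error("keystone z-scores need at least 2 samples", "insufficient_cohort")
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    gi_error("pseudocount must be positive for log10 transform",
             "validation_error")
  }
  L <- log10(matrix + pseudocount)
  mu <- colMeans(L)
  sdv <- apply(L, 2L, stats::sd)
  z <- sweep(L, 2L, mu, "-")
  pos <- sdv > 0
  z[, pos] <- sweep(z[, pos, drop = FALSE], 2L, sdv[pos], "/")
  z[, !pos] <- 0
  z
}

#' Per-sample keystone score
#'
#' Sums each sample's z-scores across the panel species. Because every
#' z-column is centered on the cohort, the keystone scores sum to zero over
#' the cohort.
#'
#' @param zmatrix Samples x species z-score matrix.
#' @return Named numeric vector of per-sample keystone scores.
#' @export
keystone_score <- function(zmatrix) {
  stopifnot(is.matrix(zmatrix), all(is.finite(zmatrix)))
  rowSums(zmatrix)
}

#' Keystone scoring for a cohort in one call
#'
#' @inheritParams extract_keystone_matrix
#' @inheritParams keystone_zscores
#' @return Data frame: \code{sample_id}, \code{keystone}, plus one
#'   \code{z.<species>} column per panel member.
#' @export
keystone_batch <- function(cohort, panel = default_keystone_panel(),
                           pseudocount = 1e-6) {
  m <- extract_keystone_matrix(cohort, panel)
  z <- keystone_zscores(m, pseudocount)
  out <- data.frame(sample_id = rownames(z),
                    keystone = unname(keystone_score(z)),
                    stringsAsFactors = FALSE)
  zdf <- as.data.frame(z)
  names(zdf) <- paste0("z.", gsub(" ", "_", colnames(z)))
  cbind(out, zdf, row.names = NULL)
}
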