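#' Compute the metagenomic aerotolerant predominance index (MAPI)
#'
#' MAPI is the natural logarithm of the ratio of the summed abundance of
#' aerotolerant genera to the summed abundance of strict anaerobic genera
#' in one sample. A score greater than 0 indicates predominance of
#' aerotolerant organisms; negative scores indicate anaerobe predominance.
#' The score is scale-invariant: counts and relative proportions give the
#' same value. Taxa absent from the classification table contribute to
#' neither sum.
#'
#' When exactly one of the two sums is zero and \code{pseudocount > 0}, the
#' pseudocount is added to \emph{both} sums (keeping the balanced-sample
#' identity MAPI = 0 intact) and the result is flagged. With
#' \code{pseudocount = 0} a zero sum is an error, and a profile with no
#' classified mass at all is always an error.
#'
#' @param profile An \code{abundance_profile}.
#' @param table An \code{aerotolerance_table}.
#' @param pseudocount Non-negative value added to both sums only when one of
#'   them is zero. Default \code{1e-6}, on the relative-abundance scale.
#' @return A one-row data frame (class \code{mapi_result}): \code{sample_id},
#'   \code{mapi}, \code{aero_mass}, \code{anaero_mass},
#'   \code{unclassified_mass}, \code{pseudocount_used}.
#' @examples
#' tab <- aerotolerance_table(
#'   genus_map = c(Escherichia = "aerotolerant", Bacteroides = "strict_anaerobe")
#' )
#' p <- abundance_profile("s1", c("g__Escherichia" = 1, "g__Bacteroides" = 99))
#' compute_mapi(p, tab)$mapi # ln(1/99)
#' @export
compute_mapi <- function(profile, table, pseudocount = 1e-6) {
  stopifnot(inherits(profile, "abundance_profile"),
            inherits(table, "aerotolerance_table"))
  if (pseudocount < 0) {
    gi_error("pseudocount must be non-negative", "validation_error")
  }
  cat_ <- classify_taxa(profile$taxa, table)
  a <- sum(profile$abundance[cat_ == "aerotolerant"])
  s <- sum(profile$abundance[cat_ == "strict_anaerobe"])
  u <- sum(profile$abundance[cat_ == "unclassified"])
  if (a == 0 && s == 0) {
    gi_error(sprintf("profile %s has no classified mass", profile$sample_id),
             "no_classified_mass")
  }
  used <- FALSE
  a_eff <- a
  s_eff <- s
  if (a == 0 || s == 0) {
    if (pseudocount == 0) {
      gi_error(sprintf(
        "profile %s: MAPI undefined (%s mass is zero and pseudocount is 0)",
        profile$sample_id, if (a == 0) "aerotolerant" else "strict-anaerobe"),
        "undefined_score")
    }
    a_eff <- a + pseudocount
    s_eff <- s + pseudocount
    used <- TRUE
  }
  res <- data.frame(
    sample_id = profile$sample_id,
    mapi = log(a_eff / s_eff),
    aero_mass = a,
    anaero_mass = s,
    unclassified_mass = u,
    pseudocount_used = used,
    stringsAsFactors = FALSE
  )
  class(res) <- c("mapi_result", "data.frame")
  res
}

#' Compute MAPI for every sample in a cohort
#'
#' Order-preserving batch scoring. Per-sample failures (no classified mass,
#' undefined score) are recorded in the \code{error} column without
#' aborting the batch; failed samples carry \code{NA} scores.
#'
#' @param cohort A \code{cohort_table}.
#' @param table An \code{aerotolerance_table}.
#' @inheritParams compute_mapi
#' @return A score table data frame with one row per sample: \code{sample_id},
#'   \code{mapi}, \code{aero_mass}, \code{anaero_mass},
#'   \code{unclassified_mass}, \code{pseudocount_used}, \code{error}.
#' @export
mapi_batch <- function(cohort, table, pseudocount = 1e-6) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (ncol(cohort$abundance) == 0L) {
    gi_error("empty cohort", "empty_input")
  }
  if (pseudocount < 0) {
    gi_error("pseudocount must be non-negative", "validation_error")
  }
  cat_ <- classify_taxa(cohort$taxa, table)
  mass_by <- function(which) {
    idx <- cat_ == which
    if (!any(idx)) return(numeric(ncol(cohort$abundance)))
    colSums(cohort$abundance[idx, , drop = FALSE])
  }
  a <- mass_by("aerotolerant")
  s <- mass_by("strict_anaerobe")
  u <- mass_by("unclassified")
  n <- ncol(cohort$abundance)
  mapi <- rep(NA_real_, n)
  used <- rep(FALSE, n)
  err <- rep(NA_character_, n)
  both_zero <- a == 0 & s == 0
  err[both_zero] <- "no_classified_mass"
  one_zero <- !both_zero & (a == 0 | s == 0)
  ok <- !both_zero & !one_zero
  mapi[ok] <- log(a[ok] / s[ok])
  if (any(one_zero)) {
    if (pseudocount > 0) {
      mapi[one_zero] <- log((a[one_zero] + pseudocount) /
                            (s[one_zero] + pseudocount))
      used[one_zero] <- TRUE
    } else {
      err[one_zero] <- "undefined_score"
    }
  }
  data.frame(
    sample_id = colnames(cohort$abundance),
    mapi = mapi,
    aero_mass = a,
    anaero_mass = s,
    unclassified_mass = u,
    pseudocount_used = used,
    error = err,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
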