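#' Default taxon panel for the synthetic generator
#'
#' Genera split by aerotolerance, with the six keystone species nested
#' among the strict anaerobes (species-level taxa alongside their genus
#' rows). All panel taxa are covered by the bundled aerotolerance table, so
#' generated profiles carry no unclassified mass.
#'
#' @return List with \code{aerotolerant} and \code{strict_anaerobe} genus
#'   vectors and \code{keystone} binomials.
#' @export
default_taxon_panel <- function() {
  list(
    aerotolerant = c("Escherichia", "Klebsiella", "Streptococcus",
                     "Enterococcus", "Lactobacillus", "Staphylococcus"),
    strict_anaerobe = c("Bacteroides", "Prevotella", "Blautia", "Roseburia",
                        "Alistipes", "Parabacteroides", "Coprococcus",
                        "Eubacterium", "Akkermansia", "Christensenella",
                        "Faecalibacterium", "Methanobrevibacter",
                        "Ruminococcus"),
    keystone = default_keystone_panel()
  )
}

keystone_lineage <- function(binomial) {
  parts <- strsplit(binomial, " ")[[1]]
  kingdom <- if (parts[1] == "Methanobrevibacter") "Archaea" else "Bacteria"
  sprintf("k__%s|g__%s|s__%s", kingdom, parts[1], parts[2])
}

genus_lineage <- function(genus) {
  kingdom <- ifelse(genus == "Methanobrevibacter", "Archaea", "Bacteria")
  sprintf("k__%s|g__%s", kingdom, genus)
}

#' Simulation configuration
#'
#' Defines the statistical structure of generated cohorts. Defaults
#' calibrate the healthy MAPI distribution to mean -5.2 and SD 1.8
#' (natural-log units), with mild and diseased phenotypes shifted by +0.5
#' and +1.0 respectively — invented effect sizes chosen so omnibus tests at
#' cohort scale are significant while the distributions overlap heavily.
#' Ages 61 and over add +0.5 to the mean (MAPI increases with age). Default
#' demographic frequencies mirror the public healthy cohort whose
#' distribution anchors the calibration. Keystone species log10 relative
#' abundances are normal with per-species means in the -1.5 to -3 range
#' (SD 0.5), depressed by \code{keystone_disease_shift} in the diseased
#' phenotype (half of it in mild) for every species except
#' \emph{Methanobrevibacter smithii}, whose direction is anomalous.
#'
#' @param n Named counts per phenotype (healthy, mild, diseased).
#' @param mapi_mean Named per-phenotype MAPI means (natural-log units).
#' @param mapi_sd MAPI standard deviation (natural-log units).
#' @param age_effect Named additive mean shift per age bin.
#' @param age_freq Named sampling frequencies per age bin (normalized).
#' @param gender_freq Named frequencies for male/female/unknown.
#' @param keystone_log10_mean,keystone_log10_sd Named per-species log10
#'   relative-abundance parameters.
#' @param keystone_disease_shift Log10 units subtracted from keystone means
#'   in the diseased phenotype (half in mild; 0 for M. smithii).
#' @param taxon_panel See \code{\link{default_taxon_panel}}.
#' @param dirichlet_concentration Symmetric Dirichlet concentration for
#'   within-category mass allocation (> 0).
#' @param seed Integer RNG seed.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n = c(healthy = 200, mild = 200, diseased = 200),
                       mapi_mean = c(healthy = -5.2, mild = -4.7,
                                     diseased = -4.2),
                       mapi_sd = 1.8,
                       age_effect = NULL,
                       age_freq = NULL,
                       gender_freq = c(male = 1075, female = 441,
                                       unknown = 551),
                       keystone_log10_mean = NULL,
                       keystone_log10_sd = NULL,
                       keystone_disease_shift = 0.25,
                       taxon_panel = default_taxon_panel(),
                       dirichlet_concentration = 1,
                       seed = 1L) {
  bins <- c("0-10", "11-20", "21-30", "31-40", "41-50", "51-60",
            "61-70", "71-80", "81+")
  if (is.null(age_effect)) {
    age_effect <- stats::setNames(c(rep(0, 6), rep(0.5, 3)), bins)
  }
  if (is.null(age_freq)) {
    # public healthy cohort age strata (81+ absent there)
    age_freq <- stats::setNames(c(203, 425, 287, 558, 10, 51, 63, 16, 0),
                                bins)
  }
  if (is.null(keystone_log10_mean)) {
    keystone_log10_mean <- stats::setNames(
      c(-2.2, -2.0, -2.8, -1.5, -3.0, -2.0), default_keystone_panel())
  }
  if (is.null(keystone_log10_sd)) {
    keystone_log10_sd <- stats::setNames(rep(0.5, length(keystone_log10_mean)),
                                         names(keystone_log10_mean))
  }
  cfg <- list(
    n = n, mapi_mean = mapi_mean, mapi_sd = mapi_sd,
    age_effect = age_effect, age_freq = age_freq / sum(age_freq),
    gender_freq = gender_freq / sum(gender_freq),
    keystone_log10_mean = keystone_log10_mean,
    keystone_log10_sd = keystone_log10_sd,
    keystone_disease_shift = keystone_disease_shift,
    taxon_panel = taxon_panel,
    dirichlet_concentration = dirichlet_concentration,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (any(cfg$n < 0)) gi_error("n must be non-negative", "config_error")
  if (cfg$mapi_sd < 0) gi_error("mapi_sd must be non-negative", "config_error")
  if (cfg$dirichlet_concentration <= 0) {
    gi_error("dirichlet_concentration must be positive", "config_error")
  }
  p <- cfg$taxon_panel
  if (length(p$aerotolerant) < 1L || length(p$strict_anaerobe) < 1L) {
    gi_error("taxon panel needs at least one genus in each category",
             "config_error")
  }
  missing <- setdiff(names(cfg$keystone_log10_mean), p$keystone)
  if (length(p$keystone) &&
      !setequal(names(cfg$keystone_log10_mean), p$keystone)) {
    gi_error("keystone_log10_mean names must match the keystone panel",
             "config_error")
  }
  invisible(cfg)
}

#' Read a simulation config from YAML
#'
#' Scalar and named-vector fields of \code{\link{sim_config}} may be set in
#' a YAML file; unset fields keep their defaults. Because YAML 1.1 reads a
#' bare \code{n} key as a boolean, the per-phenotype counts go under
#' \code{n_per_phenotype} (a quoted \code{"n"} also works).
#'
#' @param path YAML file path.
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    gi_error("the yaml package is required to read YAML configs",
             "config_error")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$n_per_phenotype)) raw$n <- raw$n_per_phenotype
  args <- list()
  for (f in c("n", "mapi_mean", "age_effect", "age_freq", "gender_freq",
              "keystone_log10_mean", "keystone_log10_sd")) {
    if (!is.null(raw[[f]])) args[[f]] <- unlist(raw[[f]])
  }
  for (f in c("mapi_sd", "keystone_disease_shift", "dirichlet_concentration",
              "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$taxon_panel)) {
    args$taxon_panel <- lapply(raw$taxon_panel, unlist)
  }
  do.call(sim_config, args)
}

# Dirichlet draw as normalized gammas; columns are samples.
rdirichlet_cols <- function(k, n, concentration) {
  g <- matrix(stats::rgamma(k * n, shape = concentration), nrow = k)
  # guard against all-zero columns at tiny concentrations
  zero <- colSums(g) == 0
  if (any(zero)) g[, zero] <- 1
  sweep(g, 2L, colSums(g), "/")
}

# Core profile builder: abundance matrix (taxa x samples) whose computed
# MAPI equals m exactly. The aerotolerant mass fraction is the logistic
# 1/(1 + exp(-m)); keystone species, when given, take their drawn masses
# out of the anaerobe side so the aerotolerant/anaerobe ratio is untouched.
build_abundance_matrix <- function(m, panel, concentration,
                                   keystone_mass = NULL) {
  n <- length(m)
  f <- stats::plogis(m) # aerotolerant fraction of classified mass
  aero <- rdirichlet_cols(length(panel$aerotolerant), n, concentration)
  aero <- sweep(aero, 2L, f, "*")
  anaero_total <- 1 - f
  rows <- c(genus_lineage(panel$aerotolerant),
            genus_lineage(panel$strict_anaerobe))
  if (is.null(keystone_mass) || length(panel$keystone) == 0L) {
    anaero <- rdirichlet_cols(length(panel$strict_anaerobe), n, concentration)
    anaero <- sweep(anaero, 2L, anaero_total, "*")
    mat <- rbind(aero, anaero)
  } else {
    # cap keystone mass below the anaerobe budget, then give remaining
    # anaerobe genera the rest; the anaerobe total (and hence MAPI) is exact
    k_tot <- colSums(keystone_mass)
    cap <- 0.8 * anaero_total
    over <- k_tot > cap
    if (any(over)) {
      keystone_mass[, over] <- sweep(keystone_mass[, over, drop = FALSE],
                                     2L, cap[over] / k_tot[over], "*")
      k_tot[over] <- cap[over]
    }
    anaero <- rdirichlet_cols(length(panel$strict_anaerobe), n, concentration)
    anaero <- sweep(anaero, 2L, anaero_total - k_tot, "*")
    mat <- rbind(aero, anaero, keystone_mass)
    rows <- c(rows, vapply(panel$keystone, keystone_lineage, character(1)))
  }
  rownames(mat) <- rows
  mat
}

#' Build a profile with an exact target MAPI
#'
#' Inverts the MAPI formula: the aerotolerant categories receive a
#' logistic fraction 1/(1 + exp(-m)) of the (unit) classified mass and the
#' strict anaerobes the rest, with within-category masses drawn from a
#' symmetric Dirichlet. The returned profile's computed MAPI equals
#' \code{m} up to floating-point error (well within 1e-9).
#'
#' @param m Target MAPI score (natural-log units).
#' @param panel Taxon panel (see \code{\link{default_taxon_panel}}).
#' @param concentration Symmetric Dirichlet concentration.
#' @param sample_id Sample identifier for the profile.
#' @return An \code{abundance_profile} on the relative-abundance scale.
#' @export
profile_from_target_mapi <- function(m, panel = default_taxon_panel(),
                                     concentration = 1,
                                     sample_id = "sim") {
  stopifnot(length(m) == 1L, is.finite(m))
  if (length(panel$aerotolerant) < 1L || length(panel$strict_anaerobe) < 1L) {
    gi_error("taxon panel needs at least one genus in each category",
             "config_error")
  }
  if (concentration <= 0) {
    gi_error("concentration must be positive", "config_error")
  }
  mat <- build_abundance_matrix(m, panel, concentration)
  abundance_profile(sample_id, stats::setNames(mat[, 1L], rownames(mat)))
}

mild_condition_pool <- function() c("bloating", "constipation", "gassiness",
                                    "IBS")
diseased_condition_pool <- function() {
  c("Celiac disease", "Crohn's disease", "gastroesophageal reflux disease",
    "inflammatory bowel disease", "ulcerative colitis")
}

draw_conditions <- function(phenotype, n) {
  vapply(seq_len(n), function(i) {
    switch(phenotype,
      healthy = "",
      mild = paste(sample(mild_condition_pool(),
                          size = sample.int(2L, 1L)), collapse = ";"),
      diseased = {
        terms <- sample(diseased_condition_pool(), 1L)
        if (stats::runif(1) < 0.3) {
          terms <- c(terms, sample(mild_condition_pool(), 1L))
        }
        paste(terms, collapse = ";")
      }
    )
  }, character(1))
}

draw_age_in_bin <- function(bin) {
  lo <- c("0-10" = 0, "11-20" = 11, "21-30" = 21, "31-40" = 31,
          "41-50" = 41, "51-60" = 51, "61-70" = 61, "71-80" = 71,
          "81+" = 81)[bin]
  hi <- c("0-10" = 10, "11-20" = 20, "21-30" = 30, "31-40" = 40,
          "41-50" = 50, "51-60" = 60, "61-70" = 70, "71-80" = 80,
          "81+" = 95)[bin]
  lo + floor(stats::runif(length(bin)) * (hi - lo + 1))
}

#' Generate a synthetic cohort
#'
#' Per sample: an age bin and gender are drawn from the configured
#' frequencies; a target MAPI is drawn from
#' Normal(mapi_mean[phenotype] + age_effect[age bin], mapi_sd); a profile
#' with exactly that MAPI is built by \code{\link{profile_from_target_mapi}}'s
#' construction; keystone-species abundances are set from log-normal
#' (base-10) draws with phenotype-shifted means, taken out of the
#' strict-anaerobe mass budget so the target MAPI is preserved; and a
#' condition list consistent with the phenotype is attached. Fully
#' reproducible from the config seed (the caller's RNG state is restored on
#' exit).
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{cohort_table} with metadata (age, age_bin, gender,
#'   conditions, phenotype) and relative-abundance profiles.
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  if (sum(config$n) == 0L) gi_error("config generates no samples",
                                    "config_error")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  phenos <- c("healthy", "mild", "diseased")
  blocks <- list()
  meta <- list()
  counter <- 0L
  for (ph in phenos) {
    n <- config$n[[ph]]
    if (is.na(n) || n == 0L) next
    bins <- sample(names(config$age_freq), n, replace = TRUE,
                   prob = config$age_freq)
    ages <- draw_age_in_bin(bins)
    gender <- sample(names(config$gender_freq), n, replace = TRUE,
                     prob = config$gender_freq)
    m <- stats::rnorm(n, config$mapi_mean[[ph]] + config$age_effect[bins],
                      config$mapi_sd)
    shift <- switch(ph, healthy = 0, mild = config$keystone_disease_shift / 2,
                    diseased = config$keystone_disease_shift)
    spp <- config$taxon_panel$keystone
    shifts <- ifelse(spp == "Methanobrevibacter smithii", 0, shift)
    kmass <- matrix(
      10 ^ stats::rnorm(length(spp) * n,
                        mean = config$keystone_log10_mean[spp] - shifts,
                        sd = config$keystone_log10_sd[spp]),
      nrow = length(spp)
    )
    mat <- build_abundance_matrix(m, config$taxon_panel,
                                  config$dirichlet_concentration,
                                  keystone_mass = kmass)
    ids <- sprintf("S%05d", counter + seq_len(n))
    counter <- counter + n
    colnames(mat) <- ids
    blocks[[ph]] <- mat
    meta[[ph]] <- data.frame(
      sample_id = ids,
      age = ages,
      age_bin = bins,
      gender = gender,
      conditions = draw_conditions(ph, n),
      phenotype = ph,
      target_mapi = m,
      stringsAsFactors = FALSE
    )
  }
  mat <- do.call(cbind, blocks)
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  taxa <- parse_lineage_frame(rownames(mat), "plain")
  new_cohort_table(mat, taxa, metadata)
}
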