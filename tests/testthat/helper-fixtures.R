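# Shared fixtures: small tables and profiles built in code.

tiny_aerotab <- function() {
  aerotolerance_table(
    genus_map = c(
      Escherichia = "aerotolerant",
      Streptococcus = "aerotolerant",
      Bacteroides = "strict_anaerobe",
      Faecalibacterium = "strict_anaerobe"
    ),
    species_overrides = c(
      "Bifidobacterium longum" = "strict_anaerobe",
      "Bifidobacterium animalis" = "aerotolerant"
    ),
    provenance = "test fixture"
  )
}

# Write a plain-dialect TSV and return its path.
write_plain_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

two_sample_table_lines <- function() {
  c("taxon\ts1\ts2",
    "k__Bacteria|g__Escherichia\t10\t0",
    "k__Bacteria|g__Bacteroides\t5\t5",
    "k__Bacteria|g__Faecalibacterium\t0\t10")
}

# Brute-force two-sided rank-sum p-value by bitmask enumeration of all
# labelings; independent of the package's combination-based enumeration.
brute_force_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  n1 <- length(x)
  r <- rank(pooled)
  mu <- n1 * (n - n1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  count <- 0L
  total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) != n1) next
    total <- total + 1L
    u <- sum(r[bits == 1L]) - n1 * (n1 + 1) / 2
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-12) count <- count + 1L
  }
  count / total
}

# Cohort of named abundance vectors (plain-dialect lineages).
make_cohort <- function(profiles_list, metadata = NULL) {
  profiles <- lapply(names(profiles_list), function(id) {
    abundance_profile(id, profiles_list[[id]])
  })
  cohort_table(profiles, metadata)
}
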