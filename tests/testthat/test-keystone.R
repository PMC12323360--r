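ks_cohort <- function() {
  make_cohort(list(
    s1 = c("k__Bacteria|g__Faecalibacterium|s__prausnitzii" = 0.12,
           "k__Bacteria|g__Bacteroides" = 0.88),
    s2 = c("k__Bacteria|g__Faecalibacterium|s__prausnitzii" = 30,
           "k__Bacteria|g__Bacteroides" = 70),
    s3 = c("k__Bacteria|g__Akkermansia|s__muciniphila" = 1,
           "k__Bacteria|g__Bacteroides" = 3)
  ))
}

test_that("the default panel holds the six keystone binomials", {
  expect_equal(default_keystone_panel(),
               c("Akkermansia muciniphila", "Bifidobacterium longum",
                 "Christensenella minuta", "Faecalibacterium prausnitzii",
                 "Methanobrevibacter smithii", "Ruminococcus bromii"))
})

test_that("keystone matrix extraction uses relative proportions and zeros for absences", {
  m <- extract_keystone_matrix(ks_cohort())
  expect_equal(dim(m), c(3L, 6L))
  expect_equal(m["s1", "Faecalibacterium prausnitzii"], 0.12)
  # counts convert to proportions
  expect_equal(m["s2", "Faecalibacterium prausnitzii"], 0.3)
  expect_equal(m["s3", "Akkermansia muciniphila"], 0.25)
  # species absent from a sample
  expect_equal(m["s1", "Christensenella minuta"], 0)
})

test_that("a panel binomial matching two distinct lineages is an ambiguity error", {
  ct <- make_cohort(list(
    s1 = c("k__Bacteria|g__Faecalibacterium|s__prausnitzii" = 1,
           "k__Bacteria|p__Firmicutes|g__Faecalibacterium|s__prausnitzii" = 1,
           "k__Bacteria|g__Bacteroides" = 2),
    s2 = c("k__Bacteria|g__Bacteroides" = 1)
  ))
  expect_error(extract_keystone_matrix(ct), class = "ambiguity_error")
})

test_that("z-scores standardize each species across the cohort", {
  # L values approx (-1, -2, -3): mean -2, sample SD 1 -> z (1, 0, -1)
  m <- matrix(c(0.1, 0.01, 0.001), ncol = 1,
              dimnames = list(c("a", "b", "c"), "Faecalibacterium prausnitzii"))
  z <- keystone_zscores(m, pseudocount = 1e-12)
  expect_equal(unname(z[, 1]), c(1, 0, -1), tolerance = 1e-6)

  # constant species: degenerate SD policy gives all-zero z
  m2 <- cbind(m, "Ruminococcus bromii" = 0.05)
  z2 <- keystone_zscores(m2, pseudocount = 1e-12)
  expect_equal(unname(z2[, 2]), c(0, 0, 0))

  expect_error(keystone_zscores(m[1, , drop = FALSE]),
               class = "insufficient_cohort")
  expect_error(keystone_zscores(m, pseudocount = 0),
               class = "validation_error")
})

test_that("z-columns center to 0 and keystone scores sum to 0 over the cohort", {
  set.seed(21)
  m <- matrix(runif(40 * 6, 0, 0.3), nrow = 40,
              dimnames = list(sprintf("s%02d", 1:40),
                              default_keystone_panel()))
  z <- keystone_zscores(m)
  expect_equal(unname(colMeans(z)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 6), tolerance = 1e-9)
  k <- keystone_score(z)
  expect_equal(sum(k), 0, tolerance = 1e-6)
  expect_equal(unname(k[3]), sum(z[3, ]))
})

test_that("per-sample scaling of abundances leaves keystone scores unchanged", {
  ct <- ks_cohort()
  scaled <- ct
  scaled$abundance <- sweep(scaled$abundance, 2, c(7, 0.01, 300), "*")
  k1 <- keystone_batch(ct)
  k2 <- keystone_batch(scaled)
  expect_equal(k2$keystone, k1$keystone, tolerance = 1e-12)
})

test_that("adding a constant in log10 space leaves a z-column unchanged", {
  set.seed(5)
  m <- matrix(10^runif(30, -4, -1), nrow = 10,
              dimnames = list(sprintf("s%d", 1:10),
                              c("Faecalibacterium prausnitzii",
                                "Ruminococcus bromii",
                                "Akkermansia muciniphila")))
  z1 <- keystone_zscores(m, pseudocount = 1e-15)
  m2 <- m
  m2[, 1] <- m2[, 1] * 10 # +1 in log10 space
  z2 <- keystone_zscores(m2, pseudocount = 1e-15)
  expect_equal(z2[, 1], z1[, 1], tolerance = 1e-9)
})

test_that("panel files read and override the default", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# custom panel", "Faecalibacterium prausnitzii",
               "Blautia_obeum", ""), path)
  panel <- read_keystone_panel(path)
  expect_equal(panel, c("Faecalibacterium prausnitzii", "Blautia obeum"))
  dup <- tempfile(fileext = ".txt")
  writeLines(c("A b", "a_B"), dup)
  expect_error(read_keystone_panel(dup), class = "validation_error")
})
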