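test_that("lineage parsing strips prefixes, drops Root, joins epithets", {
  l <- parse_lineage("Root;k__Bacteria;p__Proteobacteria;g__Escherichia",
                     "mgnify")
  expect_equal(l$genus, "Escherichia")
  expect_true(is.na(l$species))
  expect_equal(l$ranks$rank, c("k", "p", "g"))

  l2 <- parse_lineage(
    "k__Bacteria|p__Firmicutes|f__Ruminococcaceae|g__Faecalibacterium|s__prausnitzii",
    "microbiomehd")
  expect_equal(l2$genus, "Faecalibacterium")
  expect_equal(l2$species, "Faecalibacterium prausnitzii")

  # superkingdom prefix folds into k; underscores normalize to spaces
  l3 <- parse_lineage("sk__Bacteria|g__Faecalibacterium|s__Faecalibacterium_prausnitzii")
  expect_equal(l3$ranks$rank[1], "k")
  expect_equal(l3$species, "Faecalibacterium prausnitzii")
})

test_that("malformed lineages are rejected by name", {
  expect_error(parse_lineage(""), class = "malformed_lineage")
  expect_error(parse_lineage("   "), class = "malformed_lineage")
  expect_error(parse_lineage("no rank prefixes here"),
               class = "malformed_lineage")
  expect_error(parse_lineage("g__Escherichia|k__Bacteria"),
               class = "malformed_lineage")
})

test_that("unassigned ranks yield absent genus/species", {
  l <- parse_lineage("k__Bacteria|f__Lachnospiraceae|g__")
  expect_true(is.na(l$genus))
  expect_true(is.na(l$species))
})

test_that("semicolon and pipe separators parse identically", {
  cases <- c(
    "k__Bacteria|p__Firmicutes|g__Roseburia",
    "k__Bacteria|g__Bifidobacterium|s__longum",
    "k__Archaea|g__Methanobrevibacter|s__smithii"
  )
  for (x in cases) {
    a <- parse_lineage(x, "microbiomehd")
    b <- parse_lineage(gsub("|", ";", x, fixed = TRUE), "mgnify")
    expect_equal(a, b)
  }
})

test_that("MGnify fixes apply the four edits in order and idempotently", {
  raw <- c(
    "SampleID\tA\tB",
    "sk__Bacteria;p__Bacteroidetes;g__Prevotella\t3\t4",
    "Root;k__Bacteria;g__Prevotella\t1\t2",
    "k__Bacteria|g__Escherichia\t5\t6"
  )
  fixed <- apply_mgnify_fixes(raw)
  expect_equal(fixed[1], "OTU ID\tA\tB")
  expect_equal(fixed[2], "k__Bacteria|p__Bacteroidetes|g__Prevotella\t3\t4")
  expect_equal(fixed[3], "k__Bacteria|g__Prevotella\t1\t2")
  # line already free of Root and ";" is unchanged
  expect_equal(fixed[4], raw[4])
  expect_equal(apply_mgnify_fixes(fixed), fixed)
  expect_error(apply_mgnify_fixes(character(0)), class = "format_error")
})

test_that("abundance tables read with correct totals in both orientations", {
  path <- write_plain_tsv(two_sample_table_lines())
  ct <- read_abundance_table(path, "plain")
  expect_equal(dim(ct), c(3L, 2L))
  expect_equal(unname(colSums(ct$abundance)), c(15, 15))

  # transposed table with samples as rows gives the identical cohort
  tlines <- c("taxon\tk__Bacteria|g__Escherichia\tk__Bacteria|g__Bacteroides\tk__Bacteria|g__Faecalibacterium",
              "s1\t10\t5\t0",
              "s2\t0\t5\t10")
  path2 <- write_plain_tsv(tlines)
  ct2 <- read_abundance_table(path2, "plain", orientation = "samples_rows")
  expect_equal(ct2$abundance, ct$abundance)
  ct3 <- read_abundance_table(path2, "plain", orientation = "auto")
  expect_equal(ct3$abundance, ct$abundance)
})

test_that("duplicate taxon rows are summed", {
  lines <- c("taxon\ts1\ts2",
             "k__Bacteria|g__Bacteroides\t20\t1",
             "k__Bacteria|g__Escherichia\t2\t3",
             "k__Bacteria|g__Bacteroides\t5\t7")
  path <- write_plain_tsv(lines)
  ct <- read_abundance_table(path, "plain")
  # oracle: aggregate the raw rows by lineage key
  raw <- data.frame(key = c("b", "e", "b"), s1 = c(20, 2, 5),
                    s2 = c(1, 3, 7))
  expected_s1 <- tapply(raw$s1, raw$key, sum)
  expect_equal(nrow(ct$abundance), 2L)
  expect_equal(ct$abundance["k__Bacteria|g__Bacteroides", "s1"],
               unname(expected_s1["b"]))
  expect_equal(ct$abundance["k__Bacteria|g__Bacteroides", "s2"], 8)
})

test_that("bad numeric cells are rejected with location", {
  neg <- write_plain_tsv(c("taxon\ts1", "k__Bacteria|g__Escherichia\t-3"))
  expect_error(read_abundance_table(neg, "plain"),
               class = "validation_error")
  ragged <- write_plain_tsv(c("taxon\ts1\ts2", "k__Bacteria|g__Escherichia\t3"))
  expect_error(read_abundance_table(ragged, "plain"), class = "format_error")
  chr <- write_plain_tsv(c("taxon\ts1", "k__Bacteria|g__Escherichia\tabc"))
  expect_error(read_abundance_table(chr, "plain"), class = "format_error")
})

test_that("to_relative normalizes, preserves zeros, and is idempotent", {
  p <- abundance_profile("s", c("g__Escherichia" = 10, "g__Bacteroides" = 30))
  r <- to_relative(p)
  expect_equal(unname(r$abundance), c(0.25, 0.75))
  expect_equal(sum(r$abundance), 1, tolerance = 1e-9)
  r2 <- to_relative(r)
  expect_equal(r2$abundance, r$abundance, tolerance = 1e-12)

  p3 <- to_relative(abundance_profile(
    "s", c("g__Escherichia" = 1, "g__Bacteroides" = 0, "g__Prevotella" = 3)))
  expect_equal(unname(p3$abundance), c(0.25, 0, 0.75))
  expect_error(abundance_profile("z", c("g__Escherichia" = 0)),
               class = "degenerate_sample")
})

test_that("plain-dialect write/read round-trips abundances exactly", {
  set.seed(11)
  vals <- list(
    a = c("k__Bacteria|g__Escherichia" = 0.123456789012345,
          "k__Bacteria|g__Bacteroides" = 3.25),
    b = c("k__Bacteria|g__Escherichia" = 7,
          "k__Bacteria|g__Bacteroides" = 1e-6)
  )
  ct <- make_cohort(vals)
  path <- tempfile(fileext = ".tsv")
  write_abundance_table(ct, path)
  back <- read_abundance_table(path, "plain")
  expect_equal(back$abundance[rownames(ct$abundance), colnames(ct$abundance)],
               ct$abundance)
})

test_that("metadata and profiles must match one to one", {
  vals <- list(a = c("k__Bacteria|g__Escherichia" = 1),
               b = c("k__Bacteria|g__Bacteroides" = 2))
  md_bad <- data.frame(sample_id = c("a", "zzz"), age = c(30, 40))
  expect_error(make_cohort(vals, md_bad), class = "validation_error")
  md <- data.frame(sample_id = c("b", "a"), age = c(40, 30))
  ct <- make_cohort(vals, md)
  # metadata reordered to profile order, not dropped
  expect_equal(ct$metadata$sample_id, c("a", "b"))
  expect_equal(ct$metadata$age, c(30, 40))
})
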