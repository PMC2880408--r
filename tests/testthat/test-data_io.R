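# Readers, writers and validation of the tabular input types.

write_lines <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("target catalog score filtering is strictly below the cutoff", {
  path <- write_lines(c("miR-a\tG1\t-12.0",
                        "miR-a\tG2\t-9.0",
                        "miR-a\tG3\t-10.0",
                        "miR-b\tG4\t-5.0"))
  suppressMessages({
    cat_ <- read_target_catalog(path, score_cutoff = -10.0)
  })
  expect_equal(cat_$targets[["mir-a"]], "G1")     # -12 retained, -9 / -10 not
  expect_false("mir-b" %in% names(cat_$targets))  # emptied by the filter
  expect_true("mir-b" %in% cat_$dropped)
  expect_equal(cat_$universe, "G1")

  suppressMessages({
    lax <- read_target_catalog(path, score_cutoff = -10.0, strict = FALSE)
  })
  expect_setequal(lax$targets[["mir-a"]], c("G1", "G3"))
})

test_that("catalog aggregation and degenerate cutoffs behave", {
  path <- write_lines(c("miR-a\tG1\t-1", "miR-a\tG2\t-2", "miR-b\tG2\t-3",
                        "# comment", ""))
  suppressMessages(cat_ <- read_target_catalog(path))
  expect_setequal(cat_$targets[["mir-a"]], c("G1", "G2"))
  expect_equal(cat_$targets[["mir-b"]], "G2")
  expect_length(cat_$universe, 2L)

  suppressMessages(none <- read_target_catalog(path, score_cutoff = -Inf))
  expect_length(none$targets, 0L)
  suppressMessages(all_ <- read_target_catalog(path, score_cutoff = Inf))
  expect_length(all_$targets, 2L)
})

test_that("catalog format errors name the offending line", {
  bad <- write_lines(c("miR-a\tG1", "oops"))
  expect_error(suppressMessages(read_target_catalog(bad)), "line 2")
  noscore <- write_lines(c("miR-a\tG1"))
  expect_error(suppressMessages(read_target_catalog(noscore, score_cutoff = -10)),
               "no score column")
  badnum <- write_lines(c("miR-a\tG1\txyz"))
  expect_error(suppressMessages(read_target_catalog(badnum, score_cutoff = -10)),
               "not numeric")
})

test_that("similarity triples are symmetrized with self-score 1", {
  path <- write_lines(c("100000\t200000\t0.45"))
  ps <- read_phenotype_similarity(path)
  expect_equal(sim_score(ps, "200000", "100000"), 0.45)
  expect_equal(sim_score(ps, "100000", "100000"), 1)  # filled, not in file
})

test_that("similarity validation rejects bad scores and conflicts", {
  expect_error(read_phenotype_similarity(
    write_lines("100000\t200000\t1.3")), "outside")
  expect_error(read_phenotype_similarity(
    write_lines(c("100000\t200000\t0.4", "200000\t100000\t0.6"))),
    "conflicting")
  # equal duplicates are fine
  ps <- read_phenotype_similarity(
    write_lines(c("100000\t200000\t0.4", "200000\t100000\t0.4")))
  expect_equal(sim_score(ps, "100000", "200000"), 0.4)
})

test_that("square-matrix similarity dialect is auto-detected", {
  path <- write_lines(c("mim\t100000\t200000",
                        "100000\t1\t0.25",
                        "200000\t0.25\t1"))
  ps <- read_phenotype_similarity(path)
  expect_equal(sim_score(ps, "100000", "200000"), 0.25)
  expect_setequal(sim_diseases(ps), c("100000", "200000"))
})

test_that("associations de-duplicate; families reject double membership", {
  path <- write_lines(c("miR-10b\t114480", "miR-10b\t114480"))
  suppressMessages(as_ <- read_associations(path))
  expect_equal(nrow(as_$pairs), 1L)
  expect_error(suppressMessages(read_associations(write_lines(character()))),
               "empty")

  fpath <- write_lines(c("mir-10\tmiR-10a", "mir-10\tmiR-10b"))
  suppressMessages(fm <- read_family_map(fpath))
  expect_equal(family_of(fm, "miR-10b"), "mir-10")
  expect_true(is.na(family_of(fm, "miR-99")))
  expect_error(suppressMessages(read_family_map(
    write_lines(c("famA\tmiR-1", "famB\tmiR-1")))), "more than one family")
})

test_that("association holdout helpers do not mutate the original", {
  as_ <- association_set(c("m1", "m2", "m3"), c("d1", "d1", "d2"))
  r1 <- assoc_remove_pair(as_, "m1", "d1")
  expect_equal(nrow(r1$pairs), 2L)
  r2 <- assoc_remove_disease(as_, "d1")
  expect_equal(r2$pairs$mirna, "m3")
  r3 <- assoc_remove_mirnas(as_, "d1", c("m1", "m2"))
  expect_equal(r3$pairs$mirna, "m3")
  expect_equal(nrow(as_$pairs), 3L)  # untouched
})

test_that("every container round-trips through its TSV dialect", {
  syn <- synth_generate(synth_config(seed = 5, n_mirnas = 12, n_diseases = 8,
                                     n_genes = 200, n_associations = 15))
  dir <- withr::local_tempdir()

  p <- file.path(dir, "cat.tsv")
  write_target_catalog(syn$catalog, p)
  suppressMessages(back <- read_target_catalog(p))
  expect_equal(back$targets, syn$catalog$targets)
  expect_equal(back$universe, syn$catalog$universe)

  p <- file.path(dir, "sim.tsv")
  write_phenotype_similarity(syn$phenome, p)
  back <- read_phenotype_similarity(p)
  expect_equal(back$matrix, syn$phenome$matrix, tolerance = 1e-12)

  p <- file.path(dir, "assoc.tsv")
  write_associations(syn$associations, p)
  suppressMessages(back <- read_associations(p))
  expect_equal(back$pairs, syn$associations$pairs)

  p <- file.path(dir, "fam.tsv")
  write_family_map(syn$families, p)
  suppressMessages(back <- read_family_map(p))
  expect_equal(back$family, syn$families$family)
})

test_that("gzipped inputs are read transparently", {
  dir <- withr::local_tempdir()
  gz <- file.path(dir, "assoc.tsv.gz")
  con <- gzfile(gz, "wt")
  writeLines(c("miR-1\td1", "miR-2\td1"), con)
  close(con)
  suppressMessages(as_ <- read_associations(gz))
  expect_equal(nrow(as_$pairs), 2L)
})

test_that("miRNA identifiers are matched case-insensitively after trimming", {
  as_ <- association_set(c("miR-21 ", "MIR-21"), c("d1", "d1"))
  expect_equal(nrow(as_$pairs), 1L)
  expect_equal(as_$pairs$mirna, "mir-21")
})
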