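write_lines <- function(lines, dir, name = "g.csv") {
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

test_that("genotype CSV parsing handles calls, missing fields and bad rows", {
  dir <- withr::local_tempdir()
  panel <- reference_panel()
  path <- write_lines(c(
    "accession,locus,sizes",
    "ACC001,STM1049,190;203",
    "ACC001,STM1017,",
    "ACC002,STM1049,200"
  ), dir)
  gt <- read_genotype_table(path, panel)
  expect_setequal(gt$sizes[gt$accession == "ACC001" & gt$locus == "STM1049"][[1]],
                  c(190, 203))
  expect_length(gt$sizes[gt$accession == "ACC001" & gt$locus == "STM1017"][[1]], 0)

  # five distinct sizes in one call violate tetraploidy
  p5 <- write_lines(c("accession,locus,sizes",
                      "ACC001,STM1049,190;191;200;203;188"), dir)
  expect_error(read_genotype_table(p5, panel), "ACC001.*STM1049|STM1049.*ACC001")

  # unknown locus rejected
  pu <- write_lines(c("accession,locus,sizes", "ACC001,NOPE,190"), dir)
  expect_error(read_genotype_table(pu, panel), "NOPE")

  # malformed numeric reported with its line number
  pm <- write_lines(c("accession,locus,sizes", "ACC001,STM1049,190;xx"), dir)
  expect_error(read_genotype_table(pm, panel), "line 2")
})

test_that("binarize maps calls to 0/1 bin columns with presence semantics", {
  panel <- reference_panel()
  gt <- toy_genotypes(list(
    ACC001 = list(STM1049 = c(190, 203)),
    ACC002 = list(STM1049 = c(189, 191)),  # both sizes in 190 +/- 2
    ACC003 = list(STM1049 = numeric(0))    # missing call
  ))
  m <- binarize(gt, panel)
  mat <- as_matrix(m)
  expect_identical(unname(mat["ACC001", c("STM1049:190±2", "STM1049:200±2", "STM1049:203")]),
                   c(1L, 0L, 1L))
  # idempotent presence: two sizes in one interval give a single 1
  expect_identical(unname(mat["ACC002", ]), c(1L, 0L, 0L))
  # missing call: all-zero row segment plus mask entry
  expect_identical(sum(mat["ACC003", ]), 0L)
  expect_identical(missing_mask(m),
                   tibble::tibble(accession = "ACC003", locus = "STM1049"))
  # per accession per locus at most 4 ones (tetraploid)
  expect_true(all(rowSums(mat) <= 4))
})

test_that("strict mode raises on unassignable sizes, lax mode drops with warning", {
  panel <- reference_panel()
  gt <- toy_genotypes(list(ACC001 = list(STM1049 = 195)))
  expect_error(binarize(gt, panel, strict = TRUE), "195.*STM1049")
  expect_warning(m <- binarize(gt, panel, strict = FALSE), "dropped")
  expect_identical(sum(as_matrix(m)), 0L)
  # a fully dropped call is recorded as missing
  expect_identical(nrow(missing_mask(m)), 1L)
})

test_that("columns are grouped contiguously by locus in panel order", {
  panel <- toy_panel()
  gt <- toy_genotypes(list(
    A1 = list(L1 = 100, L2 = 200, L3 = c(300, 310)),
    A2 = list(L1 = c(105, 110), L2 = 210, L3 = 305)
  ))
  m <- binarize(gt, panel)
  expect_identical(column_map(m)$locus, rep(c("L1", "L2", "L3"), c(3, 2, 3)))
  expect_identical(names(m)[-1], column_map(m)$column)
})

test_that("drop_failed_loci removes only all-zero loci and reports them", {
  panel <- toy_panel()
  gt <- toy_genotypes(list(
    A1 = list(L1 = 100, L2 = numeric(0), L3 = 300),
    A2 = list(L1 = 105, L2 = numeric(0), L3 = 310)
  ))
  m <- binarize(gt, panel)
  expect_message(pruned <- drop_failed_loci(m), "L2")
  expect_identical(attr(pruned, "removed_loci"), "L2")
  expect_identical(matrix_loci(pruned), c("L1", "L3"))
  expect_identical(nrow(missing_mask(pruned)), 0L)

  # identity when nothing failed
  ok <- binarize(toy_genotypes(list(A1 = list(L1 = 100), A2 = list(L1 = 105))), panel)
  expect_identical(attr(drop_failed_loci(ok), "removed_loci"), character(0))
  expect_identical(as_matrix(drop_failed_loci(ok)), as_matrix(ok))

  # degenerate: every locus failed
  allmiss <- binarize(toy_genotypes(list(A1 = list(L1 = numeric(0)),
                                         A2 = list(L1 = numeric(0)))), panel)
  expect_warning(expect_message(empty <- drop_failed_loci(allmiss)), "every locus")
  expect_identical(ncol(as_matrix(empty)), 0L)
})

test_that("matrix and genotype writers round-trip", {
  dir <- withr::local_tempdir()
  panel <- toy_panel()
  gt <- toy_genotypes(list(
    A1 = list(L1 = c(100, 110), L2 = 200),
    A2 = list(L1 = 105, L2 = c(200, 210))
  ))
  m <- binarize(gt, panel)
  path <- file.path(dir, "m.csv")
  write_matrix(m, path)
  m2 <- read_matrix(path)
  expect_identical(as_matrix(m2), as_matrix(m))
  expect_identical(column_map(m2), column_map(m))

  gpath <- file.path(dir, "g.csv")
  write_genotype_table(gt, gpath)
  gt2 <- read_genotype_table(gpath, panel)
  expect_equal(gt2, gt, ignore_attr = TRUE)
})

test_that("column sums equal a brute-force recount on random genotypes", {
  for (seed in 1:5) {
    cfg <- simulation_config(n_accessions = 15, n_loci = 4, allele_range = c(2, 5),
                             n_clusters = 1, cluster_props = 1, dirichlet_alpha = 1)
    set.seed(seed)
    panel <- simulate_panel(cfg)
    sim <- simulate_genotypes(cfg, panel)
    m <- binarize(sim$genotypes, panel)
    mat <- as_matrix(m)
    cmap <- column_map(m)
    for (ci in seq_len(nrow(cmap))) {
      loc <- cmap$locus[ci]
      lab <- cmap$label[ci]
      bins <- panel$bins[[match(loc, panel$locus)]]
      carriers <- sum(vapply(seq_len(nrow(sim$genotypes)), function(i) {
        sim$genotypes$locus[i] == loc &&
          lab %in% assign_bin(sim$genotypes$sizes[[i]], bins)
      }, logical(1)))
      expect_identical(as.integer(colSums(mat)[[cmap$column[ci]]]),
                       as.integer(carriers))
    }
  }
})
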