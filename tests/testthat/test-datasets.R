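test_that("mutation codes parse and reject malformed input", {
  expect_equal(parseMutationCode("R282W"),
               list(wt = "R", position = 282L, mt = "W"))
  expect_error(parseMutationCode("A5A"), "silent")
  expect_error(parseMutationCode("X10G"), "not a standard")
  expect_error(parseMutationCode("R282"), "malformed")
  expect_error(parseMutationCode("282W"), "malformed")
})

test_that("free-energy conversion has its closed forms", {
  expect_identical(deltaGFromKd(1, 298), 0)
  expect_equal(deltaGFromKd(1e-9, 298),
               1.9872e-3 * 298 * log(1e-9), tolerance = 1e-12)
  # monotone in kd, linear in T
  expect_lt(deltaGFromKd(1e-9, 300), deltaGFromKd(1e-6, 300))
  expect_equal(deltaGFromKd(1e-3, 600), 2 * deltaGFromKd(1e-3, 300))
  expect_error(deltaGFromKd(0, 298), "positive")
  expect_error(deltaGFromKd(1e-9, -1), "positive")
})

test_that("binding ddG is antisymmetric and scales with the kd ratio", {
  expect_equal(ddgBinding(1e-8, 1e-8, 298), 0)
  expect_equal(ddgBinding(1e-9, 1e-8, 298),
               1.9872e-3 * 298 * log(10), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:50) {
    a <- 10^runif(1, -12, -2); b <- 10^runif(1, -12, -2)
    expect_equal(ddgBinding(a, b, 298), -ddgBinding(b, a, 298))
  }
})

test_that("stability classes follow the documented sign convention", {
  cls <- stabilityClass(c(-2, 1.5, 0))
  expect_equal(as.vector(cls),
               c("destabilizing", "stabilizing", "destabilizing"))
  expect_equal(attr(cls, "boundary"), c(FALSE, FALSE, TRUE))
  expect_error(stabilityClass(NaN), "finite")
})

test_that("the skempi dialect loads, normalizes and logs defects", {
  fx <- skempiLikeFixture(seed = 2)
  out <- loadMutationTable(fx$path, "skempi", returnLog = TRUE)
  # the malformed-numeric row is skipped at load
  expect_equal(nrow(out$skipped), fx$manifest$malformed_numeric)
  expect_match(out$skipped$reason, "KD")
  expect_equal(nrow(records(out$dataset)),
               fx$manifest$rows - fx$manifest$malformed_numeric)
  expect_equal(out$dataset@task, "protein-protein")
  # affinities are molar numbers
  kd <- records(out$dataset)$kdWT
  expect_true(all(is.na(kd) | (kd > 0 & kd < 1)))
})

test_that("celsius dialects convert temperature to Kelvin", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("pdb\tchain\tmutation\tddG\tpH\tT",
               "1abc\tA\tR282W\t-3.2\t7.0\t25"), tf)
  ds <- loadMutationTable(tf, "protherm")
  expect_equal(records(ds)$temperature, 298.15)
  expect_equal(records(ds)$ddG, -3.2)
  expect_equal(ds@task, "stability")
  # sign flip for opposite-convention tables
  ds2 <- loadMutationTable(tf, "protherm", flipSign = TRUE)
  expect_equal(records(ds2)$ddG, 3.2)
})

test_that("dataset write/load round trip preserves records", {
  fx <- skempiLikeFixture(seed = 3)
  ds <- filterSinglePoint(loadMutationTable(fx$path, "skempi"))$dataset
  tf <- tempfile(fileext = ".tsv")
  writeMutationTable(ds, tf)
  ds2 <- loadMutationTable(tf, "csmpred")
  for (colm in c("structureId", "chainId", "wt", "position", "mt",
                 "kdWT", "kdMT", "pH", "temperature"))
    expect_equal(records(ds2)[[colm]], records(ds)[[colm]], info = colm)
})

test_that("single-point filtering keeps the right rows and is idempotent", {
  recs <- data.frame(
    structureId = c("1a", "1a", "1b", "", "1c", "1d"),
    chainId = "A",
    wt = c("A", NA, "R", "K", "L", NA),
    position = c(5L, NA, 10L, 4L, 7L, NA),
    insert = "", mt = c("G", NA, "W", "E", "M", NA),
    mutationStr = c("A5G", "A5G,K9E", "R10W", "K4E", "L7M", "junk"),
    ddG = c(-1, -2, NA, 1, 2, 0.5),
    kdWT = NA_real_, kdMT = NA_real_, pH = NA_real_,
    temperature = NA_real_, source = "test",
    stringsAsFactors = FALSE)
  ds <- new("MutationDataset", records = recs, name = "toy",
            task = "stability")
  flt <- filterSinglePoint(ds)
  expect_equal(nrow(records(flt$dataset)), 2L)  # rows 1 and 5
  expect_equal(records(flt$dataset)$mutationStr, c("A5G", "L7M"))
  expect_equal(sort(flt$exclusions$reason),
               sort(c("multi_point_or_unparseable", "missing_ddg",
                      "missing_structure", "multi_point_or_unparseable")))
  # idempotent
  again <- filterSinglePoint(flt$dataset)
  expect_equal(records(again$dataset), records(flt$dataset))
  expect_equal(nrow(again$exclusions), 0L)
  # empty in, empty out
  empty <- filterSinglePoint(
    new("MutationDataset", records = recs[0, ], name = "e",
        task = "stability"))
  expect_equal(nrow(records(empty$dataset)), 0L)
})

test_that("binding ddG derivation fills gaps at the record temperature", {
  fx <- skempiLikeFixture(seed = 4)
  ds <- filterSinglePoint(loadMutationTable(fx$path, "skempi"))$dataset
  ds <- deriveBindingDdg(ds)
  r <- records(ds)
  expect_false(anyNA(r$ddG))
  expect_equal(r$ddG, ddgBinding(r$kdWT, r$kdMT, r$temperature))
})

test_that("replicate collapse takes medians per mutation", {
  recs <- data.frame(
    structureId = "1a", chainId = "A", wt = "A",
    position = c(5L, 5L, 5L, 9L), insert = "", mt = c("G", "G", "G", "W"),
    mutationStr = c("A5G", "A5G", "A5G", "A9W"),
    ddG = c(1, 2, 7, -1), kdWT = NA_real_, kdMT = NA_real_,
    pH = c(5, 7, 9, 7), temperature = 298, source = "t",
    stringsAsFactors = FALSE)
  ds <- collapseReplicates(new("MutationDataset", records = recs,
                               name = "r", task = "stability"))
  expect_equal(nrow(records(ds)), 2L)
  expect_equal(records(ds)$ddG, c(2, -1))
  expect_equal(records(ds)$pH[1], 7)
})
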