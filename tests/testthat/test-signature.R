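test_that("geometric centre behaves as the unweighted mean", {
  expect_equal(geometricCentre(cbind(x = 1, y = 2, z = 3)), c(1, 2, 3),
               ignore_attr = TRUE)
  expect_equal(geometricCentre(cbind(x = c(0, 2), y = 0, z = 0)),
               c(1, 0, 0), ignore_attr = TRUE)
  set.seed(2)
  xyz <- matrix(rnorm(30), ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  t <- c(4, -1, 7)
  expect_equal(geometricCentre(sweep(xyz, 2, t, "+")),
               geometricCentre(xyz) + t)
  expect_error(geometricCentre(xyz[0, , drop = FALSE]), "zero atoms")
})

test_that("environment boundary is inclusive at exactly r", {
  base <- glyPdbLines()[1:4]
  # glycine centre is at the mean of its 4 atoms
  ctr <- c(mean(c(0, 1.458, 2.009, 1.251)), mean(c(0, 0, 1.42, 2.39)), 0)
  mk <- function(d, serial, resno)
    sprintf("HETATM%5d  C   LIG B%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, resno, ctr[1] + d, ctr[2], ctr[3])
  tf <- writeTempPdb(c(base, mk(9.9, 90, 90), mk(10.1, 91, 91), "END"))
  s <- assignPharmacophores(readPDB(tf))
  env <- extractResidueEnvironment(s, "A", 1, r = 10)
  expect_equal(nrow(env@atoms), 5L)           # 4 GLY + the 9.9 A atom
  expect_false(any(env@atoms$resNo == 91))
  # saturating radius captures everything
  env2 <- extractResidueEnvironment(s, "A", 1, r = 100)
  expect_equal(nrow(env2@atoms), nrow(atoms(s)))
})

test_that("environment membership equals a brute-force distance check", {
  s <- structureFromFixture(fixtureSpec("point-cloud", nAtoms = 200,
                                        box = 30, seed = 9))
  at <- atoms(s)
  env <- extractResidueEnvironment(s, "X", 17, r = 10)
  ctr <- c(at$x[17], at$y[17], at$z[17])
  keep <- sqrt((at$x - ctr[1])^2 + (at$y - ctr[2])^2 +
                 (at$z - ctr[3])^2) <= 10
  expect_equal(env@atoms$serial, at$serial[keep])
})

test_that("pairwise distances are Euclidean, symmetric, zero-diagonal", {
  xyz <- cbind(x = c(0, 3, 3), y = c(0, 0, 4), z = 0)
  d <- pairwiseDistances(xyz)
  expect_equal(d[1, 2], 3)
  expect_equal(d[1, 3], 5)
  expect_equal(d[2, 3], 4)
  set.seed(4)
  r <- matrix(rnorm(150), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  dr <- pairwiseDistances(r)
  expect_equal(dr, t(dr))
  expect_equal(unname(diag(dr)), rep(0, 50))
  naive <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50)
    naive[i, j] <- sqrt(sum((r[i, ] - r[j, ])^2))
  expect_equal(unname(dr), naive)
})

test_that("cutoff scan steps and class bookkeeping are exact", {
  p <- SignatureParams(dMin = 2, dMax = 6, dStep = 2)
  d <- pairwiseDistances(cbind(x = c(0, 3), y = 0, z = 0))
  sc <- cutoffScan(d, c("hydrophobic", "hydrophobic"), p, "one")
  expect_equal(as.vector(scanCounts(sc)), c(0L, 1L, 1L))

  sc8 <- cutoffScan(pairwiseDistances(cbind(x = c(0, 1), y = 0, z = 0)),
                    c("hydrophobic", "acceptor"), p, "pharmacophore")
  co <- scanCounts(sc8)
  expect_equal(sum(co), 3L)  # one pair at all 3 cutoffs >= 1 A
  expect_equal(as.vector(co[, "hydrophobic:acceptor"]), c(1L, 1L, 1L))
  expect_true(all(co[, colnames(co) != "hydrophobic:acceptor"] == 0L))

  expect_error(cutoffScan(d, "hydrophobic", p, "one"), "do not match")
})

test_that("cutoff scans match the brute-force triple loop on random environments", {
  set.seed(31)
  p <- SignatureParams()
  grid <- cutoffGrid(p)
  for (trial in 1:12) {
    n <- sample(5:60, 1)
    xyz <- matrix(runif(3 * n, 0, 12), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z")))
    cls <- sample(pharmacophoreClasses(), n, replace = TRUE)
    d <- pairwiseDistances(xyz)
    for (sch in c("one", "binary", "pharmacophore")) {
      got <- scanCounts(cutoffScan(d, cls, p, sch))
      want <- bfCutoffScan(xyz, cls, grid, sch)
      expect_identical(unname(got), unname(want))
    }
  }
})

test_that("pharmacophore change is antisymmetric and zero on identity", {
  expect_equal(unname(pharmacophoreChange("A", "A")), rep(0L, 8))
  expect_equal(pharmacophoreChange("G", "W"),
               -pharmacophoreChange("W", "G"))
  # independent tally for GLY -> TRP
  tab <- pharmacophoreTable()
  tally <- function(res) {
    v <- setNames(integer(8), pharmacophoreClasses())
    for (cl in tab$class[tab$resName == res & tab$atomName != "OXT"])
      v[cl] <- v[cl] + 1L
    v
  }
  expect_equal(pharmacophoreChange("G", "W"), tally("TRP") - tally("GLY"))
})

test_that("signature layout arithmetic holds", {
  s <- labelledHelix(8)
  sig <- computeSignature(s, "A4G", chainId = "A")
  # 21 cutoffs x (1 + 3 + 36) pair classes + 8 pchange + pH, T, RSA
  expect_length(features(sig), 21 * 40 + 8 + 3)
  expect_false(anyDuplicated(names(features(sig))) > 0)

  p2 <- SignatureParams(schemes = c("one", "pharmacophore"))
  sig2 <- computeSignature(s, "A4G", chainId = "A", params = p2)
  expect_length(features(sig2), length(features(sig)) - 21 * 3)

  # imputation flags and defaults
  expect_setequal(sig@provenance$imputed, c("pH", "temperature"))
  expect_equal(unname(features(sig)[c("pH", "temperature")]), c(7, 25))
  sig3 <- computeSignature(s, "A4G", chainId = "A", pH = 5.5,
                           temperature = 37)
  expect_length(sig3@provenance$imputed, 0)
})

test_that("wild-type mismatch is a named validation error", {
  s <- labelledHelix(8)
  expect_error(computeSignature(s, "G4W", chainId = "A"),
               "GLY.*ALA|states GLY but structure has ALA")
})

test_that("signatures are deterministic and rigid-motion invariant", {
  s <- labelledHelix(12)
  a <- features(computeSignature(s, "A6W", chainId = "A"))
  b <- features(computeSignature(s, "A6W", chainId = "A"))
  expect_identical(a, b)

  set.seed(77)
  s2 <- rotateStructure(s, randomRotation(), shift = c(-8, 2, 3))
  c <- features(computeSignature(s2, "A6W", chainId = "A"))
  hard <- setdiff(names(a), "rsa")
  expect_equal(c[hard], a[hard])
  expect_equal(c[["rsa"]], a[["rsa"]], tolerance = 0.01)
})

test_that("full signatures match the independent end-to-end brute force", {
  p <- SignatureParams()
  s <- labelledHelix(15)
  asa <- shrakeRupley(s)
  for (mut in c("A2G", "A5W", "A8D", "A12K")) {
    got <- features(computeSignature(s, mut, chainId = "A", asa = asa))
    want <- bfSignature(s, mut, "A", p, asa = asa)
    expect_identical(got, want[names(got)], label = mut)
  }
})

test_that("cumulative monotonicity and scheme-sum consistency hold", {
  s <- structureFromFixture(fixtureSpec("point-cloud", nAtoms = 40,
                                        box = 15, seed = 3))
  env <- extractResidueEnvironment(s, "X", 10, r = 12)
  d <- pairwiseDistances(env)
  p <- SignatureParams()
  one <- scanCounts(cutoffScan(d, env@atoms$pharmacophore, p, "one"))
  bin <- scanCounts(cutoffScan(d, env@atoms$pharmacophore, p, "binary"))
  ph <- scanCounts(cutoffScan(d, env@atoms$pharmacophore, p,
                              "pharmacophore"))
  for (m in list(one, bin, ph))
    expect_true(all(apply(m, 2, function(col) all(diff(col) >= 0))))
  expect_equal(rowSums(bin), rowSums(one), ignore_attr = TRUE)
  expect_equal(rowSums(ph), rowSums(one), ignore_attr = TRUE)
  # at a cutoff beyond the diameter, the one-class count saturates
  n <- nrow(env@atoms)
  pbig <- SignatureParams(dMax = ceiling(max(d)) + 1, dStep = 1)
  onebig <- scanCounts(cutoffScan(d, env@atoms$pharmacophore, pbig, "one"))
  expect_equal(onebig[nrow(onebig), 1], n * (n - 1) / 2,
               ignore_attr = TRUE)
})
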