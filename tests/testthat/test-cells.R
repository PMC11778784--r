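test_that("nuclei CSV loading validates, dedups and labels unassigned", {
  td <- withr::local_tempdir()
  f <- file.path(td, "n.csv")
  write.csv(data.frame(x = c(0, 8, 16), y = 0, z = 0), f, row.names = FALSE)
  nuc <- loadNuclei(f)
  expect_equal(nrow(nucleiPoints(nuc)), 3)
  expect_true(all(nuc@chamber == "unassigned"))

  write.csv(data.frame(x = c(0, 0.05, 16), y = 0, z = 0), f,
            row.names = FALSE)
  expect_warning(nuc2 <- loadNuclei(f), "merged")
  expect_equal(nrow(nucleiPoints(nuc2)), 2)

  write.csv(data.frame(x = c("a", "1"), y = c(0, 0), z = c(0, 0)), f,
            row.names = FALSE)
  expect_error(loadNuclei(f), "non-numeric")
})

test_that("chamber assignment follows the disc with documented tie-break", {
  nuc <- NucleiSet(rbind(c(0, 0, 1), c(0, 0, -1), c(0, 0, 0)))
  disc <- CutDisc(c(0, 0, 0), c(0, 0, 1), 10)
  a <- suppressMessages(assignChambers(nuc, disc, atrialSide = "positive"))
  expect_equal(a@chamber, c("atrium", "ventricle", "ventricle"))
  # flipping the normal swaps the off-plane labels
  b <- suppressMessages(assignChambers(nuc, CutDisc(c(0, 0, 0),
                                                    c(0, 0, -1), 10),
                                       atrialSide = "positive"))
  expect_equal(b@chamber[1:2], c("ventricle", "atrium"))
})

test_that("lattice internuclear distance is exact for interior seeds", {
  ph <- phantomNucleiLattice(a = 8, n = c(7, 7, 7))
  nuc <- suppressMessages(assignChambers(ph$nuclei,
                                         CutDisc(c(24.1, 0, 0),
                                                 c(1, 0, 0), 1e3),
                                         atrialSide = "negative"))
  res <- internuclearDistance(nuc, k = 4)
  expect_equal(unname(res$nuclei@ind[ph$interior]),
               rep(8, sum(ph$interior)))
})

test_that("IND obeys symmetry, homogeneity and rigid-motion invariance", {
  two <- suppressMessages(assignChambers(
    NucleiSet(rbind(c(0, 0, 0), c(3, 4, 0))),
    CutDisc(c(0, 0, -5), c(0, 0, 1), 10), "positive"))
  r2 <- internuclearDistance(two, k = 1)
  expect_equal(unname(r2$nuclei@ind), c(5, 5))

  set.seed(3)
  P <- matrix(runif(90, 0, 40), ncol = 3)
  disc <- CutDisc(c(20, 0, 0), c(1, 0, 0), 1e3)
  base <- internuclearDistance(
    suppressMessages(assignChambers(NucleiSet(P), disc)), k = 4)
  # scaling doubles every IND
  scaled <- internuclearDistance(
    suppressMessages(assignChambers(NucleiSet(2 * P),
                                    CutDisc(c(40, 0, 0), c(1, 0, 0), 1e3))),
    k = 4)
  expect_equal(scaled$nuclei@ind, 2 * base$nuclei@ind)
  # rigid motion leaves INDs unchanged
  R <- rotationMatrix(c(1, 0, 1), 55)
  Pr <- P %*% t(R) + matrix(c(5, -3, 11), nrow(P), 3, byrow = TRUE)
  discR <- CutDisc(as.numeric(R %*% c(20, 0, 0)) + c(5, -3, 11),
                   as.numeric(R %*% c(1, 0, 0)), 1e3)
  rot <- internuclearDistance(
    suppressMessages(assignChambers(NucleiSet(Pr), discR)), k = 4)
  expect_equal(rot$nuclei@ind, base$nuclei@ind, tolerance = 1e-9)

  # chambers with too few nuclei are skipped with a warning
  few <- suppressMessages(assignChambers(
    NucleiSet(rbind(c(0, 0, 1), c(0, 0, 2), c(0, 0, -1))),
    CutDisc(c(0, 0, 0), c(0, 0, 1), 10), "positive"))
  expect_warning(expect_warning(internuclearDistance(few, k = 2),
                                "skipped"), "skipped")
})

test_that("region assignment buckets nuclei into quadrant sectors", {
  cl <- fxStraightCl()
  # nuclei exactly dorsal (+y), ventral, left (-x), right (+x) of the axis
  P <- rbind(c(0, 10, 50), c(0, -10, 50), c(-10, 0, 50), c(10, 0, 50))
  nuc <- NucleiSet(P, chamber = rep("ventricle", 4))
  out <- assignRegions(nuc, cl, dorsalRef = c(0, 1, 0))
  expect_equal(out@region, c("dorsal", "ventral", "outer", "inner"))
  # outer/inner mapping is configurable
  out2 <- assignRegions(nuc, cl, c(0, 1, 0), outerIsLeft = FALSE)
  expect_equal(out2@region[3:4], c("inner", "outer"))
  # 45-degree boundary joins the counter-clockwise-next sector:
  # theta grows from dorsal towards left, so (-x+y)/sqrt(2) is "outer"
  b <- assignRegions(NucleiSet(rbind(c(-10, 10, 50) / sqrt(2)),
                               chamber = "ventricle"), cl, c(0, 1, 0))
  expect_equal(b@region, "outer")
})

test_that("uniform ring nuclei spread evenly over the four sectors", {
  cl <- fxStraightCl()
  n <- 64
  th <- (seq_len(n) - 0.5) / n * 2 * pi   # off-boundary angles
  P <- cbind(10 * cos(th), 10 * sin(th), 50)
  out <- assignRegions(NucleiSet(P, chamber = rep("atrium", n)), cl,
                       c(0, 1, 0))
  counts <- table(out@region)
  expect_true(all(abs(counts - n / 4) <= 2))
})

test_that("chamber mean IND equals the count-weighted region mean exactly", {
  set.seed(9)
  P <- matrix(runif(300, 0, 60), ncol = 3)
  nuc <- suppressMessages(assignChambers(
    NucleiSet(P), CutDisc(c(30, 0, 0), c(1, 0, 0), 1e3)))
  nuc <- assignRegions(nuc, fxStraightCl(), c(0, 1, 0))
  res <- internuclearDistance(nuc, k = 4)
  for (ch in c("atrium", "ventricle")) {
    chMean <- res$per_chamber$mean_ind_um[res$per_chamber$chamber == ch]
    reg <- res$per_region[res$per_region$chamber == ch, ]
    expect_equal(chMean, sum(reg$mean_ind_um * reg$n) / sum(reg$n))
  }
})

test_that("nuclei export includes labels and IND", {
  td <- withr::local_tempdir()
  ph <- phantomNucleiLattice(a = 8, n = c(4, 4, 4))
  nuc <- suppressMessages(assignChambers(ph$nuclei,
                                         CutDisc(c(12.1, 0, 0),
                                                 c(1, 0, 0), 1e3)))
  res <- internuclearDistance(nuc, k = 3)
  f <- file.path(td, "out.csv")
  writeNucleiCsv(res$nuclei, f)
  df <- read.csv(f)
  expect_named(df, c("id", "x", "y", "z", "chamber", "region", "ind_um"))
  expect_equal(nrow(df), 64)
})
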