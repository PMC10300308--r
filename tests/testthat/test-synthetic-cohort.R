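test_that("cohort generation is deterministic and matches its spec", {
  sp <- cohortSpec(nPerGroup = 3, nRois = 5, voxelsPerRoi = 30, seed = 42)
  a <- generateCohort(sp)
  b <- generateCohort(sp)
  expect_identical(roiSamples(cohortSubjects(a)[[1]]),
                   roiSamples(cohortSubjects(b)[[1]]))
  expect_identical(roiSamples(cohortSubjects(a)[[6]]),
                   roiSamples(cohortSubjects(b)[[6]]))
  expect_equal(as.vector(table(cohortGroups(a))), c(3, 3))
  for (s in cohortSubjects(a)) {
    expect_identical(roiIds(s), 1:5)
    expect_true(all(vapply(roiSamples(s), length, integer(1)) == 30))
  }
})

test_that("invalid spec fields raise errors naming the field", {
  expect_error(cohortSpec(nPerGroup = 1), "nPerGroup")
  expect_error(cohortSpec(voxelsPerRoi = 5), "voxelsPerRoi")
  expect_error(cohortSpec(nRois = 10, affectedRois = c(3, 11)), "affectedRois")
  expect_error(cohortSpec(scaleFactor = 0), "scaleFactor")
  expect_error(cohortSpec(locationShift = NA), "locationShift")
})

test_that("null spec yields per-ROI distributions shared by the groups", {
  co <- generateCohort(cohortSpec(nPerGroup = 4, nRois = 6,
                                  voxelsPerRoi = 2000, seed = 9))
  g <- cohortGroups(co)
  for (r in 1:6) {
    pd <- unlist(lapply(cohortSubjects(co)[g == "PD"],
                        function(s) roiSamples(s)[[r]]))
    nc <- unlist(lapply(cohortSubjects(co)[g == "NC"],
                        function(s) roiSamples(s)[[r]]))
    # same generating parameters: means and SDs agree within MC error
    expect_lt(abs(mean(pd) - mean(nc)), 4 * sd(nc) / sqrt(length(nc) / 2))
    expect_lt(abs(sd(pd) / sd(nc) - 1), 0.1)
  }
  expect_equal(nrow(cohortTruth(co)$truthEdges), 0)
})

test_that("location shift moves affected-ROI means by the stated amount", {
  co <- generateCohort(cohortSpec(nPerGroup = 2, nRois = 10,
                                  voxelsPerRoi = 5000,
                                  affectedRois = 1:10, locationShift = 1.5,
                                  seed = 3))
  g <- cohortGroups(co)
  pd <- unlist(lapply(cohortSubjects(co)[g == "PD"],
                      function(s) roiSamples(s)[[1]]))
  nc <- unlist(lapply(cohortSubjects(co)[g == "NC"],
                      function(s) roiSamples(s)[[1]]))
  shiftInSd <- (mean(pd) - mean(nc)) / sd(nc)
  expect_lt(abs(shiftInSd - 1.5), 0.1)
})

test_that("empirical group divergence grows with the location shift", {
  div <- vapply(c(0.5, 1, 2), function(shift) {
    co <- generateCohort(cohortSpec(nPerGroup = 2, nRois = 2,
                                    voxelsPerRoi = 4000, affectedRois = 1L,
                                    locationShift = shift, seed = 8))
    g <- cohortGroups(co)
    pd <- roiSamples(cohortSubjects(co)[[which(g == "PD")[1]]])[[1]]
    nc <- roiSamples(cohortSubjects(co)[[which(g == "NC")[1]]])[[1]]
    abs(mean(pd) - mean(nc)) / sd(nc)
  }, numeric(1))
  expect_true(all(diff(div) > 0))
})

test_that("gamma family produces positive, right-skewed intensities", {
  co <- generateCohort(cohortSpec(nPerGroup = 2, nRois = 4,
                                  voxelsPerRoi = 3000,
                                  baseFamily = "gamma", seed = 4))
  x <- roiSamples(cohortSubjects(co)[[1]])[[1]]
  expect_true(all(x > 0))
  skew <- mean((x - mean(x))^3) / sd(x)^3
  expect_gt(skew, 0)
})

test_that("truth edge set is exactly the edges touching an affected ROI", {
  co <- generateCohort(cohortSpec(nPerGroup = 2, nRois = 6,
                                  voxelsPerRoi = 20, affectedRois = c(2L, 5L),
                                  seed = 1))
  te <- cohortTruth(co)$truthEdges
  pairs <- connectionIndexPairs(6)
  expected <- pairs[pairs[, 1] %in% c(2, 5) | pairs[, 2] %in% c(2, 5), ]
  expect_equal(unname(te), unname(expected))
})

test_that("phantom volume rendering round-trips through extraction", {
  co <- generateCohort(cohortSpec(nPerGroup = 2, nRois = 5,
                                  voxelsPerRoi = 40, seed = 2))
  s <- cohortSubjects(co)[[1]]
  vols <- renderPhantomVolume(s, c(8, 8, 4))
  rec <- extractRoiSamples(vols$intensity, vols$label, minVoxels = 2)
  expect_identical(roiIds(rec), roiIds(s))
  for (r in seq_along(roiIds(s)))
    expect_equal(sort(roiSamples(rec)[[r]]), sort(roiSamples(s)[[r]]))
  # label histogram: voxel counts per ROI match, background excluded
  expect_equal(as.vector(table(vols$label[vols$label > 0])), rep(40L, 5))
  expect_equal(sum(vols$label == 0), 8 * 8 * 4 - 200)
})

test_that("rendering fails on a grid that cannot hold all ROIs", {
  co <- generateCohort(cohortSpec(nPerGroup = 2, nRois = 5,
                                  voxelsPerRoi = 40, seed = 2))
  expect_error(renderPhantomVolume(cohortSubjects(co)[[1]], c(4, 4, 4)),
               "grid too small")
})

test_that("cohort TSV + manifest round trip preserves samples and truth", {
  co <- generateCohort(cohortSpec(nPerGroup = 2, nRois = 4, voxelsPerRoi = 15,
                                  affectedRois = 2L, locationShift = 1,
                                  seed = 6))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  man <- withr::local_tempfile(fileext = ".json")
  writeCohortTsv(co, tsv, man)
  back <- readCohortTsv(tsv, man)
  expect_equal(cohortGroups(back), cohortGroups(co))
  expect_equal(cohortTruth(back)$affectedRois, cohortTruth(co)$affectedRois)
  expect_equal(unname(cohortTruth(back)$truthEdges),
               unname(cohortTruth(co)$truthEdges))
  for (k in seq_along(cohortSubjects(co)))
    expect_equal(roiSamples(cohortSubjects(back)[[k]]),
                 roiSamples(cohortSubjects(co)[[k]]), tolerance = 1e-12)
})
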