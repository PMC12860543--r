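test_that("the defect-type factorial enumerates 27 specs in documented order", {
  d <- enumerateDefectTypes()
  expect_identical(nrow(d), 27L)
  expect_identical(d$extentDeg[1], 30)
  expect_identical(d$severity[1], 0.10)
  expect_identical(d$location[1], "anterior")
  expect_identical(sort(unique(d$severity)), c(0.10, 0.25, 0.50))
  expect_identical(sort(unique(d$extentDeg)), c(30, 60, 90))
  expect_identical(sort(unique(d$location)),
                   c("anterior", "inferior", "lateral"))
  # extent-major, then severity, then location
  expect_identical(d$extentDeg, rep(c(30, 60, 90), each = 9))
  expect_identical(d$severity[1:9], rep(c(0.10, 0.25, 0.50), each = 3))
  expect_false(any(duplicated(d)))
})

test_that("defect perturbations live in the LV wall sector and scale with severity", {
  ph <- smallPhantom()
  wall <- lvWallMask(ph)
  p1 <- defectPerturbation(ph, defectSpec(90, 0.25, "anterior"))
  expect_true(all(p1$volume[!wall] == 0))
  expect_gt(sum(p1$volume > 0), 0)
  p2 <- defectPerturbation(ph, defectSpec(90, 0.50, "anterior"))
  expect_equal(p2$volume, 2 * p1$volume, tolerance = 1e-12)
  # larger extent covers a superset of voxels
  p3 <- defectPerturbation(ph, defectSpec(30, 0.25, "anterior"))
  expect_true(all(p1$volume[p3$volume > 0] > 0))
  expect_lt(sum(p3$volume > 0), sum(p1$volume > 0))
  # the three locations select disjoint 90-degree sectors
  pa <- defectPerturbation(ph, defectSpec(90, 0.5, "anterior"))$volume > 0
  pi_ <- defectPerturbation(ph, defectSpec(90, 0.5, "inferior"))$volume > 0
  pl <- defectPerturbation(ph, defectSpec(90, 0.5, "lateral"))$volume > 0
  expect_equal(sum(pa & pi_), 0)
  expect_equal(sum(pa & pl), 0)
  expect_error(defectSpec(90, 0, "anterior"), "severity")
})

test_that("insertion subtracts the projected perturbation and spares the scatter window", {
  ph <- smallPhantom()
  proj <- smallProjections()
  spec <- defectSpec(90, 0.5, "inferior")
  ins <- insertDefect(proj, ph, spec)
  expect_identical(scatterWindow(ins$proj), scatterWindow(proj))
  # linearity oracle: independent re-projection of the perturbed activity
  pert <- defectPerturbation(ph, spec)
  ref <- forwardProject(activityMap(ph) - pert$volume, attenuationMap(ph),
                        proj@geometry)
  expect_lt(max(abs(photopeak(ins$proj) - ref)) / max(ref), 1e-6)
  # total counts drop by exactly the projected perturbation sum
  dp <- forwardProject(pert$volume, attenuationMap(ph), proj@geometry)
  expect_equal(sum(photopeak(proj)) - sum(photopeak(ins$proj)), sum(dp),
               tolerance = 1e-6)
  # zero-severity spec cannot be constructed; a tiny one changes little
  tiny <- insertDefect(proj, ph, defectSpec(30, 0.01, "anterior"))
  expect_lt(sum(photopeak(proj)) - sum(photopeak(tiny$proj)),
            0.01 * sum(photopeak(proj)))
  expect_equal(pert$centroid, ins$centroid)
})

test_that("higher severity lowers the reconstructed defect-sector intensity", {
  ph <- smallPhantom()
  proj <- smallProjections()
  geom <- proj@geometry
  sector <- defectPerturbation(ph, defectSpec(90, 0.5, "anterior"))
  vals <- vapply(c(0.10, 0.50), function(sev) {
    ins <- insertDefect(proj, ph, defectSpec(90, sev, "anterior"))
    rec <- osem(photopeak(ins$proj),
                reconConfig(4L, 6L, attenuationMap(ph)), geom)
    mean(reconVolume(rec)[sector$volume > 0])
  }, numeric(1))
  expect_gt(vals[1], vals[2])
})
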