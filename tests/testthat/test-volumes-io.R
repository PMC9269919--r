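test_that("NRRD write/read round-trips data and geometry exactly", {
  td <- withr::local_tempdir()
  set.seed(11)
  v <- image_volume(array(round(runif(4 * 4 * 4) * 1000), c(4, 4, 4)),
                    spacing = c(1, 2, 3), origin = c(-4.5, 0.25, 9))
  p <- file.path(td, "v.nrrd")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_identical(v2$data, v$data)
  expect_identical(v2$spacing, v$spacing)
  expect_identical(v2$origin, v$origin)

  # label maps come back as 8-bit 0/1
  m <- label_map(array(runif(64) > 0.5, c(4, 4, 4)), "wall",
                 spacing = c(1, 2, 3))
  pm <- file.path(td, "m.nrrd")
  write_volume(m, pm)
  m2 <- read_volume(pm)
  expect_true(all(m2$data %in% c(0, 1)))
  expect_identical(m2$data != 0, m$mask)

  z <- label_map(array(FALSE, c(3, 3, 3)))
  pz <- file.path(td, "z.nrrd")
  write_volume(z, pz)
  expect_true(all(read_volume(pz)$data == 0))
})

test_that("NIfTI write/read round-trips data and geometry", {
  td <- withr::local_tempdir()
  set.seed(12)
  v <- image_volume(array(runif(60) * 50, c(5, 4, 3)),
                    spacing = c(0.625, 0.625, 0.975), origin = c(1, -2, 3))
  p <- file.path(td, "v.nii.gz")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_equal(v2$data, v$data)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-6)
})

test_that("NRRD without spacing falls back to acquisition geometry with a warning", {
  td <- withr::local_tempdir()
  p <- file.path(td, "nospace.nrrd")
  con <- file(p, "wb")
  header <- paste0("NRRD0004\ntype: uint8\ndimension: 3\nsizes: 2 2 2\n",
                   "encoding: raw\n\n")
  writeBin(charToRaw(header), con)
  writeBin(as.raw(1:8), con)
  close(con)
  expect_warning(v <- read_volume(p), "spacing")
  expect_equal(v$spacing, c(0.625, 0.625, 0.975))
  expect_equal(as.vector(v$data), as.double(1:8))
})

test_that("malformed volumes are rejected with format errors", {
  td <- withr::local_tempdir()
  p <- file.path(td, "trunc.nrrd")
  writeLines("NRRD0004", p)
  expect_error(read_volume(p), "malformed|truncated")

  # truncated data segment
  p2 <- file.path(td, "short.nrrd")
  con <- file(p2, "wb")
  writeBin(charToRaw(paste0("NRRD0004\ntype: double\ndimension: 3\n",
                            "sizes: 4 4 4\nencoding: raw\n\n")), con)
  writeBin(as.raw(1:16), con)
  close(con)
  expect_error(suppressWarnings(read_volume(p2)), "truncated")

  expect_error(read_volume(file.path(td, "absent.nrrd")), "not found")

  # oblique direction matrix refused
  p3 <- file.path(td, "oblique.nrrd")
  con <- file(p3, "wb")
  writeBin(charToRaw(paste0(
    "NRRD0004\ntype: uint8\ndimension: 3\nsizes: 2 2 2\nencoding: raw\n",
    "space directions: (1,0.2,0) (0,1,0) (0,0,1)\n\n")), con)
  writeBin(as.raw(1:8), con)
  close(con)
  expect_error(read_volume(p3), "axis-aligned")
})

test_that("landmark tables load in order, tolerate FCSV comments, reject bad rows", {
  td <- withr::local_tempdir()
  labels <- c("ascending aorta", "descending aorta", "aortic arch",
              "left pulmonary artery", "right pulmonary artery",
              "left superior pulmonary vein", "left inferior pulmonary vein",
              "right superior pulmonary vein", "right inferior pulmonary vein",
              "left atrioventricular septum", "left atrial appendage",
              "left anterior descending artery", "aortic valve")
  set.seed(13)
  lm <- landmark_set(labels, matrix(rnorm(39), 13, 3), role = "fixed")
  p <- file.path(td, "lm.csv")
  write_landmarks(lm, p)
  # prepend FCSV-style comment lines
  txt <- c("# Markups fiducial file", "# columns = label,x,y,z",
           readLines(p))
  writeLines(txt, p)
  lm2 <- read_landmarks(p, role = "fixed")
  expect_identical(lm2$labels, labels)
  expect_equal(lm2$coords, lm$coords, ignore_attr = TRUE, tolerance = 1e-12)

  # two points load, but registration refuses them
  writeLines(c("label,x,y,z", "a,0,0,0", "b,1,1,1"), p)
  two <- read_landmarks(p)
  expect_equal(length(two$labels), 2L)
  expect_error(fit_rigid_landmarks(two, two), "3 landmarks")

  writeLines(c("label,x,y,z", "aortic arch,0,0,0", "aortic arch,1,1,1",
               "b,0,1,0"), p)
  expect_error(read_landmarks(p), "duplicate")

  writeLines(c("label,x,y,z", "a,0,zero,0", "b,1,1,1", "c,0,1,0"), p)
  expect_error(read_landmarks(p), "non-numeric")
})
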