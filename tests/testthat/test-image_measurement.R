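test_that("green channel is read verbatim as G-values", {
  d <- withr::local_tempdir()
  black <- file.path(d, "black.png")
  png::writePNG(array(0, dim = c(5, 7, 3)), black)
  img <- load_gvalue_image(black)
  expect_true(all(img$pixels == 0))

  green <- file.path(d, "green.png")
  arr <- array(0, dim = c(5, 7, 3)); arr[, , 2] <- 1
  png::writePNG(arr, green)
  expect_true(all(load_gvalue_image(green)$pixels == 255))

  gray <- file.path(d, "gray.png")
  png::writePNG(matrix(0.5, 5, 7), gray)
  expect_error(load_gvalue_image(gray), "RGB")
  expect_error(load_gvalue_image(file.path(d, "missing.png")), "not found")
  bmp <- file.path(d, "bad.bmp")
  writeLines("not an image", bmp)
  expect_error(load_gvalue_image(bmp), "format")
})

test_that("render -> load round trip is bit-exact for PNG and TIFF", {
  gen <- generate_animal_field(rat_stage_presets()$stages$HGD_CIS, 1, seed = 77,
                               width = 150, height = 24)
  q <- quantize_gvalues(gen$image)
  d <- withr::local_tempdir()
  for (ext in c("png", "tif")) {
    f <- file.path(d, paste0("img.", ext))
    write_gvalue_image(gen$image, f)
    loaded <- load_gvalue_image(f)
    expect_identical(matrix(as.integer(loaded$pixels), nrow(q)), unclass(q),
                     info = ext)
  }
})

test_that("profile extraction samples the requested number of points", {
  img <- gvalue_image(matrix(42, 64, 220))
  rat_line <- line_spec(c(5, 32), c(204, 32), 200)
  prof <- extract_line_profile(img, rat_line)
  expect_length(prof$values, 200)
  expect_true(all(prof$values == 42))
  expect_true(all(diff(prof$positions) > 0))

  human_line <- line_spec(c(0, 10), c(49, 10), 50)
  expect_length(extract_line_profile(img, human_line)$values, 50)

  expect_error(extract_line_profile(img, line_spec(c(0, 0), c(500, 0), 10)),
               "bounds")
  expect_error(line_spec(c(1, 1), c(1, 1), 10), "differ")
  expect_error(line_spec(c(0, 0), c(9, 0), 1), "n_points")
})

test_that("profile extraction is invariant to joint image/line translation", {
  set.seed(8)
  core <- matrix(round(runif(30 * 80, 20, 80)), 30, 80)
  big <- matrix(0, 60, 160)
  big[1:30, 1:80] <- core
  shifted <- matrix(0, 60, 160)
  shifted[11:40, 21:100] <- core
  l0 <- line_spec(c(2, 14), c(77, 14), 60)
  l1 <- line_spec(c(22, 24), c(97, 24), 60)
  p0 <- extract_line_profile(gvalue_image(big), l0)
  p1 <- extract_line_profile(gvalue_image(shifted), l1)
  expect_identical(p0$values, p1$values)
})

test_that("masked pixels become missing and all-masked lines error", {
  pix <- matrix(50, 10, 20)
  mask <- matrix(FALSE, 10, 20); mask[5 + 1, 6:10 + 1] <- TRUE  # 0-based x 6..10 at y 5
  img <- gvalue_image(pix, mask)
  prof <- extract_line_profile(img, line_spec(c(0, 5), c(19, 5), 20))
  expect_identical(which(is.na(prof$values)), 7:11)
  all_mask <- gvalue_image(pix, matrix(TRUE, 10, 20))
  expect_error(extract_line_profile(all_mask, line_spec(c(0, 5), c(19, 5), 20)),
               "masked")
  # companion mask file route
  d <- withr::local_tempdir()
  arr <- array(0, dim = c(10, 20, 3)); arr[, , 2] <- 50 / 255
  png::writePNG(arr, file.path(d, "img.png"))
  png::writePNG(mask * 1, file.path(d, "mask.png"))
  loaded <- load_gvalue_image(file.path(d, "img.png"), file.path(d, "mask.png"))
  expect_identical(loaded$mask, mask)
})

test_that("surface matrix is the identity without smoothing and conserves box mass", {
  img <- gvalue_image(matrix(33, 12, 12))
  expect_identical(surface_matrix(img), img$pixels)  # flat for constant input

  spike <- matrix(0, 11, 11); spike[6, 6] <- 9
  sm <- surface_matrix(gvalue_image(spike), smooth = 3)
  expect_equal(sm[5:7, 5:7], matrix(1, 3, 3))  # 1/9 of the mass per cell
  expect_equal(sum(sm), sum(spike))
  expect_true(all(sm[1, ] == 0))
  expect_error(surface_matrix(img, smooth = 4), "odd")

  masked <- gvalue_image(matrix(10, 4, 4), rbind(c(TRUE, rep(FALSE, 3)),
                                                 matrix(FALSE, 3, 4)))
  expect_true(is.na(surface_matrix(masked)[1, 1]))
})

test_that("gvalue_image enforces its invariants", {
  expect_error(gvalue_image(matrix(300, 2, 2)), "\\[0, 255\\]")
  expect_error(gvalue_image(matrix(1, 2, 2), matrix(FALSE, 3, 3)), "dimensions")
  # out-of-range values are fine when masked
  img <- gvalue_image(matrix(c(300, 1, 1, 1), 2, 2),
                      matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_s3_class(img, "gvalue_image")
})
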