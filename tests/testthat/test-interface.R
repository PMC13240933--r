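test_that("image/mask pairs round-trip through PNG with correct scaling", {
  td <- withr::local_tempdir()
  p <- generate_phantom(tiny_spec(seed = 3))
  ip <- file.path(td, "img.png"); mp <- file.path(td, "msk.png")
  octunet:::write_gray_png(p$image, ip)
  octunet:::write_mask_png(p$mask, mp)
  pair <- load_image_mask_pair(ip, mp)
  expect_equal(dim(pair$image), dim(p$image))
  expect_identical(pair$mask, p$mask)
  expect_true(max(pair$image) <= 1 && min(pair$image) >= 0)
  # 8-bit quantization error only
  expect_lt(max(abs(pair$image - p$image)), 1 / 255)
})

test_that("16-bit input scales to [0, 1] with full range preserved", {
  td <- withr::local_tempdir()
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  img[1, 1] <- 1                      # 65535 in 16-bit
  tiff::writeTIFF(img, file.path(td, "img16.tif"), bits.per.sample = 16)
  msk <- matrix(0L, 8, 8); msk[3:5, ] <- 1L
  octunet:::write_mask_png(msk, file.path(td, "m.png"))
  pair <- load_image_mask_pair(file.path(td, "img16.tif"), file.path(td, "m.png"))
  expect_equal(max(pair$image), 1.0)
})

test_that("masks binarize at the 8-bit midpoint: 127 is background", {
  td <- withr::local_tempdir()
  m <- matrix(c(127, 128, 0, 255) / 255, 2, 2)
  png::writePNG(m, file.path(td, "m.png"))
  got <- octunet:::read_mask_png(file.path(td, "m.png"))
  expect_identical(got, matrix(c(0L, 1L, 0L, 1L), 2, 2))
})

test_that("unreadable, mismatched and color inputs give distinct errors", {
  td <- withr::local_tempdir()
  p <- generate_phantom(tiny_spec(seed = 1))
  ip <- file.path(td, "img.png"); mp <- file.path(td, "msk.png")
  octunet:::write_gray_png(p$image, ip)
  octunet:::write_mask_png(p$mask[1:16, 1:16], mp)
  expect_error(load_image_mask_pair(file.path(td, "nope.png"), mp),
               "cannot read")
  expect_error(load_image_mask_pair(ip, mp), "shape mismatch")
  rgb <- array(runif(8 * 8 * 3), c(8, 8, 3))
  png::writePNG(rgb, file.path(td, "rgb.png"))
  expect_error(load_image_mask_pair(file.path(td, "rgb.png"), mp),
               "non-grayscale")
})

test_that("overlays colour manual-only red, predicted-only blue, both purple", {
  td <- withr::local_tempdir()
  img <- matrix(0.2, 16, 16)
  manual <- matrix(0L, 16, 16); manual[4:8, ] <- 1L
  pred <- matrix(0L, 16, 16); pred[6:10, ] <- 1L
  out <- file.path(td, "ov.png")
  render_overlay(img, manual, pred, out)
  rgb <- png::readPNG(out)
  hi <- 0.8
  both <- rgb[, , 1] > hi & rgb[, , 3] > hi
  red_only <- rgb[, , 1] > hi & rgb[, , 3] < 0.5
  blue_only <- rgb[, , 3] > hi & rgb[, , 1] < 0.5
  expect_true(all(both[6:8, ]))
  expect_true(all(red_only[4:5, ]))
  expect_true(all(blue_only[9:10, ]))
  # identical masks: the overlay region is entirely purple
  render_overlay(img, manual, manual, out)
  rgb2 <- png::readPNG(out)
  expect_true(all((rgb2[, , 1] > hi) == (rgb2[, , 3] > hi)))
  # disjoint masks: no purple anywhere
  pred2 <- matrix(0L, 16, 16); pred2[12:14, ] <- 1L
  render_overlay(img, manual, pred2, out)
  rgb3 <- png::readPNG(out)
  expect_false(any(rgb3[, , 1] > hi & rgb3[, , 3] > hi))
  expect_error(render_overlay(img, manual[1:4, ], pred, out), "shape")
})

test_that("run configs merge user YAML over printed defaults", {
  def <- default_run_config()
  expect_equal(def$train$learning_rate, 0.001)
  expect_equal(def$model$encoder_depth, 2L)
  td <- withr::local_tempdir()
  yaml::write_yaml(list(train = list(learning_rate = 0.01),
                        phantom = list(width = 128)),
                   file.path(td, "cfg.yaml"))
  cfg <- load_run_config(file.path(td, "cfg.yaml"))
  expect_equal(cfg$train$learning_rate, 0.01)
  expect_equal(cfg$phantom$width, 128)
  expect_equal(cfg$train$batch_size, def$train$batch_size)
  expect_error(load_run_config(file.path(td, "missing.yaml")), "not found")
})

test_that("the CLI chains generate and evaluate deterministically", {
  td <- withr::local_tempdir()
  out1 <- file.path(td, "d1"); out2 <- file.path(td, "d2")
  cfgf <- file.path(td, "ph.yaml")
  yaml::write_yaml(list(phantom = unclass(tiny_spec())), cfgf)
  expect_equal(main_cli(c("generate", "--n", "4", "--seed", "11",
                          "--config", cfgf, "--out", out1)), 0L)
  expect_equal(main_cli(c("generate", "--n", "4", "--seed", "11",
                          "--config", cfgf, "--out", out2)), 0L)
  f1 <- list.files(out1, pattern = "png$", full.names = TRUE)
  f2 <- list.files(out2, pattern = "png$", full.names = TRUE)
  expect_equal(length(f1), 8)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_true(file.exists(file.path(out1, "provenance.json")))
  # evaluate the generated masks against themselves: all-perfect report
  masks <- file.path(td, "masks")
  dir.create(masks)
  file.copy(list.files(out1, pattern = "mask", full.names = TRUE), masks)
  rep_csv <- file.path(td, "report.csv")
  expect_equal(main_cli(c("evaluate", "--pred", masks, "--truth", masks,
                          "--out", rep_csv)), 0L)
  tab <- read.csv(rep_csv)
  expect_true(all(c("accuracy", "precision", "recall", "jaccard", "dice",
                    "mae", "hausdorff") %in% names(tab)))
  expect_true(all(tab$dice[tab$image != "pooled"] == 1))
  # thickness + agreement chain
  et_csv <- file.path(td, "et.csv")
  expect_equal(main_cli(c("thickness", "--masks", masks, "--pitch-um", "5.5",
                          "--out", et_csv)), 0L)
  et <- read.csv(et_csv)
  expect_equal(nrow(et), 4)
  agr <- file.path(td, "agree.json")
  expect_equal(main_cli(c("agree", "--manual", et_csv, "--auto", et_csv,
                          "--out", agr)), 0L)
  ag <- jsonlite::read_json(agr)
  expect_equal(ag$bias_um, 0)
  expect_equal(main_cli(c("frobnicate")), 1L)
  expect_equal(main_cli(character(0)), 1L)
  expect_equal(main_cli(c("generate", "--n", "2")), 1L)  # missing --seed
})
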