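test_that("msi text files round-trip samples exactly", {
  ax <- tiny_axis()
  set.seed(11)
  s <- generate_sample(layout_three_class(c(6, 6), border = 1),
                       tiny_profiles(), noise_model(), ax,
                       sample_id = "RT1", patient_id = "PZ")$sample
  f <- withr::local_tempfile(fileext = ".txt")
  write_msi_text(s, f)
  s2 <- read_msi_text(f)
  expect_identical(s2$intensities, s$intensities)
  expect_identical(s2$grid, s$grid)
  expect_equal(as.numeric(s2$mz), as.numeric(s$mz))
  expect_identical(s2$background, s$background)
  expect_identical(s2$sample_id, "RT1")
  expect_identical(s2$patient_id, "PZ")
  # write/read/write is idempotent at the byte level
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_msi_text(s2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("flagged background spectra survive; missing lines become background", {
  ax <- mass_axis(mz_min = 100, mz_max = 101, n_channels = 5)
  x <- matrix(seq_len(4 * 5), 4, 5)
  s <- msi_sample(x, c(2, 2), ax, background = c(FALSE, TRUE, FALSE, FALSE))
  f <- withr::local_tempfile(fileext = ".txt")
  write_msi_text(s, f)
  s2 <- read_msi_text(f)
  expect_identical(s2$background, c(FALSE, TRUE, FALSE, FALSE))
  # the glass pixel's recorded noise spectrum is preserved
  expect_equal(s2$intensities, x, ignore_attr = TRUE)

  # a pixel with no spectrum line at all is background with zero signal
  lines <- readLines(f)
  writeLines(lines[!grepl("^1 1 ", lines)], f)
  s3 <- read_msi_text(f)
  expect_identical(s3$background, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(s3$intensities[4, ], rep(0, 5))
})

test_that("malformed files raise named parse and dimension errors", {
  ax <- mass_axis(mz_min = 100, mz_max = 101, n_channels = 5)
  s <- msi_sample(matrix(1, 1, 5), c(1, 1), ax)
  f <- withr::local_tempfile(fileext = ".txt")
  write_msi_text(s, f)

  lines <- readLines(f)
  # drop a channel from the single spectrum -> dimension error naming pixel
  body <- !grepl("^#", lines)
  broken <- lines
  broken[body] <- sub(" [0-9.e+-]+$", "", broken[body])
  writeLines(broken, f)
  expect_error(read_msi_text(f), "dimension error at pixel \\(0,0\\)")

  writeLines(lines[!grepl("^#grid", lines)], f)
  expect_error(read_msi_text(f), "#grid")

  writeLines(sub("^#grid 1 1", "#grid one 1", lines), f)
  expect_error(read_msi_text(f), "parse error")

  expect_error(read_msi_text(file.path(tempdir(), "nope.txt")),
               "no such file")
})

test_that("annotation masks round-trip through CSV with regions", {
  lab <- matrix("background", 4, 3)
  lab[2:3, 1:2] <- "cancer"
  lab[4, 3] <- "excluded"
  regions <- data.frame(region_id = 1L, f_cancer = 0.2, f_glands = 0,
                        f_stroma = 0.8)
  rmap <- matrix(NA_integer_, 4, 3); rmap[2:3, 1:2] <- 1L
  m <- annotation_mask(lab, regions, rmap)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_annotation_csv(m, f1, regions_path = f2, region_map_path = f3)
  m2 <- read_annotation_csv(f1, regions_path = f2, region_map_path = f3)
  expect_identical(m2$labels, m$labels)
  expect_equal(m2$regions, m$regions)
  expect_identical(m2$region_map, m$region_map)
})

test_that("annotation masks validate labels and compositions", {
  expect_error(annotation_mask(matrix("tumour", 1, 1)), "unknown mask label")
  expect_error(
    annotation_mask(matrix("cancer", 1, 1),
                    regions = data.frame(region_id = 1, f_cancer = 0.5,
                                         f_glands = 0.2, f_stroma = 0.2)),
    "sum to 1")
})

test_that("the packaged weight table has the published bookkeeping", {
  wt <- load_reference_weight_table()
  expect_equal(nrow(wt), 112)
  expect_false(anyDuplicated(wt$mz) > 0)
  counts <- weight_table_counts(wt)
  expect_equal(unname(counts), c(59L, 54L, 14L))
  # spot values: a feature shared by glands and stroma, one by cancer
  # and glands
  r1 <- wt[wt$mz == 233.7, ]
  expect_equal(r1$glands, -0.146)
  expect_equal(r1$stroma, 0.983)
  expect_false(r1$selected_cancer)
  expect_equal(r1$cancer, 0)
  r2 <- wt[wt$mz == 738.8, ]
  expect_equal(r2$cancer, 0.130)
  expect_equal(r2$glands, -0.148)
  expect_equal(r2$stroma, 0)
})

test_that("weight table loader rejects duplicate m/z rows", {
  wt <- read.csv(system.file("extdata", "reference_weight_table.csv",
                             package = "desilasso"))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(rbind(wt, wt[1, ]), f, row.names = FALSE, na = "")
  expect_error(load_reference_weight_table(f), "duplicate")
})

test_that("packaged confusion fixtures carry the published pixel counts", {
  tr <- load_reference_confusion("training")
  expect_equal(attr(tr, "n_pixels"), 45273L)
  expect_equal(unname(rowSums(tr)), c(9870, 34014, 1389))
  va <- load_reference_confusion("validation")
  expect_equal(attr(va, "n_pixels"), 31235L)
  expect_equal(unname(as.vector(diag(va))), c(6448, 23814, 523))
})
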