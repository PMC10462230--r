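rect_region <- function(x0, y0, w, h, label = "tumor", id = "r1") {
  annotated_region(id, "s1",
                   rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h),
                         c(x0, y0 + h)),
                   label)
}

test_that("a minimal triangular annotation reads back as one region", {
  tri <- annotated_region("t1", "s1",
                          rbind(c(0, 0), c(100, 0), c(50, 80)), "tumor")
  path <- withr::local_tempfile(fileext = ".geojson")
  write_annotations(list(tri), path)
  regs <- read_annotations(path, slide_id = "s1")
  expect_length(regs, 1)
  expect_equal(regs[[1]]$label_name, "tumor")
  expect_equal(nrow(regs[[1]]$contour), 3)
})

test_that("one region per tissue class round-trips with distinct labels", {
  cls <- histology_classes()
  regs <- lapply(0:15, function(k) {
    rect_region(300 * k, 0, 200, 200, label = cls$name[k + 1],
                id = sprintf("r%d", k))
  })
  path <- withr::local_tempfile(fileext = ".geojson")
  write_annotations(regs, path)
  back <- read_annotations(path, slide_id = "s1")
  expect_length(back, 16)
  expect_setequal(vapply(back, `[[`, character(1), "label_name"),
                  cls$name[1:16])
  ## coordinate round trip is lossless well below 1e-6 px
  for (i in seq_along(regs)) {
    expect_lt(max(abs(back[[i]]$contour - regs[[i]]$contour)), 1e-9)
  }
})

test_that("invalid annotation inputs produce labeled errors", {
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines("{not json", path)
  expect_error(read_annotations(path), "malformed JSON")
  expect_error(
    annotated_region("bad1", "s", rbind(c(0, 0), c(1, 1)), "tumor"),
    "bad1.*fewer than 3"
  )
  expect_error(
    annotated_region("r", "s", rbind(c(0, 0), c(1, 0), c(2, 0)), "tumor"),
    "zero area"
  )
  expect_error(
    annotated_region("r", "s", rbind(c(0, 0), c(9, 0), c(0, 9)), "glia"),
    "unknown histology class.*valid names"
  )
})

test_that("tile containment fraction follows exact rectangle arithmetic", {
  big <- rect_region(0, 0, 1000, 1000)
  expect_true(region_contains_tile(big, c(100, 100), 0.9))
  ## half-covered tile fails a 0.9 threshold
  halfp <- rect_region(0, 0, 112, 224)
  expect_false(region_contains_tile(halfp, c(0, 0), 0.9))
  ## a rectangle covering exactly 90% passes inclusively
  r90 <- rect_region(0, 0, 0.9 * 224, 224)
  expect_true(region_contains_tile(r90, c(0, 0), 0.9))
  expect_false(region_contains_tile(r90, c(0, 0), 0.95))
  ## a polygon hole is subtracted from the covered area
  holed <- annotated_region(
    "h", "s",
    rbind(c(0, 0), c(224, 0), c(224, 224), c(0, 224)),
    "tumor",
    holes = list(rbind(c(50, 50), c(162, 50), c(162, 162), c(50, 162)))
  )
  frac <- 1 - 112 * 112 / 224^2
  expect_true(region_contains_tile(holed, c(0, 0), frac - 1e-6))
  expect_false(region_contains_tile(holed, c(0, 0), frac + 1e-3))
})

test_that("containment is translation invariant and monotone in the threshold", {
  set.seed(7)
  for (rep in 1:5) {
    poly <- cbind(runif(5, 0, 400), runif(5, 0, 400))
    reg <- tryCatch(annotated_region("p", "s", poly, "stroma"),
                    error = function(e) NULL)
    if (is.null(reg)) next
    tile <- c(runif(1, 0, 200), runif(1, 0, 200))
    shift <- c(37, 91)
    reg2 <- annotated_region("p", "s",
                             sweep(reg$contour, 2, shift, `+`), "stroma")
    for (mf in c(0.1, 0.5, 0.9)) {
      expect_equal(region_contains_tile(reg, tile, mf),
                   region_contains_tile(reg2, tile + shift, mf))
    }
    ## retained set shrinks as the threshold grows
    fr <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                 function(mf) region_contains_tile(reg, tile, mf),
                 logical(1))
    expect_true(all(diff(as.integer(fr)) <= 0))
  }
})

test_that("outcome tables are read with validated counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  dev <- data.frame(
    patient_id = sprintf("P%03d", 1:85),
    outcome = c(rep("pCR", 51), rep("RD", 34))
  )
  write_outcomes(dev, path)
  tab <- suppressMessages(read_outcomes(path, "development"))
  expect_equal(nrow(tab), 85)
  expect_equal(as.vector(table(tab$outcome)), c(51, 34))

  val <- data.frame(
    patient_id = sprintf("V%03d", 1:79),
    outcome = c(rep("pCR", 41), rep("RD", 38))
  )
  write_outcomes(val, path)
  expect_equal(nrow(suppressMessages(read_outcomes(path, "validation"))), 79)

  writeLines("patient_id,outcome", path)
  empty <- suppressMessages(read_outcomes(path, "development"))
  expect_equal(nrow(empty), 0)

  writeLines(c("patient_id,outcome", "P1,pCR", "P1,RD"), path)
  expect_error(suppressMessages(read_outcomes(path, "development")),
               "duplicate")
  writeLines(c("patient_id,outcome", "P1,partial"), path)
  expect_error(suppressMessages(read_outcomes(path, "development")),
               "outside")
})
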