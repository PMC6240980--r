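test_that("ratings round-trip through long CSV bit-identically", {
  b <- smallBundle(3L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeRatings(b$colorEmotion, path)
  back <- loadRatings(path, b$colors, scaleTable(b$colorEmotion),
                      subjectIds(b$colorEmotion))
  expect_identical(dimnames(ratingValues(back)),
                   dimnames(ratingValues(b$colorEmotion)))
  expect_equal(ratingValues(back), ratingValues(b$colorEmotion),
               tolerance = 1e-12)
})

test_that("loading is row-order invariant and matches a directly built array", {
  stim <- StimulusSet(c("s1", "s2", "s3"), "music")
  scales <- bipolarScales(c("happy/sad", "warm/cool"))
  subjects <- c("k1", "k2")
  vals <- array(seq_len(12), dim = c(3, 2, 2))
  tensor <- RatingsTensor(vals, stim, scales, subjects)
  path <- withr::local_tempfile(fileext = ".csv")
  writeRatings(tensor, path)
  df <- read.csv(path)
  set.seed(42)
  write.csv(df[sample(nrow(df)), ], path, row.names = FALSE, quote = FALSE)
  back <- loadRatings(path, stim, scales, subjects)
  expect_equal(ratingValues(back), ratingValues(tensor), tolerance = 0,
               ignore_attr = FALSE)
})

test_that("missing, duplicated, unknown and out-of-range cells are named", {
  stim <- StimulusSet(c("s1", "s2"), "music")
  scales <- bipolarScales("happy/sad", bound = 10)
  df <- data.frame(stimulus = c("s1", "s2"), scale = "happy/sad",
                   subject = "k1", value = c(1, 2))
  path <- withr::local_tempfile(fileext = ".csv")

  write.csv(df[-2L, ], path, row.names = FALSE)
  expect_error(loadRatings(path, stim, scales, "k1"),
               "missing cell \\(s2, happy/sad, k1\\)")

  write.csv(rbind(df, df[1L, ]), path, row.names = FALSE)
  expect_error(loadRatings(path, stim, scales, "k1"), "duplicated cell")

  df2 <- df; df2$value[2L] <- 11
  write.csv(df2, path, row.names = FALSE)
  expect_error(loadRatings(path, stim, scales, "k1"), "out of range")

  df3 <- df; df3$stimulus[2L] <- "sX"
  write.csv(df3, path, row.names = FALSE)
  expect_error(loadRatings(path, stim, scales, "k1"), "unknown stimulus")
})

test_that("choice tables enforce the six-distinct-colors task structure", {
  colors <- StimulusSet(sprintf("c%d", 1:8), "color")
  excerpts <- StimulusSet("M01", "music")
  path <- withr::local_tempfile(fileext = ".csv")

  good <- choiceFixture(sprintf("c%d", 1:6))
  writeChoices(good, path)
  loaded <- loadChoices(path, colors, excerpts)
  expect_equal(nrow(choiceRecords(loaded)), 6L)

  rec <- choiceRecords(good)
  rec$color[rec$slot == "worst1"] <- "c1"  # same color as best1
  expect_error(ChoiceTable(rec), "duplicate color")

  expect_error(ChoiceTable(choiceRecords(good)[-1L, ]), "exactly 6 slots")

  rec <- choiceRecords(good); rec$color[1L] <- "zz"
  write.csv(rec, path, row.names = FALSE)
  expect_error(loadChoices(path, colors, excerpts), "unknown color")
})

test_that("a full-size choice table has 30 x 34 x 6 records", {
  b <- generateBundle(analysisConfig(synthetic = list(seed = 11L)))
  expect_equal(nrow(choiceRecords(b$choices)), 30L * 34L * 6L)
  expect_equal(length(unique(choiceRecords(b$choices)$subject)), 30L)
  expect_equal(length(unique(choiceRecords(b$choices)$excerpt)), 34L)
})

test_that("validateBundle reports zero findings on a consistent bundle and
           exactly the planted faults otherwise", {
  b <- smallBundle(5L)
  expect_equal(nrow(validateBundle(b)), 0L)

  # plant two inconsistencies: one unknown color id in the choices, and a
  # color-appearance tensor whose stimulus ids do not match
  rec <- choiceRecords(b$choices)
  cell <- rec$subject == rec$subject[1L] & rec$excerpt == rec$excerpt[1L]
  rec$color[cell & rec$slot == "best1"] <- "NOT_A_COLOR"
  b$choices <- ChoiceTable(rec)
  otherColors <- StimulusSet(paste0("x", seq_along(b$colors@ids)), "color")
  b$colorAppearance <- RatingsTensor(
    ratingValues(b$colorAppearance), otherColors,
    scaleTable(b$colorAppearance), subjectIds(b$colorAppearance))
  findings <- validateBundle(b)
  expect_equal(nrow(findings), 2L)
  expect_true(any(grepl("NOT_A_COLOR", findings$issue)))

  # idempotent and side-effect-free
  expect_identical(validateBundle(b), findings)
})

test_that("attribute tables round-trip and reorder to the color set", {
  b <- smallBundle(6L)
  attrs <- acrossSubjectMeans(b$colorAppearance)
  path <- withr::local_tempfile(fileext = ".csv")
  writeAttributeTable(attrs, path)
  back <- readAttributeTable(path, b$colors)
  expect_equal(back, attrs, tolerance = 1e-9)
})

test_that("config validation enforces the weight and parafac invariants", {
  expect_error(analysisConfig(mcaWeights = c(best1 = 1, best2 = 1, best3 = 1,
                                             worst1 = -1, worst2 = -1,
                                             worst3 = 0)), "sum to 0")
  expect_error(analysisConfig(parafac = list(nFactors = 0L)), "nFactors")
  expect_error(analysisConfig(synthetic = list(mode = "other")), "mode")
  cfg <- analysisConfig()
  expect_s3_class(cfg, "emomediateConfig")
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(synthetic = list(nSubjects = 4L, seed = 9L),
                        correction = "bonferroni"), path)
  cfg2 <- readAnalysisConfig(path)
  expect_equal(cfg2$synthetic$nSubjects, 4L)
  expect_equal(cfg2$correction, "bonferroni")
})
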