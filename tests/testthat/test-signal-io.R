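test_that("manifest totals and invariants", {
  expect_identical(manifest_total(kuhar_manifest()), 20750L)
  expect_identical(manifest_total(activity_manifest(character(0), integer(0))), 0L)
  expect_identical(manifest_total(activity_manifest(c("a", "b"), c(10, 20))), 30L)
  expect_error(activity_manifest(c("a", "a"), c(1, 2)), "unique")
  expect_error(activity_manifest("a", -1), "non-negative")
})

test_that("CSV round trip is bit-exact in both label modes", {
  ds <- toy_dataset(c(3, 2), T = 5L, C = 3L, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path, csv_layout(T = 5L, C = 3L), ds$manifest)
  expect_true(harformer:::dataset_equal(ds, back))

  # per-timestep labels (as produced by augmentation)
  mixed <- ds
  mixed$windows[[1]]$labels <- c(0L, 0L, 1L, 1L, 1L)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(mixed, path2,
                    csv_layout(T = 5L, C = 3L, label_mode = "timestep"))
  back2 <- read_dataset_csv(path2,
                            csv_layout(T = 5L, C = 3L, label_mode = "timestep"),
                            ds$manifest)
  expect_true(harformer:::dataset_equal(mixed, back2))
})

test_that("values land at the documented flat indices t*C + c", {
  T <- 300L; C <- 6L
  w1 <- signal_window(matrix(0, T, C), 0L, "a")
  w1$values[1, 1] <- 123.456       # t = 0, c = 0 -> flat 0
  w1$values[T, C] <- -7.89         # t = 299, c = 5 -> flat 1799
  w2 <- signal_window(matrix(1, T, C), 0L, "b")
  ds <- window_dataset(list(w1, w2), activity_manifest("only", 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path, csv_layout(T = T, C = C, header = FALSE))
  row1 <- strsplit(readLines(path, n = 1L), ",")[[1]]
  expect_equal(as.numeric(row1[1]), 123.456)       # flat index 0
  expect_equal(as.numeric(row1[1800]), -7.89)      # flat index 1799
  expect_length(row1, T * C + 1L)
})

test_that("malformed rows and bad labels are reported with the row number", {
  path <- withr::local_tempfile(fileext = ".csv")
  lay <- csv_layout(T = 2L, C = 2L, header = FALSE)
  writeLines(c("1,2,3,4,0", "1,2,3,0"), path)     # row 2 is short one value
  expect_error(read_dataset_csv(path, lay), "row 2")
  writeLines(c("1,2,3,4,0", "1,2,3,4,7"), path)
  expect_error(read_dataset_csv(path, lay, activity_manifest(c("a", "b"))),
               "label outside 0..1.*row 2")
  expect_error(read_dataset_csv("no/such/file.csv", lay), "not found")
})

test_that("stratified split hits per-class targets and conserves windows", {
  ds <- toy_dataset(c(100, 100, 100, 100))
  parts <- stratified_split(ds, c(0.70, 0.15, 0.15), seed = 1)
  expect_identical(unname(observed_counts(parts$train)), rep(70L, 4))
  expect_identical(unname(observed_counts(parts$validation)), rep(15L, 4))
  expect_identical(unname(observed_counts(parts$test)), rep(15L, 4))
  n <- vapply(parts, function(d) length(d$windows), integer(1))
  expect_identical(sum(n), 400L)
  ids <- unname(unlist(lapply(parts, function(d)
    vapply(d$windows, `[[`, "", "window_id"))))
  expect_identical(sort(ids),
                   sort(vapply(ds$windows, `[[`, "", "window_id")))
})

test_that("split respects degenerate ratios, determinism, and remainders", {
  ds <- toy_dataset(c(7, 5))
  all_train <- stratified_split(ds, c(1, 0, 0), seed = 1)
  expect_true(harformer:::dataset_equal(all_train$train, ds))
  expect_length(all_train$validation$windows, 0L)

  id_of <- function(parts) lapply(parts, function(d)
    sort(vapply(d$windows, `[[`, "", "window_id")))
  expect_identical(id_of(stratified_split(ds, seed = 7)),
                   id_of(stratified_split(ds, seed = 7)))
  expect_false(identical(id_of(stratified_split(ds, seed = 7)),
                         id_of(stratified_split(ds, seed = 8))))

  # per-class partition counts never deviate from count*ratio by more than 1
  ds2 <- toy_dataset(c(11, 23, 5))
  parts <- stratified_split(ds2, c(0.6, 0.2, 0.2), seed = 2)
  for (k in 1:3) {
    got <- c(observed_counts(parts$train)[k], observed_counts(parts$validation)[k],
             observed_counts(parts$test)[k])
    expect_true(all(abs(got - c(11, 23, 5)[k] * c(0.6, 0.2, 0.2)) <= 1))
  }
  expect_error(stratified_split(toy_dataset(c(2, 50)), c(0.4, 0.3, 0.3)),
               "fewer than")
  expect_error(stratified_split(ds, c(0.5, 0.5, 0.1)), "sum to 1")
})

test_that("layout configs load from YAML and JSON", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines("T: 4\nC: 2\nlabel_mode: timestep\nheader: false", y)
  lay <- read_csv_layout(y)
  expect_identical(lay$T, 4L)
  expect_identical(lay$label_mode, "timestep")
  expect_false(lay$header)
  j <- withr::local_tempfile(fileext = ".json")
  writeLines('{"T": 3, "C": 6}', j)
  expect_identical(read_csv_layout(j)$T, 3L)
})
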