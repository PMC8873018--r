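make_meta <- function() {
  data.frame(
    subject_id = c("a", "a", "b", "b", "c", "d"),
    scan_id = paste0("s", 1:6),
    group = c("ctrl", "ctrl", "case", "case", "ctrl", "case"),
    age = c(6, 8, 10, 12.5, 20, 30),
    sex = c("F", "F", "M", "M", "F", "M"),
    scanner = c("A", "A", "B", "B", "C", "A"))
}

test_that("consistent data assembles into a dataset; loaders agree", {
  mesh <- make_mesh(1L)
  meta <- make_meta()
  measures <- matrix(3 + rnorm(6 * 42, 0, 0.1), 6L, 42L)
  ds <- longitudinal_dataset(mesh, meta, measures)
  expect_s3_class(ds, "surf_dataset")
  expect_equal(nrow(ds$metadata), 6L)
  expect_equal(levels(ds$metadata$group), c("case", "ctrl"))

  mp <- tempfile(fileext = ".tsv")
  cp <- tempfile(fileext = ".csv")
  write_matrix_tsv(measures, mp)
  write.csv(meta, cp, row.names = FALSE)
  ds2 <- load_vertex_maps(mp, mesh, cp)
  expect_equal(ds2$measures, ds$measures, tolerance = 1e-7)
  expect_equal(as.character(ds2$metadata$subject_id),
               as.character(ds$metadata$subject_id))

  # per-scan curv files give the same matrix
  paths <- vapply(1:6, function(i) {
    f <- tempfile(fileext = ".curv")
    write_vertex_map(measures[i, ], f, "curv")
    f
  }, character(1))
  ds3 <- load_vertex_maps(paths, mesh, cp, format = "curv")
  expect_equal(ds3$measures, measures, tolerance = 1e-6)
})

test_that("dataset invariant violations are reported with specifics", {
  mesh <- make_mesh(1L)
  meta <- make_meta()
  measures <- matrix(3, 6L, 42L)

  bad <- meta
  bad$group[2L] <- "case"  # subject a now in two groups
  expect_error(longitudinal_dataset(mesh, bad, measures),
               "inconsistent group: a")

  bad <- meta
  bad$scan_id[2L] <- "s1"
  expect_error(longitudinal_dataset(mesh, bad, measures), "duplicate scan_id")

  m2 <- measures
  m2[3L, 7L] <- NA
  expect_error(longitudinal_dataset(mesh, meta, m2),
               "scan row 3, vertex 7")

  expect_error(longitudinal_dataset(mesh, meta, measures[, 1:10]),
               "mesh vertices")
  expect_error(longitudinal_dataset(mesh, meta[1:5, ], measures),
               "metadata rows")

  bad <- meta
  bad$age[1L] <- 150
  expect_error(longitudinal_dataset(mesh, bad, measures), "age out of range")

  # missing values outside the mask are tolerated
  mesh2 <- set_mesh_mask(mesh, c(FALSE, rep(TRUE, 41L)))
  m3 <- measures
  m3[1L, 1L] <- NA
  expect_s3_class(longitudinal_dataset(mesh2, meta, m3), "surf_dataset")
})

test_that("psychosis status classification applies the >=3 criterion", {
  floor_case <- data.frame(subject_id = "s1", p1 = 0, p2 = 0, p3 = 0,
                           p4 = 0, p5 = 0)[c(1, 1), ]
  expect_equal(as.character(classify_psychosis_status(floor_case)), "N-PS")

  # P4 = 3 at the second of three assessments
  s <- data.frame(subject_id = rep("s2", 3L), p1 = c(1, 2, 0),
                  p2 = c(0, 1, 1), p3 = c(2, 2, 2), p4 = c(1, 3, 0),
                  p5 = c(0, 0, 2))
  expect_equal(as.character(classify_psychosis_status(s)), "LA-PS")

  # all scales at 2 stay below threshold
  s2 <- data.frame(subject_id = rep("s3", 4L), p1 = 2, p2 = 2, p3 = 2,
                   p4 = 2, p5 = 2)
  expect_equal(as.character(classify_psychosis_status(s2)), "N-PS")

  expect_error(classify_psychosis_status(s[0, ]), "empty")
  expect_error(classify_psychosis_status(transform(s, p2 = 7)), "0-6")
})

test_that("classification is invariant to assessment order and subscale permutation", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:4, 1L)
    s <- data.frame(subject_id = "x",
                    matrix(sample(0:6, 5L * n, replace = TRUE), n, 5L))
    names(s)[2:6] <- paste0("p", 1:5)
    base <- classify_psychosis_status(s)
    shuffled <- s[sample(n), ]
    expect_identical(classify_psychosis_status(shuffled), base)
    perm <- s
    names(perm)[2:6] <- paste0("p", sample(1:5))
    expect_identical(classify_psychosis_status(perm), base)
  }
})
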