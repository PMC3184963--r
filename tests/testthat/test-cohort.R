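test_that("config validation fills defaults and reports all errors at once", {
  cfg <- validate_config(list())
  expect_s3_class(cfg, "fma_run_config")
  expect_equal(cfg$voxel_z, 0.8141)
  expect_equal(cfg$n_glomeruli_per_animal, 6)
  expect_equal(length(cfg$groups), 2)
  err <- tryCatch(validate_config(list(bogus_key = 1, size_scale = -2)),
                  error = conditionMessage)
  expect_match(err, "bogus_key")
  expect_match(err, "size_scale")
  expect_error(validate_config(list(groups = list(
    list(name = "a", preset = "sham", n_animals = 5),
    list(name = "b", preset = "snx", n_animals = 5, dropout = 1.5)))),
    "dropout")
  expect_error(validate_config(list(groups = list(
    list(name = "a", preset = "nope", n_animals = 5),
    list(name = "b", preset = "sham", n_animals = 5)))),
    "preset")
})

test_that("a YAML config round-trips through validation", {
  d <- withr::local_tempdir()
  f <- file.path(d, "cohort.yaml")
  yaml::write_yaml(list(seed = 7, groups = list(
    list(name = "ctrl", preset = "sham", n_animals = 3),
    list(name = "dz", preset = "snx", n_animals = 3))), f)
  cfg <- validate_config(f)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$groups[[1]]$name, "ctrl")
  expect_equal(cfg$voxel_z, 0.8141)
})

test_that("cohort reruns are byte-identical and reproduce the disease pattern", {
  cfg <- list(seed = 314, groups = list(
    list(name = "sham", preset = "sham", n_animals = 3),
    list(name = "snx", preset = "snx", n_animals = 3)))
  d1 <- file.path(withr::local_tempdir(), "r1")
  d2 <- file.path(withr::local_tempdir(), "r2")
  r1 <- run_cohort(c(cfg, list(out = d1)))
  r2 <- run_cohort(c(cfg, list(out = d2)))
  expect_identical(r1$measurements, r2$measurements)
  expect_identical(readLines(file.path(d1, "metrics.csv")),
                   readLines(file.path(d2, "metrics.csv")))
  expect_true(file.exists(file.path(d1, "stats.json")))
  expect_true(file.exists(file.path(d1, "run.log.jsonl")))
  expect_true(file.exists(file.path(d1, "config-echo.yaml")))
  m <- r1$measurements
  sham <- m[m$group == "sham", ]; snx <- m[m$group == "snx", ]
  expect_gt(mean(snx$glomerular_volume), mean(sham$glomerular_volume))
  expect_gt(mean(snx$glomerular_capillary_volume),
            mean(sham$glomerular_capillary_volume))
  expect_lt(mean(snx$glomerular_capillary_density),
            mean(sham$glomerular_capillary_density))
  expect_lt(mean(snx$peritubular_capillary_density),
            mean(sham$peritubular_capillary_density))
})

test_that("the run log records every threshold and filter actually applied", {
  cfg <- list(seed = 9, groups = list(
    list(name = "a", preset = "sham", n_animals = 2),
    list(name = "b", preset = "snx", n_animals = 2)))
  res <- run_cohort(cfg)
  gl <- Filter(function(e) e$stage == "glomerulus", res$log)
  cx <- Filter(function(e) e$stage == "cortex", res$log)
  expect_length(gl, 4 * res$config$n_glomeruli_per_animal)
  expect_length(cx, 4)
  for (e in res$log) {
    expect_true(is.finite(e$threshold))
    expect_equal(e$threshold_method, "otsu")
    expect_true(e$min_voxels >= 0)
    expect_true(e$connectivity %in% c(6, 18, 26))
  }
})
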