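test_that("packaged phase-property table carries the published digits", {
  tab <- abs_phase_table()
  expect_equal(nrow(tab), 12)
  bp12 <- tab[tab$system_id == "BP#12", ]
  expect_identical(bp12$volume_ratio, 0.60)
  bp5 <- tab[tab$system_id == "BP#5", ]
  expect_identical(bp5$il_rich_ph, 6.75)
  expect_identical(bp5$non_il_rich_ph, 6.75)
  bp3 <- tab[tab$system_id == "BP#3", ]
  expect_identical(bp3$il_rich_w_il, 54.0350)
  expect_identical(bp3$il_rich_w_non, 0.3349)
  expect_identical(bp3$il_rich_w_water, 43.6779)
  # stored as published: compositions are kept un-normalized and their
  # closure deviation (up to ~3.1 wt% across the measured rows) flagged
  for (i in seq_len(nrow(tab))) {
    cm <- validate_composition(tab$il_rich_w_il[i], tab$il_rich_w_non[i],
                               tab$il_rich_w_water[i], normalize = FALSE,
                               closure_tol = 3.5)
    expect_s3_class(cm, "ternary_composition")
    expect_lt(abs(attr(cm, "closure_dev")), 3.5)
  }
})

test_that("packaged Kd and Tm tables load with the published values", {
  kd <- kd_table()
  expect_equal(nrow(kd), 8)
  expect_equal(sum(!kd$binding_detected), 4)
  first_cac <- kd[kd$regime == "1st CAC", ]
  expect_identical(sort(first_cac$kd_mM), c(1.27, 6.05))
  expect_identical(sort(first_cac$kd_sd_mM), c(0.64, 1.67))

  tm <- tm_table()
  expect_identical(tm$tm_c[tm$sample == "Lys in water (DSC curve)"], 74.56)
  three <- tm$tm_c[grepl("transition", tm$sample)]
  expect_identical(three, c(80.04, 83.39, 86.40))
})

test_that("pipeline runs stages in dependency order and reproduces itself", {
  m <- binodal_model(80, -0.3, 5e-5)
  cfg <- list(
    binodal = list(points = gen_binodal(m, 25, noise_sd = 0.2, seed = 4)),
    tieline = list(x_m = 6, y_m = 45, alpha = 0.6),
    partition = list(data = gen_partition(96.25, conc_noise_cv = 0.02,
                                          seed = 4))
  )
  r1 <- run_pipeline(cfg, seed = 10)
  r2 <- run_pipeline(cfg, seed = 10)
  strip <- function(r) {
    r$manifest$timestamp <- NULL
    r
  }
  expect_identical(strip(r1), strip(r2))
  expect_s3_class(r1$binodal, "binodal_model")
  expect_s3_class(r1$tieline, "tieline")
  expect_equal(r1$partition$ee_pct, 96.25, tolerance = 1)
  expect_identical(r1$manifest$defaults_used$binodal_form, "exponential")

  # missing upstream model is a dependency error
  expect_error(run_pipeline(list(tieline = list(x_m = 6, y_m = 45,
                                                alpha = 0.6))),
               "requires a fitted binodal")
  expect_error(run_pipeline(list(nonsense = list())), "unknown")
})

test_that("pipeline reports round-trip through JSON", {
  m <- binodal_model(80, -0.3, 5e-5)
  res <- run_pipeline(list(
    binodal = list(points = gen_binodal(m, 25, noise_sd = 0, seed = 4)),
    tieline = list(x_m = 6, y_m = 45, alpha = 0.6)))
  path <- tempfile(fileext = ".json")
  write_pipeline_report(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$binodal$a, res$binodal$a, tolerance = 1e-12)
  expect_equal(back$tieline$tll, res$tieline$length, tolerance = 1e-12)
  expect_identical(back$manifest$package, "filabs")
})

test_that("YAML configurations are accepted", {
  m <- binodal_model(80, -0.3, 5e-5)
  pts_file <- tempfile(fileext = ".csv")
  write.csv(gen_binodal(m, 25, noise_sd = 0, seed = 6), pts_file,
            row.names = FALSE)
  cfg_file <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(
    binodal = list(points = pts_file, form = "exponential"))), cfg_file)
  res <- run_pipeline(cfg_file)
  expect_equal(res$binodal$a, 80, tolerance = 1e-4)
})
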