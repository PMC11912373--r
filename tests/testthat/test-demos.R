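test_that("an empty configuration resolves to the documented defaults", {
  cfg <- validate_config(NULL)
  expect_identical(cfg$shape, c(256L, 256L))
  expect_identical(cfg$kernel, "ilap3")
  expect_identical(cfg$seed, 0L)
  expect_s3_class(cfg, "run_config")
  expect_match(attr(cfg, "hash"), "^[0-9a-f]+$")
})

test_that("configuration errors name the offending field", {
  expect_error(validate_config(list(experiment = "fig9")), "experiment")
  expect_error(validate_config(list(experiment = "fig2_boxes",
                                    shape = c(4L, 4L))), "shape")
  expect_error(validate_config(list(experiment = "fig3_labyrinth",
                                    gamma = list(gamma_nogo = 0))),
               "gamma.gamma_nogo")
  expect_error(validate_config(list(experiment = "fig3_labyrinth",
                                    gamma = list(gamma_go = 1.2))),
               "supercritical")
  expect_error(validate_config(list(experiment = "fig2_boxes",
                                    kernel = "mystery")), "kernel")
})

test_that("supercritical attenuation is accepted only for the synchrony run", {
  cfg <- validate_config(list(experiment = "fig4_sync",
                              gamma = list(gamma_go = 1.2)))
  expect_identical(cfg$gamma$gamma_go, 1.2)
})

test_that("YAML text and config hashing are stable", {
  cfg1 <- validate_config("experiment: fig2_boxes\nseed: 7\n")
  expect_identical(cfg1$seed, 7L)
  cfg2 <- validate_config(list(experiment = "fig2_boxes", seed = 7L))
  expect_identical(attr(cfg1, "hash"), attr(cfg2, "hash"))
  expect_false(identical(attr(cfg1, "hash"),
                         attr(validate_config(NULL), "hash")))
})

test_that("the boxes demo runs end-to-end at reduced scale", {
  res <- run_demo("fig2_boxes",
                  list(shape = c(64L, 64L), n_steps = 600L,
                       rms_window = 256L,
                       gamma = list(wall_thickness = 8L, hole_width = 8L)))
  m <- res$metrics
  expect_true(all(c("intact", "hole", "config_hash") %in% names(m)))
  expect_lt(m$intact$containment_ratio, m$hole$containment_ratio)
  expect_true(file.exists(file.path(res$out_dir, "metrics.json")))
  expect_true(file.exists(file.path(res$out_dir, "config.yaml")))
  expect_true(file.exists(file.path(res$out_dir, "final_intact.png")))
  written <- jsonlite::read_json(file.path(res$out_dir, "metrics.json"))
  expect_equal(written$intact$containment_ratio, m$intact$containment_ratio,
               tolerance = 1e-12)
})

test_that("the band demo reports per-band metrics at reduced scale", {
  res <- run_demo("fig1_band",
                  list(shape = 256L, n_steps = 1500L, rms_window = 512L,
                       gamma = list(band_L = c(0L, 3L))))
  expect_length(res$metrics$right_rms, 2)
  expect_true(file.exists(file.path(res$out_dir, "rms_L0.csv")))
  expect_true(is.numeric(res$metrics$per_band[["3"]]$band_slope))
})

test_that("the synchrony demo runs and reports domain statistics", {
  res <- run_demo("fig4_sync",
                  list(shape = c(96L, 96L), n_steps = 1000L,
                       rms_window = 0L,
                       gamma = list(lag = 200L, min_size = 30L,
                                    threshold_quantile = 0.68)))
  expect_true(is.numeric(res$metrics$frac_synchronized))
  expect_gte(res$metrics$n_domains, 2)
})

test_that("the lighthouse demo tracks the rotating gap", {
  res <- run_demo("fig5_lighthouse",
                  list(shape = c(96L, 96L), n_steps = 1200L,
                       rms_window = 0L,
                       gamma = list(n_angles = 4L, taper_width = 6L)))
  expect_length(res$metrics$angular_error, 4)
  expect_true(all(res$metrics$angular_error >= 0 &
                    res$metrics$angular_error <= pi))
})

test_that("the dense demo reports graded band attenuation", {
  res <- run_demo("fig6_dense",
                  list(shape = 256L, n_steps = 1200L, rms_window = 512L,
                       gamma = list(band_L = c(0L, 5L), rho = 0.1)))
  expect_length(res$metrics$right_rms, 2)
  expect_lt(res$metrics$right_rms[2], res$metrics$right_rms[1])
})

test_that("demo runs are reproducible for identical config and seed", {
  ov <- list(shape = c(64L, 64L), n_steps = 300L, rms_window = 128L)
  r1 <- run_demo("fig3_labyrinth", ov)
  r2 <- run_demo("fig3_labyrinth", ov)
  expect_identical(r1$metrics$oracle_agreement, r2$metrics$oracle_agreement)
  expect_identical(readRDS(file.path(r1$out_dir, "final.rds")),
                   readRDS(file.path(r2$out_dir, "final.rds")))
})
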