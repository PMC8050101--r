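test_that("configs with unknown keys are rejected loudly", {
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(R = 2.5, L = 1.2, c = 2, bogus_key = 1), cfg,
                       auto_unbox = TRUE)
  expect_error(read_sim_config(cfg), "bogus_key")
  jsonlite::write_json(list(R = 2.5, L = 1.2, c = 2), cfg,
                       auto_unbox = TRUE)
  expect_equal(read_sim_config(cfg)$R, 2.5)
  unlink(cfg)
})

test_that("synth then quantify produces the full output set", {
  out1 <- file.path(tempdir(), "synth_out")
  cmd_synth(c("--kind", "membrane_shell", "--n", "1", "--seed", "4",
              "--out", out1, "--R_ves", "6"))
  base <- file.path(out1, "membrane_shell_001")
  expect_true(file.exists(paste0(base, "_actin.tif")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  out2 <- file.path(tempdir(), "quant_out")
  cmd_quantify(c("--stack", base, "--out", out2))
  expect_true(file.exists(file.path(out2, "proximity.csv")))
  prox <- read.csv(file.path(out2, "proximity.csv"))
  expect_true("P" %in% names(prox))
  # shell fixture rendered with the default PSF: strongly membrane-proximal
  expect_gt(prox$P[1], 0.75)
  expect_true(file.exists(file.path(out2, "skeleton.swc")))
  expect_true(file.exists(file.path(out2, "ring_report.json")))
  man <- jsonlite::read_json(file.path(out2, "manifest.json"))
  expect_equal(man$command, "quantify")
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("a small sweep writes per-condition and per-replicate outputs", {
  grid <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(conditions = list(list(boundary_mode = "confine_only"),
                           list(boundary_mode = "confine_attract")),
         base = list(R = 1.2, L = 0.4, c = 1, total_time = 2e-4,
                     snapshot_interval = 1e-4,
                     polymerization_rate = 100)),
    grid, auto_unbox = TRUE)
  out <- file.path(tempdir(), "sweep_out")
  cmd_sweep(c("--grid", grid, "--replicates", "2", "--seed", "3",
              "--out", out))
  tab <- read.csv(file.path(out, "ring_probability.csv"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n_ok + tab$n_failed, c(2, 2))
  expect_length(list.files(out, pattern = "^ring_report_.*json$"), 4)
  expect_length(list.files(out, pattern = "^mip_.*tif$"), 4)
  unlink(c(grid, out), recursive = TRUE)
})

test_that("simulate writes a replayable trajectory", {
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(R = 1.2, L = 0.4, c = 1, total_time = 2e-4,
                            snapshot_interval = 1e-4), cfg,
                       auto_unbox = TRUE)
  out <- file.path(tempdir(), "sim_out")
  cmd_simulate(c("--config", cfg, "--seed", "8", "--out", out))
  tr <- read_trajectory(file.path(out, "trajectory.rds"))
  expect_s3_class(tr, "trajectory")
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 8)
  # replay from the manifest reproduces the trajectory bit-identically
  out2 <- file.path(tempdir(), "sim_out2")
  cmd_simulate(c("--config", cfg, "--seed", "8", "--out", out2))
  tr2 <- read_trajectory(file.path(out2, "trajectory.rds"))
  expect_identical(final_snapshot(tr)$positions,
                   final_snapshot(tr2)$positions)
  unlink(c(cfg, out, out2), recursive = TRUE)
})
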