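test_that("training smoke run: finite logged losses and exact checkpointing", {
  ds <- tiny_dataset()
  cfg <- tiny_config(iter_total = 4L)
  fit <- facephys(ds, cfg, seed = 2)
  expect_s3_class(fit, "facephys")
  expect_equal(nrow(fit$history), 4)
  expect_true(all(is.finite(fit$history$L_total)))
  expect_true(all(fit$history$lambda >= 1 & fit$history$lambda < 2))
  path <- tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(back$par, fit$par)
  expect_identical(back$config, fit$config)
  pr1 <- predict(fit, ds$windows[1:2])
  pr2 <- predict(back, ds$windows[1:2])
  expect_identical(pr1, pr2)
  unlink(path)
})

test_that("identical seeds give identical loss trajectories and predictions", {
  ds <- tiny_dataset()
  cfg <- tiny_config(iter_total = 3L)
  f1 <- facephys(ds, cfg, seed = 7)
  f2 <- facephys(ds, cfg, seed = 7)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$par, f2$par)
  f3 <- facephys(ds, cfg, seed = 8)
  expect_false(identical(f1$history$L_total, f3$history$L_total))
})

test_that("no subject leaks across splits and all windows are covered", {
  ds <- tiny_dataset()
  cfg <- tiny_config(iter_total = 2L)
  fit <- facephys(ds, cfg, seed = 3)
  wsplit <- fit$split[ds$manifest$subject_id]
  expect_false(any(is.na(wsplit)))
  per_subj <- tapply(wsplit, ds$manifest$subject_id,
                     function(x) length(unique(x)))
  expect_true(all(per_subj == 1))
  expect_setequal(names(fit$split), unique(ds$manifest$subject_id))
})

test_that("short training on easy synthetic data reduces the objective", {
  ds <- generate_dataset(synthetic_config(
    n_subjects = 6L, windows_per_subject = 4L, fps = 10, L = 60L,
    noise_sigma = 0.002, seed = 19))
  cfg <- facephys_desk_config(d = 8L, depth = 1L, c1 = 3L, c2 = 4L,
                              stmap_channels = 4L, lm_channels = 2L,
                              head_hidden = 16L, n_state = 8L,
                              window_length = 60L, fps = 10,
                              batch_size = 4L, iter_total = 40L,
                              val_every = 10L)
  fit <- facephys(ds, cfg, seed = 5)
  h <- fit$history
  expect_lt(mean(tail(h$L_total, 5)), mean(head(h$L_total, 3)))
  # evaluation report has the full structure
  ev <- evaluate_facephys(fit, ds, "test")
  expect_named(ev, c("cog", "hr", "rr", "n_windows", "n_subjects"))
  expect_true(ev$n_windows > 0)
  expect_true(is.finite(ev$hr$mae))
})

test_that("depth sweep reuses one split and reports a row per run", {
  ds <- tiny_dataset()
  cfg <- tiny_config(iter_total = 2L)
  tb <- depth_sweep(ds, cfg, depths = c(1L, 2L), seeds = 1L, split_seed = 4)
  expect_equal(nrow(tb), 2)
  expect_equal(tb$depth, c(1L, 2L))
  expect_true(all(is.finite(tb$hr_mae)))
})

test_that("training aborts cleanly when labels are missing", {
  ds <- tiny_dataset()
  ds$windows <- lapply(ds$windows, function(w) { w$labels$hr_bpm <- NULL; w })
  expect_error(facephys(ds, tiny_config(), seed = 1), "all three labels")
})
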