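# Shared tiny fixtures: one 64x64 static environment, 6 train / 4 eval
# frames, plus two short fits reused by several blocks below.
det_train_dir <- file.path(tempdir(), "pensight-det-train")
det_eval_dir <- file.path(tempdir(), "pensight-det-eval")
generate_dataset(tiny_scene_config(), n_images = 6, out_dir = det_train_dir,
                 seed = 41)
generate_dataset(tiny_scene_config(), n_images = 4, out_dir = det_eval_dir,
                 seed = 42, env_seed = pensight:::derive_seed(41L, 0L))
det_fit_cfg <- detector_config(epochs = 8, batch_size = 4, lr = 3e-3, seed = 7)
det_fit_baseline <- pen_detector(det_train_dir, variant = "baseline",
                                 config = det_fit_cfg)
det_fit_bsi <- pen_detector(det_train_dir, variant = "big_fig",
                            config = detector_config(epochs = 5, batch_size = 4,
                                                     lr = 3e-3, seed = 7))

test_that("decode_and_nms turns grid activations into boxes and suppresses duplicates", {
  cfg <- detector_config(conf_threshold = 0.3, nms_iou = 0.5)
  G <- 4L
  grid <- array(-10, c(5, G, G))  # all cells inactive
  # one confident cell at (row 2, col 3): center x = (3 - 0.5) * 16 = 40,
  # y = (2 - 0.5) * 16 = 24; box 40 x 16 px in a 64 x 64 image
  grid[1, 2, 3] <- 4                      # sigmoid ~ 0.982
  grid[2, 2, 3] <- 0                      # tx -> 0.5 (cell center)
  grid[3, 2, 3] <- 0                      # ty -> 0.5
  grid[4, 2, 3] <- log(0.625 / 0.375)     # sigmoid = 0.625 -> w = 40
  grid[5, 2, 3] <- log(0.25 / 0.75)       # sigmoid = 0.25  -> h = 16
  out <- decode_and_nms(grid, cfg, 64, 64)
  expect_equal(nrow(out), 1L)
  expect_equal(out$confidence, stats::plogis(4), tolerance = 1e-10)
  expect_equal(c(out$x1, out$x2), c(20, 60), tolerance = 1e-8)
  expect_equal(c(out$y1, out$y2), c(16, 32), tolerance = 1e-8)

  # a weaker activation in the adjacent cell decoding to a heavily
  # overlapping box (IoU ~ 0.72) is removed by NMS
  grid[1, 2, 4] <- 2
  grid[2, 2, 4] <- stats::qlogis(0.01)    # center pulled back toward cell 3
  grid[3, 2, 4] <- 0
  grid[4, 2, 4] <- log(0.625 / 0.375)
  grid[5, 2, 4] <- log(0.25 / 0.75)
  out2 <- decode_and_nms(grid, cfg, 64, 64)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$confidence, stats::plogis(4), tolerance = 1e-10)

  # nothing above threshold -> empty frame
  expect_equal(nrow(decode_and_nms(array(-10, c(5, G, G)), cfg, 64, 64)), 0L)
})

test_that("training is deterministic and reduces the loss", {
  fit2 <- pen_detector(det_train_dir, variant = "baseline", config = det_fit_cfg)
  expect_s3_class(det_fit_baseline, "pen_detector")
  expect_identical(det_fit_baseline$params, fit2$params)
  expect_identical(det_fit_baseline$losses, fit2$losses)
  expect_lt(det_fit_baseline$losses[length(det_fit_baseline$losses)],
            det_fit_baseline$losses[1])
  expect_output(print(det_fit_baseline), "baseline")
  expect_output(summary(det_fit_baseline), "loss")
})

test_that("the BSI variant trains end to end and reduces the loss", {
  expect_equal(det_fit_bsi$config$stem, "bsi")
  expect_lt(det_fit_bsi$losses[length(det_fit_bsi$losses)],
            det_fit_bsi$losses[1])
})

test_that("predictions carry image ids and valid geometry", {
  for (fit in list(det_fit_baseline, det_fit_bsi)) {
    dets <- predict(fit, det_eval_dir)
    expect_true(all(c("image", "x1", "y1", "x2", "y2", "confidence") %in% names(dets)))
    if (nrow(dets)) {
      expect_true(all(dets$x2 > dets$x1 & dets$y2 > dets$y1))
      expect_true(all(dets$confidence > fit$config$conf_threshold))
      expect_true(all(dets$x1 >= 0 & dets$y1 >= 0 & dets$x2 <= 64 & dets$y2 <= 64))
    }
  }
})

test_that("evaluation produces a complete report on held-out frames", {
  rep <- evaluate_detector(det_fit_baseline, det_eval_dir)
  expect_s3_class(rep, "eval_report")
  for (f in c("ap50", "precision", "recall", "f1")) {
    expect_true(is.finite(rep[[f]]) && rep[[f]] >= 0 && rep[[f]] <= 1)
  }
})

test_that("a saved detector reloads and reproduces its predictions exactly", {
  f <- withr::local_tempfile(fileext = ".rds")
  save_pen_detector(det_fit_baseline, f)
  back <- load_pen_detector(f)
  expect_identical(predict(back, det_eval_dir),
                   predict(det_fit_baseline, det_eval_dir))
})

test_that("every ablation variant resolves to a trainable configuration", {
  for (v in c("baseline", "big", "big_fig", "big_fig_addition",
              "big_fig_concat2d", "diff_fig")) {
    vs <- pensight:::variant_settings(v)
    expect_true(vs$stem %in% c("baseline", "bsi"), info = v)
    specs <- detector_layer_specs(v, detector_config(), 64, 64)
    expect_true(model_gflops(specs) > 0, info = v)
  }
  expect_error(pensight:::variant_settings("nonsense"))
})

test_that("run_experiment returns the seen/unseen results grid", {
  res <- run_experiment(
    seen_config = tiny_scene_config(),
    unseen_config = scene_config(
      env_id = "unseen", height = 64, width = 64, n_animals = 2,
      animal_axis_range = c(5, 9),
      background_texture = list(scale = 14, rgb = c(125, 102, 78), amp = 14),
      facility_layout = list(list(x1 = 1, y1 = 40, x2 = 64, y2 = 46,
                                  brightness = 245))),
    variants = c("baseline", "big_fig"), seeds = 1,
    n_train = 4, n_test = 3,
    config = detector_config(epochs = 2, batch_size = 4, seed = 1))
  expect_s3_class(res, "data.frame")
  expect_setequal(names(res), c("variant", "seed", "env", "ap50", "f1",
                                "precision", "recall"))
  expect_equal(nrow(res), 4L)  # 2 variants x 1 seed x 2 environments
  expect_setequal(unique(res$env), c("seen", "unseen"))
  expect_true(all(res$ap50 >= 0 & res$ap50 <= 1))

  d <- withr::local_tempdir()
  write_results_table(res, file.path(d, "results"))
  expect_true(file.exists(file.path(d, "results.csv")))
  back <- utils::read.csv(file.path(d, "results.csv"))
  expect_equal(back$ap50, res$ap50, tolerance = 1e-12)
})
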