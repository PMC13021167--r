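test_that("phantom cores are bit-reproducible and honour forced class mixes", {
  p <- phantom_params(canvas_px = c(192L, 192L), n_glands = 20L,
                      gland_radius_um = c(8, 14), rng_seed = 8)
  a <- generate_core(p)
  b <- generate_core(p)
  expect_identical(a$de$draq5$data, b$de$draq5$data)
  expect_identical(a$label$data, b$label$data)
  expect_identical(a$he$data, b$he$data)

  pure <- phantom_params(canvas_px = c(192L, 192L), n_glands = 16L,
                         gland_radius_um = c(8, 14),
                         class_mix = c(Healthy = 1, GP3 = 0, GP4 = 0, GP5 = 0),
                         rng_seed = 9)
  h <- generate_core(pure)
  expect_true(all(h$label$data %in% c(0L, 1L)))
  expect_true(all(h$gland_classes == "Healthy"))
})

test_that("ground-truth invariants hold across random parameterizations", {
  for (seed in 1:10) {
    p <- phantom_params(canvas_px = c(160L, 160L),
                        n_glands = sample(8:20, 1),
                        gland_radius_um = sort(runif(2, 6, 13)),
                        lumen_fraction = runif(1, 0.3, 0.6),
                        rng_seed = seed)
    core <- generate_core(p)
    # every labeled pixel is epithelial; legend validity is enforced by type
    expect_true(all(core$epi$data[core$label$data > 0] == 1))
    expect_true(all(core$label$data %in% annotation_legend()))
    expect_equal(dim(core$he$data)[1:2], dim(core$label$data))
    # both modalities stay on the 12-bit scale
    expect_true(all(core$de$draq5$data >= 0 & core$de$draq5$data <= 4095))
    expect_true(all(core$de$eosin$data >= 0 & core$de$eosin$data <= 4095))
  }
})

test_that("realized per-gland class frequencies track the requested mix", {
  p <- phantom_params(canvas_px = c(768L, 768L), n_glands = 200L,
                      gland_radius_um = c(6, 10),
                      class_mix = c(Healthy = 0, GP3 = 0.5, GP4 = 0.5, GP5 = 0),
                      rng_seed = 10)
  core <- generate_core(p)
  freq <- table(factor(core$gland_classes, levels = c("Healthy", "GP3", "GP4", "GP5")))
  freq <- freq / sum(freq)
  expect_gt(sum(freq[c("GP3", "GP4")]), 0.999)
  expect_lt(abs(freq[["GP3"]] - 0.5), 0.1)
  expect_error(generate_core(phantom_params(canvas_px = c(40L, 40L))), "too small")
})

test_that("the generator and the crop labeler agree on single-class regions", {
  core <- generate_core(phantom_params(canvas_px = c(192L, 192L), n_glands = 14L,
                                       gland_radius_um = c(8, 14),
                                       class_mix = c(Healthy = 0, GP3 = 0,
                                                     GP4 = 1, GP5 = 0),
                                       rng_seed = 11))
  gated <- gate_annotation(core$label, core$epi)
  boxes <- crop_boxes(dim(gated$data), 0.52, 33.28)
  labs <- vapply(boxes, function(b) {
    r <- assign_crop_label(label_mask(crop_box(gated$data, b), gated$legend))
    if (is.na(r$removal_reason)) r$label else NA_character_
  }, character(1))
  kept <- labs[!is.na(labs)]
  expect_gt(length(kept), 0)
  expect_true(all(kept == "GP4"))
})

test_that("z-stacks blur away from focus and rank accordingly", {
  core <- small_phantom_core(seed = 12, canvas = c(128L, 128L))
  zs <- generate_zstack(core$de$draq5)
  expect_length(zs, 5)
  # offset 0 (index 3) is the unchanged, sharpest plane
  expect_identical(zs[[3]]$data, core$de$draq5$data)
  rf <- rank_focus(zs)
  expect_equal(rf$best, 3L)
  # symmetric offsets share a blur level
  expect_lt(abs(rf$scores[2] - rf$scores[4]), 1e-6)
  expect_lt(abs(rf$scores[1] - rf$scores[5]), 1e-6)
  one <- generate_zstack(core$de$draq5, offsets_um = 0)
  expect_identical(one[[1]]$data, core$de$draq5$data)
})

test_that("cohorts have unique cores, configurable patients, and derive seeds", {
  tpl <- phantom_params(canvas_px = c(128L, 128L), n_glands = 10L,
                        gland_radius_um = c(8, 14))
  ch <- generate_cohort(10, tpl, seed = 2)
  expect_equal(nrow(ch$manifest), 10)
  expect_equal(length(unique(ch$manifest$core_id)), 10)
  expect_equal(length(unique(ch$manifest$patient_id)), 10)
  ch2 <- generate_cohort(10, tpl, seed = 2)
  expect_identical(ch$manifest, ch2$manifest)
  expect_identical(ch$cores[[4]]$de$draq5$data, ch2$cores[[4]]$de$draq5$data)
  chp <- generate_cohort(10, tpl, seed = 3, cores_per_patient = 2)
  expect_equal(length(unique(chp$manifest$patient_id)), 5)
  expect_true(all(table(chp$manifest$patient_id) == 2))
})
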