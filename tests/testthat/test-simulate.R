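test_that("simulate_dataset produces balanced, deterministic, well-formed data", {
  cfg <- synthetic_config(classes = c("WK", "SC", "FF", "JR"),
                          n_subjects = 4, reps_per_class = 2, seed = 11)
  ds <- simulate_dataset(cfg)
  expect_length(ds, 4 * 4 * 2)
  expect_true(all(vapply(ds, function(s) nrow(s$samples) == 2500, logical(1))))
  labs <- table(vapply(ds, function(s) s$label, character(1)))
  expect_true(all(labs == 8))  # class balance
  ds2 <- simulate_dataset(cfg)
  expect_identical(lapply(ds, `[[`, "samples"), lapply(ds2, `[[`, "samples"))
  ds3 <- simulate_dataset(synthetic_config(classes = c("WK", "SC", "FF", "JR"),
                                           n_subjects = 4, reps_per_class = 2,
                                           seed = 12))
  expect_false(identical(ds[[1]]$samples, ds3[[1]]$samples))
})

test_that("static archetype with zero noise is the pure gravity projection", {
  a <- activity_archetype("STAND", "static", gravity_before = c(0, 0, 1),
                          noise_sigma = 0)
  seg <- simulate_segment(a, seed = 1, unit_scale = 1000)
  expect_equal(max(abs(seg$samples[, 1])), 0)
  expect_equal(max(abs(seg$samples[, 2])), 0)
  expect_true(all(abs(seg$samples[, 3] - 1000) < 1e-9))
})

test_that("periodic archetypes put their cadence at the periodogram peak", {
  for (seed in 1:5) {
    seg <- simulate_segment(default_archetypes()$WK,
                            subject_effects = list(amp = 1, freq = 1),
                            seed = seed)
    v <- seg$samples[, 3]
    sp <- stats::spec.pgram(v - mean(v), plot = FALSE, taper = 0)
    # restrict to the gait band: harmonics/impulses sit above, DC below
    band <- sp$freq * 250 < 2
    peak <- (sp$freq[band])[which.max(sp$spec[band])] * 250
    expect_lt(abs(peak - 1.5), 0.2 + 1.5 * default_archetypes()$WK$freq_jitter)
  }
})

test_that("falls reorient gravity between the window's ends", {
  a <- default_archetypes()$FF
  for (seed in 1:3) {
    seg <- simulate_segment(a, seed = seed, unit_scale = 1)
    pre <- colMeans(seg$samples[1:125, ])    # first 0.5 s
    post <- colMeans(seg$samples[2376:2500, ])  # last 0.5 s
    expect_equal(unname(pre), a$gravity_before, tolerance = 0.1)
    expect_equal(unname(post), a$gravity_after, tolerance = 0.1)
  }
})

test_that("the default archetype set mirrors the 15-activity taxonomy", {
  arch <- default_archetypes()
  tax <- default_taxonomy()
  expect_length(arch, 15)
  expect_setequal(names(arch), tax$abbreviation)
  kinds <- vapply(arch, `[[`, character(1), "kind")
  expect_true(all(kinds[c("WK", "UPS", "DWS", "JR", "SQ")] == "periodic"))
  expect_true(all(kinds[c("SC", "GC", "LUB", "LDB")] == "transition"))
  expect_true(all(kinds[c("FF", "FFK", "FB", "LF", "RF", "FOB")] ==
                    "transient_fall"))
  # FF and FFK differ only in impact magnitude and post-fall pitch
  expect_identical(arch$FF$gravity_before, arch$FFK$gravity_before)
  expect_identical(arch$FF$impact_axis, arch$FFK$impact_axis)
  expect_false(arch$FF$impact_magnitude == arch$FFK$impact_magnitude)
  expect_false(isTRUE(all.equal(arch$FF$gravity_after, arch$FFK$gravity_after)))
  # LF and RF are mirror images across the lateral-axis sign
  flip <- c(-1, 1, 1)
  expect_equal(arch$RF$gravity_after, arch$LF$gravity_after * flip)
  expect_equal(arch$RF$impact_axis, arch$LF$impact_axis * flip)
  expect_equal(arch$RF$impact_magnitude, arch$LF$impact_magnitude)
})

test_that("subject effects induce intra-subject correlation of amplitude", {
  cfg <- synthetic_config(classes = "WK", n_subjects = 8, reps_per_class = 6,
                          subject_effect_sd = 0.3, seed = 21)
  ds <- simulate_dataset(cfg)
  rms <- vapply(ds, function(s) sd(s$samples[, 3]), numeric(1))
  subj <- factor(vapply(ds, function(s) s$subject_id, character(1)))
  fit <- stats::aov(rms ~ subj)
  ms <- summary(fit)[[1]]$`Mean Sq`
  # between-subject mean square well above within-subject residual
  expect_gt(ms[1] / ms[2], 2)
})

test_that("generator moments recover configured parameters", {
  # amplitude scales linearly with the configured amplitude
  a1 <- activity_archetype("W1", "periodic", base_freq_hz = 1.5,
                           freq_jitter = 0, amplitude = c(0.2, 0.2, 0.4),
                           gravity_before = c(0, 0, 1), noise_sigma = 0)
  a2 <- a1; a2$amplitude <- a1$amplitude * 2
  s1 <- vapply(1:20, function(i)
    sd(simulate_segment(a1, seed = i, unit_scale = 1)$samples[, 1]), numeric(1))
  s2 <- vapply(1:20, function(i)
    sd(simulate_segment(a2, seed = i, unit_scale = 1)$samples[, 1]), numeric(1))
  expect_equal(mean(s2) / mean(s1), 2, tolerance = 0.1)
})
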