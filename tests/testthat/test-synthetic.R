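test_that("subject profiles enforce the expertise coupling shapes", {
  expect_error(subject_profile("a", "novice",
                               coupling_scale = c(rest = 0.5, drawing = 0.4,
                                                  manipulation = 1)),
               "rise rest < drawing < manipulation")
  expect_error(subject_profile("a", "expert",
                               coupling_scale = c(rest = 0.2, drawing = 1,
                                                  manipulation = 0.8)),
               "flat")
  expect_error(subject_profile("a", "novice",
                               state_durations = c(rest = -1, drawing = 10,
                                                   manipulation = 20)),
               "positive")
  # expert tolerance: 5% of the drawing multiplier
  expect_silent(subject_profile("a", "expert",
                                coupling_scale = c(rest = 0.2, drawing = 1,
                                                   manipulation = 1.05)))
  expect_error(coupling_spec(matrix(0, 13, 13)), "14x14")
  bad <- matrix(0, 14, 14); bad[1, 2] <- -0.1
  expect_error(coupling_spec(bad), "nonnegative")
})

test_that("simulation is deterministic given the seed and respects durations", {
  p <- subject_profile("s1", "novice",
                       state_durations = c(rest = 10, drawing = 8,
                                           manipulation = 12), seed = 5)
  r1 <- simulate_subject(p)
  r2 <- simulate_subject(p)
  expect_identical(r1$samples, r2$samples)
  expect_equal(ncol(r1$samples), 30 * 128)
  expect_equal(r1$annotations$state, c("rest", "drawing", "manipulation"))
  expect_equal(r1$annotations$end - r1$annotations$start + 1L,
               as.integer(c(10, 8, 12) * 128))
  p2 <- subject_profile("s1", "novice",
                        state_durations = c(rest = 10, drawing = 8,
                                            manipulation = 12), seed = 6)
  expect_false(identical(simulate_subject(p2)$samples, r1$samples))
  expect_error(simulate_subject(p, fs = 32), "fs must be >= 64")
})

test_that("without coupling the channels carry no mutual information", {
  p <- subject_profile("s0", "novice",
                       state_durations = c(rest = 40),
                       coupling_scale = c(rest = 0, drawing = 1, manipulation = 2),
                       seed = 8)
  rec <- filter_recording(simulate_subject(p, coupling_spec(matrix(0, 14, 14))))
  m <- nte_matrix(epoch_by_state(rec, "rest"), n_shuffles = 10, seed = 1)
  # bound frozen from a replicate study of the filtered no-coupling baseline
  expect_lt(max(m[row(m) != col(m)]), 0.03)
})

test_that("uncoupled, rhythm-free channels converge to the AR(1) variance", {
  p <- subject_profile("s0", "novice",
                       state_durations = c(rest = 100),  # 12800 samples
                       coupling_scale = c(rest = 0, drawing = 1, manipulation = 2),
                       noise_sd = 1.5, line_noise_amplitude = 0,
                       osc_amplitude = 0, seed = 9)
  rec <- simulate_subject(p, coupling_spec(matrix(0, 14, 14)))
  target <- 1.5^2 / (1 - 0.9^2)
  v <- apply(rec$samples, 1, var)
  expect_lt(abs(mean(v) - target) / target, 0.05)
})

test_that("cohorts have the requested composition and reproducible structure", {
  co <- make_cohort(5, 3, seed = 7)
  expect_length(co, 8)
  expertise <- vapply(co, function(s) s$profile$expertise, character(1))
  expect_equal(sum(expertise == "novice"), 5)
  expect_equal(sum(expertise == "expert"), 3)
  dr <- duration_ranges()
  for (s in co) {
    d <- s$profile$state_durations
    expect_equal(unname(d["rest"]), dr$rest)
    expect_gte(d[["drawing"]], dr$drawing[1]); expect_lte(d[["drawing"]], dr$drawing[2])
    expect_gte(d[["manipulation"]], dr$manipulation[1])
    expect_lte(d[["manipulation"]], dr$manipulation[2])
    expect_true(all(abs(s$recording$samples) < 1e3))  # dynamics stay bounded
  }
  expect_length(make_cohort(0, 0, seed = 1), 0)
})

test_that("different master seeds change samples but not the schema", {
  a <- make_cohort(2, 2, seed = 1, noise_sd = 1)
  b <- make_cohort(2, 2, seed = 2, noise_sd = 1)
  for (k in seq_along(a)) {
    expect_false(identical(a[[k]]$recording$samples[, 1:100],
                           b[[k]]$recording$samples[, 1:100]))
    expect_identical(a[[k]]$profile$subject_id, b[[k]]$profile$subject_id)
    expect_identical(a[[k]]$profile$expertise, b[[k]]$profile$expertise)
    expect_identical(rownames(a[[k]]$recording$samples),
                     rownames(b[[k]]$recording$samples))
  }
  # same master seed reproduces the cohort exactly
  a2 <- make_cohort(2, 2, seed = 1, noise_sd = 1)
  expect_identical(a[[1]]$recording$samples, a2[[1]]$recording$samples)
})

test_that("mean NTE over coupled pairs is non-decreasing in the coupling scale", {
  g <- default_coupling()
  coupled <- which(unclass(g) > 0)
  per_state <- vapply(1:20, function(r) {
    p <- subject_profile("s", "novice",
                         state_durations = c(rest = 25, drawing = 25,
                                             manipulation = 25),
                         seed = 1000 + r)
    rec <- filter_recording(simulate_subject(p))
    vapply(c("rest", "drawing", "manipulation"), function(st) {
      m <- nte_matrix(epoch_by_state(rec, st), n_shuffles = 10,
                      seed = derive_seed(r, st))
      mean(m[coupled])
    }, numeric(1))
  }, numeric(3))
  avg <- rowMeans(per_state)
  expect_lt(avg["rest"], avg["drawing"])
  expect_lt(avg["drawing"], avg["manipulation"])
})

test_that("cohorts are written with ground-truth sidecars", {
  co <- make_cohort(1, 1, seed = 3)
  dir <- tempfile()
  paths <- write_cohort(co, dir, format = "csv")
  expect_length(paths, 2)
  meta <- jsonlite::read_json(paste0(paths[1], ".json"), simplifyVector = TRUE)
  expect_equal(meta$profile$expertise, "novice")
  expect_equal(dim(matrix(unlist(meta$coupling), 14)), c(14L, 14L))
  back <- read_recording(paths[1])
  expect_identical(back$samples, co[[1]]$recording$samples)
})
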