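named14 <- function(fill = 0) {
  matrix(fill, 14, 14, dimnames = list(NTEFBN_CHANNELS, NTEFBN_CHANNELS))
}

test_that("hemisphere decomposition yields four 7x7 source->target blocks", {
  set.seed(1)
  m <- named14(runif(196)); diag(m) <- 0
  hf <- hemisphere_flows(m)
  expect_length(hf$blocks, 4)
  expect_setequal(names(hf$blocks), c("LH->LH", "LH->RH", "RH->LH", "RH->RH"))
  for (b in hf$blocks) expect_identical(dim(b), c(7L, 7L))
  # block totals partition the full matrix total
  expect_equal(sum(vapply(hf$blocks, sum, numeric(1))), sum(m))
  # outflow = row sums of each source->target block
  expect_equal(hf$outflow[["LH->RH"]], rowSums(hf$blocks[["LH->RH"]]))
  # a specific cell: flow F7 -> F8 sits in the LH->RH block as [F7, F8]
  expect_equal(hf$blocks[["LH->RH"]]["F7", "F8"], m["F8", "F7"])
})

test_that("hemisphere flows of the all-ones matrix count block cells", {
  m <- named14(1); diag(m) <- 0
  hf <- hemisphere_flows(m)
  expect_equal(unname(hf$outflow[["LH->LH"]]), rep(6, 7))  # diagonal removed
  expect_equal(unname(hf$outflow[["LH->RH"]]), rep(7, 7))
  z <- hemisphere_flows(named14(0))
  expect_true(all(unlist(z$outflow) == 0))
})

test_that("region flows sum the six directed inter-region blocks", {
  m <- named14(0)
  m["T7", "F3"] <- 0.2  # F3 -> T7: frontal to central
  rf <- region_flows(m)
  expect_equal(unname(rf$flows["F-C"]), 0.2)
  expect_equal(unname(sum(rf$flows)), 0.2)
  expect_equal(rf$max_pair, "F-C")

  ones <- named14(1); diag(ones) <- 0
  rf1 <- region_flows(ones)
  expect_equal(unname(rf1$flows), rep(16, 6))  # 4x4 cells per block

  rf0 <- region_flows(named14(0))
  expect_true(all(rf0$flows == 0))
  expect_true(is.na(rf0$max_pair) && is.na(rf0$min_pair))
})

test_that("region flows exclude within-region and prefrontal cells", {
  set.seed(2)
  m <- named14(runif(196)); diag(m) <- 0
  rf <- region_flows(m)
  reg <- region_channels()
  all12 <- unlist(reg)
  total_between <- sum(m[all12, all12]) -
    sum(vapply(reg, function(ch) sum(m[ch, ch]), numeric(1)))
  expect_equal(sum(rf$flows), total_between)
})

test_that("mean information flow is the per-source outflow", {
  m <- named14(0)
  m["T7", "AF3"] <- 0.5  # AF3 sends 0.5
  f <- mean_information_flow(m)
  expect_equal(unname(f["AF3"]), 0.5)
  expect_equal(sum(f), 0.5)
  ones <- named14(1); diag(ones) <- 0
  expect_equal(unname(mean_information_flow(ones)), rep(13, 14))
  expect_equal(unname(mean_information_flow(named14(0))), rep(0, 14))
})

test_that("the Welch test matches a hand-computed reference", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1, 19.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9, 22.1)
  res <- welch_ttest(a, b)
  # independent reference computation from the defining formulas
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_ref <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_ref <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  half <- qt(0.975, df_ref) * sqrt(va + vb)
  expect_equal(res$t, t_ref, tolerance = 1e-10)
  expect_equal(res$df, df_ref, tolerance = 1e-10)
  expect_equal(res$p, p_ref, tolerance = 1e-10)
  expect_equal(res$ci_low, (mean(a) - mean(b)) - half, tolerance = 1e-10)
  expect_equal(res$ci_high, (mean(a) - mean(b)) + half, tolerance = 1e-10)
  expect_identical(res$significant, res$p < 0.05)
})

test_that("Welch test handles identity, shifts and degenerate inputs", {
  x <- rnorm(20)
  res <- welch_ttest(x, x)
  expect_equal(res$mean_difference, 0)
  expect_equal(res$p, 1)
  set.seed(3)
  a <- rnorm(500); b <- a + 2  # pure location shift
  res2 <- welch_ttest(b, a)
  expect_equal(res2$mean_difference, 2, tolerance = 1e-9)
  expect_true(res2$significant)
  expect_true(res2$ci_low <= res2$mean_difference &&
                res2$mean_difference <= res2$ci_high)
  const <- welch_ttest(rep(1, 5), rep(1, 5))
  expect_true(const$undefined)
  expect_error(welch_ttest(1, c(1, 2)), ">= 2")
})

test_that("one-way ANOVA with Tukey-Kramer flags only true group differences", {
  set.seed(4)
  g0 <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50, mean = 5))
  res <- anova_multicompare(g0)
  expect_lt(res$p, 0.001)
  sig <- res$pairwise$significant
  names(sig) <- res$pairwise$pair
  expect_false(sig[["b-a"]])
  expect_true(sig[["c-a"]] && sig[["c-b"]])

  same <- lapply(1:3, function(i) c(1.2, 0.8, 1.0, 1.1, 0.9))
  res2 <- anova_multicompare(same, labels = c("x", "y", "z"))
  expect_equal(res2$F, 0, tolerance = 1e-9)
  expect_false(any(res2$pairwise$significant))

  expect_error(anova_multicompare(list(a = 1, b = c(1, 2))), "a")
})

test_that("two-group Tukey comparison agrees in direction with the Welch test", {
  set.seed(5)
  a <- rnorm(30); b <- rnorm(30, 1)
  res <- anova_multicompare(list(g1 = a, g2 = b))
  tt <- welch_ttest(b, a)
  expect_equal(sign(res$pairwise$mean_difference[1]), sign(tt$mean_difference))
  expect_identical(res$pairwise$significant[1], tt$significant)
})

test_that("novice mean information flow rises from drawing to manipulation; expert stays flat", {
  diffs <- function(expertise, seeds) {
    vapply(seeds, function(r) {
      p <- subject_profile("s", expertise,
                           state_durations = c(drawing = 25, manipulation = 25),
                           seed = 2000 + r)
      rec <- filter_recording(simulate_subject(p))
      f <- vapply(c("drawing", "manipulation"), function(st) {
        sum(mean_information_flow(
          nte_matrix(epoch_by_state(rec, st), n_shuffles = 10,
                     seed = derive_seed(r, st))))
      }, numeric(1))
      f[["manipulation"]] - f[["drawing"]]
    }, numeric(1))
  }
  dn <- diffs("novice", 1:10)
  expect_gte(mean(dn > 0), 0.9)
  de <- diffs("expert", 1:10)
  expect_gt(mean(de > 0), 0.1)   # paired difference centred near zero
  expect_lt(mean(de > 0), 0.9)
  expect_lt(abs(mean(de)), mean(dn) / 2)
})
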