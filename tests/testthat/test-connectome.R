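test_that("scan QC applies the mean- and max-FD rules at their boundaries", {
  meta <- tibble::tibble(
    scan_id = c("a", "b", "c", "d"),
    mean_fd = c(0.31, 0.10, 0.30, 0.10),
    max_fd = c(0.50, 1.29, 1.30, 1.31)
  )
  qc <- qc_scans(meta)
  expect_equal(qc$qc_pass, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(qc$qc_reason, c("mean_fd", NA, NA, "max_fd"))
  meta$mean_fd[2] <- NA
  expect_error(qc_scans(meta), "missing FD.*b")
})

test_that("time-series normalisation is exact, idempotent, and rejects flat series", {
  set.seed(1)
  ts <- matrix(rnorm(60, 5, 3), 4, 15, dimnames = list(paste0("r", 1:4), NULL))
  norm <- normalize_timeseries(ts)
  expect_lt(max(abs(rowMeans(norm))), 1e-12)
  expect_lt(max(abs(apply(norm, 1, sd) - 1)), 1e-12)
  expect_equal(normalize_timeseries(norm), norm, tolerance = 1e-12)
  ts[2, ] <- 7
  expect_error(normalize_timeseries(ts), "zero-variance.*r2")
})

test_that("band-pass passes in-band and suppresses out-of-band sinusoids", {
  tr <- 2.42
  t <- (0:255) * tr
  slow <- sin(2 * pi * 0.01 * t)
  mid <- sin(2 * pi * 0.05 * t)
  for (method in c("modwt", "fft")) {
    expect_lt(var(bandpass(slow, tr = tr, method = method)) / var(slow), 0.1)
    expect_gt(var(bandpass(mid, tr = tr, method = method)) / var(mid), 0.5)
  }
  set.seed(2)
  noise <- rnorm(256)
  expect_lt(var(bandpass(noise, tr = tr)), var(noise))
  expect_error(bandpass(noise, f_low = 0.025, f_high = 0.3, tr = tr), "Nyquist")
  # the two implementations agree closely on in-band content
  both <- vapply(c("modwt", "fft"), function(m) var(bandpass(mid, tr = tr, method = m)),
                 numeric(1))
  expect_lt(abs(diff(both)) / var(mid), 0.25)
})

test_that("MODWT reconstruction is exact", {
  set.seed(3)
  x <- rnorm(300)
  dec <- maturind:::modwt_d4(x, 4)
  expect_lt(max(abs(maturind:::imodwt_d4(dec) - x)), 1e-10)
})

test_that("fc_matrix returns Fisher-z correlations and flags degeneracy", {
  set.seed(4)
  base <- rnorm(500)
  ts <- rbind(r1 = base + rnorm(500, 0, 1.2), r2 = rnorm(500), r3 = rnorm(500))
  z <- fc_matrix(ts)
  expect_true(all(abs(z - t(z)) < 1e-12, na.rm = TRUE))
  expect_true(all(is.na(diag(z))))
  # known correlation: atanh recovers the Fisher transform exactly
  x <- c(1, 2, 3, 4, 5); y <- c(1, 3, 2, 5, 4)
  z2 <- fc_matrix(rbind(a = x, b = y))
  expect_equal(z2["a", "b"], atanh(cor(x, y)), tolerance = 1e-12)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)  # the unit convention
  ts_neg <- rbind(r1 = base, r2 = -base)
  expect_error(fc_matrix(ts_neg), "degenerate")
})

test_that("low-signal exclusion drops exactly the planted regions", {
  set.seed(5)
  # uniform regional variation keeps standardised minima above the threshold
  sig <- matrix(runif(20 * 50, 95, 105), 20, 50,
                dimnames = list(NULL, sprintf("r%02d", 1:50)))
  res_none <- exclude_low_signal(matrix(100, 5, 10,
                                        dimnames = list(NULL, paste0("q", 1:10))))
  expect_true(all(res_none$retained))
  sig[7, "r13"] <- 60  # one extreme low-signal region in one scan
  res <- exclude_low_signal(sig)
  expect_false(res$retained[res$region == "r13"])
  expect_true(all(res$retained[res$region != "r13"]))
})

test_that("motion regression removes a planted FD confound and is a projection", {
  set.seed(6)
  n_scans <- 80
  fd <- runif(n_scans, 0.05, 0.3)
  values <- 2 * fd + matrix(rnorm(n_scans * 45, 0, 0.05), n_scans, 45)
  stack <- stack_from_values(values, 10)
  corrected <- motion_regress(stack, fd)
  post_cor <- cor(corrected$values, fd)
  expect_lt(mean(abs(post_cor)), 0.05)
  expect_true(corrected$provenance$fd_regressed)
  # means preserved
  expect_equal(unname(colMeans(corrected$values)), colMeans(values),
               tolerance = 1e-12)
  # idempotence
  twice <- motion_regress(corrected, fd)
  expect_lt(max(abs(twice$values - corrected$values)), 1e-10)
})

test_that("by-sex motion regression equals the per-group least-squares oracle", {
  set.seed(7)
  n_scans <- 60
  sex <- rep(c("female", "male"), each = n_scans / 2)
  fd <- runif(n_scans, 0.05, 0.3)
  # only males carry an FD dependence
  values <- matrix(rnorm(n_scans * 6, 0.3, 0.05), n_scans, 6)
  values[sex == "male", ] <- values[sex == "male", ] + 3 * fd[sex == "male"]
  stack <- stack_from_values(values, 4)
  by_sex <- motion_regress(stack, fd, mode = "by_sex", sex = sex)
  for (g in c("female", "male")) {
    rows <- sex == g
    for (j in 1:6) {
      oracle <- stats::residuals(lm(values[rows, j] ~ fd[rows])) + mean(values[rows, j])
      expect_equal(unname(by_sex$values[rows, j]), unname(oracle), tolerance = 1e-10)
    }
  }
  expect_error(motion_regress(stack, rep(0.1, n_scans)), "constant")
})

test_that("covariate regression matches motion regression and rejects constants", {
  set.seed(8)
  fd <- runif(40, 0.05, 0.3)
  values <- matrix(rnorm(40 * 10), 40, 10) + outer(fd, rep(1.5, 10))
  stack <- stack_from_values(values, 5)
  a <- motion_regress(stack, fd)
  b <- covariate_regress(stack, fd, name = "mean_fd")
  expect_equal(a$values, b$values, tolerance = 1e-12)
  expect_error(covariate_regress(stack, rep(1, 40)), "constant")
  # planted ICV confound removed
  icv <- rnorm(40, 1.4e6, 1e5)
  vals2 <- matrix(rnorm(40 * 10, 0, 0.5), 40, 10) + outer((icv - 1.4e6) / 1e5, rep(1, 10))
  st2 <- covariate_regress(stack_from_values(vals2, 5), icv, name = "icv")
  expect_lt(mean(abs(cor(st2$values, icv))), 0.05)
  expect_equal(st2$provenance$covariates, "icv")
})

test_that("global signal regression leaves residuals orthogonal to the global mean", {
  set.seed(9)
  ts <- matrix(rnorm(8 * 120), 8, 120, dimnames = list(paste0("r", 1:8), NULL))
  res <- gsr(ts)
  g <- colMeans(ts)
  expect_lt(max(abs(cor(t(res), g))), 1e-10)
  # all-identical regions: residuals vanish
  same <- matrix(rep(rnorm(120), each = 4), 4, 120)
  expect_lt(max(abs(gsr(same))), 1e-10)
  expect_error(gsr(matrix(1, 3, 50)), "zero variance")
})

test_that("weighted degree matches hand values and a brute-force oracle", {
  m <- matrix(0.6, 3, 3, dimnames = list(paste0("r", 1:3), paste0("r", 1:3)))
  diag(m) <- NA
  expect_equal(weighted_degree(m)$degree, rep(0.6, 3))
  m2 <- matrix(0, 3, 3, dimnames = dimnames(m))
  m2[1, 2] <- m2[2, 1] <- 1
  diag(m2) <- NA
  expect_equal(weighted_degree(m2)$degree, c(0.5, 0.5, 0))
  for (seed in 1:5) {
    mr <- random_fc_matrix(10, seed)
    k <- weighted_degree(mr)$degree
    oracle <- vapply(1:10, function(i) {
      acc <- 0
      for (j in 1:10) if (j != i) acc <- acc + mr[i, j]
      acc / 9
    }, numeric(1))
    expect_equal(k, oracle, tolerance = 1e-12)
    # double-counting identity
    expect_equal(mean(k), mean(mr[upper.tri(mr)]), tolerance = 1e-12)
  }
})

test_that("stack degrees agree with per-scan weighted degree", {
  co <- simulate_cohort(cohort_config(n_subjects = 10, n_regions_cortical = 8,
                                      n_regions_subcortical = 0, seed = 3))
  deg <- stack_degrees(co$fc)
  s <- co$metadata$scan_id[4]
  expect_equal(unname(deg[s, ]), weighted_degree(fc_matrix_of(co$fc, s))$degree,
               tolerance = 1e-12)
  gf <- global_fc(co$fc)
  expect_equal(gf$global_fc, unname(rowMeans(deg)), tolerance = 1e-12)
})

test_that("block means respect the partition and collapse to degree for one class", {
  m <- random_fc_matrix(6, seed = 11)
  part <- setNames(rep("all", 6), rownames(m))
  bm <- block_means(m, part)
  expect_equal(bm$mean_fc, weighted_degree(m)$degree, tolerance = 1e-12)
  part2 <- setNames(c("x", "x", "x", "y", "y", "y"), rownames(m))
  bm2 <- block_means(m, part2)
  # hand evaluation: region r01 against class y = mean of its edges to r04-r06
  expect_equal(bm2$mean_fc[bm2$region == "r01" & bm2$class == "y"],
               mean(m["r01", c("r04", "r05", "r06")]), tolerance = 1e-12)
  expect_equal(bm2$mean_fc[bm2$region == "r01" & bm2$class == "x"],
               mean(m["r01", c("r02", "r03")]), tolerance = 1e-12)
})

test_that("fc_stack round-trips matrices and preserves labels", {
  mats <- list(s1 = random_fc_matrix(5, 1), s2 = random_fc_matrix(5, 2))
  for (nm in names(mats)) diag(mats[[nm]]) <- NA
  st <- fc_stack_from_matrices(mats)
  back <- fc_matrix_of(st, "s2")
  expect_equal(back[upper.tri(back)], mats$s2[upper.tri(mats$s2)], tolerance = 1e-12)
  expect_equal(glance(st)$n_edges, 10)
  long <- tidy(st)
  expect_equal(nrow(long), 20)
  expect_equal(long$fc[long$scan_id == "s1" & long$edge == "r01|r02"],
               mats$s1["r01", "r02"])
})
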