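test_that("class PMFs are valid probability vectors across the parameter grid", {
  grid <- expand.grid(tf = c(0, 0.1, 0.5, 1), amp = c(0, 0.25, 0.6),
                      ssm = c(0, 0.15, 0.6))
  for (i in seq_len(nrow(grid))) {
    p <- make_class_pmf(profile_model_params(
      tumor_fraction = grid$tf[i], oscillation_amplitude = grid$amp[i],
      short_shift_mass = grid$ssm[i]))
    expect_true(all(p$values >= 0))
    expect_equal(sum(p$values), 1, tolerance = 1e-12)
    expect_length(p$values, 200)
  }
})

test_that("a pure mode model is unimodal with its peak at 166 bp", {
  p <- make_class_pmf(profile_model_params(oscillation_amplitude = 0,
                                           tumor_fraction = 0))
  expect_equal(p$sizes[which.max(p$values)], 166)
  # unimodality: values increase to the peak and decrease after
  pk <- which.max(p$values)
  expect_true(all(diff(p$values[1:pk]) >= 0))
  expect_true(all(diff(p$values[pk:length(p$values)]) <= 0))
})

test_that("tumor fraction strictly increases sub-150 bp mass and zero reproduces healthy", {
  p0 <- make_class_pmf(profile_model_params(tumor_fraction = 0))
  p3 <- make_class_pmf(profile_model_params(tumor_fraction = 0.3))
  below <- function(p) sum(p$values[p$sizes < 150])
  expect_gt(below(p3), below(p0))
  # short/long mass in [51,150] as stated for the benchmark interval
  expect_gt(sum(p3$values[p3$sizes <= 150]), sum(p0$values[p0$sizes <= 150]))
  p0b <- make_class_pmf(profile_model_params(tumor_fraction = 0))
  expect_identical(p0$values, p0b$values)
})

test_that("invalid model parameters are rejected", {
  expect_error(profile_model_params(oscillation_amplitude = -1),
               class = "fragwave_parameter_error")
  expect_error(profile_model_params(tumor_fraction = 1.5),
               class = "fragwave_parameter_error")
  expect_error(make_class_pmf(profile_model_params(), size_range = c(250, 51)),
               class = "fragwave_parameter_error")
})

test_that("cohort generation is seed-reproducible and structurally sound", {
  spec <- cohort_spec(5, 5, bins_per_sample = 8, fragments_per_bin = 800,
                      seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(lapply(a$counts, `[[`, "counts"),
                   lapply(b$counts, `[[`, "counts"))
  expect_identical(a$metadata, b$metadata)

  expect_equal(nrow(a$metadata), 10)
  expect_equal(as.integer(table(a$metadata$class)[c("cancer", "healthy")]),
               c(5L, 5L))
  expect_false(anyDuplicated(a$metadata$patient_id) > 0)
  for (x in a$counts) {
    expect_true(all(x$counts >= 0))
    expect_true(all(x$counts == round(x$counts)))
  }
  # a different seed changes the draws
  c2 <- generate_cohort(cohort_spec(5, 5, bins_per_sample = 8,
                                    fragments_per_bin = 800, seed = 43))
  expect_false(identical(a$counts[[1]]$counts, c2$counts[[1]]$counts))
})

test_that("identical class models yield indistinguishable pooled size distributions", {
  # two-sample Kolmogorov-Smirnov distance between pooled class PMFs,
  # against the critical value at alpha = 0.001
  same <- profile_model_params(tumor_fraction = 0)
  co <- generate_cohort(cohort_spec(10, 10, bins_per_sample = 20,
                                    fragments_per_bin = 2000, seed = 7),
                        healthy_params = same, cancer_params = same)
  pooled <- function(cl) {
    ids <- co$metadata$sample_id[co$metadata$class == cl]
    Reduce(`+`, lapply(co$counts[ids], function(x) colSums(x$counts)))
  }
  h <- pooled("healthy"); c_ <- pooled("cancer")
  n1 <- sum(h); n2 <- sum(c_)
  ks <- max(abs(cumsum(h) / n1 - cumsum(c_) / n2))
  crit <- 1.95 * sqrt((n1 + n2) / (n1 * n2))
  expect_lt(ks, crit)
})

test_that("summed sample histograms match the class PMF (chi-square goodness of fit)", {
  rejections <- 0; n_samples <- 0
  for (seed in c(3, 4, 5)) {
    co <- tiny_cohort(n_healthy = 10, n_cancer = 10, seed = seed)
    pmfs <- list(healthy = make_class_pmf(profile_model_params()),
                 cancer = make_class_pmf(co$cancer_params))
    for (i in seq_len(nrow(co$metadata))) {
      obs <- colSums(co$counts[[co$metadata$sample_id[i]]]$counts)
      p <- pmfs[[co$metadata$class[i]]]$values
      # pool cells with small expected counts for chi-square validity
      expc <- sum(obs) * p
      grp <- pmin(findInterval(cumsum(expc), seq(0, sum(expc), by = 20)),
                  length(expc))
      o <- tapply(obs, grp, sum); e <- tapply(expc, grp, sum)
      stat <- sum((o - e)^2 / e)
      pval <- stats::pchisq(stat, df = length(o) - 1, lower.tail = FALSE)
      n_samples <- n_samples + 1
      if (pval < 0.01) rejections <- rejections + 1
    }
  }
  expect_lte(rejections / n_samples, 0.05)
})

test_that("the short/long ratio of the model PMF rises strictly with tumor fraction", {
  ratios <- vapply(seq(0, 0.4, by = 0.1), function(tf) {
    benchmark_features(make_class_pmf(
      profile_model_params(tumor_fraction = tf)))[["short_long_ratio"]]
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})
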