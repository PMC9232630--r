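test_that("a single-binary-predictor LR test equals the G-test on the same 2x2", {
  set.seed(21)
  for (i in 1:20) {
    counts <- rpois(4, 15) + 1
    d <- data.frame(
      y = rep(c(TRUE, FALSE, TRUE, FALSE), counts),
      g = rep(c("a", "a", "b", "b"), counts)
    )
    fit <- logistic_lr_fit(d, y ~ g)
    m <- as.matrix(table(d$g, d$y))
    g <- g_test(m)$statistic
    expect_equal(fit$terms$lr_chi2, g, tolerance = 1e-6 * max(g, 1))
  }
})

test_that("constant responses and missing variation are rejected", {
  d <- data.frame(y = rep(TRUE, 10), g = rep(c("a", "b"), 5))
  expect_error(logistic_lr_fit(d, y ~ g), "constant")
})

test_that("perfect separation is flagged, not fatal", {
  d <- data.frame(y = rep(c(TRUE, FALSE), each = 20),
                  g = rep(c("a", "b"), each = 20))
  expect_warning(fit <- logistic_lr_fit(d, y ~ g), "separation")
  expect_true(fit$separation)
  expect_true(fit$terms$lr_chi2 > 0)
  expect_true(glance(fit)$separation)
})

test_that("temporal trend recovers a rising backcross frequency, year df = 1", {
  set.seed(4)
  years <- 2006:2011
  d <- purrr::map_dfr(years, function(yr) {
    p <- stats::plogis(-3 + 0.8 * (yr - 2006))
    n <- 120
    bc <- stats::rbinom(1, n, p)
    fixture_from_counts(tibble::tibble(
      village = rep(c("VK7", "Soumousso"), each = 1),
      year = yr, swarm_type = "COL", n_swarms = 2L, sex = "M",
      n_pure_col = c(n - bc, n - bc), n_pure_gam = 0L, n_f1 = 0L,
      n_backcross = c(bc, bc)
    ))
  })
  d$sample_id <- sprintf("t%05d", seq_len(nrow(d)))
  cl <- classify_genotypes(d)
  fit <- temporal_trend(cl, species = "COL")
  yr_row <- fit$terms[fit$terms$term == "year", ]
  expect_equal(yr_row$df, 1)
  expect_gt(yr_row$lr_chi2, 0)
  expect_lt(yr_row$p_value, 0.001)
  # the trend coefficient is positive
  expect_gt(unname(fit$coefficients[["year"]]), 0)

  one_loc <- dplyr::filter(cl, .data$village == "VK7")
  expect_warning(fit1 <- temporal_trend(one_loc, species = "COL"),
                 "single location")
  expect_equal(fit1$terms$term, "year")
})

test_that("life-stage comparison uses df = 2 for chromosome and stage", {
  set.seed(8)
  panel <- dis_panel()
  # stage-uniform introgression: 2L entirely heterozygous in ~30%
  mk <- function(stage, n, start) {
    d <- purrr::map_dfr(seq_len(n), function(i) {
      if (stats::runif(1) < 0.3) make_individual("F", "CC", "CG", "CC")
      else make_individual("F", "CC", "CC", "CC")
    })
    d$sample_id <- sprintf("%s%04d", stage, start + seq_len(n))
    d$life_stage <- stage
    d
  }
  d <- dplyr::bind_rows(mk("swarming", 80, 0), mk("indoor", 80, 100),
                        mk("larva", 80, 200))
  cl <- classify_genotypes(d, panel)
  fit <- life_stage_comparison(cl)
  expect_equal(fit$terms$df[fit$terms$term == "chromosome"], 2)
  expect_equal(fit$terms$df[fit$terms$term == "life_stage"], 2)
  expect_true("chromosome:life_stage" %in% fit$terms$term)
  expect_equal(fit$n, 3 * 240)

  mono <- dplyr::mutate(d, life_stage = "larva")
  expect_error(life_stage_comparison(classify_genotypes(mono, panel)),
               "two life stages")
})

test_that("stage-uniform data rarely shows a spurious life-stage effect", {
  # type-I error check over seeded replicates
  reject <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    n <- 60
    d <- purrr::map_dfr(seq_len(3 * n), function(i) {
      if (stats::runif(1) < 0.25) make_individual("F", "CC", "CG", "CC")
      else make_individual("F", "CC", "CC", "CC")
    })
    d$sample_id <- sprintf("u%05d", seq_len(nrow(d)))
    d$life_stage <- rep(c("swarming", "indoor", "larva"), each = n)
    cl <- classify_genotypes(d)
    fit <- life_stage_comparison(cl)
    p <- fit$terms$p_value[fit$terms$term == "life_stage"]
    if (p <= 0.05) reject <- reject + 1
  }
  expect_lte(reject / n_rep, 0.10)
})
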