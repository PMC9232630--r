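panel <- dis_panel()

mk_kdr <- function(n_rr, n_rs, n_ss, n_na, village = "VK7", year = 2008L,
                   x = "CC", a2 = "CC", a3 = "CC", prefix = "k") {
  n <- n_rr + n_rs + n_ss + n_na
  if (n == 0) return(NULL)
  d <- purrr::map_dfr(seq_len(n), \(i) make_individual("F", x, a2, a3))
  d$sample_id <- sprintf("%s-%s-%s-%04d", prefix, village, year, seq_len(n))
  d$village <- village
  d$year <- year
  d$kdr <- rep(c("RR", "RS", "SS", NA), c(n_rr, n_rs, n_ss, n_na))
  d
}

test_that("kdr frequencies are per-stratum proportions over genotyped individuals", {
  d <- dplyr::bind_rows(
    mk_kdr(8, 1, 1, 0, year = 2008L),
    mk_kdr(0, 0, 0, 5, year = 2011L, prefix = "m")
  )
  cl <- classify_genotypes(d, panel)
  kf <- kdr_frequencies(cl)
  r2008 <- kf[kf$year == 2008, ]
  expect_equal(r2008$n, 10)
  expect_equal(c(r2008$freq_RR, r2008$freq_RS, r2008$freq_SS),
               c(0.8, 0.1, 0.1))
  expect_equal(r2008$freq_RR + r2008$freq_RS + r2008$freq_SS, 1,
               tolerance = 1e-9)
  r2011 <- kf[kf$year == 2011, ]
  expect_equal(r2011$n, 0)
  expect_true(is.na(r2011$freq_RR))
})

test_that("2L recovery classes are exhaustive and exclusive for eligible records", {
  d <- dplyr::bind_rows(
    mk_kdr(1, 0, 0, 0, a2 = "CC", prefix = "rec"),  # RR + coluzzii 2L
    mk_kdr(1, 0, 0, 0, a2 = "CG", prefix = "gam"),  # RR + entire het 2L
    mk_kdr(0, 0, 1, 0, a2 = "CC", prefix = "sus")   # SS + coluzzii 2L
  )
  cl <- classify_genotypes(d, panel)
  rc <- classify_2l_recovery(cl, panel)
  got <- stats::setNames(rc$recovery_class, substr(rc$sample_id, 1, 3))
  expect_equal(unname(got[c("rec", "gam", "sus")]),
               c("COL_RECOVERED_2L", "GAM_LIKE_2L", "OTHER"))

  # fuzz: every eligible record gets exactly one class
  fz <- random_records(2000, panel, seed = 13)
  fz$kdr <- sample(c("RR", "RS", "SS", NA), nrow(fz), replace = TRUE)
  fz$village <- "V"; fz$year <- 2008L
  clf <- suppressMessages(classify_genotypes(fz, panel))
  rcf <- classify_2l_recovery(clf, panel)
  expect_true(all(rcf$recovery_class %in%
                    c("COL_RECOVERED_2L", "GAM_LIKE_2L", "OTHER")))
  expect_true(all(rcf$species == "COL" & !is.na(rcf$kdr)))

  # k restricts the pericentromeric requirement
  part <- mk_kdr(1, 0, 0, 0, a2 = "CC", prefix = "px")
  part[["2L_5"]] <- "GG" # distal locus gambiae, proximal 4 coluzzii
  clp <- classify_genotypes(part, panel)
  expect_equal(classify_2l_recovery(clp, panel, k = 4)$recovery_class,
               "COL_RECOVERED_2L")
  expect_equal(classify_2l_recovery(clp, panel, k = 5)$recovery_class,
               "OTHER")
})

test_that("recovery trend responds to a shifting class balance across years", {
  flat <- dplyr::bind_rows(
    mk_kdr(10, 0, 0, 0, year = 2008L, a2 = "CC", prefix = "a8"),
    mk_kdr(10, 0, 0, 0, year = 2008L, a2 = "CG", prefix = "b8"),
    mk_kdr(10, 0, 0, 0, year = 2011L, a2 = "CC", prefix = "a11"),
    mk_kdr(10, 0, 0, 0, year = 2011L, a2 = "CG", prefix = "b11")
  )
  clf <- classify_genotypes(flat, panel)
  res_flat <- recovery_trend(classify_2l_recovery(clf, panel))
  expect_lt(res_flat$statistic, 1e-9)

  shift <- dplyr::bind_rows(
    mk_kdr(2, 0, 0, 0, year = 2008L, a2 = "CC", prefix = "c8"),
    mk_kdr(18, 0, 0, 0, year = 2008L, a2 = "CG", prefix = "d8"),
    mk_kdr(18, 0, 0, 0, year = 2011L, a2 = "CC", prefix = "c11"),
    mk_kdr(2, 0, 0, 0, year = 2011L, a2 = "CG", prefix = "d11")
  )
  cls <- classify_genotypes(shift, panel)
  res <- recovery_trend(classify_2l_recovery(cls, panel))
  expect_lt(res$p_value, 0.001)

  one_year <- dplyr::filter(clf, .data$year == 2008)
  expect_error(recovery_trend(classify_2l_recovery(one_year, panel)),
               "two year")
})

test_that("dual kdr locus calls combine by resistant-allele presence", {
  f <- c("RS", "SS", "RR", NA, "SS", NA)
  s <- c("RS", "RS", "SS", "RS", NA, NA)
  expect_equal(combine_kdr_calls(f, s),
               c("RR", "RS", "RR", "RS", "SS", NA))
  expect_equal(combine_kdr_calls(f, s, mode = "f_only"), f)
  expect_error(combine_kdr_calls("XX", "RS"), "unknown kdr")
})
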