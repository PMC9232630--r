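panel <- dis_panel()

test_that("completeness requires every DIS call, and only DIS calls", {
  full <- make_individual("F", "CC", "CC", "CC")
  expect_true(is_complete(full, panel))

  hole <- full
  hole[["2L_3"]] <- NA_character_
  expect_false(is_complete(hole, panel))

  with_kdr <- tibble::add_column(full, kdr = NA_character_)
  expect_true(is_complete(with_kdr, panel))
})

test_that("category rules reproduce the canonical cases", {
  cases <- dplyr::bind_rows(
    make_individual("F", "CG", "CG", "CG", "f1_female"),
    make_individual("M", "C", "CC", "CC", "pure_col_male"),
    make_individual("M", "C", "GG", "GG", "soumousso_male"),
    make_individual("M", "G", "CG", "CG", "f1_male_gam_x"),
    make_individual("M", "C", "CG", "CG", "f1_male_col_x"),
    make_individual("F", "GG", "GG", "GG", "pure_gam_female"),
    make_individual("F", "CC", "CG", "GG", "mosaic_female")
  )
  cl <- classify_genotypes(cases, panel)
  got <- stats::setNames(cl$category, cl$sample_id)
  expect_equal(unname(got[c("f1_female", "pure_col_male", "soumousso_male",
                            "f1_male_gam_x", "f1_male_col_x",
                            "pure_gam_female", "mosaic_female")]),
               c("F1", "PURE_COL", "BACKCROSS", "F1", "F1",
                 "PURE_GAM", "BACKCROSS"))
})

test_that("majority rule matches hand counts, incl. the X-islands backcross male", {
  # X coluzzii, autosomes gambiae: 7 vs 16 copies -> gambiae backcross
  m <- make_individual("M", "C", "GG", "GG")
  cl <- classify_genotypes(m, panel)
  expect_equal(cl$n_col_alleles, 7)
  expect_equal(cl$n_gam_alleles, 16)
  expect_equal(cl$species, "GAM")
  expect_equal(cl$category, "BACKCROSS")

  # female: X coluzzii (14), 2L het (5/5), 3L gambiae (6) -> 19 vs 11
  f <- make_individual("F", "CC", "CG", "GG")
  clf <- classify_genotypes(f, panel)
  expect_equal(clf$n_col_alleles, 19)
  expect_equal(clf$n_gam_alleles, 11)
  expect_equal(clf$species, "COL")

  # pure gambiae female: 0 vs 30
  pg <- classify_genotypes(make_individual("F", "GG", "GG", "GG"), panel)
  expect_equal(unname(c(pg$n_col_alleles, pg$n_gam_alleles)), c(0, 30))
})

test_that("allele-tally ties break by X island and are flagged", {
  # X: 5 CC + 2 CG (col 12, gam 2); 2L: GG (gam 10); 3L: CG (3 each)
  # -> 15 vs 15 with a recombined X: no majority, no fallback
  tie <- make_individual("F", "CC", "GG", "CG")
  tie$X_1 <- "CG"
  tie$X_2 <- "CG"
  expect_message(cl <- classify_genotypes(tie, panel), "tie")
  expect_equal(cl$n_col_alleles, cl$n_gam_alleles)
  expect_true(cl$species_tie)
  expect_true(is.na(cl$species))

  # X: CC (col 14); 2L: GG; 3L: GG GG CG -> 15 vs 15, and the
  # homospecific coluzzii X breaks the tie
  tie2 <- make_individual("F", "CC", "GG", "GG")
  tie2[["3L_3"]] <- "CG"
  cl2 <- suppressMessages(classify_genotypes(tie2, panel))
  expect_equal(cl2$n_col_alleles, cl2$n_gam_alleles)
  expect_equal(cl2$species, "COL")

  # a complete male carries 7 + 16 = 23 allele copies: ties are
  # impossible for males
  males <- random_records(2000, panel, seed = 5)
  males <- males[males$sex == "M", ]
  clm <- classify_genotypes(males, panel)
  expect_false(any(clm$species_tie))
})

test_that("island states distinguish entire-island introgression from recombination", {
  ind <- make_individual("F", "CC", "CG", "GG")
  ind[["2L_1"]] <- "CC"
  ind[["2L_2"]] <- "CC" # 2L mixture hom/het
  st <- island_states(ind, panel)
  expect_equal(st$state, c("HOM_COL", "RECOMBINED", "HOM_GAM"))

  het2l <- island_states(make_individual("F", "CC", "CG", "CC"), panel)
  expect_equal(het2l$state[het2l$island == "2L"], "HET_ENTIRE")

  # hemizygous male X counts as homospecific, never HET_ENTIRE
  males <- random_records(300, panel, seed = 11)
  males <- males[males$sex == "M", ]
  stm <- island_states(males, panel)
  expect_false(any(stm$state[stm$island == "X"] == "HET_ENTIRE"))
  expect_true(all(stm$state[stm$island == "X"] %in%
                    c("HOM_COL", "HOM_GAM", "RECOMBINED")))
})

test_that("male diploid X calls are rejected", {
  bad <- make_individual("F", "CG", "CG", "CG")
  bad$sex <- "M"
  expect_error(classify_genotypes(bad, panel), "hemizygous")
  bad2 <- make_individual("M", "C", "CC", "CC")
  bad2$sex <- "F"
  expect_error(classify_genotypes(bad2, panel), "diploid")
})

test_that("male F1s report their maternal X species", {
  both <- dplyr::bind_rows(
    make_individual("M", "G", "CG", "CG", "gam_mother"),
    make_individual("M", "C", "CG", "CG", "col_mother"),
    make_individual("F", "CG", "CG", "CG", "f1_female")
  )
  cl <- classify_genotypes(both, panel)
  fm <- f1_maternal_species(cl)
  expect_equal(nrow(fm), 2)
  expect_equal(stats::setNames(fm$f1_maternal_species, fm$sample_id),
               c(gam_mother = "GAM", col_mother = "COL"))
  expect_true(is.na(cl$f1_maternal_species[cl$sample_id == "f1_female"]))
})

test_that("X/rDNA discordance flags within-X recombination candidates", {
  d <- dplyr::bind_rows(
    make_individual("M", "C", "GG", "GG", "discordant", rdna = "gam"),
    make_individual("M", "G", "GG", "GG", "concordant", rdna = "gam"),
    make_individual("F", "CG", "CG", "CG", "het_x", rdna = "gam"),
    make_individual("M", "C", "CC", "CC", "no_rdna", rdna = NA_character_)
  )
  cl <- classify_genotypes(d, panel)
  got <- stats::setNames(cl$x_rdna_discordant, cl$sample_id)
  expect_true(got[["discordant"]])
  expect_false(got[["concordant"]])
  expect_true(is.na(got[["het_x"]]))
  expect_true(is.na(got[["no_rdna"]]))
})

test_that("incomplete records are dropped with a message, or kept on request", {
  d <- dplyr::bind_rows(
    make_individual("F", "CC", "CC", "CC", "ok"),
    make_individual("F", "CC", "CC", "CC", "hole")
  )
  d[["3L_3"]][2] <- NA_character_
  expect_message(cl <- classify_genotypes(d, panel), "incomplete")
  expect_equal(cl$sample_id, "ok")
  kept <- classify_genotypes(d, panel, keep_incomplete = TRUE)
  expect_equal(nrow(kept), 2)
  expect_true(is.na(kept$category[kept$sample_id == "hole"]))
})
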