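panel <- dis_panel()

test_that("swarm typing is all-or-nothing: any second species makes a swarm mixed", {
  expect_equal(assign_swarm_type(rep("COL", 30)), "COL")
  expect_equal(assign_swarm_type(c(rep("COL", 29), "GAM")), "MIXED")
  expect_equal(assign_swarm_type(rep("GAM", 2)), "GAM")
  expect_error(assign_swarm_type(character(0)), "no members")
  # permutation-invariant and idempotent on the summary
  set.seed(1)
  members <- sample(c(rep("COL", 5), rep("GAM", 3)))
  expect_equal(assign_swarm_type(members), "MIXED")
})

test_that("swarm_types derives per-swarm composition from classifications", {
  geno <- fixture_from_counts(tibble::tibble(
    village = c("V", "V"), year = 2008L, swarm_type = c("COL", "MIXED"),
    n_swarms = c(2L, 1L), sex = "M",
    n_pure_col = c(4L, 2L), n_pure_gam = c(0L, 2L), n_f1 = 0L,
    n_backcross = c(6L, 0L)
  ), panel)
  cl <- classify_genotypes(geno, panel)
  sw <- swarm_types(cl)
  expect_equal(nrow(sw), 3)
  expect_equal(sort(sw$swarm_type), c("COL", "COL", "MIXED"))
  expect_equal(sum(sw$n), 14)
})

test_that("island match predicate: only homospecific-for-the-swarm islands match", {
  expect_true(island_matches_swarm("HOM_COL", "COL"))
  expect_false(island_matches_swarm("HET_ENTIRE", "COL"))
  expect_false(island_matches_swarm("RECOMBINED", "COL"))
  expect_false(island_matches_swarm("HOM_COL", "GAM")) # the exceptional male
  expect_error(island_matches_swarm("HOM_COL", "MIXED"), "monospecific")
})

test_that("match table restrictions nest and rows are individuals x 3", {
  # one COL swarm: 2 pure, 1 backcross with entire 2L, 1 with recombined 2L
  geno <- dplyr::bind_rows(
    make_individual("M", "C", "CC", "CC", "p1"),
    make_individual("M", "C", "CC", "CC", "p2"),
    make_individual("M", "C", "CG", "CC", "bc_entire"),
    make_individual("M", "C", "CG", "CC", "bc_recomb")
  )
  geno[["2L_1"]][4] <- "CC"
  geno$swarm_id <- "S1"
  geno$village <- "V"
  geno$year <- 2008L
  cl <- classify_genotypes(geno, panel)

  non <- build_match_table(cl, restriction = "nonrecombinant")
  ent <- build_match_table(cl, restriction = "entire_islands")
  all_r <- build_match_table(cl, restriction = "all")
  expect_equal(nrow(non), 2 * 3)
  expect_equal(nrow(ent), 3 * 3)
  expect_equal(nrow(all_r), 4 * 3)
  expect_true(all(ent$matches_swarm[ent$island != "2L"]))
  bc_rows <- ent[ent$sample_id == "bc_entire", ]
  expect_equal(bc_rows$matches_swarm[bc_rows$island == "2L"], FALSE)

  # a fully homozygous individual with islands of both species is a
  # non-recombinant whose heterospecific island mismatches
  imm <- make_individual("M", "C", "GG", "GG", "hom_mixed",
                         swarm_id = "S1", village = "V", year = 2008L)
  cl2 <- classify_genotypes(dplyr::bind_rows(geno, imm), panel)
  sw2 <- swarm_types(cl2)
  expect_equal(sw2$swarm_type, "MIXED") # majority-GAM member flips the swarm
})

test_that("individuals from mixed swarms and F1s are excluded from match tables", {
  geno <- dplyr::bind_rows(
    make_individual("M", "C", "CC", "CC", "col1", swarm_id = "A"),
    make_individual("M", "C", "CC", "CC", "col2", swarm_id = "A"),
    make_individual("M", "C", "CG", "CG", "f1", swarm_id = "A"),
    make_individual("M", "C", "CC", "CC", "col3", swarm_id = "B"),
    make_individual("M", "G", "GG", "GG", "gam1", swarm_id = "B")
  )
  geno$village <- "V"; geno$year <- 2008L
  cl <- classify_genotypes(geno, panel)
  mt <- build_match_table(cl, restriction = "all")
  # swarm B is mixed; the F1 male in swarm A is excluded
  expect_setequal(unique(mt$sample_id), c("col1", "col2"))
})

test_that("Wilson intervals behave at the boundaries", {
  ci <- match_proportions(
    tibble::tibble(species = "COL", sex = "M", island = "X",
                   matches_swarm = rep(TRUE, 50))
  )
  expect_equal(ci$prop_match, 1)
  expect_lt(ci$conf_low, 1)
  expect_gt(ci$conf_low, 0.9)
  expect_equal(ci$conf_high, 1)
})
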