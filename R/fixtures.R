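canonical_pattern <- function(panel, category, species, sex, f1_maternal) {
  loci <- panel$locus_id
  x <- panel$island == "X"
  calls <- character(length(loci))
  sp_token <- function(sp) if (sp == "COL") "C" else "G"
  if (category == "PURE_COL") {
    calls <- ifelse(sex == "M" & x, "C", "CC")
  } else if (category == "PURE_GAM") {
    calls <- ifelse(sex == "M" & x, "G", "GG")
  } else if (category == "F1") {
    calls <- rep("CG", length(loci))
    if (sex == "M") calls[x] <- sp_token(f1_maternal)
  } else if (category == "BACKCROSS") {
    # canonical backcross: homospecific background with one entirely
    # heterozygous heterospecific island -- 2L for coluzzii (the
    # dominant observed introgression), 3L for gambiae
    if (species == "COL") {
      calls <- ifelse(sex == "M" & x, "C", "CC")
      calls[panel$island == "2L"] <- "CG"
    } else {
      calls <- ifelse(sex == "M" & x, "G", "GG")
      calls[panel$island == "3L"] <- "CG"
    }
  } else {
    stop("unknown category: ", category, call. = FALSE)
  }
  stats::setNames(calls, loci)
}

check_backcross_majority <- function(panel, species, sex) {
  calls <- canonical_pattern(panel, "BACKCROSS", species, sex, NULL)
  n_col <- sum(c(CC = 2, GG = 0, CG = 1, C = 1, G = 0)[calls])
  n_gam <- sum(c(CC = 0, GG = 2, CG = 1, C = 0, G = 1)[calls])
  ok <- if (species == "COL") n_col > n_gam else n_gam > n_col
  if (!ok) {
    stop("the canonical ", species, " backcross pattern cannot carry a ",
         species, " majority under this panel", call. = FALSE)
  }
}

#' Build a deterministic genotype fixture from per-stratum category counts
#'
#' Reconstructs a genotype table whose classification reproduces a given
#' composition exactly, using one canonical genotype pattern per
#' category: non-hybrids are homospecific at every locus; F1s
#' heterozygous at all loci (females) or all autosomal loci with a
#' single-species hemizygous X (males); backcrosses carry a homospecific
#' background with one entirely heterozygous heterospecific island (2L
#' for *An. coluzzii*, 3L for *An. gambiae*), preserving the requested
#' majority species. This lets published composition tables be replayed
#' through the classification pipeline as worked examples.
#'
#' @param counts A tibble with one row per sampling stratum and columns
#'   `village`, `year`, `swarm_type` (`"COL"`, `"GAM"` or `"MIXED"`),
#'   `n_swarms`, `sex` (`"M"`/`"F"`), `n_pure_col`, `n_pure_gam`, `n_f1`,
#'   `n_backcross`. In monospecific strata, F1s get the swarm species as
#'   maternal X and backcrosses the swarm species as majority; in mixed
#'   strata backcrosses and F1s are assigned to *An. coluzzii*. Members
#'   are spread round-robin over the stratum's swarms.
#' @param panel The [dis_panel()].
#' @param life_stage Life stage recorded for all rows.
#' @return A genotype tibble ready for [classify_genotypes()].
#' @examples
#' fixture_from_counts(table1_male_counts()) |> nrow() # the 2063 males
#' @export
fixture_from_counts <- function(counts, panel = dis_panel(),
                                life_stage = "swarming") {
  panel <- validate_panel(panel)
  counts <- tibble::as_tibble(counts)
  required <- c("village", "year", "swarm_type", "sex", "n_pure_col",
                "n_pure_gam", "n_f1", "n_backcross")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols) > 0) {
    stop("counts is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"n_swarms" %in% names(counts)) counts$n_swarms <- 1L
  n_cols <- c("n_pure_col", "n_pure_gam", "n_f1", "n_backcross")
  if (any(as.matrix(counts[n_cols]) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }

  rows <- purrr::imap_dfr(split(counts, seq_len(nrow(counts))), function(row, i) {
    total <- row$n_pure_col + row$n_pure_gam + row$n_f1 + row$n_backcross
    if (total == 0) return(NULL)
    mono <- row$swarm_type %in% c("COL", "GAM")
    bc_species <- if (mono) row$swarm_type else "COL"
    f1_maternal <- if (mono) row$swarm_type else "COL"
    check_backcross_majority(panel, bc_species, row$sex)
    spec <- tibble::tibble(
      category = rep(c("PURE_COL", "PURE_GAM", "F1", "BACKCROSS"),
                     times = c(row$n_pure_col, row$n_pure_gam, row$n_f1,
                               row$n_backcross)),
      species = rep(c("COL", "GAM", f1_maternal, bc_species),
                    times = c(row$n_pure_col, row$n_pure_gam, row$n_f1,
                              row$n_backcross))
    )
    # interleave species so multi-swarm mixed strata stay mixed
    if (row$swarm_type == "MIXED" && dplyr::n_distinct(spec$species) > 1) {
      col_idx <- which(spec$species == "COL")
      gam_idx <- which(spec$species == "GAM")
      interleave <- integer(0)
      m <- max(length(col_idx), length(gam_idx))
      for (j in seq_len(m)) {
        if (j <= length(col_idx)) interleave <- c(interleave, col_idx[j])
        if (j <= length(gam_idx)) interleave <- c(interleave, gam_idx[j])
      }
      spec <- spec[interleave, ]
    }
    n_swarms <- max(1L, row$n_swarms)
    calls <- t(vapply(seq_len(nrow(spec)), function(k) {
      canonical_pattern(panel, spec$category[k], spec$species[k], row$sex,
                        spec$species[k])
    }, character(nrow(panel))))
    tibble::as_tibble(calls) |>
      dplyr::mutate(
        sample_id = sprintf("%s-%s-%s-%s-%04d", row$village, row$year,
                            row$swarm_type, i, seq_len(nrow(spec))),
        sex = row$sex,
        life_stage = life_stage,
        village = row$village,
        year = row$year,
        swarm_id = sprintf("%s-%s-%s-%s-S%02d", row$village, row$year,
                           row$swarm_type, i,
                           rep_len(seq_len(n_swarms), nrow(spec))),
        .before = 1
      )
  })
  rows
}

#' Published swarm composition tables as count specifications
#'
#' Per-stratum (village x year x swarm type) category counts of the
#' swarm-caught males (`table1_male_counts()`, 2063 individuals in 106
#' swarms) and mating-pair females (`table2_female_counts()`, 266
#' individuals), transcribed from the published composition tables of
#' the Burkina Faso swarm survey. Feed them to [fixture_from_counts()]
#' to replay the published compositions through the pipeline.
#'
#' @return A tibble in the [fixture_from_counts()] `counts` format.
#' @export
table1_male_counts <- function() {
  tibble::tribble(
    ~village, ~year, ~swarm_type, ~n_swarms, ~n_pure_col, ~n_pure_gam, ~n_f1, ~n_backcross,
    "Bana", 2012L, "COL", 16L, 1L, 0L, 0L, 64L,
    "Bana", 2012L, "GAM", 9L, 0L, 57L, 0L, 0L,
    "Soumousso", 2006L, "GAM", 2L, 0L, 26L, 0L, 2L,
    "Soumousso", 2007L, "COL", 2L, 30L, 0L, 0L, 6L,
    "Soumousso", 2007L, "GAM", 13L, 0L, 356L, 0L, 18L,
    "Soumousso", 2008L, "GAM", 12L, 0L, 164L, 1L, 11L,
    "Soumousso", 2008L, "MIXED", 1L, 4L, 1L, 0L, 3L,
    "Soumousso", 2011L, "COL", 1L, 1L, 0L, 0L, 14L,
    "Soumousso", 2011L, "MIXED", 1L, 1L, 3L, 0L, 4L,
    "Soumousso", 2011L, "GAM", 7L, 0L, 73L, 0L, 1L,
    "VK7", 2006L, "COL", 2L, 17L, 0L, 0L, 50L,
    "VK7", 2006L, "GAM", 1L, 0L, 15L, 0L, 1L,
    "VK7", 2006L, "MIXED", 1L, 8L, 1L, 0L, 15L,
    "VK7", 2008L, "COL", 24L, 9L, 0L, 0L, 484L,
    "VK7", 2011L, "COL", 14L, 9L, 0L, 1L, 612L
  ) |>
    dplyr::mutate(sex = "M")
}

#' @rdname table1_male_counts
#' @export
table2_female_counts <- function() {
  tibble::tribble(
    ~village, ~year, ~swarm_type, ~n_swarms, ~n_pure_col, ~n_pure_gam, ~n_f1, ~n_backcross,
    "Soumousso", 2007L, "GAM", 5L, 0L, 14L, 0L, 0L,
    "Soumousso", 2008L, "GAM", 11L, 0L, 37L, 0L, 2L,
    "Soumousso", 2008L, "MIXED", 1L, 0L, 1L, 0L, 0L,
    "Soumousso", 2011L, "MIXED", 1L, 0L, 3L, 0L, 0L,
    "Soumousso", 2011L, "GAM", 7L, 0L, 14L, 0L, 1L,
    "VK7", 2006L, "COL", 1L, 0L, 0L, 0L, 1L,
    "VK7", 2006L, "MIXED", 1L, 0L, 1L, 0L, 0L,
    "VK7", 2008L, "COL", 27L, 1L, 0L, 0L, 141L,
    "VK7", 2011L, "COL", 12L, 1L, 0L, 0L, 49L
  ) |>
    dplyr::mutate(sex = "F")
}
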