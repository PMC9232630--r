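#' @importFrom rlang .data
NULL

# Species-coded genotype tokens. "C" = the An. coluzzii diagnostic allele,
# "G" = the An. gambiae one (a coding convention, not nucleotides):
#   CC / GG  homozygous coluzzii / gambiae      (diploid calls)
#   CG       heterozygous                       (diploid calls)
#   C / G    hemizygous coluzzii / gambiae      (male X calls)
#   NA       missing
DIPLOID_TOKENS <- c("CC", "GG", "CG")
HEMI_TOKENS <- c("C", "G")

normalize_call <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x %in% c("", "NA", ".")] <- NA_character_
  x[x == "GC"] <- "CG"
  x
}

# Extract and validate the call matrix (individuals x panel loci).
genotype_matrix <- function(data, panel) {
  loci <- panel$locus_id
  missing_cols <- setdiff(loci, names(data))
  if (length(missing_cols) > 0) {
    stop("genotype table is missing panel locus column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(grep("^(X|2L|3L)_", names(data), value = TRUE), loci)
  if (length(extra) > 0) {
    stop("genotype table carries locus column(s) absent from the panel: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  m <- vapply(data[loci], normalize_call, character(nrow(data)))
  m <- matrix(m, nrow = nrow(data), dimnames = list(NULL, loci))
  bad <- !is.na(m) & !(m %in% c(DIPLOID_TOKENS, HEMI_TOKENS))
  if (any(bad)) {
    stop("unknown genotype token(s): ",
         paste(unique(m[bad]), collapse = ", "), call. = FALSE)
  }
  sex <- validate_sex(data)
  x_loci <- panel_loci(panel, "X")
  xm <- m[, x_loci, drop = FALSE]
  male <- sex == "M"
  if (any(male & any_call_in(xm, DIPLOID_TOKENS))) {
    stop("male X-island calls must be hemizygous (C/G); found a diploid call ",
         "on a male X locus", call. = FALSE)
  }
  if (any(!male & any_call_in(xm, HEMI_TOKENS))) {
    stop("female X-island calls must be diploid; found a hemizygous call ",
         "on a female X locus", call. = FALSE)
  }
  auto <- m[, setdiff(panel$locus_id, x_loci), drop = FALSE]
  if (any(any_call_in(auto, HEMI_TOKENS))) {
    stop("autosomal calls must be diploid; found a hemizygous 2L/3L call",
         call. = FALSE)
  }
  m
}

# rowwise: does any cell of m fall in `tokens`?
any_call_in <- function(m, tokens) {
  if (ncol(m) == 0) return(rep(FALSE, nrow(m)))
  rowSums(matrix(m %in% tokens, nrow = nrow(m))) > 0
}

validate_sex <- function(data) {
  if (!"sex" %in% names(data)) stop("column `sex` is required", call. = FALSE)
  sex <- toupper(as.character(data$sex))
  if (any(is.na(sex)) || !all(sex %in% c("M", "F"))) {
    stop("`sex` must be \"M\" or \"F\" for every individual", call. = FALSE)
  }
  sex
}

#' Which individuals have complete DIS genotypes?
#'
#' Individuals with any missing DIS call are excluded from all analyses
#' except those focused on the kdr sweep; the optional `rdna` and `kdr`
#' columns play no part in completeness.
#'
#' @param data Genotype tibble (one row per individual, one column per
#'   panel locus).
#' @param panel A [dis_panel()].
#' @return Logical vector, `TRUE` where no panel call is missing.
#' @export
is_complete <- function(data, panel = dis_panel()) {
  panel <- validate_panel(panel)
  m <- genotype_matrix(data, panel)
  rowSums(is.na(m)) == 0
}

island_state_of <- function(m, loci) {
  sub <- m[, loci, drop = FALSE]
  n_miss <- rowSums(is.na(sub))
  n_col <- rowSums(matrix(sub %in% c("CC", "C"), nrow = nrow(sub)))
  n_gam <- rowSums(matrix(sub %in% c("GG", "G"), nrow = nrow(sub)))
  n_het <- rowSums(matrix(sub %in% "CG", nrow = nrow(sub)))
  k <- length(loci)
  dplyr::case_when(
    n_miss > 0 ~ "MISSING",
    n_col == k ~ "HOM_COL",
    n_gam == k ~ "HOM_GAM",
    n_het == k ~ "HET_ENTIRE",
    .default = "RECOMBINED"
  )
}

#' Per-island genotype states
#'
#' Summarises each individual's DIS calls within each island of
#' speciation. `HOM_COL` / `HOM_GAM`: every call homospecific (hemizygous
#' male X calls count as homospecific); `HET_ENTIRE`: heterozygous at all
#' loci of the island, the signature of an entirely introgressed
#' heterospecific island; `RECOMBINED`: any other mixture, evidence of
#' crossover within the island; `MISSING`: any call missing.
#'
#' @inheritParams is_complete
#' @return A tibble with one row per individual x island: `sample_id`,
#'   `island`, `state`.
#' @export
island_states <- function(data, panel = dis_panel()) {
  panel <- validate_panel(panel)
  m <- genotype_matrix(data, panel)
  islands <- c("X", "2L", "3L")
  purrr::map_dfr(islands, function(isl) {
    tibble::tibble(
      sample_id = as.character(data$sample_id),
      island = isl,
      state = island_state_of(m, panel_loci(panel, isl))
    )
  })
}

#' Classify individuals from their DIS genotypes
#'
#' The central classifier. Each complete individual is placed in exactly
#' one hybridization category:
#'
#' * `PURE_COL` / `PURE_GAM` — non-hybrid, homospecific at every panel
#'   locus (hemizygous male X calls included);
#' * `F1` — first-generation hybrid: a female heterozygous at all loci,
#'   or a male heterozygous at all autosomal loci with a single-species
#'   hemizygous X (inherited from his mother);
#' * `BACKCROSS` — any other (recombinant) genotype, the F1+n class.
#'
#' Each individual is then assigned to *An. coluzzii* or *An. gambiae* by
#' a simple majority rule over species-specific allele copies (homozygous
#' calls contribute 2 copies, heterozygous 1 to each species, hemizygous
#' 1). Exact ties are broken by the species of the X island — the island
#' that drives swarm membership and never recombined in field data; a tie
#' with a heterozygous X has no majority and yields `NA` species. Tie
#' events are flagged in `species_tie` and counted in a message.
#'
#' Per-island states ([island_states()]), the maternal X species of male
#' F1s, and discordance between the X-island DIS species and the optional
#' `rdna` ITS diagnostic (a marker closer to the X centromere, whose
#' disagreement with a homospecific DIS X flags a rare within-island
#' recombination event) are reported alongside.
#'
#' @inheritParams is_complete
#' @param keep_incomplete Keep rows with missing DIS calls? Default drops
#'   them with a message (they remain usable for kdr-only analyses when
#'   kept; their classification columns are `NA`).
#' @return The input tibble plus columns `complete`, `category`,
#'   `species`, `n_col_alleles`, `n_gam_alleles`, `species_tie`,
#'   `state_X`, `state_2L`, `state_3L`, `f1_maternal_species`,
#'   `x_rdna_discordant`.
#' @examples
#' panel <- dis_panel()
#' geno <- fixture_from_counts(
#'   tibble::tibble(village = "VK7", year = 2008, swarm_type = "COL",
#'                  n_swarms = 2, sex = "M",
#'                  n_pure_col = 3, n_pure_gam = 0, n_f1 = 1, n_backcross = 4),
#'   panel
#' )
#' classify_genotypes(geno, panel) |> dplyr::count(category)
#' @export
classify_genotypes <- function(data, panel = dis_panel(), keep_incomplete = FALSE) {
  panel <- validate_panel(panel)
  data <- tibble::as_tibble(data)
  if (!"sample_id" %in% names(data)) {
    stop("column `sample_id` is required", call. = FALSE)
  }
  if (anyDuplicated(data$sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(utils::head(unique(data$sample_id[duplicated(data$sample_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  sex <- validate_sex(data)
  m <- genotype_matrix(data, panel)
  complete <- rowSums(is.na(m)) == 0

  x_loci <- panel_loci(panel, "X")
  auto_loci <- setdiff(panel$locus_id, x_loci)
  state_x <- island_state_of(m, x_loci)
  state_2l <- island_state_of(m, panel_loci(panel, "2L"))
  state_3l <- island_state_of(m, panel_loci(panel, "3L"))

  n_col <- rowSums(matrix(c(CC = 2, GG = 0, CG = 1, C = 1, G = 0)[m],
                          nrow = nrow(m)))
  n_gam <- rowSums(matrix(c(CC = 0, GG = 2, CG = 1, C = 0, G = 1)[m],
                          nrow = nrow(m)))
  n_col[!complete] <- NA_real_
  n_gam[!complete] <- NA_real_

  all_col <- rowSums(matrix(m %in% c("CC", "C"), nrow = nrow(m))) == ncol(m)
  all_gam <- rowSums(matrix(m %in% c("GG", "G"), nrow = nrow(m))) == ncol(m)
  auto_het <- rowSums(matrix(m[, auto_loci, drop = FALSE] %in% "CG",
                             nrow = nrow(m))) == length(auto_loci)
  is_f1 <- (sex == "F" & auto_het & state_x == "HET_ENTIRE") |
    (sex == "M" & auto_het & state_x %in% c("HOM_COL", "HOM_GAM"))
  category <- dplyr::case_when(
    !complete ~ NA_character_,
    all_col ~ "PURE_COL",
    all_gam ~ "PURE_GAM",
    is_f1 ~ "F1",
    .default = "BACKCROSS"
  )

  x_species <- dplyr::case_when(
    state_x == "HOM_COL" ~ "COL",
    state_x == "HOM_GAM" ~ "GAM",
    .default = NA_character_
  )
  tie <- complete & n_col == n_gam
  species <- dplyr::case_when(
    !complete ~ NA_character_,
    n_col > n_gam ~ "COL",
    n_gam > n_col ~ "GAM",
    .default = x_species
  )
  n_tie <- sum(tie, na.rm = TRUE)
  if (n_tie > 0) {
    message(n_tie, " individual(s) had an exact allele-tally tie; ",
            "resolved by X-island species (NA where the X is heterozygous)")
  }

  f1_maternal <- ifelse(category == "F1" & sex == "M", x_species, NA_character_)

  rdna <- if ("rdna" %in% names(data)) {
    toupper(as.character(data$rdna))
  } else {
    rep(NA_character_, nrow(data))
  }
  rdna[rdna %in% c("", "NA")] <- NA_character_
  if (!all(is.na(rdna) | rdna %in% c("COL", "GAM"))) {
    stop("`rdna` values must be col/gam or NA", call. = FALSE)
  }
  discordant <- ifelse(is.na(rdna) | is.na(x_species), NA, x_species != rdna)

  out <- data
  out$complete <- complete
  out$category <- category
  out$species <- species
  out$n_col_alleles <- n_col
  out$n_gam_alleles <- n_gam
  out$species_tie <- tie
  out$state_X <- state_x
  out$state_2L <- state_2l
  out$state_3L <- state_3l
  out$f1_maternal_species <- f1_maternal
  out$x_rdna_discordant <- discordant

  if (!keep_incomplete && any(!complete)) {
    message("dropped ", sum(!complete),
            " individual(s) with incomplete DIS genotypes")
    out <- out[complete, , drop = FALSE]
  }
  out
}

#' Maternal X species of male F1 hybrids
#'
#' Males inherit their single X from their mother, so a male F1's
#' hemizygous X-island species identifies the maternal parent species of
#' the cross.
#'
#' @param classified Output of [classify_genotypes()].
#' @return A tibble of the male F1 rows with `sample_id`, and
#'   `f1_maternal_species`; errors if called on rows that are not male F1s.
#' @export
f1_maternal_species <- function(classified) {
  check_classified(classified)
  out <- dplyr::filter(classified, .data$category == "F1", .data$sex == "M")
  dplyr::select(out, "sample_id", "f1_maternal_species")
}

check_classified <- function(x, cols = c("sample_id", "sex", "category",
                                         "species", "state_X", "state_2L",
                                         "state_3L")) {
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0) {
    stop("expected a classify_genotypes() result; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
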