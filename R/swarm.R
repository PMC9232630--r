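#' Type swarms as monospecific or mixed from member species assignments
#'
#' A swarm is a pure (monospecific) *An. coluzzii* or *An. gambiae* type
#' when every member — backcrosses included, via their majority-rule
#' species — is assigned to that species, and mixed when both species are
#' present in any proportion. Members without a species assignment
#' (allele-tally ties with a heterozygous X) are ignored for typing.
#'
#' @param classified Output of [classify_genotypes()]; rows without a
#'   `swarm_id` are ignored.
#' @return A tibble with one row per swarm: `swarm_id`, `village`, `year`,
#'   `n`, `n_col`, `n_gam`, `swarm_type` (`"COL"`, `"GAM"` or `"MIXED"`).
#' @examples
#' # see classify_genotypes() for building `classified`
#' @export
swarm_types <- function(classified) {
  check_classified(classified)
  if (!"swarm_id" %in% names(classified)) {
    stop("column `swarm_id` is required to type swarms", call. = FALSE)
  }
  members <- dplyr::filter(classified, !is.na(.data$swarm_id),
                           .data$swarm_id != "")
  if (nrow(members) == 0) stop("no swarm members to type", call. = FALSE)
  for (col in c("village", "year")) {
    if (!col %in% names(members)) members[[col]] <- NA
  }
  members |>
    dplyr::group_by(.data$swarm_id) |>
    dplyr::summarise(
      village = dplyr::first(.data$village),
      year = dplyr::first(.data$year),
      n = dplyr::n(),
      n_col = sum(.data$species == "COL", na.rm = TRUE),
      n_gam = sum(.data$species == "GAM", na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(swarm_type = assign_swarm_type_counts(.data$n_col, .data$n_gam)) |>
    dplyr::arrange(.data$village, .data$year, .data$swarm_id)
}

assign_swarm_type_counts <- function(n_col, n_gam) {
  dplyr::case_when(
    n_col > 0 & n_gam == 0 ~ "COL",
    n_gam > 0 & n_col == 0 ~ "GAM",
    n_col > 0 & n_gam > 0 ~ "MIXED",
    .default = NA_character_
  )
}

#' Swarm type from a vector of member species
#'
#' Vector-level form of the swarm-typing rule, for use outside the main
#' pipeline.
#'
#' @param species Character vector of member species (`"COL"`/`"GAM"`);
#'   order is irrelevant.
#' @return `"COL"`, `"GAM"` or `"MIXED"`.
#' @export
assign_swarm_type <- function(species) {
  species <- species[!is.na(species)]
  if (length(species) == 0) stop("swarm has no members with a species",
                                 call. = FALSE)
  if (!all(species %in% c("COL", "GAM"))) {
    stop("species must be COL or GAM", call. = FALSE)
  }
  assign_swarm_type_counts(sum(species == "COL"), sum(species == "GAM"))
}

#' Does an island genotype match the swarm it was captured in?
#'
#' The match predicate behind the association analysis: an island matches
#' a monospecific swarm if and only if it is homospecific (`HOM_*`) for
#' the swarm's species. Entirely heterozygous, recombined, and
#' homospecific-for-the-other-species islands all count as mismatches.
#'
#' @param state Island state(s) as returned by [island_states()].
#' @param swarm_type `"COL"` or `"GAM"` (recycled); mixed swarms have no
#'   match definition and raise an error.
#' @return Logical vector.
#' @export
island_matches_swarm <- function(state, swarm_type) {
  if (any(!swarm_type %in% c("COL", "GAM"))) {
    stop("island match is defined only for monospecific swarms", call. = FALSE)
  }
  state == paste0("HOM_", swarm_type)
}

#' Build the individual-by-island swarm match table
#'
#' Expands each retained individual into one row per island recording
#' whether that island's genotype matches the (monospecific) swarm the
#' individual was captured in. Individuals from mixed swarms are
#' excluded. F1 hybrids are excluded throughout: the analysis contrasts
#' non-hybrids with F1+n recombinants.
#'
#' The `restriction` reproduces the nested analysis sets used for the
#' association tables:
#' * `"nonrecombinant"` — individuals homozygous at every locus, i.e.
#'   every island `HOM_COL` or `HOM_GAM` (almost all are pure
#'   non-hybrids, but a fully homozygous backcross with islands of both
#'   species qualifies);
#' * `"entire_islands"` — adds recombinant individuals whose
#'   heterospecific islands are all entirely heterozygous (whole-island
#'   introgression, no within-island crossover);
#' * `"all"` — adds within-island recombinants too.
#'
#' @param classified Output of [classify_genotypes()] (complete records).
#' @param swarms Output of [swarm_types()]; computed from `classified`
#'   when omitted.
#' @param restriction One of `"nonrecombinant"`, `"entire_islands"`,
#'   `"all"`.
#' @return A tibble with one row per individual x island: `sample_id`,
#'   `sex`, `species`, `swarm_id`, `swarm_type`, `island`, `island_state`,
#'   `matches_swarm`, `restriction`.
#' @export
build_match_table <- function(classified, swarms = NULL,
                              restriction = c("entire_islands",
                                              "nonrecombinant", "all")) {
  restriction <- match.arg(restriction)
  check_classified(classified)
  if (is.null(swarms)) swarms <- swarm_types(classified)
  mono <- dplyr::filter(swarms, .data$swarm_type %in% c("COL", "GAM"))
  members <- classified |>
    dplyr::filter(!is.na(.data$swarm_id), .data$category != "F1",
                  !is.na(.data$species)) |>
    dplyr::inner_join(dplyr::select(mono, "swarm_id", "swarm_type"),
                      by = "swarm_id")

  st <- cbind(members$state_X, members$state_2L, members$state_3L)
  hom <- st == "HOM_COL" | st == "HOM_GAM"
  keep <- switch(restriction,
    nonrecombinant = rowSums(hom) == 3,
    entire_islands = rowSums(hom | st == "HET_ENTIRE") == 3,
    all = rep(TRUE, nrow(members))
  )
  members <- members[keep, , drop = FALSE]

  members |>
    dplyr::select("sample_id", "sex", "species", "swarm_id", "swarm_type",
                  "state_X", "state_2L", "state_3L") |>
    tidyr::pivot_longer(c("state_X", "state_2L", "state_3L"),
                        names_to = "island", names_prefix = "state_",
                        values_to = "island_state") |>
    dplyr::mutate(
      island = factor(.data$island, levels = c("X", "2L", "3L")),
      matches_swarm = island_matches_swarm(.data$island_state,
                                           .data$swarm_type),
      restriction = restriction
    )
}

#' Island-by-island swarm match proportions with Wilson intervals
#'
#' Summarises a match table into the proportion of island genotypes
#' matching the swarm of capture, per species, sex and island — the
#' quantity whose near-perfection on the X chromosome and breakdown on 2L
#' is the study's headline contrast. Confidence intervals are Wilson
#' score intervals (well-behaved at proportions of 0 or 1, where the
#' interesting values sit).
#'
#' @param match_table Output of [build_match_table()].
#' @param conf_level Confidence level for the Wilson interval.
#' @return A tibble with `species`, `sex`, `island`, `n`, `n_match`,
#'   `prop_match`, `conf_low`, `conf_high`.
#' @export
match_proportions <- function(match_table, conf_level = 0.95) {
  match_table |>
    dplyr::group_by(.data$species, .data$sex, .data$island) |>
    dplyr::summarise(n = dplyr::n(), n_match = sum(.data$matches_swarm),
                     .groups = "drop") |>
    dplyr::mutate(
      prop_match = .data$n_match / .data$n,
      wilson_ci(.data$n_match, .data$n, conf_level)
    )
}

wilson_ci <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  tibble::tibble(conf_low = pmax(0, centre - half),
                 conf_high = pmin(1, centre + half))
}
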