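normalize_kdr <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x %in% c("", "NA", ".")] <- NA_character_
  x[x == "SR"] <- "RS"
  bad <- !is.na(x) & !x %in% c("RR", "RS", "SS")
  if (any(bad)) {
    stop("unknown kdr genotype(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' kdr genotype frequencies by village, year and species
#'
#' Summarises the knockdown-resistance (kdr) genotypes — RR resistant
#' homozygote, RS heterozygote, SS susceptible homozygote — per
#' village x year x species stratum. The kdr target-site mutations sit
#' inside the 2L island, so the sweep of the resistant allele through
#' *An. coluzzii* tracks the adaptive introgression of that island from
#' *An. gambiae*. Individuals without a kdr call are excluded from the
#' denominators; empty strata keep an `n = 0` row.
#'
#' @param classified Output of [classify_genotypes()] (needs `kdr`,
#'   `village`, `year`, `species` columns); incomplete DIS genotypes may
#'   be retained here (`keep_incomplete = TRUE`), the kdr analyses being
#'   the stated exception to the completeness filter.
#' @return A tibble with `village`, `year`, `species`, `n`, `freq_RR`,
#'   `freq_RS`, `freq_SS`.
#' @export
kdr_frequencies <- function(classified) {
  if (!"kdr" %in% names(classified)) {
    stop("column `kdr` is required", call. = FALSE)
  }
  classified$kdr <- normalize_kdr(classified$kdr)
  classified |>
    dplyr::group_by(.data$village, .data$year, .data$species) |>
    dplyr::summarise(
      n = sum(!is.na(.data$kdr)),
      freq_RR = sum(.data$kdr == "RR", na.rm = TRUE) / n,
      freq_RS = sum(.data$kdr == "RS", na.rm = TRUE) / n,
      freq_SS = sum(.data$kdr == "SS", na.rm = TRUE) / n,
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("freq_"),
                                \(f) ifelse(.data$n > 0, f, NA_real_)))
}

#' Classify An. coluzzii 2L islands by kdr-driven recovery status
#'
#' After the *An. gambiae* 2L island introgressed into *An. coluzzii* on
#' the back of the resistant kdr allele, within-island recombination
#' produced haplotypes combining coluzzii-like pericentromeric DIS loci
#' with the resistant allele. At the (unphased) individual level:
#'
#' * `COL_RECOVERED_2L` — carries the resistant allele (RR or RS) and is
#'   homozygous coluzzii at the centromere-proximal 2L DIS loci (ranks
#'   `1..k`);
#' * `GAM_LIKE_2L` — 2L island entirely heterozygous or homozygous
#'   gambiae (heterospecific pericentromeric signal);
#' * `OTHER` — everything else, including resistant-free (SS)
#'   coluzzii-typical 2L islands of the pre-introgression type.
#'
#' @param classified Output of [classify_genotypes()]; rows are filtered
#'   to *An. coluzzii* with a kdr call and complete 2L calls.
#' @param panel The [dis_panel()].
#' @param k Number of centromere-proximal 2L loci required homozygous
#'   coluzzii for recovery (default: all of them).
#' @return The filtered tibble with an added `recovery_class` column.
#' @export
classify_2l_recovery <- function(classified, panel = dis_panel(), k = NULL) {
  check_classified(classified)
  if (!"kdr" %in% names(classified)) {
    stop("column `kdr` is required", call. = FALSE)
  }
  panel <- validate_panel(panel)
  loci_2l <- panel |>
    dplyr::filter(.data$island == "2L") |>
    dplyr::arrange(.data$rank)
  if (is.null(k)) k <- nrow(loci_2l)
  if (k < 1 || k > nrow(loci_2l)) {
    stop("`k` must be between 1 and the number of 2L loci", call. = FALSE)
  }
  prox <- loci_2l$locus_id[seq_len(k)]
  d <- classified
  d$kdr <- normalize_kdr(d$kdr)
  d <- dplyr::filter(d, .data$species == "COL", !is.na(.data$kdr),
                     .data$state_2L != "MISSING")
  prox_m <- as.matrix(as.data.frame(lapply(d[prox], normalize_call)))
  prox_col <- if (nrow(d) == 0) logical(0) else
    rowSums(matrix(prox_m == "CC", nrow = nrow(d))) == k
  d$recovery_class <- dplyr::case_when(
    d$kdr %in% c("RR", "RS") & prox_col ~ "COL_RECOVERED_2L",
    d$state_2L %in% c("HET_ENTIRE", "HOM_GAM") ~ "GAM_LIKE_2L",
    .default = "OTHER"
  )
  d
}

#' Trend test for 2L island recovery
#'
#' G-test of year against 2L class (`COL_RECOVERED_2L` vs `GAM_LIKE_2L`)
#' among kdr-genotyped *An. coluzzii*: a significant association with
#' rising recovered frequency indicates the population progressively
#' regaining its species-specific 2L island after integrating the
#' resistant kdr allele.
#'
#' @param recovery Output of [classify_2l_recovery()], typically filtered
#'   to one village.
#' @return A `dis_assoc` object; the underlying year-by-class count table
#'   is in `$table`.
#' @export
recovery_trend <- function(recovery) {
  if (!"recovery_class" %in% names(recovery)) {
    stop("expected a classify_2l_recovery() result", call. = FALSE)
  }
  d <- dplyr::filter(recovery,
                     .data$recovery_class %in% c("COL_RECOVERED_2L",
                                                 "GAM_LIKE_2L"))
  years <- sort(unique(d$year))
  if (length(years) < 2) {
    stop("at least two year strata are required", call. = FALSE)
  }
  m <- as.matrix(table(factor(d$year, levels = years),
                       factor(d$recovery_class,
                              levels = c("COL_RECOVERED_2L", "GAM_LIKE_2L"))))
  g_test(m)
}

#' Combine L1014F and L1014S kdr locus calls into one resistance genotype
#'
#' The knockdown-resistance target site carries two alternative
#' resistance mutations, L1014F ("West African") and L1014S ("East
#' African"), both inside the 2L island. The default counts a resistant
#' allele scored at either locus; `mode = "f_only"` restricts to the
#' L1014F call alone.
#'
#' @param kdr_f,kdr_s Genotype vectors (`RR`/`RS`/`SS`/`NA`) at the two
#'   mutations.
#' @param mode `"either"` or `"f_only"`.
#' @return A combined genotype vector: number of haplotypes carrying a
#'   resistant allele at either considered locus, capped at 2, expressed
#'   as `RR`/`RS`/`SS` (`NA` where all considered calls are missing).
#' @export
combine_kdr_calls <- function(kdr_f, kdr_s, mode = c("either", "f_only")) {
  mode <- match.arg(mode)
  kdr_f <- normalize_kdr(kdr_f)
  if (mode == "f_only") return(kdr_f)
  kdr_s <- normalize_kdr(kdr_s)
  r_count <- function(x) c(RR = 2L, RS = 1L, SS = 0L)[x]
  n_r <- pmin(2L, dplyr::coalesce(r_count(kdr_f), 0L) +
                dplyr::coalesce(r_count(kdr_s), 0L))
  out <- c("SS", "RS", "RR")[n_r + 1L]
  out[is.na(kdr_f) & is.na(kdr_s)] <- NA_character_
  out
}
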