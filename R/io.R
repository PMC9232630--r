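#' Read a DIS genotype table
#'
#' Reads the standard delimited genotype table (TSV by default; comma
#' detected automatically): one row per individual with columns
#' `sample_id`, `sex` (M/F), `life_stage` (swarming/indoor/larva),
#' `village`, `year`, `swarm_id` (may be empty), one column per panel
#' locus with calls in `CC`/`GG`/`CG`/`C`/`G`/`NA`, and optional `rdna`
#' (col/gam) and `kdr` (RR/RS/SS) columns. Rows violating the genotype
#' model — a diploid call on a male X locus, an unknown token, a
#' duplicated sample id — are rejected with row-numbered diagnostics; a
#' summary of rows read, incomplete and rejected is messaged.
#'
#' @param path File path.
#' @param panel The [dis_panel()] the table is keyed by.
#' @return A genotype tibble ready for [classify_genotypes()], with an
#'   attribute `read_log` (rows read / incomplete / rejected).
#' @export
read_genotype_table <- function(path, panel = dis_panel()) {
  panel <- validate_panel(panel)
  header <- readLines(path, n = 1)
  delim <- if (stringr::str_count(header, ",") >
               stringr::str_count(header, "\t")) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character(), year = readr::col_integer()
  ), na = c("", "NA"))
  required <- c("sample_id", "sex", "life_stage", "village", "year",
                "swarm_id", panel$locus_id)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  rejected <- character(0)
  reject <- function(rows, why) {
    rejected <<- c(rejected,
                   sprintf("row %d (%s): %s", rows,
                           raw$sample_id[rows] %||% "?", why))
    rows
  }
  bad <- integer(0)
  dup <- which(duplicated(raw$sample_id) |
                 duplicated(raw$sample_id, fromLast = TRUE))
  if (length(dup) > 0) {
    stop("duplicate sample_id(s): ",
         paste(unique(raw$sample_id[dup]), collapse = ", "), call. = FALSE)
  }
  sex <- toupper(raw$sex)
  bad <- union(bad, reject(which(!sex %in% c("M", "F")), "invalid sex"))

  m <- vapply(raw[panel$locus_id], normalize_call, character(nrow(raw)))
  m <- matrix(m, nrow = nrow(raw))
  unknown <- !is.na(m) & !(m %in% c(DIPLOID_TOKENS, HEMI_TOKENS))
  bad <- union(bad, reject(which(rowSums(unknown) > 0),
                           "unknown genotype token"))
  x_cols <- match(panel_loci(panel, "X"), panel$locus_id)
  xm <- m[, x_cols, drop = FALSE]
  male <- sex == "M"
  bad_male_x <- which(male & rowSums(matrix(xm %in% DIPLOID_TOKENS,
                                            nrow = nrow(raw))) > 0)
  bad <- union(bad, reject(bad_male_x,
                           "diploid call on a male X locus (males are hemizygous)"))
  bad_female_x <- which(!male & rowSums(matrix(xm %in% HEMI_TOKENS,
                                               nrow = nrow(raw))) > 0)
  bad <- union(bad, reject(bad_female_x, "hemizygous call on a female X locus"))
  auto <- m[, -x_cols, drop = FALSE]
  bad <- union(bad, reject(which(rowSums(matrix(auto %in% HEMI_TOKENS,
                                                nrow = nrow(raw))) > 0),
                           "hemizygous autosomal call"))

  if (length(rejected) > 0) {
    message("rejected ", length(bad), " row(s):\n  ",
            paste(rejected, collapse = "\n  "))
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  out <- raw[keep, , drop = FALSE]
  out$sex <- toupper(out$sex)
  for (loc in panel$locus_id) out[[loc]] <- normalize_call(out[[loc]])
  n_incomplete <- sum(!is_complete(out, panel))
  message("read ", nrow(raw), " row(s): ", length(keep), " kept, ",
          n_incomplete, " incomplete, ", length(bad), " rejected")
  attr(out, "read_log") <- c(read = nrow(raw), kept = length(keep),
                             incomplete = n_incomplete,
                             rejected = length(bad))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @rdname read_genotype_table
#' @param data Genotype tibble to write.
#' @return [write_genotype_table()] returns `path` invisibly.
#' @export
write_genotype_table <- function(data, path) {
  readr::write_tsv(data, path, na = "NA")
  invisible(path)
}

#' Write the standard analysis report tables
#'
#' Runs the downstream summaries on a classified dataset and writes them
#' as TSV files into `outdir`: a composition table (per
#' village x year x swarm-type category counts and percentages, in the
#' style of the published tables, percentages to 1 decimal), the swarm
#' summary, island-by-island match proportions, pairwise island
#' comparisons per species and sex, kdr frequency tables when a `kdr`
#' column is present, and a run manifest recording counts at each filter
#' step. Output ordering is deterministic (village, year, swarm, sample),
#' so identical inputs give byte-identical files.
#'
#' @param classified Output of [classify_genotypes()].
#' @param outdir Output directory, created if needed.
#' @param restriction Passed to [build_match_table()].
#' @return Invisibly, the named vector of files written.
#' @export
write_report <- function(classified, outdir,
                         restriction = "entire_islands") {
  check_classified(classified)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  emit <- function(x, name) {
    path <- file.path(outdir, name)
    readr::write_tsv(x, path, na = "NA")
    files[[name]] <<- path
  }

  composition <- classified |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::count(.data$village, .data$year, .data$sex, .data$category) |>
    dplyr::group_by(.data$village, .data$year, .data$sex) |>
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$village, .data$year, .data$sex, .data$category)
  emit(composition, "composition.tsv")

  has_swarms <- "swarm_id" %in% names(classified) &&
    any(!is.na(classified$swarm_id))
  if (has_swarms) {
    swarms <- swarm_types(classified)
    emit(swarms, "swarms.tsv")
    match_tbl <- build_match_table(classified, swarms,
                                   restriction = restriction)
    emit(dplyr::arrange(match_tbl, .data$swarm_id, .data$sample_id,
                        .data$island),
         "match_table.tsv")
    emit(match_proportions(match_tbl), "match_proportions.tsv")
    pairwise <- match_tbl |>
      dplyr::group_by(.data$species, .data$sex) |>
      dplyr::group_modify(function(d, key) {
        pairs <- list(c("X", "2L"), c("X", "3L"), c("2L", "3L"))
        purrr::map_dfr(pairs, function(pr) {
          res <- tryCatch(
            tidy(pairwise_match_comparison(d, pr[1], pr[2])),
            error = function(e) tibble::tibble(statistic = NA_real_)
          )
          dplyr::mutate(res, comparison = paste(pr, collapse = " vs "),
                        .before = 1)
        })
      }) |>
      dplyr::ungroup()
    emit(pairwise, "pairwise_comparisons.tsv")
  }

  if ("kdr" %in% names(classified)) {
    emit(kdr_frequencies(classified), "kdr_frequencies.tsv")
  }

  manifest <- tibble::tibble(
    key = c("n_input", "n_complete", "n_classified", "n_swarm_members",
            "package_version", "r_version"),
    value = c(nrow(classified),
              sum(classified$complete %||% rep(TRUE, nrow(classified))),
              sum(!is.na(classified$category)),
              if (has_swarms) sum(!is.na(classified$swarm_id)) else 0,
              as.character(utils::packageVersion("disswarm")),
              paste(R.version$major, R.version$minor, sep = "."))
  )
  emit(manifest, "manifest.tsv")
  invisible(unlist(files))
}
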