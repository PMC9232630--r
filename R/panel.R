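#' Build a divergence-island SNP (DIS) panel definition
#'
#' The DIS panel is the ordered set of SNP loci lying inside the three
#' pericentromeric islands of speciation of the *An. gambiae* complex:
#' the X island, the 2L island and the 3L island. Each locus is fixed for
#' alternative alleles in non-introgressed *An. coluzzii* and
#' *An. gambiae* s.s., so its genotype reads directly as species ancestry.
#' The default panel carries 7 X, 5 2L and 3 3L loci.
#'
#' Within each island loci are ranked by physical order, rank 1 being the
#' locus nearest the centromere. No genome coordinates are modelled: the
#' analyses only ever use island membership and centromere-proximal order.
#'
#' @param n_x,n_2l,n_3l Number of loci per island.
#' @param coluzzii_allele,gambiae_allele Optional character vectors of
#'   diagnostic nucleotides, one per locus (coluzzii first). Defaults are
#'   arbitrary distinct pairs: genotype tables are species-coded
#'   (`CC`/`GG`/`CG`/`C`/`G`), so the nucleotides are carried as panel
#'   metadata only.
#'
#' @return A tibble of class `dis_panel` with columns `locus_id`, `island`
#'   (one of `"X"`, `"2L"`, `"3L"`), `rank` (1 = nearest centromere),
#'   `coluzzii_allele` and `gambiae_allele`.
#' @examples
#' dis_panel()
#' @export
dis_panel <- function(n_x = 7L, n_2l = 5L, n_3l = 3L,
                      coluzzii_allele = NULL, gambiae_allele = NULL) {
  sizes <- c(X = as.integer(n_x), `2L` = as.integer(n_2l), `3L` = as.integer(n_3l))
  if (any(is.na(sizes)) || any(sizes < 1L)) {
    stop("each island must contain at least one locus", call. = FALSE)
  }
  island <- rep(names(sizes), sizes)
  rank <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  n <- sum(sizes)
  if (is.null(coluzzii_allele)) {
    coluzzii_allele <- rep_len(c("A", "C", "T", "G"), n)
  }
  if (is.null(gambiae_allele)) {
    gambiae_allele <- rep_len(c("G", "T", "C", "A"), n)
  }
  panel <- tibble::tibble(
    locus_id = paste0(island, "_", rank),
    island = island,
    rank = as.integer(rank),
    coluzzii_allele = coluzzii_allele,
    gambiae_allele = gambiae_allele
  )
  validate_panel(panel)
}

#' Validate a DIS panel definition
#'
#' Checks the structural invariants a panel must satisfy before any
#' classification: unique locus ids, each locus in exactly one island,
#' ranks unique and contiguous within island, and distinct diagnostic
#' alleles at every locus.
#'
#' @param panel A data frame with columns `locus_id`, `island`, `rank`,
#'   `coluzzii_allele`, `gambiae_allele`.
#' @return The panel (as a `dis_panel` tibble), invisibly usable in
#'   pipelines; errors if any invariant fails.
#' @export
validate_panel <- function(panel) {
  required <- c("locus_id", "island", "rank", "coluzzii_allele", "gambiae_allele")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  panel <- tibble::as_tibble(panel)
  if (nrow(panel) == 0) stop("panel has no loci", call. = FALSE)
  if (anyDuplicated(panel$locus_id)) {
    stop("duplicate locus ids: ",
         paste(unique(panel$locus_id[duplicated(panel$locus_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_island <- setdiff(unique(panel$island), c("X", "2L", "3L"))
  if (length(bad_island) > 0) {
    stop("unknown island(s): ", paste(bad_island, collapse = ", "), call. = FALSE)
  }
  dup_rank <- panel |>
    dplyr::count(.data$island, .data$rank) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_rank) > 0) {
    stop("duplicated rank within island ",
         paste(unique(dup_rank$island), collapse = ", "), call. = FALSE)
  }
  if (any(panel$coluzzii_allele == panel$gambiae_allele)) {
    stop("diagnostic alleles must differ at every locus", call. = FALSE)
  }
  class(panel) <- unique(c("dis_panel", class(panel)))
  panel
}

#' @return For [island_sizes()], a named integer vector of locus counts per island.
#' @rdname dis_panel
#' @export
island_sizes <- function(panel) {
  panel <- validate_panel(panel)
  tab <- table(factor(panel$island, levels = c("X", "2L", "3L")))
  stats::setNames(as.integer(tab), names(tab))
}

panel_loci <- function(panel, island = NULL) {
  if (is.null(island)) return(panel$locus_id)
  panel$locus_id[panel$island %in% island]
}

#' Read or write a panel definition as a YAML config
#'
#' The config file holds one entry per locus with its island, rank and the
#' two species-diagnostic alleles, e.g.
#' `- {locus_id: X_1, island: X, rank: 1, coluzzii_allele: A, gambiae_allele: G}`.
#'
#' @param path File path.
#' @return [read_panel()] returns a validated `dis_panel` tibble;
#'   [write_panel()] returns `path` invisibly.
#' @export
read_panel <- function(path) {
  entries <- yaml::read_yaml(path)
  if (is.null(entries$loci)) loci <- entries else loci <- entries$loci
  panel <- purrr::map_dfr(loci, tibble::as_tibble)
  panel$rank <- as.integer(panel$rank)
  validate_panel(panel)
}

#' @param panel A `dis_panel`.
#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  yaml::write_yaml(
    list(loci = purrr::pmap(panel, \(...) list(...))),
    path
  )
  invisible(path)
}
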