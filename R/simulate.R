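#' Parameters for the forward two-species swarm simulator
#'
#' Bundles the simulation parameters with defaults representing the
#' study system: two large species pools fixed for opposite DIS alleles,
#' rare hybridization, island-specific recombination suppression
#' (complete on X, near-complete on 3L, weakest on 2L), strong positive
#' selection on the resistant kdr allele inside 2L, and swarm assembly
#' driven by the X-island genotype.
#'
#' @param n_col,n_gam Founding pool sizes (total population size is kept
#'   at `n_col + n_gam`).
#' @param generations Number of discrete, non-overlapping generations.
#' @param h Hybridization rate: probability that a mating is
#'   cross-species.
#' @param r_x,r_2l,r_3l Per-meiosis recombination probability within each
#'   island (at most one breakpoint, uniform over adjacent marker gaps).
#'   `r_x = 0` reflects that within-X recombination was never observed in
#'   the field; `r_3l` is far smaller than `r_2l`, matching the rarity of
#'   recombined 3L versus 2L chromosomes.
#' @param s Selective advantage of the resistant kdr allele: offspring
#'   viability is weighted by `(1 + s)` per R allele carried.
#' @param kdr_r_freq_gam Founder frequency of the resistant allele on
#'   *An. gambiae* 2L haplotypes (the R allele starts absent from
#'   *An. coluzzii* and introgresses with the 2L island).
#' @param swarm_size_mean Target mean swarm size (members are split into
#'   near-equal swarms of about this size); the field data average about
#'   19 males per swarm.
#' @param swarm_assembly_error Probability `eps` that a swarming
#'   individual joins a swarm not matching its X-island species.
#' @param sample_fraction Fraction of each output generation's adults
#'   recorded in the output tables.
#' @param stage_weights Probabilities that a recorded individual is
#'   sampled as a swarming adult, an indoor-resting adult, or a larva.
#' @param missing_rate Per-call probability of a missing DIS genotype in
#'   the output table.
#' @param output_generations Which generations to record (default: the
#'   final three, giving multi-year output for trend analyses).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_col = 1000, n_gam = 1000, generations = 10,
                       h = 0.01, r_x = 0, r_2l = 0.05, r_3l = 0.005,
                       s = 0.2, kdr_r_freq_gam = 0.8, swarm_size_mean = 19,
                       swarm_assembly_error = 0, sample_fraction = 0.5,
                       stage_weights = c(swarming = 0.5, indoor = 0.3,
                                         larva = 0.2),
                       missing_rate = 0, output_generations = NULL) {
  p <- list(n_col = as.integer(n_col), n_gam = as.integer(n_gam),
            generations = as.integer(generations), h = h, r_x = r_x,
            r_2l = r_2l, r_3l = r_3l, s = s,
            kdr_r_freq_gam = kdr_r_freq_gam,
            swarm_size_mean = swarm_size_mean,
            swarm_assembly_error = swarm_assembly_error,
            sample_fraction = sample_fraction,
            stage_weights = stage_weights / sum(stage_weights),
            missing_rate = missing_rate,
            output_generations = output_generations)
  probs <- unlist(p[c("h", "r_x", "r_2l", "r_3l", "kdr_r_freq_gam",
                      "swarm_assembly_error", "sample_fraction",
                      "missing_rate")])
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p$s < 0) stop("`s` must be non-negative", call. = FALSE)
  if (p$n_col + p$n_gam < 2 || p$n_col < 1 || p$n_gam < 1) {
    stop("both founding pools must be non-empty", call. = FALSE)
  }
  if (is.null(p$output_generations)) {
    p$output_generations <- seq(max(1, p$generations - 2), p$generations)
  }
  class(p) <- "sim_params"
  p
}

# One gamete per row: single-breakpoint meiosis across the columns of an
# island, choosing the starting haplotype at random and crossing over
# with probability r at a uniform marker gap.
meiosis <- function(h1, h2, r) {
  n <- nrow(h1)
  m <- ncol(h1)
  start2 <- stats::runif(n) < 0.5
  if (m == 1 || r == 0) {
    sel2 <- matrix(start2, n, m)
  } else {
    rec <- stats::runif(n) < r
    bp <- sample.int(m - 1, n, replace = TRUE) # crossover after column bp
    flip <- rec & outer(bp, seq_len(m), function(b, j) j > b)
    sel2 <- xor(matrix(start2, n, m), flip)
  }
  h1 * (1 - sel2) + h2 * sel2
}

# Allele coding: 0 = coluzzii, 1 = gambiae at DIS loci; at the kdr
# position (2L column 2, between DIS ranks 1 and 2) 1 = resistant R.
hap_species <- function(hap_matrix, x_cols) {
  rowMeans(hap_matrix[, x_cols, drop = FALSE]) > 0.5
}

founder_pop <- function(p, n_x = 7L) {
  n <- p$n_col + p$n_gam
  gam <- c(rep(FALSE, p$n_col), rep(TRUE, p$n_gam))
  male <- rep_len(c(TRUE, FALSE), n)
  fill <- function(cols) matrix(as.numeric(gam), n, cols)
  kdr_hap <- function() ifelse(gam, stats::runif(n) < p$kdr_r_freq_gam, 0)
  a2 <- function() {
    m <- fill(6L)
    m[, 2] <- kdr_hap()
    m
  }
  x2 <- fill(n_x)
  x2[male, ] <- NA_real_
  list(male = male, X1 = fill(n_x), X2 = x2, A2a = a2(), A2b = a2(),
       A3a = fill(3L), A3b = fill(3L))
}

# Advance one generation. Mating pools are X-island pools: a male belongs
# to his hemizygous X's species; a female to her X species, choosing one
# of her two X haplotypes at random (per mating) when heterozygous.
# X-heterozygous females reproduce but never enter swarm samples.
next_generation <- function(pop, p) {
  n <- length(pop$male)
  males <- which(pop$male)
  females <- which(!pop$male)
  if (length(males) == 0 || length(females) == 0) {
    stop("a sex died out; increase the population size", call. = FALSE)
  }
  male_gam <- hap_species(pop$X1[males, , drop = FALSE],
                          seq_len(ncol(pop$X1)))
  if (all(male_gam) || !any(male_gam)) {
    stop("one species' male pool died out", call. = FALSE)
  }

  n_cand <- 2L * n
  mi <- females[sample.int(length(females), n_cand, replace = TRUE)]
  f_sp1 <- hap_species(pop$X1[mi, , drop = FALSE], seq_len(ncol(pop$X1)))
  f_sp2 <- hap_species(pop$X2[mi, , drop = FALSE], seq_len(ncol(pop$X2)))
  coin <- stats::runif(n_cand) < 0.5
  mother_pool <- ifelse(coin, f_sp1, f_sp2) # TRUE = gambiae
  cross <- stats::runif(n_cand) < p$h
  father_pool <- xor(mother_pool, cross)
  gam_males <- males[male_gam]
  col_males <- males[!male_gam]
  fi <- integer(n_cand)
  fi[father_pool] <- gam_males[sample.int(length(gam_males),
                                          sum(father_pool), replace = TRUE)]
  fi[!father_pool] <- col_males[sample.int(length(col_males),
                                           sum(!father_pool), replace = TRUE)]

  son <- stats::runif(n_cand) < 0.5
  x_mat <- meiosis(pop$X1[mi, , drop = FALSE], pop$X2[mi, , drop = FALSE],
                   p$r_x)
  a2_mat <- meiosis(pop$A2a[mi, , drop = FALSE], pop$A2b[mi, , drop = FALSE],
                    p$r_2l)
  a2_pat <- meiosis(pop$A2a[fi, , drop = FALSE], pop$A2b[fi, , drop = FALSE],
                    p$r_2l)
  a3_mat <- meiosis(pop$A3a[mi, , drop = FALSE], pop$A3b[mi, , drop = FALSE],
                    p$r_3l)
  a3_pat <- meiosis(pop$A3a[fi, , drop = FALSE], pop$A3b[fi, , drop = FALSE],
                    p$r_3l)
  x_pat <- pop$X1[fi, , drop = FALSE] # hemizygous X passes intact
  x_pat[son, ] <- NA_real_

  # viability selection on the kdr resistant allele, within each
  # species pool: larval sites are species-segregated, so density
  # regulation holds each pool at its founding size while the resistant
  # allele sweeps within the pool
  n_r <- a2_mat[, 2] + a2_pat[, 2]
  w <- (1 + p$s)^n_r
  keep <- integer(0)
  for (pool_gam in c(FALSE, TRUE)) {
    cand <- which(mother_pool == pool_gam)
    n_pool <- if (pool_gam) p$n_gam else p$n_col
    if (length(cand) < n_pool) {
      stop("a species pool produced too few offspring candidates; ",
           "increase the population size", call. = FALSE)
    }
    keep <- c(keep, cand[sample.int(length(cand), n_pool,
                                    prob = w[cand])])
  }

  list(
    pop = list(male = son[keep],
               X1 = x_mat[keep, , drop = FALSE],
               X2 = x_pat[keep, , drop = FALSE],
               A2a = a2_mat[keep, , drop = FALSE],
               A2b = a2_pat[keep, , drop = FALSE],
               A3a = a3_mat[keep, , drop = FALSE],
               A3b = a3_pat[keep, , drop = FALSE]),
    n_matings = n,
    n_cross = sum(cross[keep]),
    cross = cross[keep]
  )
}

hap_to_tokens <- function(h1, h2, male = NULL) {
  g <- h1 + h2
  tok <- matrix(NA_character_, nrow(h1), ncol(h1))
  tok[g == 0] <- "CC"
  tok[g == 1] <- "CG"
  tok[g == 2] <- "GG"
  if (!is.null(male) && any(male)) {
    tok[male, ] <- c("C", "G")[h1[male, , drop = FALSE] + 1]
  }
  tok
}

#' Simulate swarm-sampled genotype data for the two-species system
#'
#' Runs a discrete-generation forward simulation: founders fixed for
#' opposite alleles at every DIS locus; matings within X-island species
#' pools except for a fraction `h` of cross-species matings; at most one
#' recombination breakpoint per island per meiosis with island-specific
#' probabilities; hemizygous X transmission from mother to son; viability
#' selection favouring kdr-resistant offspring; and, for each recorded
#' generation, sampling of adults into swarming / indoor-resting / larval
#' collections with swarming individuals assembled into swarms by
#' X-island species (mis-assembled with probability
#' `swarm_assembly_error`). X-heterozygous females reproduce (their
#' mating pool is a coin flip over their two X haplotypes) but do not
#' enter swarm samples, matching the absence of X-heterozygous females
#' from field swarm collections.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return A list of class `dis_sim`: `individuals` (genotype tibble in
#'   the standard table format, one row per sampled mosquito), `swarms`
#'   (swarm membership with the intended type), `truth` (per-individual
#'   true X species, cross-mating parentage and swarm-assembly flips) and
#'   `matings` (per-generation mating and cross-mating counts).
#' @examples
#' sim <- simulate_swarms(sim_params(n_col = 60, n_gam = 60,
#'                                   generations = 3), seed = 1)
#' dplyr::count(sim$individuals, life_stage)
#' @export
simulate_swarms <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  p <- params
  panel <- dis_panel()
  pop <- founder_pop(p)
  individuals <- list()
  swarms <- list()
  truth <- list()
  matings <- list()
  cross_flag <- rep(FALSE, length(pop$male))

  for (g in seq_len(p$generations)) {
    step <- next_generation(pop, p)
    pop <- step$pop
    cross_flag <- step$cross
    matings[[g]] <- tibble::tibble(generation = g, n_matings = step$n_matings,
                                   n_cross = step$n_cross)
    if (!g %in% p$output_generations) next

    n <- length(pop$male)
    recorded <- which(stats::runif(n) < p$sample_fraction)
    if (length(recorded) == 0) next
    stage <- sample(c("swarming", "indoor", "larva"), length(recorded),
                    replace = TRUE, prob = p$stage_weights)
    male <- pop$male[recorded]
    sp1 <- hap_species(pop$X1[recorded, , drop = FALSE],
                       seq_len(ncol(pop$X1)))
    sp2 <- ifelse(male, sp1,
                  hap_species(pop$X2[recorded, , drop = FALSE],
                              seq_len(ncol(pop$X2))))
    x_het <- !male & sp1 != sp2
    stage[stage == "swarming" & x_het] <- "indoor"
    x_gam <- sp1 # defined for swarm entrants (males and X-hom females)

    swarming <- stage == "swarming"
    flip <- swarming & stats::runif(length(recorded)) < p$swarm_assembly_error
    intended_gam <- xor(x_gam, flip)

    swarm_id <- rep(NA_character_, length(recorded))
    for (pool_gam in c(FALSE, TRUE)) {
      idx <- which(swarming & intended_gam == pool_gam)
      if (length(idx) == 0) next
      k <- max(1L, round(length(idx) / p$swarm_size_mean))
      assignment <- sample(rep_len(seq_len(k), length(idx)))
      swarm_id[idx] <- sprintf("G%d-%s-%02d", g,
                               ifelse(pool_gam, "GAM", "COL"), assignment)
    }

    tokens_x <- hap_to_tokens(pop$X1[recorded, , drop = FALSE],
                              pop$X2[recorded, , drop = FALSE], male)
    a2a <- pop$A2a[recorded, , drop = FALSE]
    a2b <- pop$A2b[recorded, , drop = FALSE]
    tokens_2l <- hap_to_tokens(a2a[, -2, drop = FALSE],
                               a2b[, -2, drop = FALSE])
    tokens_3l <- hap_to_tokens(pop$A3a[recorded, , drop = FALSE],
                               pop$A3b[recorded, , drop = FALSE])
    calls <- cbind(tokens_x, tokens_2l, tokens_3l)
    colnames(calls) <- panel$locus_id
    if (p$missing_rate > 0) {
      calls[matrix(stats::runif(length(calls)) < p$missing_rate,
                   nrow(calls))] <- NA_character_
    }
    n_r <- a2a[, 2] + a2b[, 2]
    kdr <- c("SS", "RS", "RR")[n_r + 1]
    rdna <- dplyr::case_when(
      male & pop$X1[recorded, 1] == 0 ~ "col",
      male & pop$X1[recorded, 1] == 1 ~ "gam",
      !male & pop$X1[recorded, 1] == pop$X2[recorded, 1] ~
        ifelse(pop$X1[recorded, 1] == 0, "col", "gam"),
      .default = NA_character_
    )

    ids <- sprintf("G%d-%05d", g, seq_along(recorded))
    individuals[[length(individuals) + 1]] <- tibble::as_tibble(calls) |>
      dplyr::mutate(
        sample_id = ids, sex = ifelse(male, "M", "F"),
        life_stage = stage, village = "SIM", year = 2000L + g,
        swarm_id = swarm_id, rdna = rdna, kdr = kdr,
        .before = 1
      )
    truth[[length(truth) + 1]] <- tibble::tibble(
      sample_id = ids, generation = g,
      x_species = ifelse(x_het, NA_character_,
                         ifelse(x_gam, "GAM", "COL")),
      x_het = x_het,
      from_cross_mating = cross_flag[recorded],
      swarming = swarming,
      intended_swarm_type = ifelse(swarming,
                                   ifelse(intended_gam, "GAM", "COL"),
                                   NA_character_),
      assembly_flipped = flip
    )
    sw <- tibble::tibble(sample_id = ids, swarm_id = swarm_id,
                         generation = g,
                         intended_type = ifelse(intended_gam, "GAM", "COL"))
    swarms[[length(swarms) + 1]] <- dplyr::filter(sw, !is.na(.data$swarm_id))
  }

  structure(
    list(individuals = dplyr::bind_rows(individuals),
         swarms = dplyr::bind_rows(swarms),
         truth = dplyr::bind_rows(truth),
         matings = dplyr::bind_rows(matings),
         params = p, seed = seed),
    class = "dis_sim"
  )
}

#' Recover simulator parameters from a simulation's truth records
#'
#' Estimates the hybridization rate `h` as the realized fraction of
#' cross-species matings among all matings that produced surviving
#' offspring, and the swarm-assembly error `eps` as the frequency of
#' swarm members whose observable X-island species differs from their
#' swarm's intended type. Both estimators are exact at their parameter's
#' zero (no cross matings, no mismatches).
#'
#' @param sim A `dis_sim` from [simulate_swarms()].
#' @return A one-row tibble with `h_hat`, `eps_hat`, `n_matings`,
#'   `n_swarm_members`.
#' @export
recover_parameters <- function(sim) {
  stopifnot(inherits(sim, "dis_sim"))
  truth <- dplyr::filter(sim$truth, .data$swarming)
  mismatch <- truth$x_species != truth$intended_swarm_type
  tibble::tibble(
    h_hat = sum(sim$matings$n_cross) / sum(sim$matings$n_matings),
    eps_hat = if (nrow(truth) > 0) mean(mismatch) else NA_real_,
    n_matings = sum(sim$matings$n_matings),
    n_swarm_members = nrow(truth)
  )
}

#' @export
print.dis_sim <- function(x, ...) {
  cat("Forward two-species swarm simulation\n")
  cat("  generations:", x$params$generations, " seed:", x$seed, "\n")
  cat("  recorded individuals:", nrow(x$individuals),
      " swarms:", length(unique(stats::na.omit(x$individuals$swarm_id))), "\n")
  invisible(x)
}
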