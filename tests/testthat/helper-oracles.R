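# Independent oracles and fixture generators used across the suite.
# Everything here is deliberately naive (loops, factorial arithmetic) so
# it shares no code path with the package implementation.

# Random complete genotype records honouring the sex/hemizygosity model.
# `bias` skews allele draws per record so species tallies vary widely.
random_records <- function(n, panel = dis_panel(), seed = 1) {
  set.seed(seed)
  x_loci <- panel$locus_id[panel$island == "X"]
  sex <- sample(c("M", "F"), n, replace = TRUE)
  bias <- stats::runif(n) # per-record coluzzii allele frequency
  out <- tibble::tibble(sample_id = sprintf("R%06d", seq_len(n)), sex = sex)
  for (loc in panel$locus_id) {
    a1 <- stats::runif(n) < bias # TRUE = coluzzii allele
    a2 <- stats::runif(n) < bias
    diploid <- dplyr::case_when(
      a1 & a2 ~ "CC", !a1 & !a2 ~ "GG", .default = "CG"
    )
    if (loc %in% x_loci) {
      out[[loc]] <- ifelse(sex == "M", ifelse(a1, "C", "G"), diploid)
    } else {
      out[[loc]] <- diploid
    }
  }
  out
}

# Relabel COL <-> GAM in every call of a genotype table.
swap_species_labels <- function(data, panel = dis_panel()) {
  swap <- c(CC = "GG", GG = "CC", CG = "CG", C = "G", G = "C")
  for (loc in panel$locus_id) {
    x <- as.character(data[[loc]])
    data[[loc]] <- ifelse(is.na(x), NA_character_, unname(swap[x]))
  }
  data
}

# Brute-force allele tally: loop over loci, count species-specific
# copies one call at a time.
tally_oracle <- function(record, panel = dis_panel()) {
  n_col <- 0
  n_gam <- 0
  for (loc in panel$locus_id) {
    call <- as.character(record[[loc]])
    if (is.na(call)) next
    for (a in strsplit(call, "")[[1]]) {
      if (a == "C") n_col <- n_col + 1 else n_gam <- n_gam + 1
    }
  }
  c(col = n_col, gam = n_gam)
}

# Cellwise G statistic by direct summation.
g_oracle <- function(m) {
  n <- sum(m)
  g <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / n
      if (m[i, j] > 0) g <- g + 2 * m[i, j] * log(m[i, j] / e)
    }
  }
  g
}

# Pearson chi-square by direct summation.
pearson_oracle <- function(m) {
  n <- sum(m)
  s <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      e <- sum(m[i, ]) * sum(m[, j]) / n
      s <- s + (m[i, j] - e)^2 / e
    }
  }
  s
}

# Exhaustive two-sided Fisher p: enumerate every table with the observed
# margins, probabilities from binomial coefficients.
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- sapply(support, function(a) {
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  })
  p_obs <- prob[support == m[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Canonical complete individuals for hand-built cases.
make_individual <- function(sex, x, a2, a3, sample_id = "S1", ...) {
  panel <- dis_panel()
  calls <- c(rep(x, 7), rep(a2, 5), rep(a3, 3))
  out <- tibble::as_tibble(as.list(stats::setNames(calls, panel$locus_id)))
  tibble::add_column(out, sample_id = sample_id, sex = sex, .before = 1) |>
    tibble::add_column(...)
}
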