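#' Logistic regression with per-term likelihood-ratio tests
#'
#' Fits a binomial-logit model and reports, for every term in the model,
#' the likelihood-ratio chi-square obtained by deleting that term's
#' columns from the model matrix and refitting — the "effect likelihood
#' ratio" style of test. Factors are coded with sum-to-zero contrasts so
#' that deleting a main effect in the presence of its interaction tests
#' the centred main effect (a type-III-style test).
#'
#' Perfect separation does not raise an error: the fit is returned with
#' `separation = TRUE` and its (boundary) likelihood-ratio statistics,
#' which remain well defined even when coefficient estimates diverge.
#'
#' @param data A data frame.
#' @param formula Model formula; the response must be logical or 0/1 and
#'   must not be constant.
#' @return A `dis_logit` object: list with `terms` (tibble of `term`,
#'   `df`, `lr_chi2`, `p_value`), `coefficients`, `n`, `deviance`,
#'   `null_deviance`, `separation`, `formula`. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @examples
#' d <- data.frame(y = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
#'                 g = c("a", "a", "a", "b", "b", "b"))
#' tidy(logistic_lr_fit(d, y ~ g))
#' @export
logistic_lr_fit <- function(data, formula) {
  data <- as.data.frame(data)
  trm <- stats::terms(formula, data = data)
  mf <- stats::model.frame(trm, data = data, drop.unused.levels = TRUE)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (!is.numeric(y) || !all(y %in% c(0, 1))) {
    stop("response must be logical or 0/1", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("response is constant; the model is undefined", call. = FALSE)
  }
  # sum-to-zero contrasts for every factor-like predictor
  for (v in names(mf)) {
    if (is.character(mf[[v]])) mf[[v]] <- factor(mf[[v]])
    if (is.factor(mf[[v]])) stats::contrasts(mf[[v]]) <- stats::contr.sum(nlevels(mf[[v]]))
  }
  x <- stats::model.matrix(trm, mf)
  assign <- attr(x, "assign")
  labels <- attr(trm, "term.labels")

  separation <- FALSE
  fit_dev <- function(xm) {
    fit <- withCallingHandlers(
      stats::glm.fit(xm, y, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    fit
  }
  full <- fit_dev(x)
  # complete separation drives the deviance to its zero boundary
  if (full$deviance < 1e-6) separation <- TRUE
  term_tests <- purrr::map_dfr(seq_along(labels), function(i) {
    keep <- assign != i
    reduced <- fit_dev(x[, keep, drop = FALSE])
    lr <- max(0, reduced$deviance - full$deviance)
    df <- sum(assign == i)
    tibble::tibble(term = labels[i], df = df, lr_chi2 = lr,
                   p_value = stats::pchisq(lr, df, lower.tail = FALSE))
  })
  if (separation) {
    warning("possible complete separation; coefficient estimates are at ",
            "the boundary (likelihood-ratio tests remain valid)",
            call. = FALSE)
  }
  structure(
    list(terms = term_tests, coefficients = stats::setNames(full$coefficients,
                                                            colnames(x)),
         n = length(y), deviance = full$deviance,
         null_deviance = full$null.deviance, separation = separation,
         formula = formula),
    class = "dis_logit"
  )
}

#' Temporal trend in backcross frequency
#'
#' Tests whether the frequency of F1+n backcrossed genotypes changed over
#' the sampling years, with location as a covariate — the model behind
#' the observation that *An. coluzzii* recombinant frequency rose over
#' the study. Year enters as a continuous covariate (df = 1) by default;
#' `year_as_categorical = TRUE` switches to a factor coding. With a
#' single location the location and interaction terms are dropped with a
#' warning.
#'
#' @param classified Output of [classify_genotypes()], already filtered
#'   to one species (use `species` to filter here).
#' @param species Optional species filter (`"COL"` or `"GAM"`).
#' @param year_as_categorical Treat year as a factor?
#' @return A `dis_logit` object; the response is membership of the
#'   `BACKCROSS` category.
#' @export
temporal_trend <- function(classified, species = NULL,
                           year_as_categorical = FALSE) {
  check_classified(classified)
  if (!is.null(species)) {
    classified <- dplyr::filter(classified, .data$species == !!species)
  }
  d <- dplyr::filter(classified, !is.na(.data$category))
  if (length(unique(d$year)) < 2) {
    stop("at least two sampling years are required", call. = FALSE)
  }
  d$is_backcross <- d$category == "BACKCROSS"
  d$year <- if (year_as_categorical) factor(d$year) else as.numeric(d$year)
  if (length(unique(d$village)) < 2) {
    warning("single location: location and interaction terms dropped",
            call. = FALSE)
    logistic_lr_fit(d, is_backcross ~ year)
  } else {
    logistic_lr_fit(d, is_backcross ~ village * year)
  }
}

#' Compare entire-island introgression across life stages
#'
#' Expands individuals of one species and sex into one observation per
#' chromosome, with response "island entirely heterozygous"
#' (whole-island heterospecific introgression), and fits chromosome and
#' life-stage effects. Life-stage differences would indicate
#' stage-specific selection against recombinants; the chromosome effect
#' captures the very unequal introgression of X, 2L and 3L. The
#' chromosome-by-stage interaction is tested by a likelihood ratio
#' between the main-effects and interaction models and reported as an
#' extra row of `terms`.
#'
#' @param classified Output of [classify_genotypes()], typically filtered
#'   to one species and sex.
#' @return A `dis_logit` object fitted to the main-effects model, with
#'   the interaction test appended to `terms`.
#' @export
life_stage_comparison <- function(classified) {
  check_classified(classified)
  if (!"life_stage" %in% names(classified)) {
    stop("column `life_stage` is required", call. = FALSE)
  }
  d <- dplyr::filter(classified, !is.na(.data$category))
  if (length(unique(d$life_stage)) < 2) {
    stop("at least two life stages are required", call. = FALSE)
  }
  long <- d |>
    dplyr::select("sample_id", "life_stage", "state_X", "state_2L",
                  "state_3L") |>
    tidyr::pivot_longer(c("state_X", "state_2L", "state_3L"),
                        names_to = "chromosome", names_prefix = "state_",
                        values_to = "state") |>
    dplyr::mutate(introgressed = .data$state == "HET_ENTIRE")
  fit <- logistic_lr_fit(long, introgressed ~ chromosome + life_stage)
  inter <- logistic_lr_fit(long, introgressed ~ chromosome * life_stage)
  lr <- max(0, fit$deviance - inter$deviance)
  df <- sum(inter$terms$df) - sum(fit$terms$df)
  fit$terms <- dplyr::bind_rows(
    fit$terms,
    tibble::tibble(term = "chromosome:life_stage", df = df, lr_chi2 = lr,
                   p_value = stats::pchisq(lr, df, lower.tail = FALSE))
  )
  fit
}

#' @export
print.dis_logit <- function(x, ...) {
  cat("Logistic regression (likelihood-ratio term tests), n =", x$n, "\n")
  if (x$separation) cat("  [flagged: possible complete separation]\n")
  print(as.data.frame(x$terms), row.names = FALSE)
  invisible(x)
}

#' Tidy a logistic LR fit
#'
#' @param x A `dis_logit` object.
#' @param ... Unused.
#' @return [tidy()]: one row per model term with `term`, `df`,
#'   `statistic` (LR chi-square) and `p.value`. [glance()]: one-row model
#'   summary.
#' @method tidy dis_logit
#' @export
tidy.dis_logit <- function(x, ...) {
  tibble::tibble(term = x$terms$term, df = x$terms$df,
                 statistic = x$terms$lr_chi2, p.value = x$terms$p_value)
}

#' @rdname tidy.dis_logit
#' @method glance dis_logit
#' @export
glance.dis_logit <- function(x, ...) {
  tibble::tibble(n = x$n, deviance = x$deviance,
                 null.deviance = x$null_deviance,
                 separation = x$separation)
}
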