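#' Default distributional targets for the synthetic pregnancy cohort
#'
#' Mean and standard deviation of daily nutrient intake in the cohort the
#' package emulates: 171 pregnant women consuming a mixed diet, of whom 65.5%
#' consume at least one beef serve per week.
#'
#' @return A tibble with `nutrient`, `mean`, `sd`.
#' @export
default_intake_targets <- function() {
  tibble::tibble(
    nutrient = c("protein", "fiber", "iron", "zinc", "calcium", "folate"),
    mean = c(97.8, 23.3, 14.2, 12.6, 984.1, 280.2),
    sd = c(45.3, 8.8, 6.9, 5.0, 332.9, 118.6)
  )
}

#' Configure a synthetic intake cohort
#'
#' Nutrient marginals are log-normal with parameters solved from the target
#' mean and SD (dietary intakes are right-skewed, which log-normality
#' captures: generated medians fall below means, as observed in real FFQ
#' data). Dependence between nutrients comes from a Gaussian copula with an
#' exchangeable correlation. Weekly beef serves follow a zero-inflated
#' Poisson whose inflation is solved so that the expected fraction of the
#' cohort with at least one serve per week equals `eligible_fraction`.
#'
#' @param n Cohort size (default 171).
#' @param targets Per-nutrient `mean`/`sd` tibble
#'   (default [default_intake_targets()]).
#' @param correlation Either a single exchangeable latent correlation
#'   (default 0.3) or a full positive-semidefinite correlation matrix of
#'   dimension `nrow(targets)`.
#' @param eligible_fraction Expected fraction consuming >= 1 beef serve/week
#'   (default 0.655).
#' @param serves_lambda Poisson mean of weekly serves among non-inflated
#'   individuals (default 2); must satisfy
#'   `eligible_fraction <= 1 - exp(-serves_lambda)`.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n = 171,
                                    targets = default_intake_targets(),
                                    correlation = 0.3,
                                    eligible_fraction = 0.655,
                                    serves_lambda = 2,
                                    seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop_input("n must be a single count >= 1", "sustainaswap_validation_error")
  }
  missing <- setdiff(c("nutrient", "mean", "sd"), names(targets))
  if (length(missing) > 0) {
    stop_input(paste0("targets is missing column(s): ",
                      paste(missing, collapse = ", ")),
               "sustainaswap_schema_error")
  }
  if (any(targets$mean <= 0) || any(targets$sd <= 0)) {
    stop_input("target means and SDs must be > 0",
               "sustainaswap_validation_error")
  }
  k <- nrow(targets)
  if (is.matrix(correlation)) {
    if (!identical(dim(correlation), c(k, k)) ||
        any(abs(correlation - t(correlation)) > 1e-12) ||
        any(abs(diag(correlation) - 1) > 1e-12)) {
      stop_input("correlation matrix must be symmetric with unit diagonal and match targets",
                 "sustainaswap_validation_error")
    }
    if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8) {
      stop_input("correlation matrix must be positive semidefinite",
                 "sustainaswap_validation_error")
    }
    R <- correlation
  } else {
    rho <- correlation
    if (!is.numeric(rho) || length(rho) != 1 ||
        rho < -1 / (k - 1) || rho > 1) {
      stop_input("exchangeable correlation must lie in [-1/(k-1), 1]",
                 "sustainaswap_validation_error")
    }
    R <- matrix(rho, k, k)
    diag(R) <- 1
  }
  if (eligible_fraction < 0 || eligible_fraction > 1) {
    stop_input("eligible_fraction must lie in [0, 1]",
               "sustainaswap_validation_error")
  }
  if (serves_lambda <= 0) {
    stop_input("serves_lambda must be > 0", "sustainaswap_validation_error")
  }
  if (eligible_fraction > 1 - exp(-serves_lambda) + 1e-12) {
    stop_input(
      "eligible_fraction exceeds 1 - exp(-serves_lambda); increase serves_lambda",
      "sustainaswap_validation_error"
    )
  }
  structure(
    list(n = as.integer(n), targets = tibble::as_tibble(targets),
         correlation = R, eligible_fraction = eligible_fraction,
         serves_lambda = serves_lambda, seed = seed),
    class = "synthetic_cohort_config"
  )
}

# Log-normal parameters with the target arithmetic mean and SD:
# sdlog^2 = log(1 + (sd/mean)^2), meanlog = log(mean) - sdlog^2 / 2.
lognormal_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic cohort of daily nutrient intakes
#'
#' Draws `n` records with log-normal nutrient marginals moment-matched to
#' the configured mean/SD targets, coupled through a Gaussian copula, plus
#' zero-inflated-Poisson weekly beef serves. Identical seeds give identical
#' cohorts.
#'
#' @param config A [synthetic_cohort_config()].
#' @return A cohort tibble (see [load_cohort()] for the schema).
#' @examples
#' cohort <- generate_cohort(synthetic_cohort_config(n = 50, seed = 1))
#' recover_parameters(cohort)
#' @export
generate_cohort <- function(config = synthetic_cohort_config()) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  targets <- config$targets
  k <- nrow(targets)

  # Gaussian copula: correlated standard normals -> uniforms -> log-normal
  # quantiles. chol() of a PSD-but-singular matrix can fail; add a whisker
  # of ridge only in that degenerate case.
  L <- tryCatch(chol(config$correlation), error = function(e) {
    chol(config$correlation + diag(1e-10, k))
  })
  z <- matrix(rnorm(n * k), nrow = n) %*% L
  u <- pnorm(z)

  intakes <- vapply(seq_len(k), function(j) {
    p <- lognormal_params(targets$mean[j], targets$sd[j])
    qlnorm(u[, j], meanlog = p$meanlog, sdlog = p$sdlog)
  }, numeric(n))
  colnames(intakes) <- cohort_nutrients()[targets$nutrient]

  # Zero-inflated Poisson serves: inflation pi solves
  # P(serves = 0) = pi + (1 - pi) exp(-lambda) = 1 - eligible_fraction.
  p0 <- exp(-config$serves_lambda)
  pi0 <- ((1 - config$eligible_fraction) - p0) / (1 - p0)
  pi0 <- min(max(pi0, 0), 1)
  structural_zero <- runif(n) < pi0
  serves <- ifelse(structural_zero, 0L, rpois(n, config$serves_lambda))

  out <- tibble::as_tibble(intakes)
  out$person_id <- sprintf("P%04d", seq_len(n))
  out$beef_serves_per_week <- as.numeric(serves)
  validate_cohort(out)
  out[cohort_columns()]
}

#' Recover distributional parameters from a cohort
#'
#' Sample moments per nutrient plus the empirical eligible fraction —
#' the parameter-recovery counterpart of [generate_cohort()].
#'
#' @param cohort A cohort tibble.
#' @return A list with `moments` (tibble `nutrient`, `mean`, `sd`) and
#'   `eligible_fraction` (share with >= 1 beef serve/week).
#' @export
recover_parameters <- function(cohort) {
  cohort <- validate_cohort(cohort)
  moments <- dplyr::bind_rows(lapply(names(cohort_nutrients()), function(nm) {
    x <- cohort[[cohort_nutrients()[[nm]]]]
    tibble::tibble(nutrient = nm, mean = mean(x),
                   sd = if (length(x) > 1) sd(x) else 0)
  }))
  list(
    moments = moments,
    eligible_fraction = mean(cohort$beef_serves_per_week >= 1)
  )
}
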