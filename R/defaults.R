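# Default synthetic study conditions.
#
# Ten harmonized categorical socio-demographic/health variables with
# marginals loosely calibrated to published census-eligible summary
# statistics for a mid-life (40-69) population, a Gaussian-copula latent
# correlation encoding the usual social gradients (age-health,
# education-tenure, household-cars, ...), a census-like reference design
# (5% random subsample, 95% response), and a volunteer-selection mechanism
# with 5.5% overall participation loaded on health, socio-economic status
# and age.

.default_variables <- function() {
  list(
    list(name = "sex", levels = c("female", "male"),
         probs = c(0.508, 0.492)),
    list(name = "age_group", levels = c("40-49", "50-59", "60-69"),
         probs = c(0.34, 0.33, 0.33),
         numeric = c("40-49" = 44.5, "50-59" = 54.5, "60-69" = 64.5)),
    list(name = "self_health", levels = c("good", "fair", "poor"),
         probs = c(0.700, 0.207, 0.093),
         numeric = c(good = 1, fair = 2, poor = 3)),
    list(name = "education", levels = c("degree", "secondary", "none"),
         probs = c(0.278, 0.450, 0.272),
         numeric = c(degree = 17, secondary = 12, none = 10)),
    list(name = "employment",
         levels = c("paid_work", "retired", "incapacitated", "unemployed",
                    "other"),
         probs = c(0.609, 0.249, 0.069, 0.033, 0.040)),
    list(name = "tenure", levels = c("owner", "renter"),
         probs = c(0.736, 0.264)),
    list(name = "cars", levels = c("two_plus", "one", "none"),
         probs = c(0.50, 0.36, 0.14),
         numeric = c(two_plus = 2, one = 1, none = 0)),
    list(name = "ethnicity", levels = c("white", "other"),
         probs = c(0.888, 0.112)),
    list(name = "one_person", levels = c("no", "yes"),
         probs = c(0.819, 0.181)),
    list(name = "region", levels = c("A", "B", "C"),
         probs = c(0.40, 0.35, 0.25))
  )
}

# latent correlation in the order of .default_variables(); the latent
# direction of each variable follows its level order (later level = higher
# latent score), so e.g. a positive age/self_health entry means older
# persons report worse health
.default_latent_correlation <- function() {
  v <- vapply(.default_variables(), `[[`, character(1), "name")
  R <- diag(length(v))
  dimnames(R) <- list(v, v)
  set_ <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set_("age_group", "self_health", 0.30)
  set_("age_group", "employment", 0.55)
  set_("age_group", "education", 0.20)
  set_("age_group", "one_person", 0.10)
  set_("self_health", "education", 0.45)
  set_("self_health", "employment", 0.60)
  set_("self_health", "tenure", 0.40)
  set_("self_health", "cars", 0.40)
  set_("education", "tenure", 0.35)
  set_("education", "cars", 0.40)
  set_("employment", "tenure", 0.20)
  set_("employment", "cars", 0.25)
  set_("tenure", "cars", 0.35)
  set_("tenure", "one_person", 0.25)
  set_("cars", "one_person", 0.40)
  set_("ethnicity", "region", 0.20)
  set_("ethnicity", "tenure", 0.15)
  set_("sex", "employment", 0.10)
  R
}

#' Default synthetic population specification
#'
#' @param n_population population size (default 500 000).
#' @param seed integer seed.
#' @return a [population_spec()].
#' @export
default_population_spec <- function(n_population = 500000L, seed = 1L) {
  population_spec(n_population, .default_variables(),
                  latent_correlation = .default_latent_correlation(),
                  seed = seed)
}

#' Default codebook of the synthetic study
#'
#' @return a [codebook()] matching [default_population_spec()].
#' @export
default_codebook <- function() {
  population_codebook(default_population_spec(1000))
}

#' Default volunteer-selection mechanism
#'
#' Probit selection at an overall 5.5% participation rate, favouring older,
#' healthier, more educated, home-owning, white and employed persons — the
#' healthy-volunteer pattern. The loadings roughly halve the poor-health
#' share inside the cohort and attenuate every health/SES association
#' towards zero while keeping the inverse-probability weights moderate
#' (oracle-weight Kish effective sample size around 60% of the cohort).
#'
#' @param seed integer seed.
#' @return a [selection_spec()].
#' @export
default_selection_spec <- function(seed = 1L) {
  selection_spec(
    coefficients = c(
      "main:age_group=50-59" = 0.15,
      "main:age_group=60-69" = 0.35,
      "main:self_health=good" = 0.15,
      "main:self_health=poor" = -0.30,
      "main:education=degree" = 0.25,
      "main:education=none" = -0.15,
      "main:employment=retired" = 0.05,
      "main:employment=incapacitated" = -0.25,
      "main:employment=unemployed" = -0.20,
      "main:tenure=owner" = 0.25,
      "main:ethnicity=white" = 0.20,
      "main:sex=female" = 0.08,
      "main:cars=none" = -0.10),
    target_rate = 0.055, seed = seed)
}

#' Sign-reversal selection preset
#'
#' A selection mechanism whose age-by-health interaction is strong enough
#' that the cohort's unweighted poor-health/oldest-age-group slope has the
#' opposite sign of the population slope: older poor-health persons almost
#' never volunteer, so within the cohort the oldest group looks
#' *healthier*. Inverse-probability weighting restores the positive
#' population gradient. Pair it with
#' `assoc("self_health=poor", "age_group=60-69")`.
#'
#' @param seed integer seed.
#' @return a [selection_spec()].
#' @export
sign_reversal_selection_spec <- function(seed = 1L) {
  selection_spec(
    coefficients = c(
      "main:age_group=50-59" = 0.30,
      "main:age_group=60-69" = 0.60,
      "main:self_health=poor" = -0.20,
      "int:age_group=50-59:self_health=poor" = -0.50,
      "int:age_group=60-69:self_health=poor" = -1.00),
    target_rate = 0.055, seed = seed)
}

#' Concentrated selection preset
#'
#' Selection loaded heavily and monotonically on single levels of a few
#' variables, so the cohort is concentrated in a narrow slice of the
#' population and the cohort standard deviations of the numeric-mapped
#' variables shrink below their population values.
#'
#' @param seed integer seed.
#' @return a [selection_spec()].
#' @export
concentrated_selection_spec <- function(seed = 1L) {
  selection_spec(
    coefficients = c(
      "main:age_group=50-59" = 0.40,
      "main:age_group=60-69" = 0.80,
      "main:self_health=good" = 0.60,
      "main:self_health=poor" = -0.60,
      "main:education=degree" = 0.70,
      "main:education=none" = -0.40,
      "main:cars=two_plus" = 0.50,
      "main:cars=none" = -0.35),
    target_rate = 0.055, seed = seed)
}

#' Default association batch
#'
#' Ten bivariate linear probability models between level indicators and
#' three standardized linear models between the numeric-mapped variables.
#' Every pair links two variables the selection mechanism loads on, so each
#' has a substantial volunteer-bias distortion relative to its sampling
#' noise; pairs whose cohort and reference slopes barely differ are
#' deliberately excluded because a bias-reduction ratio is uninformative
#' when its denominator is within noise of zero.
#'
#' @return list of [assoc()] specifications.
#' @export
default_associations <- function() {
  list(
    assoc("self_health=poor", "employment=paid_work"),
    assoc("self_health=poor", "age_group=60-69"),
    assoc("self_health=poor", "education=degree"),
    assoc("self_health=poor", "tenure=owner"),
    assoc("self_health=poor", "cars=none"),
    assoc("self_health=poor", "employment=incapacitated"),
    assoc("self_health=poor", "employment=unemployed"),
    assoc("age_group=60-69", "employment=retired"),
    assoc("self_health=good", "education=degree"),
    assoc("self_health=good", "tenure=owner"),
    assoc("self_health", "age_group", type = "std"),
    assoc("cars", "education", type = "std"),
    assoc("self_health", "education", type = "std")
  )
}
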