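#' Two-group study design
#'
#' Describes the subject layout and the true differential-abundance structure
#' of a simulated two-group (e.g. cancer vs control) metabolomics study.
#'
#' @param n_group1,n_group2 subjects per group (each at least 3).
#' @param de_fraction proportion of metabolites carrying a true group effect,
#'   in `[0, 1]`. Exactly `round(de_fraction * n_metabolites)` metabolites are
#'   flagged differential when a study is generated, so truth counts are
#'   deterministic.
#' @param effect_size standardized mean shift (log-scale SD units) added to
#'   group-1 means of differential metabolites; must be non-negative.
#' @return an object of class `group_design`.
#' @seealso [generate_paired_study()]
#' @export
group_design <- function(n_group1, n_group2, de_fraction = 0, effect_size = 0) {
  if (n_group1 < 3 || n_group2 < 3)
    stop_param("each group needs at least 3 subjects")
  if (de_fraction < 0 || de_fraction > 1)
    stop_param("'de_fraction' must lie in [0, 1]")
  if (effect_size < 0)
    stop_param("'effect_size' must be non-negative")
  structure(
    list(n_group1 = as.integer(n_group1), n_group2 = as.integer(n_group2),
         de_fraction = de_fraction, effect_size = effect_size),
    class = "group_design")
}

#' Between-biospecimen correlation profile
#'
#' Defines the distribution from which each metabolite's true
#' between-biospecimen correlation is drawn: a beta distribution rescaled to
#' `[r_min, r_max]` with its mode placed at `r_mode`. Two presets mirror
#' correlation structures commonly seen in multi-biospecimen studies:
#' `"high"` (range \[-0.2, 0.98\], mode 0.5, as in plasma/serum GC-TOF data)
#' and `"low"` (range \[-0.3, 0.3\], mode 0, as in lung-tissue/serum HILIC
#' data).
#'
#' @param name `"high"`, `"low"`, or `"custom"` (then supply the bounds).
#' @param r_min,r_max,r_mode correlation bounds and mode; required for
#'   `"custom"`, ignored otherwise. Must satisfy
#'   `-1 < r_min < r_mode < r_max < 1`.
#' @param concentration beta concentration (a + b); larger values tighten the
#'   distribution around the mode. Default 8.
#' @return an object of class `correlation_profile` with the beta shape
#'   parameters (`shape1`, `shape2`) and the implied distribution `mean`.
#' @export
correlation_profile <- function(name = c("high", "low", "custom"),
                                r_min = NULL, r_max = NULL, r_mode = NULL,
                                concentration = 8) {
  name <- match.arg(name)
  if (name == "high") {
    r_min <- -0.2; r_max <- 0.98; r_mode <- 0.5
  } else if (name == "low") {
    r_min <- -0.3; r_max <- 0.3; r_mode <- 0
  } else if (is.null(r_min) || is.null(r_max) || is.null(r_mode)) {
    stop_param("custom profiles need r_min, r_max and r_mode")
  }
  if (!(-1 < r_min && r_min < r_mode && r_mode < r_max && r_max < 1))
    stop_param("need -1 < r_min < r_mode < r_max < 1")
  if (concentration <= 2)
    stop_param("'concentration' must exceed 2 for a unimodal interior mode")
  m <- (r_mode - r_min) / (r_max - r_min)
  shape1 <- 1 + (concentration - 2) * m
  shape2 <- 1 + (concentration - 2) * (1 - m)
  structure(
    list(name = name, r_min = r_min, r_max = r_max, r_mode = r_mode,
         concentration = concentration, shape1 = shape1, shape2 = shape2,
         mean = r_min + (r_max - r_min) * shape1 / (shape1 + shape2)),
    class = "correlation_profile")
}

#' Draw between-biospecimen correlations from a profile
#'
#' @param profile a [correlation_profile()].
#' @param n number of draws.
#' @param seed optional seed; when given, draws are made under a temporary
#'   RNG state.
#' @return numeric vector of `n` correlations inside
#'   `[profile$r_min, profile$r_max]`.
#' @export
sample_correlations <- function(profile, n, seed = NULL) {
  stopifnot(inherits(profile, "correlation_profile"))
  draw <- function() profile$r_min +
    (profile$r_max - profile$r_min) * stats::rbeta(n, profile$shape1, profile$shape2)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a complete paired-biospecimen study
#'
#' Simulates raw (positive) abundance matrices for two biospecimens measured
#' on the same subjects. For metabolite i a true correlation `r_i` is drawn
#' from `profile`; each subject's log-abundances in the two biospecimens are
#' then bivariate normal with correlation `r_i` and metabolite-specific means
#' and SDs (log-means uniform on `mu_range`, log-SDs uniform on `sd_range`,
#' reflecting the wide dynamic range of MS intensity data). Differential
#' metabolites receive an `effect_size`-SD upward shift of the group-1 mean
#' in both biospecimens (shared biology), or in biospecimen A only when
#' `shift_both = FALSE`. Finally values are exponentiated to the raw scale.
#'
#' @param design a [group_design()].
#' @param profile a [correlation_profile()].
#' @param n_metabolites number of metabolites M (>= 2).
#' @param seed integer seed; the full study is reproducible from it.
#' @param mu_range,sd_range ranges for metabolite log-means and log-SDs.
#' @param shift_both logical; shift differential metabolites in both
#'   biospecimens (default) or only in A.
#' @return a [paired_study] object with complete raw-scale matrices, the
#'   per-metabolite generating correlation (`true_r`) and differential flags
#'   (`true_de`).
#' @examples
#' st <- generate_paired_study(group_design(48, 31, 0.23, 1),
#'                             correlation_profile("high"), 176, seed = 1)
#' dim(st$A)  # 176 x 79
#' @export
generate_paired_study <- function(design, profile, n_metabolites, seed,
                                  mu_range = c(3, 10), sd_range = c(0.3, 1.2),
                                  shift_both = TRUE) {
  stopifnot(inherits(design, "group_design"),
            inherits(profile, "correlation_profile"))
  if (n_metabolites < 2) stop_param("need at least 2 metabolites")
  m <- as.integer(n_metabolites)
  n <- design$n_group1 + design$n_group2
  with_seed(seed, {
    r <- sample_correlations(profile, m)
    mu_a <- stats::runif(m, mu_range[1], mu_range[2])
    mu_b <- stats::runif(m, mu_range[1], mu_range[2])
    sd_a <- stats::runif(m, sd_range[1], sd_range[2])
    sd_b <- stats::runif(m, sd_range[1], sd_range[2])
    n_de <- round(design$de_fraction * m)
    de <- rep(FALSE, m)
    if (n_de > 0) de[sample.int(m, n_de)] <- TRUE
    groups <- factor(rep(c("case", "control"),
                         c(design$n_group1, design$n_group2)),
                     levels = c("case", "control"))
    g1 <- as.numeric(groups == "case")
    z1 <- matrix(stats::rnorm(m * n), m, n)
    z2 <- r * z1 + sqrt(1 - r^2) * matrix(stats::rnorm(m * n), m, n)
    shift_a <- de * design$effect_size * sd_a
    shift_b <- if (shift_both) de * design$effect_size * sd_b else 0
    log_a <- mu_a + outer(shift_a, g1) + sd_a * z1
    log_b <- mu_b + outer(shift_b, g1) + sd_b * z2
    met_ids <- sprintf("M%04d", seq_len(m))
    sub_ids <- sprintf("S%03d", seq_len(n))
    dimnames(log_a) <- dimnames(log_b) <- list(met_ids, sub_ids)
    paired_study(exp(log_a), exp(log_b), groups,
                 true_r = r, true_de = de, log_scale = FALSE)
  })
}
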