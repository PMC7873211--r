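#' Configuration for the multi-arm trial generator
#'
#' Describes a pooled multi-arm preclinical trial: several drug arms, one of
#' which ("the treated arm") carries a graded dose series whose effect on the
#' behavioral outcomes follows `dose_effect_shape` (inverted-U by default),
#' graded injury severity, and correlated behavioral + histological outcome
#' batteries driven by two latent factors (recovery and lesion load).
#'
#' @param n_subjects Total number of subjects across all arms.
#' @param arms Named list; each element is the numeric vector of dose levels
#'   for that arm (single-dose arms have one level). Subjects are allocated
#'   as evenly as possible over all (arm, dose) cells.
#' @param treated_arm Name of the arm carrying the dose-response effect.
#' @param severity_range Interval for the tissue-deformation-like injury
#'   severity scalar, sampled uniformly per subject.
#' @param n_behavioral,n_histological Number of outcome variables per domain.
#' @param latent_loading_behavioral,latent_loading_histological Loadings (in
#'   `[0, 1]`) of the outcomes on their latent factor.
#' @param dose_effect_shape Per-dose mean shift (in outcome SD units) added to
#'   the behavioral outcomes of the treated arm; its length must equal the
#'   number of dose levels of `treated_arm`.
#' @param noise_sd Residual SD of each outcome around its latent signal.
#' @param missing_rate Probability that any single outcome entry is missing
#'   (completely at random); must be in `[0, 1)`.
#' @param discretize If `TRUE`, the second and third behavioral outcomes are
#'   discretized to ordinal ranges (0-5 and 0-9) after generation.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `trial_sim_config` list.
#' @export
trial_sim_config <- function(n_subjects = 159,
                             arms = list(
                               sTNFR1 = 0:4,
                               minocycline = 1,
                               ciclopirox = 1,
                               methylprednisolone = 1,
                               vehicle = 0
                             ),
                             treated_arm = "sTNFR1",
                             severity_range = c(50, 100),
                             n_behavioral = 6,
                             n_histological = 4,
                             latent_loading_behavioral = 0.8,
                             latent_loading_histological = 0.8,
                             dose_effect_shape = c(0, 1.0, 1.8, 1.0, 0.25),
                             noise_sd = 0.6,
                             missing_rate = 0.05,
                             discretize = FALSE,
                             seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("n_subjects must be a positive count")
  if (!is.list(arms) || is.null(names(arms)) || any(names(arms) == ""))
    stop("`arms` must be a named list of dose-level vectors")
  if (!all(vapply(arms, is.numeric, logical(1))))
    stop("each arm must give a numeric vector of dose levels")
  if (any(vapply(arms, anyDuplicated, integer(1)) > 0))
    stop("duplicate dose levels within an arm")
  if (!treated_arm %in% names(arms))
    stop(sprintf("treated_arm '%s' is not one of the arms", treated_arm))
  if (length(dose_effect_shape) != length(arms[[treated_arm]]))
    stop("dose_effect_shape length must equal the number of dose levels of the treated arm")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (length(severity_range) != 2 || diff(severity_range) <= 0)
    stop("severity_range must be an increasing interval")
  structure(list(
    n_subjects = as.integer(n_subjects), arms = arms,
    treated_arm = treated_arm, severity_range = severity_range,
    n_behavioral = as.integer(n_behavioral),
    n_histological = as.integer(n_histological),
    latent_loading_behavioral = latent_loading_behavioral,
    latent_loading_histological = latent_loading_histological,
    dose_effect_shape = dose_effect_shape, noise_sd = noise_sd,
    missing_rate = missing_rate, discretize = discretize,
    seed = as.integer(seed)
  ), class = "trial_sim_config")
}

behavioral_names <- function(n) {
  base <- c("paw_preference", "grooming", "ibb_score")
  c(base, sprintf("behav_%d", seq_len(max(0, n - 3))))[seq_len(n)]
}

histological_names <- function(n) {
  base <- c("pct_sparing", "lesion_area", "white_matter_sparing",
            "motor_neuron_count")
  c(base, sprintf("hist_%d", seq_len(max(0, n - 4))))[seq_len(n)]
}

#' Simulate a pooled multi-arm preclinical outcome table
#'
#' Generates subjects with arm/dose/severity metadata. A latent lesion factor
#' (tied to severity) drives the histological outcomes and a latent recovery
#' factor (anti-correlated with lesion load) drives the behavioral outcomes,
#' so the two outcome domains form one correlated syndromic space. The treated
#' arm additionally shifts its behavioral outcomes by `dose_effect_shape`
#' at the subject's dose level. Entries are masked missing completely at
#' random at `missing_rate`.
#'
#' @param config A [trial_sim_config()].
#' @return A list with elements `data` (an [outcome_matrix()]) and `truth`
#'   (latent factor values, per-cell true shifts, and allocation).
#' @export
simulate_trial <- function(config = trial_sim_config()) {
  stopifnot(inherits(config, "trial_sim_config"))
  withr::with_seed(config$seed, {
    cells <- do.call(rbind, lapply(names(config$arms), function(a) {
      data.frame(arm = a, dose = config$arms[[a]], stringsAsFactors = FALSE)
    }))
    n_cells <- nrow(cells)
    n <- config$n_subjects
    base <- n %/% n_cells
    cell_n <- rep(base, n_cells)
    extra <- n - base * n_cells
    if (extra > 0) cell_n[seq_len(extra)] <- cell_n[seq_len(extra)] + 1L

    arm <- rep(cells$arm, cell_n)
    dose <- rep(cells$dose, cell_n)
    ids <- sprintf("S%03d", seq_len(n))

    severity <- stats::runif(n, config$severity_range[1], config$severity_range[2])
    sev_z <- as.numeric(scale(severity))
    # lesion load tracks severity; recovery is hindered by lesion load
    lesion <- 0.9 * sev_z + sqrt(1 - 0.9^2) * stats::rnorm(n)
    recovery <- -0.7 * lesion + sqrt(1 - 0.7^2) * stats::rnorm(n)

    shift <- numeric(n)
    treated <- arm == config$treated_arm
    dose_levels <- config$arms[[config$treated_arm]]
    shift[treated] <- config$dose_effect_shape[match(dose[treated], dose_levels)]

    nb <- config$n_behavioral
    nh <- config$n_histological
    behav <- matrix(stats::rnorm(n * nb, sd = config$noise_sd), n, nb)
    behav <- behav + config$latent_loading_behavioral * recovery + shift
    hist_out <- matrix(stats::rnorm(n * nh, sd = config$noise_sd), n, nh)
    hist_out <- hist_out + config$latent_loading_histological * lesion

    outcomes <- cbind(behav, hist_out)
    colnames(outcomes) <- c(behavioral_names(nb), histological_names(nh))
    rownames(outcomes) <- ids

    if (config$discretize && nb >= 3) {
      to_ordinal <- function(x, lo, hi) {
        r <- range(x)
        pmin(hi, pmax(lo, round(lo + (x - r[1]) / diff(r) * (hi - lo))))
      }
      outcomes[, 2] <- to_ordinal(outcomes[, 2], 0, 5)  # grooming scale
      outcomes[, 3] <- to_ordinal(outcomes[, 3], 0, 9)  # IBB scale
    }

    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(length(outcomes)) < config$missing_rate,
                     nrow(outcomes))
      outcomes[mask] <- NA_real_
    }

    meta <- data.frame(
      subject_id = ids, arm = arm, dose = dose, severity = severity,
      stringsAsFactors = FALSE
    )
    list(
      data = outcome_matrix(outcomes, meta),
      truth = list(
        recovery = stats::setNames(recovery, ids),
        lesion = stats::setNames(lesion, ids),
        behavioral_shift = stats::setNames(shift, ids),
        dose_effect_shape = config$dose_effect_shape,
        cells = cbind(cells, n = cell_n),
        config = config
      )
    )
  })
}

#' Configuration for the planted-module expression generator
#'
#' Describes an RNA-seq-like experiment with three ordered sample groups
#' (uninjured reference, lesioned + vehicle, lesioned + treated), planted
#' co-expression modules generated from shared latent factors, injury genes
#' shifted in both lesioned groups, and reversal genes whose treated-group
#' shift is pulled back toward the reference by `reversal_fraction`.
#'
#' @param n_genes Total number of genes.
#' @param n_samples_per_group Samples per group.
#' @param groups Ordered group labels (reference first).
#' @param n_modules,module_size Number and size of planted modules.
#' @param within_module_cor Target average intra-module correlation in (0,1).
#' @param n_injury_genes Genes shifted by injury (in both lesioned groups).
#'   When `n_modules >= 6`, modules 5 and 6 are designated injury-responsive
#'   and their genes are counted first; the remainder is drawn from background
#'   genes.
#' @param n_reversal_genes Injury genes whose change is reversed by treatment;
#'   must not exceed `n_injury_genes`.
#' @param injury_shift Log2-scale shift applied to injury genes.
#' @param reversal_fraction Fraction in (0,1] of the injury shift removed in
#'   the treated group for reversal genes (1 = full return to reference).
#' @param library_size Mean total counts per sample.
#' @param noise_sd Residual log2-scale biological noise SD.
#' @param seed Integer seed.
#' @return An `expr_sim_config` list.
#' @export
expr_sim_config <- function(n_genes = 2000,
                            n_samples_per_group = 5,
                            groups = c("sham", "vehicle", "treated"),
                            n_modules = 10,
                            module_size = 50,
                            within_module_cor = 0.7,
                            n_injury_genes = 300,
                            n_reversal_genes = 225,
                            injury_shift = 3,
                            reversal_fraction = 0.8,
                            library_size = 2e6,
                            noise_sd = 0.5,
                            seed = 1L) {
  if (n_modules * module_size > n_genes)
    stop("module budget exceeds n_genes (module_size * n_modules must be <= n_genes)")
  if (n_reversal_genes > n_injury_genes)
    stop("n_reversal_genes must not exceed n_injury_genes")
  if (length(groups) != 3)
    stop("`groups` must give three ordered labels (reference, vehicle, treated)")
  if (within_module_cor <= 0 || within_module_cor >= 1)
    stop("within_module_cor must be in (0, 1)")
  if (reversal_fraction <= 0 || reversal_fraction > 1)
    stop("reversal_fraction must be in (0, 1]")
  n_background <- n_genes - n_modules * module_size
  n_designated <- if (n_modules >= 6) 2 * module_size else 0
  if (n_injury_genes > n_designated + n_background)
    stop("n_injury_genes exceeds the designated-module plus background gene budget")
  structure(list(
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    groups = groups, n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    within_module_cor = within_module_cor,
    n_injury_genes = as.integer(n_injury_genes),
    n_reversal_genes = as.integer(n_reversal_genes),
    injury_shift = injury_shift, reversal_fraction = reversal_fraction,
    library_size = library_size, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "expr_sim_config")
}

#' Simulate a planted-module RNA-seq-like count matrix
#'
#' Log2-scale latent expression is built from a per-gene baseline, shared
#' module factors scaled to achieve `within_module_cor`, group shifts for
#' injury and reversal genes, and Gaussian noise; counts are then drawn as
#' Poisson observations of the latent signal with sample-specific library
#' sizes (log-normal latent + Poisson observation model, which reproduces
#' overdispersion qualitatively).
#'
#' @param config An [expr_sim_config()].
#' @return A list with elements `counts` (genes x samples integer matrix),
#'   `groups` (named character vector sample -> group), and `truth` (per-gene
#'   module labels, injury sign, reversal flag).
#' @export
simulate_expression <- function(config = expr_sim_config()) {
  stopifnot(inherits(config, "expr_sim_config"))
  withr::with_seed(config$seed, {
    ns <- config$n_samples_per_group
    n_samples <- 3L * ns
    group <- rep(config$groups, each = ns)
    sample_ids <- paste(group, rep(seq_len(ns), times = 3), sep = "_")
    gene_ids <- sprintf("g%04d", seq_len(config$n_genes))

    module <- rep("none", config$n_genes)
    if (config$n_modules > 0) {
      idx <- seq_len(config$n_modules * config$module_size)
      module[idx] <- rep(sprintf("M%d", seq_len(config$n_modules)),
                         each = config$module_size)
    }
    background <- which(module == "none")

    # injury pool: designated modules (5 and 6) first, then background genes
    designated <- integer(0)
    if (config$n_modules >= 6)
      designated <- which(module %in% c("M5", "M6"))
    pool <- c(designated, background)
    injury_idx <- pool[seq_len(config$n_injury_genes)]
    reversal_idx <- injury_idx[seq_len(config$n_reversal_genes)]

    sign_g <- numeric(config$n_genes)
    # module genes shift coherently (one sign per module); background injury
    # genes alternate direction
    sign_g[injury_idx] <- rep_len(c(1, -1), length(injury_idx))
    if (length(designated)) {
      sign_g[module == "M5" & seq_along(module) %in% injury_idx] <- 1
      sign_g[module == "M6" & seq_along(module) %in% injury_idx] <- -1
    }

    sigma <- config$noise_sd
    lambda <- sigma * sqrt(config$within_module_cor / (1 - config$within_module_cor))

    baseline <- stats::rnorm(config$n_genes, mean = 4, sd = 1.5)
    z <- matrix(stats::rnorm(config$n_genes * n_samples, sd = sigma),
                config$n_genes, n_samples)
    z <- z + baseline
    if (config$n_modules > 0) {
      factors <- matrix(stats::rnorm(config$n_modules * n_samples),
                        config$n_modules, n_samples)
      for (m in seq_len(config$n_modules)) {
        rows <- which(module == sprintf("M%d", m))
        # injury-responsive modules cohere mainly through the response they
        # share; their residual coordination factor is halved so the
        # treatment signal, not free-running coordination noise, dominates
        lam <- if (length(designated) && m %in% 5:6) lambda / 2 else lambda
        z[rows, ] <- z[rows, ] + lam * rep(factors[m, ], each = length(rows))
      }
    }

    lesioned <- group != config$groups[1]
    treated <- group == config$groups[3]
    shift <- matrix(0, config$n_genes, n_samples)
    if (length(injury_idx)) {
      shift[injury_idx, lesioned] <- config$injury_shift * sign_g[injury_idx]
      # reversal genes move back toward reference in the treated group
      shift[reversal_idx, treated] <-
        config$injury_shift * (1 - config$reversal_fraction) * sign_g[reversal_idx]
    }
    z <- z + shift

    lib <- config$library_size * exp(stats::rnorm(n_samples, sd = 0.15))
    mu <- 2^z
    mu <- sweep(mu, 2, lib / colSums(mu), `*`)
    counts <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    dimnames(counts) <- list(gene_ids, sample_ids)

    list(
      counts = counts,
      groups = stats::setNames(group, sample_ids),
      truth = list(
        module = stats::setNames(module, gene_ids),
        injury_sign = stats::setNames(sign_g, gene_ids),
        injury = stats::setNames(seq_len(config$n_genes) %in% injury_idx, gene_ids),
        reversal = stats::setNames(seq_len(config$n_genes) %in% reversal_idx, gene_ids),
        latent_log2 = z,
        config = config
      )
    )
  })
}
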