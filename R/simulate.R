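#' Configuration for the multi-study expression simulator
#'
#' Defines the generative conditions for [simulate_multistudy()]: several
#' studies on two or more simulated platforms with partially overlapping
#' gene sets, a minority metastasis class, a subset of genes carrying a
#' consistent cross-study mean shift between outcome classes, and
#' per-platform per-gene affine distortions.
#'
#' Defaults mirror the study mix the pipeline is designed for: eight
#' cohorts, a few thousand genes per platform, a minority class around 30%
#' (typical of distant metastasis in untreated node-negative breast cancer
#' cohorts), and a planted standardized effect of one noise SD.
#'
#' @param n_studies Number of studies to generate.
#' @param genes_per_platform Number of genes measured by each platform.
#' @param shared_gene_fraction Fraction of each platform's genes shared by
#'   all platforms, in (0, 1].
#' @param n_planted Number of outcome-associated genes. Planted genes are
#'   always drawn from the cross-platform shared set, so downstream gene
#'   matching can retain them.
#' @param effect_size Standardized between-class mean difference of planted
#'   genes, in units of `noise_sd`.
#' @param study_effect_sd Between-study heterogeneity of the planted
#'   signal: each study scales each planted gene's effect by an
#'   independent `N(1, study_effect_sd)` factor (truncated at 0), so the
#'   expected effect stays `effect_size` while cohorts differ in which
#'   genes carry it strongly. 0 (the default) gives homogeneous studies.
#' @param signal_penetrance Within-class heterogeneity, mimicking
#'   molecular subgroups: each metastasis sample activates each planted
#'   gene independently with this probability, so the per-gene mean
#'   between-class difference is `signal_penetrance * effect_size` noise
#'   SDs while individual tumours carry only part of the signature. 1
#'   (the default) gives a homogeneous metastasis class.
#' @param samples_per_study Samples per study: a single count, or a vector
#'   of length `n_studies` (cohort sizes commonly differ between studies,
#'   and test cohorts are often the largest).
#' @param metastasis_fraction Fraction of samples in the metastasis class,
#'   in (0, 0.5]. Class counts are fixed by rounding, not resampled.
#' @param platform_assignment Optional character vector of length
#'   `n_studies` of platform labels. `NULL` picks a default layout: the
#'   last four studies (train, train, test, test under the default role
#'   split) on platform `"P1"`, earlier studies alternating `"P1"`/`"P2"`.
#' @param platform_scale_sd SD (log scale) of the per-gene multiplicative
#'   platform distortion; 0 disables it.
#' @param platform_shift_sd SD of the per-gene additive platform offset;
#'   0 disables it.
#' @param noise_sd Within-class SD of expression values.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_studies = 8,
                              genes_per_platform = 2000,
                              shared_gene_fraction = 0.7,
                              n_planted = 50,
                              effect_size = 1.0,
                              study_effect_sd = 0,
                              signal_penetrance = 1,
                              samples_per_study = 60,
                              metastasis_fraction = 0.3,
                              platform_assignment = NULL,
                              platform_scale_sd = 0,
                              platform_shift_sd = 0,
                              noise_sd = 1,
                              seed = 1) {
  assert_count(n_studies, "n_studies")
  assert_count(genes_per_platform, "genes_per_platform")
  assert_fraction(shared_gene_fraction, "shared_gene_fraction")
  assert_count(n_planted, "n_planted", min = 0)
  if (!length(samples_per_study) %in% c(1L, n_studies)) {
    abort_config("`samples_per_study` must be a single count or one per study")
  }
  for (v in samples_per_study) assert_count(v, "samples_per_study", min = 4)
  assert_fraction(metastasis_fraction, "metastasis_fraction", hi = 0.5)
  if (n_planted > genes_per_platform) {
    abort_config("`n_planted` must not exceed `genes_per_platform`")
  }
  n_shared <- round(shared_gene_fraction * genes_per_platform)
  if (n_planted > n_shared) {
    abort_config(
      "`n_planted` exceeds the shared gene set; planted genes must be shared across platforms"
    )
  }
  if (any(round(metastasis_fraction * samples_per_study) < 2)) {
    abort_config(
      "`metastasis_fraction * samples_per_study` must be >= 2 so both classes are nonempty"
    )
  }
  if (platform_scale_sd < 0 || platform_shift_sd < 0) {
    abort_config("platform distortion SDs must be nonnegative")
  }
  if (study_effect_sd < 0) abort_config("`study_effect_sd` must be nonnegative")
  assert_fraction(signal_penetrance, "signal_penetrance")
  if (noise_sd <= 0) abort_config("`noise_sd` must be positive")
  if (!is.null(platform_assignment) &&
      length(platform_assignment) != n_studies) {
    abort_config("`platform_assignment` must have one label per study")
  }
  assert_count(seed, "seed", min = 0)

  if (is.null(platform_assignment)) {
    platform_assignment <- rep(c("P1", "P2"), length.out = n_studies)
    if (n_studies >= 5) {
      platform_assignment[(n_studies - 3):n_studies] <- "P1"
    }
  }

  structure(
    list(
      n_studies = as.integer(n_studies),
      genes_per_platform = as.integer(genes_per_platform),
      shared_gene_fraction = shared_gene_fraction,
      n_planted = as.integer(n_planted),
      effect_size = effect_size,
      study_effect_sd = study_effect_sd,
      signal_penetrance = signal_penetrance,
      samples_per_study = rep(as.integer(samples_per_study),
                              length.out = n_studies),
      metastasis_fraction = metastasis_fraction,
      platform_assignment = as.character(platform_assignment),
      platform_scale_sd = platform_scale_sd,
      platform_shift_sd = platform_shift_sd,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

default_roles <- function(n_studies) {
  if (n_studies < 5) {
    return(rep("feature_definer", n_studies))
  }
  c(
    rep("feature_definer", n_studies - 4),
    "train", "train", "test", "test"
  )
}

#' Simulate a collection of cross-platform expression studies
#'
#' Generates `config$n_studies` studies. Baseline expression is
#' `N(0, noise_sd)` per gene; planted genes get `effect_size * noise_sd`
#' added in metastasis samples. Each platform measures its own gene set
#' (a shared core plus platform-specific genes) and, when the distortion
#' SDs are nonzero, applies a fixed per-gene affine distortion
#' `a_g * x + b_g` common to all studies on that platform.
#'
#' @param config A [simulation_config()].
#' @param roles Optional character vector of study roles
#'   (`"feature_definer"`/`"train"`/`"test"`). `NULL` uses the default
#'   split: with 5 or more studies, the last four are train, train, test,
#'   test and the rest feature definers; otherwise all feature definers.
#'
#' @return An object of class `multistudy_sim`: a list with `studies`
#'   (list of [expression_study()]), `planted_genes` (character vector of
#'   ground-truth outcome-associated gene symbols), and `config`.
#' @export
simulate_multistudy <- function(config, roles = NULL) {
  if (!inherits(config, "simulation_config")) {
    abort_config("`config` must be a `simulation_config`")
  }
  roles <- roles %||% default_roles(config$n_studies)
  if (length(roles) != config$n_studies ||
      !all(roles %in% c("feature_definer", "train", "test"))) {
    abort_config("`roles` must give a valid role per study")
  }

  platforms <- unique(config$platform_assignment)
  n_shared <- round(config$shared_gene_fraction * config$genes_per_platform)
  shared_genes <- sprintf("GS%05d", seq_len(n_shared))
  planted <- head(shared_genes, config$n_planted)
  gene_sets <- lapply(platforms, function(p) {
    n_own <- config$genes_per_platform - n_shared
    own <- if (n_own > 0) sprintf("G%s_%05d", p, seq_len(n_own)) else character()
    c(shared_genes, own)
  })
  names(gene_sets) <- platforms

  withr::with_seed(config$seed, {
    distortions <- lapply(platforms, function(p) {
      g <- length(gene_sets[[p]])
      list(
        a = if (config$platform_scale_sd > 0) {
          exp(rnorm(g, 0, config$platform_scale_sd))
        } else {
          rep(1, g)
        },
        b = if (config$platform_shift_sd > 0) {
          rnorm(g, 0, config$platform_shift_sd)
        } else {
          rep(0, g)
        }
      )
    })
    names(distortions) <- platforms

    studies <- lapply(seq_len(config$n_studies), function(i) {
      n <- config$samples_per_study[i]
      n_pos <- round(config$metastasis_fraction * n)
      platform <- config$platform_assignment[i]
      genes <- gene_sets[[platform]]
      study_id <- sprintf("study%02d", i)
      m <- matrix(
        rnorm(length(genes) * n, 0, config$noise_sd),
        nrow = length(genes),
        dimnames = list(genes, sprintf("%s_S%03d", study_id, seq_len(n)))
      )
      outcome <- c(rep(1L, n_pos), rep(0L, n - n_pos))
      if (config$n_planted > 0 && n_pos > 0) {
        idx <- match(planted, genes)
        eff <- rep(config$effect_size * config$noise_sd, config$n_planted)
        if (config$study_effect_sd > 0) {
          eff <- eff * pmax(rnorm(config$n_planted, 1, config$study_effect_sd), 0)
        }
        shift <- matrix(eff, config$n_planted, n_pos)
        if (config$signal_penetrance < 1) {
          active <- matrix(
            stats::runif(config$n_planted * n_pos) < config$signal_penetrance,
            config$n_planted, n_pos
          )
          shift <- shift * active
        }
        m[idx, outcome == 1L] <- m[idx, outcome == 1L] + shift
      }
      d <- distortions[[platform]]
      m <- d$a * m + d$b
      expression_study(study_id, platform, m, outcome, role = roles[i])
    })

    structure(
      list(studies = studies, planted_genes = planted, config = config),
      class = "multistudy_sim"
    )
  })
}

#' @export
print.multistudy_sim <- function(x, ...) {
  cat(sprintf(
    "<multistudy_sim> %d studies on %d platform(s), %d planted genes\n",
    length(x$studies), length(unique(x$config$platform_assignment)),
    length(x$planted_genes)
  ))
  for (s in x$studies) print(s)
  invisible(x)
}

#' Apply a per-gene affine platform distortion to a study
#'
#' Each gene `g` is transformed as `a_g * x + b_g` with
#' `a_g ~ lognormal(0, scale_sd)` and `b_g ~ N(0, shift_sd)`, drawn once
#' per gene; outcome labels are unchanged. With both SDs zero this is the
#' identity. Note that on a per-gene standardized scale this emulates the
#' residual location/scale mismatch between platforms that standardization
#' of the raw data cannot be relied on to remove.
#'
#' @param study An [expression_study()].
#' @param scale_sd,shift_sd Nonnegative distortion SDs (log-scale
#'   multiplicative, additive).
#' @param seed Integer seed for the per-gene draws.
#'
#' @return The distorted `expression_study`.
#' @export
apply_platform_effect <- function(study, scale_sd, shift_sd, seed) {
  if (scale_sd < 0 || shift_sd < 0) {
    abort_config("distortion SDs must be nonnegative")
  }
  withr::with_seed(as.integer(seed), {
    g <- n_genes(study)
    a <- if (scale_sd > 0) exp(rnorm(g, 0, scale_sd)) else rep(1, g)
    b <- if (shift_sd > 0) rnorm(g, 0, shift_sd) else rep(0, g)
    study$matrix <- a * study$matrix + b
    study
  })
}
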