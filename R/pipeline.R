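# End-to-end orchestration: simulate -> fit -> sensitivities -> trait
# regressions -> mediation -> ANOVA / Friedman / power -> report + manifest.

#' Pipeline configuration
#'
#' Two profiles trade fidelity for runtime: `"ci"` (50 MLE restarts, 1000
#' bootstrap draws) for continuous testing, `"paper"` (300 restarts, 5000
#' draws) for study-faithful runs. Either knob can be overridden
#' individually.
#'
#' @param profile `"ci"` or `"paper"`.
#' @param cohort An [cohort_config()].
#' @param n_restarts,bootstrap_B Optional overrides of the profile values.
#' @param gamma_max Upper bound for the consistency parameter.
#' @return List of class `ha_pipeline_config`.
#' @export
pipeline_config <- function(profile = c("ci", "paper"),
                            cohort = cohort_config(),
                            n_restarts = NULL, bootstrap_B = NULL,
                            gamma_max = 50) {
  profile <- match.arg(profile)
  structure(
    list(profile = profile, cohort = cohort,
         n_restarts = n_restarts %||% if (profile == "ci") 50 else 300,
         bootstrap_B = bootstrap_B %||% if (profile == "ci") 1000 else 5000,
         gamma_max = gamma_max),
    class = "ha_pipeline_config"
  )
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: generate the study; fit the harm-aversion model per subject and
#' session; per-cell logistic sensitivities and their other-self contrasts;
#' trait-interaction regressions (hyperaltruism, relative harm and money
#' sensitivity) per treatment; moderated mediation with cluster bootstrap
#' per treatment; repeated-measures ANOVA on less-painful choice
#' proportions and on the hyperaltruism index; Friedman tests on framing;
#' Cohen's f2 and post-hoc power from the relative-harm-sensitivity trait
#' regression. All tables are written as plain CSV, the report as JSON, and
#' a manifest records an MD5 checksum per output so reruns with the same
#' seed are verifiably identical.
#'
#' @param config A [pipeline_config()].
#' @param seed Master seed; every stage derives a [child_seed()] from it.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory stage results plus
#'   `manifest` and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = tempfile("ha_run_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_study(config$cohort, seed = child_seed(seed, "study"))
  files <- c(
    choices = .write_csv(study$choices, file.path(out_dir, "choices.csv")),
    traits = .write_csv(study$traits, file.path(out_dir, "traits.csv")),
    framing = .write_csv(study$framing, file.path(out_dir, "framing.csv")),
    truth = .write_csv(study$truth, file.path(out_dir, "truth.csv"))
  )
  stopifnot(nrow(validate_tables(choices = study$choices, traits = study$traits,
                                 framing = study$framing)) == 0)

  fits <- fit_subjects(study$choices, n_restarts = config$n_restarts,
                       gamma_max = config$gamma_max,
                       seed = child_seed(seed, "fit"))
  files["fits"] <- .write_csv(fits, file.path(out_dir, "fits.csv"))

  logits <- cell_logits(study$choices)
  rel <- relative_sensitivities(logits)
  files["sensitivities"] <- .write_csv(rel$table,
                                       file.path(out_dir, "sensitivities.csv"))

  treatments <- unique(study$choices$treatment)
  fits$hyper_gain <- fits$kappa_gain_other - fits$kappa_gain_self
  fits$hyper_loss <- fits$kappa_loss_other - fits$kappa_loss_self

  trait_regs <- list()
  mediations <- list()
  power <- list()
  for (trt in treatments) {
    f <- fits[fits$treatment == trt, ]
    r <- rel$table[rel$table$treatment == trt, ]
    base <- merge(
      rbind(data.frame(subject_id = f$subject_id, context = "gain",
                       hyper = f$hyper_gain),
            data.frame(subject_id = f$subject_id, context = "loss",
                       hyper = f$hyper_loss)),
      r[, c("subject_id", "context", "rel_harm_sens", "rel_money_sens")],
      by = c("subject_id", "context")
    )
    base <- merge(base, study$traits, by = "subject_id")
    regs <- list()
    for (m in c("hyper", "rel_harm_sens", "rel_money_sens")) {
      d <- data.frame(outcome = base[[m]], EC = base$EC, IH = base$IH,
                      IB = base$IB, context = base$context)
      regs[[m]] <- trait_regression(d)
    }
    trait_regs[[trt]] <- regs
    f2 <- cohen_f2(regs$rel_harm_sens$r_squared)
    # post-hoc power of the 7-regressor trait model; undefined for cohorts
    # too small to estimate it
    power[[trt]] <- if (config$cohort$n_subjects > 8) {
      regression_posthoc_power(f2, 7, config$cohort$n_subjects)
    } else {
      structure(list(f2 = f2, n_predictors = 7,
                     N = config$cohort$n_subjects, alpha = 0.05,
                     lambda = NA_real_, df1 = 7, df2 = NA_real_,
                     power = NA_real_), class = "ha_power")
    }

    med_data <- merge(base, study$framing[study$framing$treatment == trt,
                                          c("subject_id", "context", "framing")],
                      by = c("subject_id", "context"))
    med_data <- data.frame(subject_id = med_data$subject_id,
                           context = med_data$context, IH = med_data$IH,
                           IB = med_data$IB, EC = med_data$EC,
                           M = med_data$framing, Y = med_data$rel_harm_sens)
    mediations[[trt]] <- bootstrap_mediation(
      med_data, B = config$bootstrap_B,
      seed = child_seed(seed, paste0("boot_", trt))
    )
  }

  # choice-proportion ANOVA: per subject x cell fraction of less-painful picks
  prop <- stats::aggregate(choice ~ subject_id + treatment + context + recipient,
                           data = study$choices, FUN = mean)
  names(prop)[names(prop) == "choice"] <- "value"
  anova_factors <- if (length(treatments) > 1) {
    c("treatment", "context", "recipient")
  } else {
    c("context", "recipient")
  }
  anova_prop <- rm_anova(prop, dv = "value", factors = anova_factors)
  simple <- list()
  for (trt in treatments) {
    simple[[trt]] <- simple_effects(prop[prop$treatment == trt, ], dv = "value",
                                    factor = "recipient", within = "context")
  }
  hyper_long <- rbind(
    data.frame(subject_id = fits$subject_id, treatment = fits$treatment,
               context = "gain", value = fits$hyper_gain),
    data.frame(subject_id = fits$subject_id, treatment = fits$treatment,
               context = "loss", value = fits$hyper_loss)
  )
  anova_hyper <- if (length(treatments) > 1) {
    rm_anova(hyper_long, dv = "value", factors = c("treatment", "context"))
  } else {
    rm_anova(hyper_long, dv = "value", factors = "context")
  }

  friedman <- NULL
  if (length(treatments) > 1) {
    fr <- study$framing
    fr$cell <- paste(fr$context, fr$treatment, sep = "_")
    wide <- stats::reshape(fr[, c("subject_id", "cell", "framing")],
                           idvar = "subject_id", timevar = "cell",
                           direction = "wide")
    mat <- as.matrix(wide[, -1])
    colnames(mat) <- sub("^framing\\.", "", colnames(mat))
    friedman <- friedman_test(mat, pairwise = TRUE)
  }

  report <- list(
    seed = seed, profile = config$profile,
    n_subjects = config$cohort$n_subjects, study = config$cohort$study,
    anova_choice_proportion = anova_prop$table,
    simple_effects_recipient_by_context = lapply(simple, identity),
    anova_hyperaltruism = anova_hyper$table,
    hyperaltruism_group_means = stats::aggregate(
      value ~ treatment + context, data = hyper_long, FUN = mean),
    sensitivity_tests = rel$tests,
    trait_regressions = lapply(trait_regs, function(r) {
      lapply(r, function(x) list(table = x$table, r_squared = x$r_squared))
    }),
    power = lapply(power, unclass),
    mediation = lapply(mediations, function(m) {
      list(estimates = as.list(m$estimates), ci = as.data.frame(m$ci),
           p = as.list(m$p), B = m$B, type = m$type)
    }),
    friedman = if (!is.null(friedman)) {
      list(chi2 = friedman$chi2, df = friedman$df, p = friedman$p,
           contrasts = friedman$contrasts)
    }
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = 10,
                       force = TRUE, pretty = TRUE)
  files["report"] <- report_path

  manifest <- data.frame(
    file = basename(unname(files)),
    md5 = unname(tools::md5sum(unname(files))),
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(out_dir, "manifest.csv")
  .write_csv(manifest, manifest_path)

  invisible(list(study = study, fits = fits, sensitivities = rel,
                 trait_regressions = trait_regs, mediation = mediations,
                 anova_choice = anova_prop, anova_hyper = anova_hyper,
                 simple_effects = simple, friedman = friedman, power = power,
                 report = report, manifest = manifest, out_dir = out_dir))
}
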