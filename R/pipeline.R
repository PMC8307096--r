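#' End-to-end analysis pipeline
#'
#' Runs the full study analysis in order: CRLB quality filter, Bayesian rank
#' correlations per group and score, the hierarchical group models for each
#' clinical score, the covariate-adjusted metabolite model, and the
#' frequentist replication suite, assembled into a single report that can be
#' rendered as JSON, CSV or text. Per-stage seeds are derived
#' deterministically from the master seed so any stage can be re-run in
#' isolation.
#'
#' @name pipeline
NULL

#' Chain and filter settings for a pipeline run
#'
#' @param crlb_threshold CRLB inclusion threshold in percent (strict `<`).
#' @param n_kept,thin,burn_in MCMC settings passed to every Bayesian stage;
#'   defaults 11000 retained draws, thinning 10, burn-in 1000.
#' @param seed master integer seed.
#' @return A list of class `analysis_settings`.
#' @export
analysis_settings <- function(crlb_threshold = 30, n_kept = 11000L,
                              thin = 10L, burn_in = 1000L, seed = 1L) {
  structure(list(crlb_threshold = crlb_threshold,
                 n_kept = as.integer(n_kept), thin = as.integer(thin),
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "analysis_settings")
}

# Deterministic per-stage seed below 2^31, derived from the master seed and
# the stage name so stages are independent and individually re-runnable.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h * 31) %% 2147483629 + 1)
}

#' Run the full analysis on a cohort
#'
#' @param cohort a [cohort_table()].
#' @param settings an [analysis_settings()].
#' @return A list of class `analysis_report` with elements `demographics`
#'   (per-variable frequentist comparisons), `rank_correlations` (CHR:
#'   SOFAS/SOPS/CAST, HC: SOFAS — entries whose score is entirely missing
#'   are omitted with a warning), `glm_unadjusted` (group models for CAST,
#'   AUDIT-C, SOFAS), `glm_adjusted` (metabolite model with the SOFAS
#'   covariate, plus its group difference and effect size),
#'   `frequentist_replication` (hierarchical regression, median split,
#'   three-group ANOVA + Tukey, classical rank correlations) and
#'   `run_metadata`.
#' @export
run_full_analysis <- function(cohort, settings = analysis_settings()) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(settings, "analysis_settings"))
  n_before <- nrow(cohort)
  filtered <- filter_by_crlb(cohort, settings$crlb_threshold)
  counts <- table(factor(filtered$group, levels = c("CHR", "HC")))
  if (any(counts == 0L))
    stop("CRLB filtering stage left group '", names(counts)[counts == 0L][1L],
         "' empty: cannot run between-group analyses")
  chr <- filtered[filtered$group == "CHR", ]
  hc <- filtered[filtered$group == "HC", ]
  mc <- function(n_kept = settings$n_kept) n_kept

  # --- demographics (frequentist, Table-1 shape) -------------------------
  demographics <- list()
  gender_tab <- rbind(CHR = c(male = sum(chr$gender == "male"),
                              female = sum(chr$gender == "female")),
                      HC = c(male = sum(hc$gender == "male"),
                             female = sum(hc$gender == "female")))
  demographics$gender <- tryCatch(pearson_chi2(gender_tab),
                                  error = function(e) NULL)
  for (v in c("age", "cast", "audit_c", "sofas")) {
    demographics[[v]] <- tryCatch(two_sample_t(chr[[v]], hc[[v]]),
                                  error = function(e) NULL)
  }

  # --- Bayesian rank correlations ---------------------------------------
  corr_specs <- list(
    list(group = "CHR", score = "sofas"),
    list(group = "CHR", score = "sops_total"),
    list(group = "CHR", score = "cast"),
    list(group = "HC", score = "sofas")
  )
  rank_correlations <- list()
  for (cs in corr_specs) {
    dat <- if (cs$group == "CHR") chr else hc
    key <- paste0(cs$group, "_", cs$score)
    ok <- !is.na(dat$gsh) & !is.na(dat[[cs$score]])
    if (sum(ok) < 5L) {
      warning("rank correlation ", key, " skipped: fewer than 5 complete pairs")
      next
    }
    rank_correlations[[key]] <- bayesian_spearman(
      dat$gsh[ok], dat[[cs$score]][ok],
      n_kept = settings$n_kept, thin = settings$thin,
      burn_in = settings$burn_in,
      seed = stage_seed(settings$seed, paste0("corr_", key)))
  }

  # --- hierarchical Bayesian GLMs ---------------------------------------
  glm_unadjusted <- list()
  for (v in c("cast", "audit_c", "sofas")) {
    ok <- !is.na(filtered[[v]])
    glm_unadjusted[[v]] <- fit_group_model(
      filtered[[v]][ok], filtered$group[ok],
      n_kept = settings$n_kept, thin = settings$thin,
      burn_in = settings$burn_in,
      seed = stage_seed(settings$seed, paste0("glm_", v)))
  }
  ok <- !is.na(filtered$gsh) & !is.na(filtered$sofas)
  glm_adjusted <- fit_group_covariate_model(
    filtered$gsh[ok], filtered$group[ok], filtered$sofas[ok],
    n_kept = settings$n_kept, thin = settings$thin,
    burn_in = settings$burn_in,
    seed = stage_seed(settings$seed, "glm_gsh_adjusted"))
  gsh_diff <- group_difference(glm_adjusted, "HC", "CHR")

  # --- frequentist replication ------------------------------------------
  ok <- !is.na(filtered$gsh) & !is.na(filtered$sofas)
  hier <- hierarchical_regression(
    filtered$gsh[ok],
    cbind(sofas = filtered$sofas[ok]),
    cbind(diagnosis = as.numeric(filtered$group[ok] == "HC")))  # CHR = 0, HC = 1
  split_lab <- median_split(chr$gsh)
  split_t <- tryCatch(
    two_sample_t(chr$sofas[split_lab == "low"], chr$sofas[split_lab == "high"]),
    error = function(e) NULL)
  three_groups <- c(ifelse(split_lab == "low", "CHR_lowGSH", "CHR_highGSH"),
                    rep("HC", nrow(hc)))
  anova_gsh <- anova_tukey(c(chr$gsh, hc$gsh), three_groups)
  anova_sofas <- anova_tukey(c(chr$sofas, hc$sofas), three_groups)
  spearman_classical <- lapply(rank_correlations, function(r) NULL)
  for (cs in corr_specs) {
    dat <- if (cs$group == "CHR") chr else hc
    key <- paste0(cs$group, "_", cs$score)
    res <- tryCatch(spearman_corr(dat$gsh, dat[[cs$score]]),
                    error = function(e) NULL)
    if (!is.null(res)) spearman_classical[[key]] <- res
  }
  frequentist_replication <- list(
    hierarchical_regression = hier,
    median_split = list(labels = split_lab,
                        n_low = sum(split_lab == "low"),
                        n_high = sum(split_lab == "high"),
                        sofas_t = split_t),
    anova_gsh = anova_gsh,
    anova_sofas = anova_sofas,
    spearman = spearman_classical
  )

  structure(
    list(
      demographics = demographics,
      rank_correlations = rank_correlations,
      glm_unadjusted = glm_unadjusted,
      glm_adjusted = glm_adjusted,
      gsh_group_difference = gsh_diff,
      frequentist_replication = frequentist_replication,
      run_metadata = list(
        seed = settings$seed,
        n_kept = settings$n_kept, thin = settings$thin,
        burn_in = settings$burn_in,
        crlb_threshold = settings$crlb_threshold,
        n_before_filter = n_before, n_after_filter = nrow(filtered),
        n_chr = nrow(chr), n_hc = nrow(hc),
        package_version = as.character(utils::packageVersion("mrsbayes")))
    ),
    class = "analysis_report"
  )
}

summary_row <- function(name, s) {
  c(list(parameter = name),
    lapply(as.list(s)[c("mean", "median", "mode", "hdi_low", "hdi_high", "pp")],
           unname))
}

test_row <- function(name, tr) {
  if (is.null(tr)) return(NULL)
  row <- list(variable = name, method = tr$method, statistic = tr$statistic,
              df = tr$df, p = tr$p_value)
  if (!is.na(tr$estimate)) row$estimate <- tr$estimate
  row
}

# Plain-list image of a report: the single serialisation source for the
# JSON/CSV/text renderers, so all formats agree.
report_to_list <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  posterior_table <- lapply(names(report$glm_adjusted$summaries), function(p)
    summary_row(p, report$glm_adjusted$summaries[[p]]))
  posterior_table <- c(posterior_table, lapply(names(report$rank_correlations),
    function(k) summary_row(paste0("rho_", k),
                            report$rank_correlations[[k]]$rho_summary)))
  list(
    demographics = Filter(Negate(is.null),
                          lapply(names(report$demographics), function(v)
                            test_row(v, report$demographics[[v]]))),
    posterior_table = posterior_table,
    rank_correlations = lapply(report$rank_correlations, function(r)
      list(n = r$n, bf10 = r$bf10, acceptance_rate = r$acceptance_rate,
           summary = summary_row("rho", r$rho_summary))),
    gsh_group_difference = list(
      difference = summary_row("difference", report$gsh_group_difference$difference),
      effect_size = summary_row("effect_size", report$gsh_group_difference$effect_size)),
    score_group_differences = lapply(report$glm_unadjusted, function(g)
      summary_row("difference", g$difference)),
    frequentist = list(
      hierarchical_regression = unclass(report$frequentist_replication$hierarchical_regression),
      median_split = list(
        n_low = report$frequentist_replication$median_split$n_low,
        n_high = report$frequentist_replication$median_split$n_high,
        sofas_t = test_row("sofas",
                           report$frequentist_replication$median_split$sofas_t)),
      anova_gsh = test_row("gsh", report$frequentist_replication$anova_gsh$omnibus),
      anova_sofas = test_row("sofas", report$frequentist_replication$anova_sofas$omnibus),
      tukey_gsh = report$frequentist_replication$anova_gsh$tukey,
      spearman = Filter(Negate(is.null),
                        lapply(names(report$frequentist_replication$spearman),
                               function(k) test_row(k,
                                 report$frequentist_replication$spearman[[k]])))),
    run_metadata = report$run_metadata
  )
}

#' Render an analysis report
#'
#' @param report an `analysis_report` from [run_full_analysis()].
#' @param format `"json"` (full report, lossless precision), `"csv"`
#'   (demographics grid) or `"text"` (posterior-summary grid plus
#'   demographics grid).
#' @return A single character string with the serialized document.
#' @export
render_report <- function(report, format = c("json", "csv", "text")) {
  format <- match.arg(format)
  x <- report_to_list(report)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                         dataframe = "rows", na = "null")))
  }
  demo <- do.call(rbind, lapply(x$demographics, function(r)
    data.frame(variable = r$variable, method = r$method,
               statistic = r$statistic, df = paste(signif(r$df, 6), collapse = ";"),
               p = r$p,
               estimate = if (is.null(r$estimate)) NA_real_ else r$estimate)))
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(demo, con, row.names = FALSE, na = "")
    close(con)
    return(paste(out, collapse = "\n"))
  }
  post <- do.call(rbind, lapply(x$posterior_table, function(r)
    data.frame(parameter = r$parameter, mean = r$mean, median = r$median,
               mode = r$mode, hdi_low = r$hdi_low, hdi_high = r$hdi_high,
               pp = r$pp)))
  num <- vapply(post, is.numeric, TRUE)
  post[num] <- lapply(post[num], function(v) sprintf("%8.3f", v))
  lines <- c(
    "Posterior summaries (mean / median / mode / 95% HDI / PP)",
    utils::capture.output(print(post, row.names = FALSE)),
    "",
    "Demographics comparisons",
    utils::capture.output(print(demo, row.names = FALSE))
  )
  paste(lines, collapse = "\n")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}
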