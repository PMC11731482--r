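# End-to-end orchestration: simulate (or load) a cohort, derive annual
# records and inclusion, match controls to cases, fit trajectory models per
# lipid, compute VIM quintiles, run case/control association tables, and fit
# the nested risk models with AUROC comparison. Every stage writes CSV
# artifacts and the run ends with a manifest recording seed and row counts.

#' Run the full analysis pipeline
#'
#' @param config list (or path to a YAML file) with elements:
#'   \code{cohort} (a \code{\link{cohort_config}} or arguments for one; the
#'   pipeline simulates its input), \code{outdir}, \code{seed},
#'   \code{lipids} (lipids to model, default c("hdl", "tc")),
#'   \code{traj_groups}/\code{traj_orders}/\code{traj_starts} (sweep grid),
#'   \code{run_mixed} (fit the longitudinal mixed model stage; default
#'   TRUE), \code{mixed_candidates} (candidate fixed effects).
#' @return run manifest (list), invisibly written as YAML to
#'   \code{outdir/manifest.yaml}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- config$outdir %||% tempfile("lipidtraj_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  lipids <- config$lipids %||% c("hdl", "tc")
  manifest <- list(seed = seed, stages = list(),
                   package_version = as.character(utils::packageVersion("lipidtraj")))
  stage <- function(name, rows, note = "") {
    manifest$stages[[name]] <<- list(rows = rows, note = note)
  }

  # -- simulate ---------------------------------------------------------
  cc <- config$cohort %||% cohort_config(seed = seed)
  if (!inherits(cc, "cohort_config"))
    cc <- do.call(cohort_config, utils::modifyList(cc, list(seed = seed)))
  cohort <- generate_cohort(cc)
  write_cohort(cohort, file.path(outdir, "cohort"))
  stage("simulate", nrow(cohort$subjects))

  # -- derive -----------------------------------------------------------
  annual <- aggregate_annual(cohort$measurements)
  eligible <- apply_inclusion_filter(annual[, c("id", "rel_year")])
  dropped <- setdiff(unique(cohort$subjects$id), eligible)
  annual <- annual[annual$id %in% eligible, ]
  subjects <- cohort$subjects[cohort$subjects$id %in% eligible, ]
  utils::write.csv(annual, file.path(outdir, "annual_records.csv"),
                   row.names = FALSE)
  stage("derive", nrow(annual),
        sprintf("%d subject(s) excluded by the 3-year rule", length(dropped)))

  # -- match ------------------------------------------------------------
  brk <- match_group_breaks()
  subjects$age_group <- cut(subjects$age, brk$age, right = FALSE)
  subjects$med_user <- as.integer(subjects$id %in%
                                    unique(cohort$orders$id))
  mc <- match_cohort(subjects,
                     exact_vars = c("female", "age_group", "bmi_group",
                                    "med_user"),
                     nearest_vars = c("race", "apoe2", "apoe4",
                                      "educ_gt12"),
                     ratio = config$match_ratio %||% 4L)
  utils::write.csv(mc$matched, file.path(outdir, "matched_cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(mc$balance, file.path(outdir, "balance.csv"),
                   row.names = FALSE)
  stage("match", nrow(mc$matched),
        sprintf("%d unmatched case(s)", length(mc$unmatched_cases)))
  analysis <- merge(subjects, mc$matched[, c("id", "set_id", "weight")],
                    by = "id")

  # -- trajectories -----------------------------------------------------
  traj <- list()
  for (lp in lipids) {
    dat <- annual[annual$id %in% analysis$id,
                  c("id", "rel_year", lp, "on_med")]
    names(dat)[3] <- "value"
    sel <- sweep_and_select(dat,
                            n_groups = config$traj_groups %||% 1:3,
                            orders = config$traj_orders %||% 0:1,
                            refine = isTRUE(config$traj_refine),
                            starts = config$traj_starts %||% 3L,
                            seed = seed)
    utils::write.csv(sel$report,
                     file.path(outdir, sprintf("traj_report_%s.csv", lp)),
                     row.names = FALSE)
    if (sel$status == "ok") {
      utils::write.csv(trajectory_curves(sel$fit),
                       file.path(outdir, sprintf("traj_curves_%s.csv", lp)),
                       row.names = FALSE)
      analysis[[paste0(lp, "_traj")]] <-
        sel$fit$assignment[match(analysis$id, sel$fit$ids)]
    }
    traj[[lp]] <- sel
    stage(paste0("trajectories_", lp), nrow(sel$report), sel$status)
  }

  # -- vim --------------------------------------------------------------
  for (lp in lipids) {
    summ <- subject_lipid_summaries(annual[annual$id %in% analysis$id, ], lp)
    vr <- compute_vim(summ)
    vr$quintile <- assign_quintiles(vr$vim)
    utils::write.csv(vr, file.path(outdir, sprintf("vim_%s.csv", lp)),
                     row.names = FALSE)
    analysis[[paste0(lp, "_vim_q")]] <-
      vr$quintile[match(analysis$id, vr$id)]
    stage(paste0("vim_", lp), nrow(vr),
          sprintf("exponent %.3f", attr(vr, "exponent")))
  }

  # -- associations -----------------------------------------------------
  assoc <- list()
  for (lp in lipids) {
    for (kind in c("_traj", "_vim_q")) {
      v <- analysis[[paste0(lp, kind)]]
      if (is.null(v) || length(unique(v)) < 2L) next
      a <- group_case_association(v, analysis$case,
                                  m_family = 2L * length(lipids))
      assoc[[paste0(lp, kind)]] <- data.frame(
        grouping = paste0(lp, kind), statistic = a$statistic, df = a$df,
        p_value = a$p_value, p_bonferroni = a$p_bonferroni)
    }
  }
  assoc_df <- do.call(rbind, assoc)
  if (!is.null(assoc_df))
    utils::write.csv(assoc_df, file.path(outdir, "associations.csv"),
                     row.names = FALSE)
  stage("associations", length(assoc))

  # -- mixed models -----------------------------------------------------
  if (isTRUE(config$run_mixed %||% TRUE)) {
    lp <- lipids[1]
    long <- merge(annual[, c("id", "rel_year", lp, "on_med")],
                  analysis[, c("id", "age", "female", "educ_gt12",
                               "diabetes", "prs_hdl", "prs_tc")],
                  by = "id")
    long$age_at <- long$age + long$rel_year
    names(long)[names(long) == lp] <- "y"
    cand <- config$mixed_candidates %||%
      c("age_at", "female", "on_med", "diabetes",
        if (lp == "hdl") "prs_hdl" else "prs_tc")
    sel <- aic_backward_select(long, "y", cand,
                               locked_terms = character(),
                               random_slope = "age_at")
    utils::write.csv(sel$fit$coefficients,
                     file.path(outdir, sprintf("mixed_%s.csv", lp)),
                     row.names = FALSE)
    utils::write.csv(sel$trace,
                     file.path(outdir, sprintf("mixed_%s_trace.csv", lp)),
                     row.names = FALSE)
    stage("mixed", nrow(long),
          sprintf("%s; %d term(s) retained", lp, length(sel$terms)))
  }

  # -- risk models ------------------------------------------------------
  analysis$hdl_g1 <- as.integer((analysis$hdl_traj %||% 3L) == 1L)
  analysis$hdl_g2 <- as.integer((analysis$hdl_traj %||% 3L) == 2L)
  vim_col <- paste0(lipids[min(2L, length(lipids))], "_vim_q")
  analysis$vim_q1 <- as.integer((analysis[[vim_col]] %||% 2L) == 1L)
  base_terms <- c("age_c", "female", "educ_gt12", "weight",
                  paste0("pc", 1:3))
  lipid_terms <- c(if (!is.null(analysis$hdl_traj)) c("hdl_g1", "hdl_g2"),
                   "vim_q1")
  gen_terms <- c("prs_ad", "prs_tc")
  sets <- list(base = base_terms,
               base_lipids = c(base_terms, lipid_terms),
               base_genetics = c(base_terms, gen_terms),
               base_lipids_genetics = c(base_terms, lipid_terms, gen_terms))
  fits <- lapply(sets, function(tms)
    fit_logistic_cluster(analysis,
                         stats::as.formula(paste("case ~",
                                                 paste(tms, collapse = " + "))),
                         cluster = analysis$set_id))
  full <- fits$base_lipids_genetics
  utils::write.csv(full$coefficients, file.path(outdir, "risk_model.csv"),
                   row.names = FALSE)
  hl <- hosmer_lemeshow(full)
  lt <- link_test(full)
  cmp <- compare_aurocs(fits, names(sets))
  utils::write.csv(cmp$auc, file.path(outdir, "auroc.csv"),
                   row.names = FALSE)
  utils::write.csv(cmp$comparisons, file.path(outdir, "auroc_tests.csv"),
                   row.names = FALSE)
  mg <- predictive_margins(full, "prs_ad",
                           seq(-2, 2, by = 0.5), fix = list(age_c = 0))
  utils::write.csv(mg, file.path(outdir, "margins_prs_ad.csv"),
                   row.names = FALSE)
  stage("risk", nrow(analysis),
        sprintf("HL p=%.3f; link %s; AUC base %.3f full %.3f",
                hl$p_value, ifelse(isTRUE(lt$pass), "pass", "flagged"),
                cmp$auc$auc[1], cmp$auc$auc[4]))

  manifest$outdir <- outdir
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
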