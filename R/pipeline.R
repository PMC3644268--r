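#' Run the full diagnostic pipeline
#'
#' Fits the consistency model to a contrast-level input, and writes into
#' \code{out_dir}: (i) \code{stats.json} with the treatment estimates, the
#' league table of all contrasts, the per-design direct estimates, the
#' full Q decomposition and the per-design detach summaries; (ii)
#' \code{qdiff.csv}, the labelled Q-difference matrix; and (iii)
#' \code{netheat.<format>}, the net heat plot. When no design is
#' detachable (a network without loops) only the stats file is written,
#' with a warning, since the inconsistency assessment is undefined.
#'
#' @param input contrast table: a file path or data frame.
#' @param arm_vars optional arm-variance table (path or data frame).
#' @param out_dir output directory, created if needed.
#' @param color_cap,cluster,format net heat options, see [netheat()].
#' @param quiet suppress progress messages?
#' @return Invisibly, a list with the fitted \code{netgls} object and the
#'   paths written.
#' @export
run_pipeline <- function(input, arm_vars = NULL, out_dir = ".",
                         color_cap = 8, cluster = TRUE, format = "svg",
                         quiet = FALSE) {
  stopifnot(color_cap > 0)
  if (is.character(input)) input <- read_contrast_data(input)
  if (is.character(arm_vars)) arm_vars <- read_arm_variances(arm_vars)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  fit <- netgls(input, arm_vars)
  say(sprintf("fitted network: %d studies, %d designs, %d treatments",
              fit$net$S, fit$net$D, length(fit$net$treatments)))

  det <- detachable_designs(fit)
  paths <- list(stats = file.path(out_dir, "stats.json"))
  jsonlite::write_json(stats_payload(fit, det), paths$stats,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote ", paths$stats)

  if (length(det) == 0L) {
    warning("inconsistency unassessable (no loops): ",
            "Q-difference matrix and net heat plot skipped")
    return(invisible(list(fit = fit, paths = paths)))
  }

  qd <- q_diff_matrix(fit)
  paths$qdiff <- file.path(out_dir, "qdiff.csv")
  utils::write.csv(as.data.frame(unclass_qdiff(qd)), paths$qdiff)
  say("wrote ", paths$qdiff)

  paths$netheat <- file.path(out_dir, paste0("netheat.", format))
  netheat(fit, file = paths$netheat, format = format,
          color_cap = color_cap, cluster = cluster)
  say("wrote ", paths$netheat)
  invisible(list(fit = fit, paths = paths))
}

stats_payload <- function(fit, det) {
  se <- sqrt(diag(fit$vcov))
  league <- relative_effects(fit)
  Q <- fit$Q
  detach_summ <- lapply(det, function(d) {
    r <- detach_design(fit, d)
    list(design = d, Q = r$Q, df = r$df, p = r$p,
         deviation = as.list(r$theta_dir_ind))
  })
  list(
    schema_version = "1.0",
    treatments = fit$net$treatments,
    reference = fit$net$reference,
    estimates = list(treatment = names(fit$theta),
                     estimate = unname(fit$theta), se = unname(se)),
    contrasts = list(labels = rownames(league$estimate),
                     estimate = league$estimate, se = league$se),
    directs = lapply(fit$directs, function(d)
      list(design = d$design, theta_dir = as.list(d$theta_dir),
           se = as.list(sqrt(diag(d$V_dir))))),
    q = list(
      network = list(Q = Q$Q_net, df = Q$df_net, p = Q$p_net),
      heterogeneity = list(Q = Q$Q_het, df = Q$df_het, p = Q$p_het,
                           per_design = lapply(Q$per_design_het, function(h)
                             list(Q = h$Q, df = h$df, p = h$p))),
      inconsistency = list(Q = Q$Q_inc, df = Q$df_inc, p = Q$p_inc,
                           per_design = as.list(Q$per_design_inc))),
    hat = list(labels = rownames(fit$H), values = fit$H),
    detach = detach_summ)
}
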