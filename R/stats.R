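#' Group table for one morphometric parameter
#'
#' Named per-group value vectors for a single parameter, with a designated
#' control group whose mean defines 100% for percent-of-control scaling.
#'
#' @param parameter name of the parameter (one of [profile_parameters()]).
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param control_group name of the control group (must be in `groups`).
#' @return a `group_table`.
#' @export
group_table <- function(parameter, groups, control_group = "control") {
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (!control_group %in% names(groups)) {
    stopf("control group '%s' not found", control_group)
  }
  structure(list(parameter = parameter, groups = groups,
                 control_group = control_group),
            class = "group_table")
}

#' Express values as percent of the control-group mean
#'
#' The control group's mean is defined as 100%; every value in every group is
#' divided by it and multiplied by 100.
#'
#' @param table a [group_table()].
#' @return a `group_table` of percents.
#' @export
normalize_to_control <- function(table) {
  ctrl_mean <- mean(table$groups[[table$control_group]])
  if (ctrl_mean == 0) stopf("control-group mean is zero; cannot normalize")
  out <- table
  out$groups <- lapply(table$groups, function(v) 100 * v / ctrl_mean)
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: `F = MSB / MSW` with
#' `MSB = SSB / (g - 1)` (between groups) and `MSW = SSW / (N - g)` (within
#' groups); `p` is the upper tail of the F distribution. Two identical groups
#' give `F = 0`, `p = 1`.
#'
#' @param groups named or unnamed list of numeric vectors; >= 2 groups with
#'   n >= 2 each.
#' @return list with `F`, `p`, `df` (c(between, within)), and the per-group
#'   means.
#' @export
one_way_anova <- function(groups) {
  g <- length(groups)
  if (g < 2) stopf("need at least 2 groups")
  n_i <- lengths(groups)
  if (any(n_i < 2)) stopf("every group needs n >= 2")
  all_v <- unlist(groups, use.names = FALSE)
  N <- length(all_v)
  grand <- mean(all_v)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw == 0 && ssb == 0) stopf("zero total variance; ANOVA undefined")
  if (ssw == 0) stopf("zero within-group variance; ANOVA undefined")
  df1 <- g - 1L
  df2 <- N - g
  Fval <- (ssb / df1) / (ssw / df2)
  list(F = Fval, p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
       df = c(between = df1, within = df2), means = means)
}

# significance tier from a p value: p<0.05 *, p<0.01 **, p<0.001 ***
significance_tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "ns"))))
}

#' Compare groups across all ten morphometric parameters
#'
#' For each parameter: per-group mean and SD, percent-of-control (control
#' mean = 100%), the omnibus one-way ANOVA F and p over all groups, a
#' per-group two-group F and p vs the control group (the vs-control stars the
#' figures report), significance tiers at p < 0.05 / 0.01 / 0.001, and a
#' Holm-adjusted vs-control p column (an extension beyond the source
#' convention, clearly labeled).
#'
#' @param profiles data.frame with a `group` column and the parameter
#'   columns (see [profile_cohort()]).
#' @param control_group name of the control group.
#' @param parameters parameter columns to compare.
#' @return data.frame, one row per (parameter, group).
#' @export
compare_profiles <- function(profiles, control_group = "control",
                             parameters = profile_parameters()) {
  if (!"group" %in% names(profiles)) stopf("profiles needs a 'group' column")
  grp_names <- unique(profiles$group)
  if (!control_group %in% grp_names) stopf("control group '%s' missing", control_group)

  rows <- list()
  for (par in parameters) {
    groups <- split(profiles[[par]], profiles$group)[grp_names]
    ctrl_mean <- mean(groups[[control_group]])
    omni <- tryCatch(one_way_anova(groups), error = function(e) NULL)
    for (gn in grp_names) {
      v <- groups[[gn]]
      vs <- if (gn == control_group) {
        list(F = NA_real_, p = NA_real_)
      } else {
        tryCatch(one_way_anova(groups[c(control_group, gn)]),
                 error = function(e) list(F = NA_real_, p = NA_real_))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, group = gn, n = length(v),
        mean = mean(v), sd = stats::sd(v),
        percent_of_control = if (ctrl_mean != 0) 100 * mean(v) / ctrl_mean else NA_real_,
        F_omnibus = omni$F %||% NA_real_, p_omnibus = omni$p %||% NA_real_,
        F_vs_control = vs$F, p_vs_control = vs$p,
        tier = significance_tier(vs$p)
      )
    }
  }
  out <- do.call(rbind, rows)
  # Holm correction across parameters, within each non-control group (extension)
  out$p_vs_control_holm <- NA_real_
  for (gn in setdiff(grp_names, control_group)) {
    sel <- out$group == gn
    out$p_vs_control_holm[sel] <- stats::p.adjust(out$p_vs_control[sel], "holm")
  }
  out
}
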