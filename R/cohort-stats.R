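#' Validate a cohort analysis table
#'
#' A cohort table has one row per subject with `subject_id`, `group`
#' (`"RCT"` or `"CONTROL"`), `csa_deg`, `gta_deg`, `if_rom_deg`;
#' `sum_deg` is (re)computed as `csa_deg + gta_deg`.
#'
#' @param table data frame with the columns above.
#' @return The table as a tibble with `sum_deg`, validated.
#' @export
cohort_table <- function(table) {
  tb <- as_tibble(table)
  need <- c("subject_id", "group", "csa_deg", "gta_deg", "if_rom_deg")
  miss <- setdiff(need, names(tb))
  if (length(miss)) {
    abort(sprintf("cohort table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!all(tb$group %in% c("RCT", "CONTROL"))) {
    abort("group must be 'RCT' or 'CONTROL'")
  }
  if (any(tb$if_rom_deg < 0 | tb$if_rom_deg > 120)) {
    abort("if_rom_deg must lie in [0, 120]")
  }
  tb$sum_deg <- tb$csa_deg + tb$gta_deg
  tb
}

#' Group comparison of the cohort variables
#'
#' Per continuous variable: group means, standard deviations and ranges,
#' a two-sample Student t test (pooled variance by default; `welch =
#' TRUE` for the unequal-variance form) and Shapiro-Wilk normality
#' p-values per group.
#'
#' @param table a [cohort_table()].
#' @param vars variables to compare.
#' @param welch use the Welch t test instead of the pooled-variance
#'   Student form.
#' @return Tibble, one row per variable.
#' @export
group_compare <- function(table,
                          vars = c("csa_deg", "gta_deg", "sum_deg", "if_rom_deg"),
                          welch = FALSE) {
  tb <- cohort_table(table)
  a <- tb[tb$group == "RCT", ]
  b <- tb[tb$group == "CONTROL", ]
  if (nrow(a) < 2L || nrow(b) < 2L) abort("each group needs at least 2 subjects")
  purrr::map_dfr(vars, function(v) {
    x <- a[[v]]; y <- b[[v]]
    tt <- t.test(x, y, var.equal = !welch)
    shap <- function(z) {
      if (length(unique(z)) < 3) NA_real_ else shapiro.test(z)$p.value
    }
    tibble(variable = v,
           mean_rct = mean(x), sd_rct = sd(x), min_rct = min(x), max_rct = max(x),
           mean_control = mean(y), sd_control = sd(y),
           min_control = min(y), max_control = max(y),
           t_statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value,
           test = if (welch) "welch_t" else "student_t",
           shapiro_p_rct = shap(x), shapiro_p_control = shap(y))
  })
}

#' Chi-square test of proportions on a 2x2 table
#'
#' Pearson chi-square with df = 1, with or without the Yates continuity
#' correction (the two published proportion comparisons of the source
#' cohort are each consistent with a different variant, so the choice is
#' explicit and recorded in the output).
#'
#' @param counts 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param correction apply the Yates continuity correction.
#' @return One-row tibble with `chi2`, `df`, `p_value`, `correction`.
#' @export
chi2_proportions <- function(counts, correction = FALSE) {
  M <- as.matrix(counts)
  if (!all(dim(M) == c(2L, 2L))) abort("counts must be a 2x2 matrix")
  if (any(M < 0) || any(M != round(M))) abort("counts must be non-negative integers")
  if (any(rowSums(M) == 0) || any(colSums(M) == 0)) {
    abort("all margins must be positive")
  }
  ct <- suppressWarnings(chisq.test(M, correct = correction))
  tibble(chi2 = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value, correction = correction)
}

#' Correlation battery of the cohort variables
#'
#' The published analysis pattern: Pearson r between CSA and GTA (the two
#' morphological angles, expected uncorrelated), and Spearman rank
#' correlations (average ranks for ties) of CSA, GTA and their sum
#' against the impingement-free range of motion. Spearman p-values use
#' the exact distribution for n <= 10 without ties and the t
#' approximation otherwise.
#'
#' @param table a [cohort_table()].
#' @return Tibble with `var1`, `var2`, `method`, `estimate`, `p_value`, `n`.
#' @export
correlation_battery <- function(table) {
  tb <- cohort_table(table)
  if (nrow(tb) < 3L) abort("need at least 3 subjects")
  pairs <- list(
    c("csa_deg", "gta_deg", "pearson"),
    c("csa_deg", "if_rom_deg", "spearman"),
    c("gta_deg", "if_rom_deg", "spearman"),
    c("sum_deg", "if_rom_deg", "spearman"))
  purrr::map_dfr(pairs, function(p) {
    x <- tb[[p[1]]]; y <- tb[[p[2]]]
    for (nm in c(p[1], p[2])) {
      if (sd(tb[[nm]]) < 1e-12) {
        abort(sprintf("correlation undefined: column '%s' is constant", nm))
      }
    }
    exact <- p[3] == "spearman" && nrow(tb) <= 10 &&
      !anyDuplicated(x) && !anyDuplicated(y)
    ct <- suppressWarnings(
      cor.test(x, y, method = p[3], exact = if (p[3] == "spearman") exact else NULL))
    tibble(var1 = p[1], var2 = p[2], method = p[3],
           estimate = unname(ct$estimate), p_value = ct$p.value, n = nrow(tb))
  })
}

#' Generate, measure, simulate and analyse a synthetic cohort
#'
#' The full pipeline on synthetic subjects: each shoulder is generated
#' with [make_shoulder()], CSA and GTA are *measured from the meshes*
#' (not taken from the generator targets), scaption is simulated and the
#' IF-ROM recorded, and the assembled table is run through
#' [group_compare()] and [correlation_battery()]. Deterministic under
#' the cohort seed.
#'
#' @param cp a [cohort_params()].
#' @param config a [simulation_config()].
#' @param progress print one line per subject to stderr.
#' @return A `cohort_analysis` object: `table` (cohort tibble),
#'   `group_comparison`, `correlations`, plus the inputs.
#' @export
end_to_end_cohort <- function(cp = cohort_params(),
                              config = simulation_config(),
                              progress = FALSE) {
  subjects <- sample_cohort(cp)
  rows <- purrr::pmap_dfr(
    list(subjects$subject_id, subjects$group, subjects$params),
    function(id, grp, par) {
      model <- make_shoulder(par)
      ang <- measure_angles(model)
      sim <- simulate_scaption(model, config)
      if (progress) {
        message(sprintf("%s %s: CSA %.1f GTA %.1f IF-ROM %g",
                        id, grp, ang$csa_deg, ang$gta_deg, sim$if_rom_deg))
      }
      tibble(subject_id = id, group = grp,
             csa_deg = ang$csa_deg, gta_deg = ang$gta_deg,
             csa_target_deg = par$csa_deg, gta_target_deg = par$gta_deg,
             if_rom_deg = sim$if_rom_deg)
    })
  tb <- cohort_table(rows)
  structure(list(table = tb,
                 group_comparison = group_compare(tb),
                 correlations = correlation_battery(tb),
                 cohort_params = cp, config = config),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d subjects (%d RCT, %d CONTROL)\n",
              nrow(x$table), sum(x$table$group == "RCT"),
              sum(x$table$group == "CONTROL")))
  cr <- x$correlations
  for (i in seq_len(nrow(cr))) {
    cat(sprintf("  %s(%s, %s) = %.2f (p = %.3g)\n", cr$method[i],
                cr$var1[i], cr$var2[i], cr$estimate[i], cr$p_value[i]))
  }
  invisible(x)
}

#' @rdname end_to_end_cohort
#' @param x,object a `cohort_analysis`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.cohort_analysis <- function(x, ...) x$table

#' @rdname end_to_end_cohort
#' @exportS3Method generics::glance
glance.cohort_analysis <- function(x, ...) {
  cr <- x$correlations
  pick <- function(v1, v2) cr$estimate[cr$var1 == v1 & cr$var2 == v2]
  tibble(n = nrow(x$table),
         pearson_csa_gta = pick("csa_deg", "gta_deg"),
         spearman_csa_ifrom = pick("csa_deg", "if_rom_deg"),
         spearman_gta_ifrom = pick("gta_deg", "if_rom_deg"),
         spearman_sum_ifrom = pick("sum_deg", "if_rom_deg"),
         mean_ifrom_rct = mean(x$table$if_rom_deg[x$table$group == "RCT"]),
         mean_ifrom_control = mean(x$table$if_rom_deg[x$table$group == "CONTROL"]))
}

#' @rdname end_to_end_cohort
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_analysis <- function(object, ...) {
  tb <- object$table
  long <- dplyr::bind_rows(
    tibble(predictor = "CSA (deg)", value = tb$csa_deg,
           if_rom_deg = tb$if_rom_deg, group = tb$group),
    tibble(predictor = "GTA (deg)", value = tb$gta_deg,
           if_rom_deg = tb$if_rom_deg, group = tb$group),
    tibble(predictor = "CSA + GTA (deg)", value = tb$sum_deg,
           if_rom_deg = tb$if_rom_deg, group = tb$group))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$if_rom_deg,
                                     colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "IF-ROM (deg)") +
    ggplot2::theme_minimal()
}
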