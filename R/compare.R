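#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Compare the four reconstruction arms on a cohort of case scores
#'
#' Builds the study's comparison table for one stratum: per-arm mean, SD
#' and median of the streak scores, percent change against the NOMAR
#' baseline, and Wilcoxon signed-rank p-values for the three paired
#' contrasts (each corrected arm vs NOMAR, IMAR vs DEMAR, IMAR vs
#' IMAR+DEMAR). Cases are paired by `case_id`; every case must carry all
#' four arms.
#'
#' @param scores Tibble with columns `case_id`, `arm`, `mean_score` (and
#'   optionally `stratum`), one row per case x arm.
#' @param stratum Optional stratum filter (`"hip"` or `"dental"`).
#' @return An object of class `arm_comparison`: list with `summary`
#'   (per-arm tibble), `contrasts` (paired-test tibble), `scores_wide`,
#'   `stratum` and `n_cases`.
#' @export
compare_arms <- function(scores, stratum = NULL) {
  if (!is.null(stratum)) {
    scores <- scores[scores$stratum == stratum, , drop = FALSE]
  }
  missing_arms <- setdiff(ARM_LABELS, unique(scores$arm))
  if (length(missing_arms) > 0) {
    stop("missing arm(s): ", paste(missing_arms, collapse = ", "),
         call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    scores[, c("case_id", "arm", "mean_score")],
    names_from = "arm", values_from = "mean_score"
  )
  incomplete <- wide$case_id[!stats::complete.cases(wide)]
  if (length(incomplete) > 0) {
    stop("case(s) missing an arm: ", paste(incomplete, collapse = ", "),
         call. = FALSE)
  }
  nomar <- wide$NOMAR
  per_arm <- lapply(ARM_LABELS, function(a) {
    v <- wide[[a]]
    tibble::tibble(
      arm = a, n = length(v), mean = mean(v), sd = sd(v),
      median = median(v),
      pct_vs_nomar = percent_reduction(mean(v), mean(nomar)),
      p_vs_nomar = if (a == "NOMAR") NA_real_ else
        suppressWarnings(wilcoxon_signed_rank(v, nomar)$p.value)
    )
  })
  contrasts <- tibble::tibble(
    contrast = c("DEMAR vs NOMAR", "IMAR vs NOMAR", "IMAR+DEMAR vs NOMAR",
                 "IMAR vs DEMAR", "IMAR vs IMAR+DEMAR"),
    p = c(
      wilcoxon_signed_rank(wide$DEMAR, nomar)$p.value,
      wilcoxon_signed_rank(wide$IMAR, nomar)$p.value,
      wilcoxon_signed_rank(wide$`IMAR+DEMAR`, nomar)$p.value,
      wilcoxon_signed_rank(wide$IMAR, wide$DEMAR)$p.value,
      wilcoxon_signed_rank(wide$IMAR, wide$`IMAR+DEMAR`)$p.value
    )
  )
  structure(
    list(summary = dplyr::bind_rows(per_arm), contrasts = contrasts,
         scores_wide = wide,
         stratum = stratum %||%
           (if ("stratum" %in% names(scores))
              paste(unique(scores$stratum), collapse = "+") else "all"),
         n_cases = nrow(wide)),
    class = "arm_comparison"
  )
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat(sprintf("Arm comparison (%s stratum, %d cases)\n", x$stratum, x$n_cases))
  print(as.data.frame(x$summary), digits = 4)
  cat("\nPaired contrasts (Wilcoxon signed rank):\n")
  print(as.data.frame(x$contrasts), digits = 4)
  invisible(x)
}

#' Tidy an arm comparison into its per-arm summary table
#'
#' @param x An `arm_comparison`.
#' @param ... Unused.
#' @return The per-arm summary tibble (arm, n, mean, sd, median,
#'   pct_vs_nomar, p_vs_nomar) with the stratum attached.
#' @export
tidy.arm_comparison <- function(x, ...) {
  dplyr::mutate(x$summary, stratum = x$stratum, .before = 1)
}

#' One-row overview of an arm comparison
#'
#' @param x An `arm_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: stratum, n_cases, the NOMAR median, the three
#'   corrected arms' percent change vs NOMAR, and whether the expected
#'   ordering NOMAR > DEMAR > IMAR > IMAR+DEMAR holds by median.
#' @export
glance.arm_comparison <- function(x, ...) {
  med <- stats::setNames(x$summary$median, x$summary$arm)
  tibble::tibble(
    stratum = x$stratum, n_cases = x$n_cases,
    median_nomar = med[["NOMAR"]],
    pct_demar = x$summary$pct_vs_nomar[x$summary$arm == "DEMAR"],
    pct_imar = x$summary$pct_vs_nomar[x$summary$arm == "IMAR"],
    pct_imar_demar = x$summary$pct_vs_nomar[x$summary$arm == "IMAR+DEMAR"],
    ordering_holds = med[["NOMAR"]] > med[["DEMAR"]] &&
      med[["DEMAR"]] > med[["IMAR"]] &&
      med[["IMAR"]] > med[["IMAR+DEMAR"]]
  )
}

#' Bar chart of per-arm streak scores
#'
#' Mean low-frequency amplitude sum per arm with an SD whisker, the shape
#' of the study's quantitative summary figure.
#'
#' @param object An `arm_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.arm_comparison <- function(object, ...) {
  df <- dplyr::mutate(object$summary,
                      arm = factor(.data$arm, levels = ARM_LABELS))
  ggplot2::ggplot(df, ggplot2::aes(.data$arm, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = .data$mean + .data$sd),
      width = 0.25
    ) +
    ggplot2::labs(
      x = NULL, y = "sum of low-frequency amplitudes",
      title = sprintf("Streak artefact score by arm (%s, n = %d)",
                      object$stratum, object$n_cases)
    ) +
    ggplot2::theme_minimal()
}
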