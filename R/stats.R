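# Proportion statistics and run reporting.

#' Wald confidence interval for a proportion
#'
#' Asymptotic-normal (Wald) interval `p +- z * sqrt(p(1-p)/n)`, clipped to
#' \[0, 1\]. At the boundaries (k = 0 or k = n) the interval degenerates to
#' a point — a known limitation of the Wald form, retained as the reporting
#' convention for the ensemble fractions.
#'
#' @param k number of successes.
#' @param n number of trials (>= 1).
#' @param level confidence level.
#' @return numeric `c(lo, hi)`.
#' @examples
#' proportion_ci(8900, 10000)
#' @export
proportion_ci <- function(k, n, level = 0.95) {
  if (n < 1) stop("n must be at least 1")
  if (k < 0 || k > n) stop("need 0 <= k <= n")
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  half <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

#' Significance tier symbols
#'
#' Maps p-values to the figure-legend symbols: `***` (< 0.001), `**`
#' (< 0.01), `*` (< 0.05), `n.s.` otherwise.
#'
#' @param p vector of p-values.
#' @return character vector.
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "n.s.")))
}

#' Pairwise chi-square comparisons of scenario proportions
#'
#' Pearson chi-square tests (no continuity correction; at ensemble sample
#' sizes the Yates correction is immaterial) on the 2x2 apoptotic/surviving
#' tables of every scenario pair, with Bonferroni adjustment. The adjusted
#' p-value is `min(1, m * p)` where `m` is the correction family size —
#' by default the number of comparisons performed.
#'
#' @param results a [scenario_fractions()] data.frame (or any data.frame
#'   with `scenario`, `n`, `n_apoptotic`).
#' @param family_size Bonferroni multiplier; defaults to the number of
#'   pairwise tests.
#' @return data.frame with `scenario_a`, `scenario_b`, `statistic`, `p_raw`,
#'   `p_adjusted`, `tier`.
#' @export
pairwise_chisq <- function(results, family_size = NULL) {
  stopifnot(nrow(results) >= 2)
  pairs <- utils::combn(nrow(results), 2)
  m <- if (is.null(family_size)) ncol(pairs) else family_size
  rows <- lapply(seq_len(ncol(pairs)), function(idx) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    tab <- matrix(c(results$n_apoptotic[i],
                    results$n[i] - results$n_apoptotic[i],
                    results$n_apoptotic[j],
                    results$n[j] - results$n_apoptotic[j]),
                  nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("zero-margin table for ", results$scenario[i], " vs ",
              results$scenario[j], "; p set to 1")
      stat <- 0; p <- 1
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      stat <- unname(ct$statistic); p <- ct$p.value
    }
    data.frame(scenario_a = results$scenario[i],
               scenario_b = results$scenario[j],
               statistic = stat, p_raw = p,
               p_adjusted = min(1, m * p))
  })
  out <- do.call(rbind, rows)
  out$tier <- significance_tier(out$p_adjusted)
  rownames(out) <- NULL
  out
}

#' Assemble a run report
#'
#' Collects completed pipeline stages into one machine-readable summary
#' (JSON) plus a human-readable text rendering. The report records the
#' package version, the seeds and exclusion counts attached to the stage
#' objects, and every stage table; content is deterministic given the
#' inputs.
#'
#' @param stages named list of completed stage results (at least one), e.g.
#'   `list(scenarios = <scenario_fractions>, comparisons = <pairwise_chisq>,
#'   windows = <list of viability_window>, golden_hour =
#'   <intervention_panel>)`.
#' @param path optional output path (without extension); writes
#'   `<path>.json` and `<path>.txt`.
#' @return the report list, invisibly.
#' @export
run_report <- function(stages, path = NULL) {
  if (!length(stages) || is.null(names(stages)) || any(names(stages) == ""))
    stop("no completed stages supplied; expected a named list with at ",
         "least one of: scenarios, comparisons, stratified, windows, ",
         "perturbation, sensitivity, golden_hour")
  meta <- list(package = "beclinduality",
               version = as.character(utils::packageVersion("beclinduality")))
  for (nm in names(stages)) {
    sd <- attr(stages[[nm]], "seed")
    if (!is.null(sd)) meta[[paste0("seed_", nm)]] <- sd
    ex <- attr(stages[[nm]], "exclusions")
    if (!is.null(ex)) meta[[paste0("exclusions_", nm)]] <- as.list(ex)
  }
  serialise <- function(x) {
    if (inherits(x, "viability_window"))
      return(list(S = x$S, theta_L = x$theta_L, theta_H = x$theta_H,
                  empty = x$empty))
    if (inherits(x, "golden_hour"))
      return(list(S = x$S, t_star = x$t_star, unbounded = x$unbounded))
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, serialise))
    x
  }
  report <- list(meta = meta, stages = lapply(stages, serialise))
  if (!is.null(path)) {
    jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    txt <- c(paste0("beclinduality run report (v", meta$version, ")"), "")
    for (nm in names(stages)) {
      txt <- c(txt, paste0("== ", nm, " =="),
               utils::capture.output(print(stages[[nm]])), "")
    }
    writeLines(txt, paste0(path, ".txt"))
  }
  invisible(report)
}

#' Write / read a trajectory as tidy CSV
#'
#' Columns `time, B, Bc, A, M, C, J`, one row per output time.
#'
#' @param traj a `beclin_trajectory` from [simulate_cell()].
#' @param path CSV file path.
#' @return `read_trajectory` returns the data.frame; `write_trajectory` the
#'   path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(traj[, c("time", "B", "Bc", "A", "M", "C", "J")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tr <- read.csv(path)
  class(tr) <- c("beclin_trajectory", "data.frame")
  tr
}
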