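#' Summarize a stakitt analysis into per-bank and gap statistics
#'
#' Combines opposing-leaf measurements into gap deviations (the sum of the
#' two retraction-positive leaf deviations, so a positive gap deviation
#' means the gap is wider than planned), computes per-bank mean and SD,
#' and flags out-of-tolerance measurements.
#'
#' Default action limits follow the interim recommendation for routine
#' MLC positional QA: +/- 0.5 mm at gantry 0 and +/- 1.0 mm at the other
#' cardinal gantry angles.
#'
#' @param analysis a [stakitt_analysis][analyze_stakitt], or a
#'   measurement data.frame as returned by [measure_tips()].
#' @param action_limit tolerance in mm; `NULL` selects the gantry-angle
#'   default above.
#' @param gantry_angle used only when `analysis` is a bare data.frame.
#' @return An object of class `stakitt_result`: list with `measurements`,
#'   `gaps` (leaf, stakitt, gap_deviation), `bank_stats` (bank, mean, sd,
#'   n), `gap_mean`, `gap_sd`, `out_of_tolerance` (subset of
#'   measurements), `action_limit`, `gantry_angle`.
#' @export
summarize_stakitt <- function(analysis, action_limit = NULL,
                              gantry_angle = NULL) {
  if (inherits(analysis, "stakitt_analysis")) {
    meas <- analysis$measurements
    gantry_angle <- analysis$gantry_angle
  } else {
    meas <- analysis
    if (is.null(gantry_angle)) gantry_angle <- 0
  }
  ok <- meas[meas$flag == "ok" & is.finite(meas$deviation), ]
  if (nrow(ok) < 1) stop("summarize_stakitt: no valid measurements")
  if (is.null(action_limit))
    action_limit <- if (normalize_angle(gantry_angle) == 0) 0.5 else 1.0

  a <- ok[ok$bank == "A", c("leaf", "stakitt", "deviation")]
  b <- ok[ok$bank == "B", c("leaf", "stakitt", "deviation")]
  gaps <- merge(a, b, by = c("leaf", "stakitt"), suffixes = c("_a", "_b"))
  if (nrow(gaps) == 0) stop("summarize_stakitt: mismatched leaf pairing")
  gaps$gap_deviation <- gaps$deviation_a + gaps$deviation_b
  gaps <- gaps[order(gaps$leaf, gaps$stakitt),
               c("leaf", "stakitt", "gap_deviation")]
  rownames(gaps) <- NULL

  bank_stats <- do.call(rbind, lapply(c("A", "B"), function(bk) {
    d <- ok$deviation[ok$bank == bk]
    data.frame(bank = bk, mean = mean(d), sd = stats::sd(d), n = length(d))
  }))
  oot <- ok[abs(ok$deviation) > action_limit, ]
  rownames(oot) <- NULL
  structure(
    list(measurements = meas, gaps = gaps, bank_stats = bank_stats,
         gap_mean = mean(gaps$gap_deviation),
         gap_sd = stats::sd(gaps$gap_deviation),
         out_of_tolerance = oot, action_limit = action_limit,
         gantry_angle = gantry_angle),
    class = "stakitt_result"
  )
}

#' @export
print.stakitt_result <- function(x, ...) {
  cat(sprintf("<stakitt_result> G%.0f, action limit %.2f mm\n",
              x$gantry_angle, x$action_limit))
  for (i in seq_len(nrow(x$bank_stats)))
    cat(sprintf("  Bank %s: %+.3f +/- %.3f mm (n = %d)\n",
                x$bank_stats$bank[i], x$bank_stats$mean[i],
                x$bank_stats$sd[i], x$bank_stats$n[i]))
  cat(sprintf("  Gap:    %+.3f +/- %.3f mm (n = %d)\n",
              x$gap_mean, x$gap_sd, nrow(x$gaps)))
  cat(sprintf("  Out of tolerance: %d measurement(s)\n",
              nrow(x$out_of_tolerance)))
  invisible(x)
}

#' Deviation histograms (bank A, bank B, gap)
#'
#' Three-panel histogram of the per-leaf deviations and the gap
#' deviations, binned at 0.05 mm over +/- 1 mm, with the action limit
#' drawn as dashed lines.
#'
#' @param result a [stakitt_result][summarize_stakitt].
#' @return a ggplot object.
#' @export
plot_stakitt <- function(result) {
  ok <- result$measurements[result$measurements$flag == "ok", ]
  df <- rbind(
    data.frame(panel = "Bank A", deviation = ok$deviation[ok$bank == "A"]),
    data.frame(panel = "Bank B", deviation = ok$deviation[ok$bank == "B"]),
    data.frame(panel = "Gap", deviation = result$gaps$gap_deviation)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = deviation)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "steelblue", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * result$action_limit,
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~panel, ncol = 3) +
    ggplot2::coord_cartesian(xlim = c(-1, 1)) +
    ggplot2::labs(x = "Deviation from nominal (mm)", y = "Count",
                  title = sprintf("Stakitt deviations, gantry %.0f",
                                  result$gantry_angle)) +
    ggplot2::theme_bw()
}
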