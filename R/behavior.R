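# Behavioral analysis of hand-pointing localization responses: handedness
# mirroring, pointing-bias estimation from the visual-localization
# conditions, bias correction (laser-pointer condition exempt), the 45
# degree outlier rule, and signed/absolute angular-error summaries.

#' The eight experimental conditions
#'
#' Machine-readable condition table: four blocks varying the available
#' visual information (blind-folded; virtual room without loudspeakers;
#' real/virtual room with loudspeakers; virtual room with laser pointer),
#' the task stimulus (visual or acoustic localization) and whether the HMD
#' was worn. Condition identifiers are \code{block-visual-stimulus-hmd}
#' slugs.
#'
#' @return data.frame with columns \code{condition}, \code{block},
#'   \code{visual_information}, \code{stimulus}, \code{hmd},
#'   \code{visual_localization} (the two visual-search conditions used for
#'   bias estimation) and \code{laser} (the bias-exempt condition).
#' @export
condition_table <- function() {
  d <- data.frame(
    block = c("I", "I", "II", "III", "III", "III", "III", "IV"),
    visual_information = c("blindfolded", "blindfolded", "ve_room",
                           "ve_ls", "re", "re", "ve_ls", "ve_ls_laser"),
    stimulus = c("acoustic", "acoustic", "acoustic", "visual", "visual",
                 "acoustic", "acoustic", "acoustic"),
    hmd = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  )
  d$condition <- sprintf("%s-%s-%s-%s", d$block, d$visual_information,
                         d$stimulus, ifelse(d$hmd, "hmd", "nohmd"))
  d$visual_localization <- d$stimulus == "visual"
  d$laser <- d$visual_information == "ve_ls_laser"
  d[, c("condition", "block", "visual_information", "stimulus", "hmd",
        "visual_localization", "laser")]
}

check_records <- function(records) {
  need <- c("subject", "condition", "target_azimuth_deg", "target_elevation_deg",
            "response_azimuth_deg", "response_elevation_deg", "repetition",
            "handedness")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("response records lack columns: ", paste(miss, collapse = ", "))
  invisible(records)
}

#' Mirror left-handed subjects on the median plane
#'
#' Target and response azimuths of left-handed subjects are negated so that
#' pointing-hand effects line up across the cohort; elevations and
#' right-handed records are unchanged. The operation is an involution.
#'
#' @param records Response data.frame (see [read_responses()] for the schema).
#' @return Records with mirrored azimuths and \code{handedness} set to
#'   \code{"right"} for mirrored rows (so applying the analysis twice cannot
#'   double-mirror); the original handedness is kept in
#'   \code{handedness_original}.
#' @export
mirror_handedness <- function(records) {
  check_records(records)
  if (is.null(records$handedness_original)) {
    records$handedness_original <- records$handedness
  }
  left <- records$handedness == "left"
  records$target_azimuth_deg[left] <- -records$target_azimuth_deg[left]
  records$response_azimuth_deg[left] <- -records$response_azimuth_deg[left]
  records$handedness[left] <- "right"
  records
}

#' Estimate per-subject pointing bias
#'
#' The pointing bias (from the shape of the hand-held controller and each
#' subject's internal reference of where the pointing ray emerges) is the
#' mean signed azimuth and elevation error over all targets and repetitions
#' in the two visual-localization conditions. The group bias is the mean of
#' the per-subject biases.
#'
#' @param records Response data.frame.
#' @param conditions Condition table (defaults to [condition_table()]);
#'   rows with \code{visual_localization == TRUE} define the estimation set.
#' @return Object of class \code{bias_estimate}: list with
#'   \code{azimuth_bias}, \code{elevation_bias} (group, degrees) and
#'   \code{per_subject} (data.frame subject/azimuth_bias/elevation_bias/n).
#'   Subjects without visual-localization trials are excluded with a warning.
#' @export
estimate_pointing_bias <- function(records, conditions = condition_table()) {
  check_records(records)
  if (nrow(records) == 0) stop("no response records")
  vis <- conditions$condition[conditions$visual_localization]
  r <- records[records$condition %in% vis, ]
  missing <- setdiff(unique(records$subject), unique(r$subject))
  if (length(missing)) {
    warning("no visual-localization trials for subject(s): ",
            paste(missing, collapse = ", "), "; excluded from bias estimation")
  }
  if (nrow(r) == 0) stop("no visual-localization trials to estimate bias from")
  err <- signed_errors(r$target_azimuth_deg, r$target_elevation_deg,
                       r$response_azimuth_deg, r$response_elevation_deg)
  per <- do.call(rbind, lapply(split(err, r$subject), function(e) {
    data.frame(azimuth_bias = mean(e$azimuth_error),
               elevation_bias = mean(e$elevation_error),
               n = nrow(e))
  }))
  per <- data.frame(subject = rownames(per), per, row.names = NULL)
  structure(list(azimuth_bias = mean(per$azimuth_bias),
                 elevation_bias = mean(per$elevation_bias),
                 per_subject = per),
            class = "bias_estimate")
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat(sprintf("Pointing bias (group, n = %d subjects): azimuth %+.2f deg, elevation %+.2f deg\n",
              nrow(x$per_subject), x$azimuth_bias, x$elevation_bias))
  invisible(x)
}

#' Subtract the pointing bias from responses
#'
#' Per-subject biases are subtracted from the responses in every condition
#' except the laser-pointer condition, where on-screen feedback of the
#' pointing direction makes the controller-shape bias irrelevant.
#'
#' @param records Response data.frame.
#' @param bias A \code{bias_estimate} covering every subject present.
#' @param conditions Condition table; rows with \code{laser == TRUE} are
#'   exempt from correction.
#' @return Corrected records (azimuth re-wrapped to (-180, 180]).
#' @export
apply_bias_correction <- function(records, bias, conditions = condition_table()) {
  check_records(records)
  missing <- setdiff(unique(records$subject), bias$per_subject$subject)
  if (length(missing)) {
    stop("no bias estimate for subject(s): ", paste(missing, collapse = ", "))
  }
  exempt <- conditions$condition[conditions$laser]
  idx <- match(records$subject, bias$per_subject$subject)
  fix <- !(records$condition %in% exempt)
  records$response_azimuth_deg[fix] <- wrap_angle(
    records$response_azimuth_deg[fix] - bias$per_subject$azimuth_bias[idx[fix]])
  records$response_elevation_deg[fix] <-
    records$response_elevation_deg[fix] - bias$per_subject$elevation_bias[idx[fix]]
  records
}

#' Remove outlier responses
#'
#' A response farther than \code{threshold} degrees from the target in
#' either azimuth (wrapped) or elevation is treated as an outlier.
#' "Farther than" is strict: an error of exactly 45 degrees is kept.
#'
#' @param records Response data.frame.
#' @param threshold Outlier threshold in degrees (default 45).
#' @return List with \code{kept}, \code{removed} (data.frames) and
#'   \code{removed_fraction}.
#' @export
filter_outliers <- function(records, threshold = 45) {
  check_records(records)
  stopifnot(threshold > 0)
  err <- signed_errors(records$target_azimuth_deg, records$target_elevation_deg,
                       records$response_azimuth_deg, records$response_elevation_deg)
  out <- abs(err$azimuth_error) > threshold | abs(err$elevation_error) > threshold
  list(kept = records[!out, , drop = FALSE],
       removed = records[out, , drop = FALSE],
       removed_fraction = if (nrow(records)) mean(out) else 0)
}

#' Summarize localization errors
#'
#' Per group (default: condition x target direction) and per error
#' dimension (azimuth, elevation): mean absolute error, median and
#' quartiles of the signed error, 1.5 IQR whisker bounds for boxplot
#' parity, and the trial count. Quartiles use R's default inclusive
#' linear-interpolation convention (\code{quantile} type 7) so boxplot
#' statistics are reproducible bit for bit.
#'
#' @param records Response data.frame (nonempty).
#' @param keys Character vector of grouping columns.
#' @return data.frame of class \code{error_table} in long format with
#'   columns: the keys, \code{dimension}, \code{mean_absolute},
#'   \code{median_signed}, \code{q1}, \code{q3}, \code{whisker_lo},
#'   \code{whisker_hi}, \code{n}.
#' @export
summarize_errors <- function(records,
                             keys = c("condition", "target_azimuth_deg",
                                      "target_elevation_deg")) {
  check_records(records)
  if (nrow(records) == 0) stop("no records to summarize")
  err <- signed_errors(records$target_azimuth_deg, records$target_elevation_deg,
                       records$response_azimuth_deg, records$response_elevation_deg)
  long <- rbind(
    data.frame(records[keys], dimension = "azimuth", error = err$azimuth_error),
    data.frame(records[keys], dimension = "elevation", error = err$elevation_error)
  )
  grp <- interaction(c(long[keys], list(long$dimension)), drop = TRUE, lex.order = TRUE)
  cells <- lapply(split(long, grp), function(g) {
    q <- unname(stats::quantile(g$error, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    data.frame(g[1, c(keys, "dimension"), drop = FALSE],
               mean_absolute = mean(abs(g$error)),
               median_signed = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[3] + 1.5 * iqr,
               n = nrow(g))
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  class(out) <- c("error_table", "data.frame")
  out
}

#' Left-minus-right hemifield contrasts
#'
#' For each |azimuth| > 0 present in the table, the difference between the
#' left (-azimuth) and right (+azimuth) cell statistics, per dimension and
#' per remaining grouping key. Cells without a mirror counterpart are
#' skipped with a warning; azimuth 0 is excluded.
#'
#' @param table An \code{error_table} grouped by (at least)
#'   \code{target_azimuth_deg}.
#' @return data.frame with the non-azimuth keys, \code{abs_azimuth_deg},
#'   \code{dimension}, and left-minus-right differences
#'   \code{d_mean_absolute}, \code{d_median_signed}.
#' @export
hemifield_contrast <- function(table) {
  stopifnot("target_azimuth_deg" %in% names(table))
  stats_cols <- c("mean_absolute", "median_signed")
  other <- setdiff(names(table), c(stats_cols, "q1", "q3", "whisker_lo",
                                   "whisker_hi", "n", "target_azimuth_deg"))
  tab <- table[table$target_azimuth_deg != 0, , drop = FALSE]
  tab$abs_azimuth_deg <- abs(tab$target_azimuth_deg)
  key <- interaction(c(tab[other], list(tab$abs_azimuth_deg)), drop = TRUE)
  rows <- lapply(split(tab, key), function(g) {
    l <- g[g$target_azimuth_deg < 0, , drop = FALSE]
    r <- g[g$target_azimuth_deg > 0, , drop = FALSE]
    if (nrow(l) != 1 || nrow(r) != 1) {
      warning("missing mirror cell at |azimuth| = ", g$abs_azimuth_deg[1],
              " (", paste(unlist(g[1, other]), collapse = "/"), "); skipped")
      return(NULL)
    }
    data.frame(l[1, other, drop = FALSE],
               abs_azimuth_deg = l$abs_azimuth_deg,
               d_mean_absolute = l$mean_absolute - r$mean_absolute,
               d_median_signed = l$median_signed - r$median_signed)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(data.frame())
  rownames(out) <- NULL
  out
}

#' Run the full behavioral pipeline
#'
#' Handedness mirroring, pointing-bias estimation on the
#' visual-localization conditions, bias correction (laser condition
#' exempt), outlier screening, and error summaries. Outlier filtering runs
#' after bias correction, i.e. on the errors the analysis actually uses.
#'
#' @param records Response data.frame.
#' @param outlier_threshold Degrees (default 45).
#' @param keys Grouping keys for the error table.
#' @param conditions Condition table.
#' @return Object of class \code{localization_analysis}: list with
#'   \code{bias}, \code{records} (corrected, kept), \code{removed},
#'   \code{removed_fraction}, \code{errors} (error table) and
#'   \code{by_condition} (error table keyed by condition only).
#' @export
analyze_responses <- function(records, outlier_threshold = 45,
                              keys = c("condition", "target_azimuth_deg",
                                       "target_elevation_deg"),
                              conditions = condition_table()) {
  records <- mirror_handedness(records)
  bias <- estimate_pointing_bias(records, conditions)
  corrected <- apply_bias_correction(records, bias, conditions)
  flt <- filter_outliers(corrected, outlier_threshold)
  structure(list(
    bias = bias,
    records = flt$kept,
    removed = flt$removed,
    removed_fraction = flt$removed_fraction,
    errors = summarize_errors(flt$kept, keys),
    by_condition = summarize_errors(flt$kept, "condition")
  ), class = "localization_analysis")
}

#' @export
print.localization_analysis <- function(x, ...) {
  cat("Localization analysis\n")
  print(x$bias)
  cat(sprintf("  %d records kept, %d outliers removed (%.2f%%)\n",
              nrow(x$records), nrow(x$removed), 100 * x$removed_fraction))
  el <- x$by_condition[x$by_condition$dimension == "elevation", ]
  el <- el[order(el$mean_absolute, decreasing = TRUE), ]
  cat("  Mean absolute elevation error by condition [deg]:\n")
  for (i in seq_len(nrow(el))) {
    cat(sprintf("    %-32s %6.2f (n = %d)\n", el$condition[i],
                el$mean_absolute[i], el$n[i]))
  }
  invisible(x)
}
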