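# Assembles the reliability report of a two-reader, two-modality torsion
# study: inter-modality ICC per reader, inter-reader ICC per modality, SEMs,
# the pooled paired modality comparison, and the observed range.

#' Build a reliability report from a measurement table
#'
#' Computes, for a table with two readers and two modalities (CT/MRI):
#' inter-modality ICC(A,1) per reader (two-way mixed tag), inter-reader
#' ICC(A,1) per modality (two-way random tag), the SEM of each comparison,
#' the pooled MRI - CT paired t-test over both readers with limits of
#' agreement, per-reader signed and absolute mean modality differences, and
#' the observed angle range.
#'
#' @param table A measurement table (see [as_measurement_table()]).
#' @param listwise `"per_comparison"`: each comparison drops only hips missing
#'   one of its own two cells. `"across_all"`: hips missing any of the four
#'   cells are dropped from every comparison (one complete-case cohort, as a
#'   single SPSS-style analysis dataset).
#' @param conf_level Confidence level for ICC intervals.
#' @return An object of class `fem_reliability`; see [tidy.fem_reliability()].
#' @export
#' @examples
#' tab <- simulate_measurement_table(n_subjects = 20, seed = 3)
#' rep <- build_report(tab)
#' tidy(rep)
build_report <- function(table, listwise = c("per_comparison", "across_all"),
                         conf_level = 0.95) {
  listwise <- match.arg(listwise)
  tb <- as_measurement_table(table)
  readers <- sort(unique(tb$reader))
  modalities <- sort(unique(tb$modality))
  if (length(readers) != 2L || length(modalities) != 2L) {
    abort("report needs exactly 2 readers and 2 modalities in the table",
          class = "femtor_error_configuration")
  }
  wide <- tidyr::pivot_wider(tb, id_cols = c("subject", "side"),
                             names_from = c("reader", "modality"),
                             values_from = "angle_deg",
                             names_glue = "r{reader}_{modality}")
  cols <- as.vector(outer(readers, modalities,
                          function(r, m) paste0("r", r, "_", m)))
  for (cl in cols) {
    if (!cl %in% names(wide)) wide[[cl]] <- NA_real_
  }
  if (listwise == "across_all") {
    wide <- wide[complete.cases(wide[cols]), , drop = FALSE]
  }
  comparisons <- list(
    list(comparison = "inter_modality", stratum = paste0("reader ", readers[1]),
         cols = paste0("r", readers[1], "_", modalities), model = "mixed"),
    list(comparison = "inter_modality", stratum = paste0("reader ", readers[2]),
         cols = paste0("r", readers[2], "_", modalities), model = "mixed"),
    list(comparison = "inter_reader", stratum = modalities[1],
         cols = paste0("r", readers, "_", modalities[1]), model = "random"),
    list(comparison = "inter_reader", stratum = modalities[2],
         cols = paste0("r", readers, "_", modalities[2]), model = "random"))
  icc_objects <- list()
  rows <- lapply(comparisons, function(cp) {
    M <- as.matrix(wide[cp$cols])
    M <- M[complete.cases(M), , drop = FALSE]
    icc <- icc_agreement_single(M, model = cp$model, conf_level = conf_level)
    icc_objects[[paste(cp$comparison, cp$stratum)]] <<- icc
    tibble::tibble(comparison = cp$comparison, stratum = cp$stratum,
                   model = cp$model, estimate = icc$estimate,
                   conf_low = icc$conf_low, conf_high = icc$conf_high,
                   n = icc$n, k = icc$k,
                   sem = sem_from_icc(as.vector(M), icc))
  })
  icc_tbl <- dplyr::bind_rows(rows)
  # pooled MRI - CT paired comparison over both readers (CT first so the
  # difference is second-modality minus first, i.e. MRI - CT)
  ct <- modalities[modalities %in% "CT"]
  mri <- modalities[modalities %in% "MRI"]
  if (length(ct) == 1L && length(mri) == 1L) {
    x <- c(wide[[paste0("r", readers[1], "_", ct)]],
           wide[[paste0("r", readers[2], "_", ct)]])
    y <- c(wide[[paste0("r", readers[1], "_", mri)]],
           wide[[paste0("r", readers[2], "_", mri)]])
  } else {
    x <- c(wide[[paste0("r", readers[1], "_", modalities[1])]],
           wide[[paste0("r", readers[2], "_", modalities[1])]])
    y <- c(wide[[paste0("r", readers[1], "_", modalities[2])]],
           wide[[paste0("r", readers[2], "_", modalities[2])]])
  }
  diff_tbl <- paired_difference(x, y)
  diff_tbl$loa_low <- diff_tbl$mean_diff - 1.96 * diff_tbl$sd_diff
  diff_tbl$loa_high <- diff_tbl$mean_diff + 1.96 * diff_tbl$sd_diff
  per_reader <- dplyr::bind_rows(lapply(readers, function(r) {
    xr <- wide[[paste0("r", r, "_", if (length(ct) == 1L) ct else modalities[1])]]
    yr <- wide[[paste0("r", r, "_", if (length(mri) == 1L) mri else modalities[2])]]
    keep <- !is.na(xr) & !is.na(yr)
    tibble::tibble(reader = r,
                   mean_signed_diff = mean(yr[keep] - xr[keep]),
                   mean_abs_diff = mean(abs(yr[keep] - xr[keep])),
                   n = sum(keep))
  }))
  all_angles <- tb$angle_deg[!is.na(tb$angle_deg)]
  structure(list(icc = icc_tbl, difference = diff_tbl,
                 per_reader = per_reader,
                 range = c(min = min(all_angles), max = max(all_angles)),
                 n_hips = nrow(wide), listwise = listwise,
                 icc_objects = icc_objects),
            class = "fem_reliability")
}

#' @export
print.fem_reliability <- function(x, ...) {
  cat(sprintf("<reliability report> %d hips (%s deletion)\n",
              x$n_hips, gsub("_", "-", x$listwise)))
  for (i in seq_len(nrow(x$icc))) {
    r <- x$icc[i, ]
    cat(sprintf("  %-14s %-9s ICC(A,1) %.3f (%.3f; %.3f)  SEM %.2f deg  n = %d\n",
                r$comparison, r$stratum, r$estimate, r$conf_low, r$conf_high,
                r$sem, r$n))
  }
  d <- x$difference
  cat(sprintf("  MRI - CT pooled: mean %.2f deg (SD %.2f), t(%d) = %.2f, p = %.3f, n = %d pairs\n",
              d$mean_diff, d$sd_diff, d$df, d$t, d$p_value, d$n_pairs))
  cat(sprintf("  observed range: %.1f to %.1f deg\n", x$range["min"], x$range["max"]))
  invisible(x)
}

#' Tidy/glance a reliability report
#'
#' @param x A `fem_reliability` object.
#' @param ... Unused.
#' @return `tidy()`: the ICC table (one row per comparison, with SEM and n).
#'   `glance()`: a one-row tibble with the pooled difference summary, range
#'   and hip count.
#' @export
tidy.fem_reliability <- function(x, ...) x$icc

#' @rdname tidy.fem_reliability
#' @export
glance.fem_reliability <- function(x, ...) {
  d <- x$difference
  tibble::tibble(mean_diff = d$mean_diff, sd_diff = d$sd_diff, t = d$t,
                 df = d$df, p_value = d$p_value, n_pairs = d$n_pairs,
                 loa_low = d$loa_low, loa_high = d$loa_high,
                 min_angle = unname(x$range["min"]),
                 max_angle = unname(x$range["max"]),
                 n_hips = x$n_hips)
}

#' Write a reliability report
#'
#' `write_report_json()` serializes all report tables; `format()` renders a
#' human-readable text table.
#'
#' @param x A `fem_reliability` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  stopifnot(inherits(x, "fem_reliability"))
  out <- list(icc = x$icc, difference = x$difference,
              per_reader = x$per_reader,
              range = as.list(x$range), n_hips = x$n_hips,
              listwise = x$listwise)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @export
format.fem_reliability <- function(x, ...) {
  paste(utils::capture.output(print(x)), collapse = "\n")
}
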